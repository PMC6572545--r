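## File formats: xvg-dialect two-column time series with '#'/'@' comment
## headers, a TSV sidecar for window metadata, and TSV profiles with a
## commented YAML header block.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a window trajectory as xvg-style text
#'
#' Two whitespace-separated columns (time ps, z nm), '@' plot headers and
#' '#' key=value metadata lines; numbers are written with 17 significant
#' digits so the round trip is bit-exact.
#'
#' @param trajectory A `window_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "window_trajectory"))
  tr <- trajectory
  hdr <- c(
    "@    title \"reaction coordinate\"",
    "@    xaxis  label \"Time (ps)\"",
    "@    yaxis  label \"z (nm)\"",
    sprintf("# center = %s", fmt17(tr$bias$center)),
    sprintf("# force_constant = %s", fmt17(tr$bias$force_constant)),
    sprintf("# dt = %s", fmt17(tr$dt)),
    sprintf("# seed = %.0f", tr$seed),
    sprintf("# temperature = %s", fmt17(tr$temperature)),
    sprintf("# model_id = %s", tr$model_id))
  t_ <- (seq_along(tr$samples) - 1) * tr$dt
  writeLines(c(hdr, paste(fmt17(t_), fmt17(tr$samples))), path)
  invisible(path)
}

parse_header_meta <- function(lines) {
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  meta
}

#' Read an xvg-style window time series
#'
#' Lines starting with '#' or '@' are ignored as data; metadata (bias
#' centre, force constant, seed, temperature) is taken from the sidecar
#' table if given, otherwise from '#' key=value header lines. The time
#' column must be uniformly spaced (relative tolerance 1e-9).
#'
#' @param path File to read.
#' @param sidecar Optional data.frame from [read_sidecar()]; the row is
#'   matched by `basename(path)` and missing entries are an error.
#' @return A `window_trajectory`.
#' @export
read_timeseries <- function(path, sidecar = NULL) {
  lines <- readLines(path)
  data <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (length(data) == 0) stop("no data rows in ", path)
  fields <- strsplit(trimws(data), "\\s+")
  if (any(lengths(fields) != 2))
    stop("expected two whitespace-separated columns in ", path)
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) stop("non-numeric rows in ", path)
  m <- matrix(vals, ncol = 2, byrow = TRUE)
  t_ <- m[, 1]; z <- m[, 2]
  if (length(t_) < 2) stop("need at least 2 samples")
  dts <- diff(t_)
  dt <- dts[1]
  if (dt <= 0 || any(abs(dts - dt) > 1e-9 * abs(dt)))
    stop("non-uniform sampling in time column of ", path)
  if (!is.null(sidecar)) {
    row <- sidecar[sidecar$filename == basename(path), , drop = FALSE]
    if (nrow(row) != 1)
      stop("no sidecar entry for ", basename(path))
    meta <- as.list(row)
  } else {
    meta <- parse_header_meta(lines)
    if (is.null(meta$center) || is.null(meta$force_constant))
      stop("no sidecar given and no bias metadata in header of ", path)
  }
  num <- function(x, default = NA_real_)
    if (is.null(x)) default else as.numeric(x)
  new_window_trajectory(
    z, dt,
    bias_spec(num(meta$center), num(meta$force_constant, 0)),
    seed = num(meta$seed), model_id = as.character(meta$model_id %||% NA),
    temperature = num(meta$temperature, 300))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read the window metadata sidecar
#'
#' TSV with columns filename, center, force_constant, seed, dt,
#' temperature, model_id.
#'
#' @param meta data.frame of window metadata.
#' @param path TSV file.
#' @return `path` / the data.frame.
#' @export
write_sidecar <- function(meta, path) {
  stopifnot(is.data.frame(meta), "filename" %in% names(meta))
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

profile_header <- function(meta) {
  y <- strsplit(yaml::as.yaml(meta), "\n")[[1]]
  paste0("# ", y)
}

read_profile_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  if (length(hdr) == 0) return(list())
  yaml::yaml.load(paste(sub("^# ", "", hdr), collapse = "\n"))
}

#' Write / read a free-energy profile as TSV
#'
#' Columns z, w, stderr with a commented YAML header recording the
#' temperature and reference convention.
#'
#' @param profile A `free_energy_profile`.
#' @param path TSV file.
#' @param extra Optional named list merged into the header.
#' @return `path` / the profile.
#' @export
write_profile <- function(profile, path, extra = list()) {
  stopifnot(inherits(profile, "free_energy_profile"))
  meta <- c(list(type = "free_energy_profile",
                 temperature = profile$temperature,
                 reference = profile$reference,
                 units = list(z = "nm", w = "kJ/mol")), extra)
  d <- as.data.frame(profile)
  if (is.null(d$stderr)) d$stderr <- NA_real_
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(profile_header(meta), con)
  writeLines(paste("z", "w", "stderr", sep = "\t"), con)
  writeLines(paste(fmt17(d$z), fmt17(d$w), fmt17(d$stderr), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  meta <- read_profile_header(path)
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  new_fe_profile(d$z, d$w,
                 stderr = if (!all(is.na(d$stderr))) d$stderr,
                 reference = meta$reference %||% "raw",
                 temperature = meta$temperature %||% 300)
}

#' Write / read a diffusion profile as TSV
#'
#' Columns z, D_nm2_ps, D_m2_s, stderr with a commented YAML header.
#'
#' @param dprof A `diffusion_profile`.
#' @param path TSV file.
#' @param extra Optional named list merged into the header.
#' @return `path` / the profile.
#' @export
write_diffusion_profile <- function(dprof, path, extra = list()) {
  stopifnot(inherits(dprof, "diffusion_profile"))
  meta <- c(list(type = "diffusion_profile", method = dprof$method,
                 units = list(z = "nm", D = "nm^2/ps and m^2/s")), extra)
  d <- as.data.frame(dprof)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(profile_header(meta), con)
  writeLines(paste(names(d), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(d, fmt17), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_diffusion_profile
#' @export
read_diffusion_profile <- function(path) {
  meta <- read_profile_header(path)
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(list(z = d$z, D = d$D_nm2_ps, D_m2s = d$D_m2_s,
                 stderr = d$stderr, n = d$n,
                 method = meta$method %||% "acf"),
            class = "diffusion_profile")
}

#' Literature-reported permeability coefficients
#'
#' Reported permeability coefficients (m/s) of CH4, CO2 and H2S across
#' choline-benzoate and choline-lactate liquid slabs, for the full slab
#' and for the interfacial range |z| = 1.5-3 nm, shipped as package data.
#' These are external reference values used to exercise the
#' permselectivity arithmetic.
#'
#' @return data.frame with columns system, range, solute, Pm.
#' @export
reported_permeabilities <- function() {
  path <- system.file("extdata", "reported_permeabilities.tsv",
                      package = "slabperm")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
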