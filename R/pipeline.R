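#' Example slab models
#'
#' Two synthetic solutes on the same slab geometry (interfaces at
#' |z| = 2 nm, box half-length 7 nm, 300 K), with ground-truth parameters
#' chosen at the scale of the reference systems: a methane-like solute
#' with an unfavourable interior plateau of 11.79 kJ/mol and shallow
#' interfacial wells, and a strongly absorbed acid-gas-like solute with a
#' favourable interior. Bulk diffusion coefficients are of order 1e-9
#' m^2/s (1e-3 nm^2/ps) and rise by a factor 2.5 towards the low-density
#' interface.
#'
#' @return Named list of `slab_model` ("methane_like", "acid_gas_like").
#' @export
example_slab_models <- function() {
  geom <- list(z_int = 2, interface_width = 0.25, slab_half_width = 2)
  dens <- list(rho_bulk = 1100, interface_width = 0.3)
  list(
    methane_like = build_slab_model(
      pmf_params = c(list(well_depth = -2, plateau = 11.79), geom),
      diff_params = list(d_vapor = 5e-3, d_bulk = 2e-3,
                         transition_width = 0.25),
      density_params = dens, temperature = 300, box_half_length = 7,
      label = "methane_like"),
    acid_gas_like = build_slab_model(
      pmf_params = c(list(well_depth = -4, plateau = -7.84), geom),
      diff_params = list(d_vapor = 2.5e-3, d_bulk = 1e-3,
                         transition_width = 0.25),
      density_params = dens, temperature = 300, box_half_length = 7,
      label = "acid_gas_like"))
}

#' Assemble and validate a pipeline configuration
#'
#' A single document describing the whole run: one slab model per solute,
#' the umbrella-sampling protocol, analysis settings and integration
#' ranges. Round-trips losslessly through YAML ([read_config()] /
#' [write_config()]).
#'
#' @param solutes Named list; each element a list with `pmf_params`,
#'   `diff_params`, `density_params` (see [build_slab_model()]).
#' @param protocol List of campaign settings (see
#'   [generate_us_campaign()]): `window_spacing`, `n_windows`,
#'   `n_offsets`, `force_constant`, `n_steps`, `dt`, `thin`,
#'   `n_replicates`.
#' @param analysis List: `bin_width`, `discard_fraction`, `tol`,
#'   `max_iter`, `truncation` ("first-zero" or "exp-tail"), `n_boot`.
#' @param ranges List with `full = c(z1, z2)` and
#'   `interface = c(z1, z2)`.
#' @param temperature K.
#' @param seed Master seed.
#' @param box_half_length nm.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(solutes, protocol = list(), analysis = list(),
                            ranges = list(full = c(-3, 3),
                                          interface = c(1.5, 3)),
                            temperature = 300, seed = 1,
                            box_half_length = 7) {
  proto <- utils::modifyList(
    list(window_spacing = 1.0, n_windows = 6, n_offsets = 10,
         force_constant = 2000, n_steps = 400000, dt = 0.01, thin = 10,
         n_replicates = 25, z_min = 0), protocol)
  ana <- utils::modifyList(
    list(bin_width = 0.01, discard_fraction = 0.1, tol = 1e-7,
         max_iter = 1e5, truncation = "first-zero", n_boot = 0), analysis)
  cfg <- structure(list(solutes = solutes, protocol = proto, analysis = ana,
                        ranges = ranges, temperature = temperature,
                        seed = seed, box_half_length = box_half_length),
                   class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` (or plain list with the same shape).
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config$solutes), length(config$solutes) >= 1)
  if (is.null(names(config$solutes)) || any(names(config$solutes) == ""))
    stop("solutes must be named")
  p <- config$protocol
  if (p$n_steps < 1 || p$dt <= 0 || p$n_replicates < 1 || p$n_windows < 1)
    stop("invalid protocol")
  if (p$force_constant < 0) stop("negative force constant")
  a <- config$analysis
  if (a$bin_width <= 0 || a$discard_fraction < 0 || a$discard_fraction >= 1)
    stop("invalid analysis settings")
  if (!a$truncation %in% c("first-zero", "exp-tail"))
    stop("truncation must be 'first-zero' or 'exp-tail'")
  for (rn in names(config$ranges)) {
    r <- config$ranges[[rn]]
    if (length(r) != 2 || r[1] >= r[2]) stop("invalid range ", rn)
  }
  if (config$temperature <= 0) stop("temperature must be positive")
  ## every solute must build into a valid model
  for (s in names(config$solutes)) build_config_model(config, s)
  invisible(TRUE)
}

build_config_model <- function(config, solute) {
  sp <- config$solutes[[solute]]
  build_slab_model(pmf_params = sp$pmf_params, diff_params = sp$diff_params,
                   density_params = sp$density_params,
                   temperature = config$temperature,
                   box_half_length = config$box_half_length, label = solute)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return A `pipeline_config` / `path`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(solutes = raw$solutes,
                  protocol = raw$protocol %||% list(),
                  analysis = raw$analysis %||% list(),
                  ranges = lapply(raw$ranges, unlist),
                  temperature = raw$temperature %||% 300,
                  seed = raw$seed %||% 1,
                  box_half_length = raw$box_half_length %||% 7)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) fnv1a32(yaml::as.yaml(unclass(config)))

#' Run the full permeability pipeline
#'
#' For each solute: simulate the umbrella campaign, build per-replicate
#' WHAM profiles, reference them to the vapor plateau, average them,
#' mirror to the full slab, estimate the diffusion profile, and evaluate
#' the permeability over every configured range; finally form the
#' selectivity table per range. Fully deterministic given the config
#' (master seed included).
#'
#' @param config A `pipeline_config`.
#' @param outdir Optional directory: profiles (TSV) and the report (JSON)
#'   are written there.
#' @param verbose Print one line per stage.
#' @return Report list: per-solute profiles and `permeability_result`s,
#'   selectivity tables, seeds and the config hash.
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = interactive()) {
  validate_config(config)
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  a <- config$analysis
  results <- list()
  for (solute in names(config$solutes)) {
    stage <- function(name, expr) {
      t0 <- proc.time()[["elapsed"]]
      out <- tryCatch(force(expr), error = function(e)
        stop(sprintf("stage '%s' failed for solute '%s': %s",
                     name, solute, conditionMessage(e)), call. = FALSE))
      say("[%s] %s: %.1f s", solute, name,
          proc.time()[["elapsed"]] - t0)
      out
    }
    model <- build_config_model(config, solute)
    seed_s <- derive_seed(config$seed, match(solute, names(config$solutes)),
                          0L)
    p <- config$protocol
    camp <- stage("simulate", generate_us_campaign(
      model, window_spacing = p$window_spacing, n_windows = p$n_windows,
      n_offsets = p$n_offsets, force_constant = p$force_constant,
      n_steps = p$n_steps, dt = p$dt, thin = p$thin,
      n_replicates = p$n_replicates, seed = seed_s, z_min = p$z_min))
    centers <- sort(unique(camp$meta$center))
    half_bin <- a$bin_width / 2
    edges <- seq(min(centers) - 0.15 - half_bin,
                 max(centers) + 0.15 + half_bin, by = a$bin_width)
    fep <- stage("wham", {
      reps <- campaign_replicates(camp)
      profs <- lapply(reps, function(trs) {
        pr <- wham(histogram_windows(trs, edges, a$discard_fraction),
                   tol = a$tol, max_iter = a$max_iter)
        set_reference(pr, vapor_region(pr))
      })
      avg <- average_profiles(common_grid(profs))
      mirror_profile(avg)
    })
    boot <- if (a$n_boot >= 2) stage("bootstrap", {
      mirror_profile(bootstrap_error(
        campaign_replicates(camp)[[1]], edges, n_boot = a$n_boot,
        seed = derive_seed(seed_s, 999L, 0L),
        discard_fraction = a$discard_fraction, tol = a$tol,
        max_iter = a$max_iter))
    })
    dprof <- stage("diffusion", mirror_profile(diffusion_profile(
      camp, method = a$truncation, discard_fraction = a$discard_fraction)))
    perms <- list()
    for (rn in names(config$ranges)) {
      r <- config$ranges[[rn]]
      mode <- if (rn == "interface") "interface" else "full"
      perms[[rn]] <- stage(paste0("permeability:", rn),
                           permeability(fep, dprof, r[1], r[2],
                                        range_mode = mode,
                                        temperature = config$temperature))
    }
    if (!is.null(outdir)) {
      write_profile(fep, file.path(outdir, paste0("fep_", solute, ".tsv")),
                    extra = list(config_hash = hash, seed = seed_s,
                                 solute = solute))
      write_diffusion_profile(
        dprof, file.path(outdir, paste0("dprof_", solute, ".tsv")),
        extra = list(config_hash = hash, seed = seed_s, solute = solute))
    }
    results[[solute]] <- list(model_id = model$model_id, seed = seed_s,
                              fep = fep, dprof = dprof,
                              bootstrap = boot, permeability = perms)
  }
  sel <- lapply(setNames(names(config$ranges), names(config$ranges)),
                function(rn) {
    selectivity(lapply(results, function(r) r$permeability[[rn]]))
  })
  report <- list(config_hash = hash, seed = config$seed,
                 package_version = as.character(utils::packageVersion("slabperm")),
                 solutes = results, selectivity = sel)
  if (!is.null(outdir)) {
    jsonlite::write_json(report_json(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

## JSON-serializable view of the report (profiles as plain tables)
report_json <- function(report) {
  list(config_hash = report$config_hash, seed = report$seed,
       package_version = report$package_version,
       solutes = lapply(report$solutes, function(r) {
         list(model_id = r$model_id, seed = r$seed,
              fep = as.data.frame(r$fep),
              dprof = as.data.frame(r$dprof),
              permeability = lapply(r$permeability, function(p)
                list(Pm_m_s = p$Pm, resistance_s_m = p$resistance,
                     range_mode = p$range_mode,
                     z_range = p$z_range, temperature = p$temperature)))
       }),
       selectivity = lapply(report$selectivity, function(s)
         data.frame(a = s$a, b = s$b, ratio = s$ratio)))
}
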