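#' Default run configuration
#'
#' A fully populated configuration list describing one reproducible
#' analysis run: the physical-parameter profile, kernel specification,
#' activity source, grid size, requested analyses and seed. The
#' `"default"` profile reproduces the standard human-cochlea constants
#' bit-exactly.
#'
#' @param analyses character vector from `"modes"`, `"phase_diagram"`,
#'   `"respond"`, `"selftune"`.
#' @param N grid size.
#' @param seed integer seed recorded with (and used by) every stochastic
#'   analysis.
#' @return a named list of class `"cochlea_config"`.
#' @export
default_run_config <- function(analyses = "modes", N = 1000L, seed = 1L) {
  structure(list(
    profile = "default",
    params = list(),                      # overrides of cochlea_params()
    N = as.integer(N),
    kernel = list(family = "single_exp", alpha = 2),
    activity = list(type = "fraction", f = 0.99),
    respond = list(freq_hz = 2000, amplitude = 1),
    selftune = list(h0_multiple = 10, noise_sd = 1, n_steps = 600),
    phase_diagram = list(alpha = c(0.5, 1, 2, 4, 8),
                         f = c(0.90, 0.99, 1.00)),
    analyses = analyses,
    seed = as.integer(seed)
  ), class = "cochlea_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected so that typos fail loudly; missing keys take
#' their [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return a `"cochlea_config"`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_run_config()
  bad <- setdiff(names(raw), names(base))
  if (length(bad))
    stop("invalid config: unknown key(s): ", paste(bad, collapse = ", "))
  for (nm in names(raw)) base[[nm]] <- raw[[nm]]
  base$N <- as.integer(base$N)
  base$seed <- as.integer(base$seed)
  base
}

#' Write a run configuration to YAML
#'
#' @param config a `"cochlea_config"`.
#' @param path output file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_params <- function(config) {
  do.call(cochlea_params, c(list(N = config$N), config$params))
}

config_kernel <- function(config) {
  do.call(hair_cell_kernel, config$kernel)
}

config_activity <- function(config, params, kernel) {
  a <- config$activity
  switch(a$type,
    passive = activity_profile(rep(0, params$N), cochlea_grid(params)$x,
                               provenance = "passive"),
    fraction = activity_for_fraction(kernel, params, a$f),
    file = {
      tb <- utils::read.csv(a$path)
      activity_profile(tb$C, tb$x, provenance = paste("file:", a$path))
    },
    stop("invalid config: activity$type must be passive/fraction/file, got ",
         a$type))
}

#' Execute a configured analysis run
#'
#' Runs every analysis listed in the configuration and writes tidy CSV
#' outputs plus a JSON metadata file (configuration echo, seed, config
#' hash, package version, wall time) into `out_dir`. Deterministic
#' analyses are bit-reproducible from the configuration alone; stochastic
#' ones are reproducible given the recorded seed.
#'
#' @param config a `"cochlea_config"` (see [default_run_config()],
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; side effect: files
#'   `modes.csv` (`re`, `im`, `freq_hz`, `class`, `x_pred`),
#'   `phase_diagram.csv`, `response.csv` (`x`, `amplitude_norm`,
#'   `net_friction_res`), `selftune.csv` (trajectory) / `selftune_final.csv`,
#'   and `run_metadata.json`.
#' @export
run_analysis <- function(config, out_dir) {
  stopifnot(inherits(config, "cochlea_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  set.seed(config$seed)
  params <- config_params(config)
  kernel <- config_kernel(config)

  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  for (an in config$analyses) {
    if (an == "modes") {
      C <- config_activity(config, params, kernel)
      md <- eigenmodes(build_jacobian(params, kernel, C),
                       values_only = params$N > 400L)
      utils::write.csv(md$table, file.path(out_dir, "modes.csv"),
                       row.names = FALSE)
    } else if (an == "phase_diagram") {
      pd_cfg <- config$phase_diagram
      fam <- config$kernel$family
      grid <- if (fam == "single_exp") pd_cfg$alpha else
        expand.grid(alpha1 = pd_cfg$alpha, alpha2 = pd_cfg$alpha)
      pd <- phase_diagram(fam, grid, f_list = pd_cfg$f,
                          params = cochlea_params(N = min(params$N, 300L)))
      utils::write.csv(pd, file.path(out_dir, "phase_diagram.csv"),
                       row.names = FALSE)
    } else if (an == "respond") {
      C <- config_activity(config, params, kernel)
      omega <- 2 * pi * config$respond$freq_hz
      dr <- driven_response(params, kernel, C, omega,
                            amplitude = config$respond$amplitude)
      wres <- attr(C, "omega_res")
      if (is.null(wres)) wres <- resonant_frequency_active(kernel, C, params, dr$x)
      utils::write.csv(
        data.frame(x = dr$x, amplitude_norm = dr$amplitude_norm,
                   net_friction_res = net_friction(kernel, C, params, dr$x, wres)),
        file.path(out_dir, "response.csv"), row.names = FALSE)
    } else if (an == "selftune") {
      st_cfg <- config$selftune
      ts <- self_tune(params, kernel, h0_multiple = st_cfg$h0_multiple,
                      noise_sd = st_cfg$noise_sd, n_steps = st_cfg$n_steps)
      utils::write.csv(ts$trajectory, file.path(out_dir, "selftune.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(x = cochlea_grid(params)$x, C = as.numeric(ts$C),
                   rms = ts$rms, h0 = ts$h0),
        file.path(out_dir, "selftune_final.csv"), row.names = FALSE)
    } else stop("invalid config: unknown analysis '", an, "'")
  }

  meta <- list(config = unclass(config), config_hash = cfg_hash,
               seed = config$seed,
               package_version = as.character(utils::packageVersion("activecochlea")),
               r_version = R.version.string,
               wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Deterministic fixtures for experiments and tests
#'
#' Generates the small parameter sets and stimulus definitions used by the
#' perturbation experiments: a plateau-scale grid (`N = 101`), the
#' dead-zone interval (middle 10% of the membrane), and a 1%-standard-
#' deviation multiplicative stiffness perturbation drawn with the given
#' seed.
#'
#' @param seed integer seed for the stochastic fixtures.
#' @param dir optional directory; when given, fixtures are also written as
#'   YAML/CSV files.
#' @return list with `params_plateau` (a [cochlea_params()] with
#'   `N = 101`), `dead_zone` (length-2 interval, m), `stiffness_factor`
#'   (length-`N` multiplicative factors for `N = 101`), `tone_hz`
#'   (standard probe tones), `seed`.
#' @export
make_fixtures <- function(seed = 1L, dir = NULL) {
  set.seed(seed)
  p101 <- cochlea_params(N = 101L)
  fac <- 1 + 0.01 * stats::rnorm(p101$N)
  fx <- list(params_plateau = p101,
             dead_zone = c(0.45, 0.55) * p101$L,
             stiffness_factor = fac,
             tone_hz = c(300, 2000),
             seed = as.integer(seed))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(list(N = 101L, dead_zone = fx$dead_zone,
                          tone_hz = fx$tone_hz, seed = fx$seed),
                     file.path(dir, "fixtures.yaml"))
    utils::write.csv(data.frame(x = cochlea_grid(p101)$x,
                                stiffness_factor = fac),
                     file.path(dir, "stiffness_factor.csv"),
                     row.names = FALSE)
  }
  fx
}
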