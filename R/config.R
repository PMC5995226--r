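#' Default configuration for a simulator module
#'
#' @param module one of `"tumor"`, `"growth"`, `"invasion"`, `"metastasis"`,
#'   `"fractal"`, `"fixture"`.
#' @return Named list of default parameter values (the validation schema:
#'   unknown keys are rejected by [load_config()]).
#' @export
default_config <- function(module) {
  switch(module,
    tumor = list(
      lattice_size = 200, spacing = 20, t_end = 720, dt = 0.1,
      base_birth_rate = 0.025, birth_rate_increment = 0.025,
      oxygen_hill_n = 4, oxygen_ramp = "hill", pO2_P = 10, pO2_N = 5,
      d_N_star = 0.1, d_A_star = 0.002, d_A_max = 0.1,
      eta = 1, alpha = 7200, drug_hill_h = 1,
      T_D_apoptotic = 8.6, T_D_necrotic = 60,
      perinecrotic_prob = 0.03, perinecrotic_mode = "hazard",
      mutation_prob = 0.01, neighborhood = "moore",
      oxygen_D = 1e5, oxygen_lambda = 0.01, oxygen_uptake = 10,
      oxygen_dirichlet = 38,
      drug_D = 1e5, drug_lambda = 0.01, drug_uptake = 10,
      drug_time = 528, drug_value = 5,
      snapshot_every = NA, stop_at_first_necrosis = FALSE),
    growth = list(
      lambda = 0.192, phi_stim = 0.00873, phi_inhib = 5.85,
      C0 = 1e6, K0 = 1e6, mu = 0, theta = 2 / 3, form = "literal",
      t_end = 100, dt = 0.01),
    invasion = list(
      D_C = 4e-5, rho = 1, delta = 1, gamma = 2, chi = 0,
      grid_size = 400, spacing = 1, t_end = 50, dt = 0.2),
    metastasis = list(
      n_agents = 1000, max_steps = 400, clustering_strength = 0.05,
      migration_rate = 0.05, noise_sd = 0.2, capture_radius = 1),
    fractal = list(
      image = NA, measure = "sum", n_bins = 20, noise_threshold = 0.001),
    fixture = list(
      kind = "koch", depth = 5, size = 256, ratio = 0.7, angle = 25),
    stop(sprintf("unknown module '%s'; available: tumor, growth, invasion, metastasis, fractal, fixture",
                 module)))
}

.suggest_key <- function(key, known) {
  # compare against both full keys and their underscore-stripped forms so
  # that e.g. 'birthrate' still points at 'base_birth_rate'
  d <- pmin(adist(key, known, ignore.case = TRUE),
            adist(gsub("_", "", key), gsub("_", "", known), ignore.case = TRUE))
  best <- known[which.min(d)]
  if (min(d) <= max(4, nchar(key)))
    sprintf(" (did you mean '%s'?)", best) else ""
}

#' Load and validate a layered run configuration
#'
#' Resolution order: module defaults, then keys from the YAML/JSON file,
#' then command-line style overrides.  Unknown keys are rejected with a
#' nearest-key suggestion.
#'
#' @param module module name (see [default_config()]).
#' @param path optional path to a YAML (or JSON) configuration file; an
#'   empty or absent file leaves all defaults in place.
#' @param overrides named list of final overrides (e.g. parsed from
#'   `key=value` CLI arguments).
#' @param seed integer RNG seed stored in the config.
#' @return A `run_config` list with fields `module`, `seed`, `params`.
#' @examples
#' cfg <- load_config("metastasis", overrides = list(n_agents = 500), seed = 7)
#' cfg$params$n_agents
#' @export
load_config <- function(module, path = NULL, overrides = list(), seed = 1L) {
  defaults <- default_config(module)
  file_cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
    file_cfg <- yaml::read_yaml(path)
    if (is.null(file_cfg)) file_cfg <- list()
  }
  params <- defaults
  for (layer in list(file_cfg, overrides)) {
    if (length(layer) == 0) next
    if (is.null(names(layer)) || any(names(layer) == ""))
      stop("configuration entries must all be named")
    if ("seed" %in% names(layer)) {
      seed <- as.integer(layer$seed)
      layer$seed <- NULL
    }
    unknown <- setdiff(names(layer), names(defaults))
    if (length(unknown) > 0)
      stop(sprintf("unknown configuration key '%s' for module '%s'%s",
                   unknown[1], module, .suggest_key(unknown[1], names(defaults))))
    params <- modifyList(params, layer)
  }
  structure(list(module = module, seed = as.integer(seed), params = params),
            class = "run_config")
}

# one RNG stream per module instance, derived from the top-level seed by a
# stable hash of the module name (kept below 2^31)
derive_seed <- function(seed, module) {
  h <- 0
  for (ch in utf8ToInt(module)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Execute a configured simulation run
#'
#' Dispatches to the named simulator, writes its outputs (CSV time series or
#' summaries, optional PNG snapshots) into `out_dir`, and records a manifest
#' JSON echoing the fully resolved configuration, seed and package version.
#' Identical config and seed give byte-identical CSV outputs.
#'
#' @param config a [load_config()] result.
#' @param out_dir output directory (created if missing).
#' @return List with `result` (the simulator return value) and `files`
#'   (paths written), invisibly.
#' @export
run_simulation <- function(config, out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  seed <- derive_seed(config$seed, config$module)
  files <- character(0)
  put <- function(name) { f <- file.path(out_dir, name); files <<- c(files, f); f }

  result <- switch(config$module,
    tumor = {
      params <- automaton_params(
        base_birth_rate = p$base_birth_rate,
        birth_rate_increment = p$birth_rate_increment,
        oxygen_hill_n = p$oxygen_hill_n, oxygen_ramp = p$oxygen_ramp,
        pO2_P = p$pO2_P, pO2_N = p$pO2_N, d_N_star = p$d_N_star,
        d_A_star = p$d_A_star, d_A_max = p$d_A_max, eta = p$eta,
        alpha = p$alpha, drug_hill_h = p$drug_hill_h,
        T_D_apoptotic = p$T_D_apoptotic, T_D_necrotic = p$T_D_necrotic,
        perinecrotic_prob = p$perinecrotic_prob,
        perinecrotic_mode = p$perinecrotic_mode,
        mutation_prob = p$mutation_prob, neighborhood = p$neighborhood,
        dt = p$dt)
      run <- run_tumor_simulation(
        n = p$lattice_size, spacing = p$spacing, t_end = p$t_end, params = params,
        oxygen_params = substrate_params(p$oxygen_D, p$oxygen_lambda,
                                         p$oxygen_uptake, p$oxygen_dirichlet),
        drug_params = substrate_params(p$drug_D, p$drug_lambda,
                                       p$drug_uptake, 0),
        drug_time = p$drug_time, drug_value = p$drug_value, seed = seed,
        snapshot_every = if (is.na(p$snapshot_every)) NULL else p$snapshot_every,
        stop_at_first_necrosis = isTRUE(p$stop_at_first_necrosis))
      write.csv(run$time_series, put("time_series.csv"), row.names = FALSE)
      write_state_png(run$lattice$state, put("final_state.png"))
      run
    },
    growth = {
      params <- growth_params(lambda = p$lambda, phi_stim = p$phi_stim,
                              phi_inhib = p$phi_inhib, C0 = p$C0, K0 = p$K0,
                              mu = p$mu, theta = p$theta, form = p$form)
      traj <- simulate_growth(params, t_end = p$t_end, dt = p$dt)
      write.csv(traj, put("trajectory.csv"), row.names = FALSE)
      # histogram-style export: tumor (green) and burden (red) over time bins
      grDevices::png(put("histograms.png"), width = 800, height = 400)
      keep <- seq(1, nrow(traj), length.out = min(40, nrow(traj)))
      graphics::barplot(rbind(traj$C[keep], traj$M[keep]), beside = TRUE,
                        names.arg = round(traj$t[keep], 1),
                        col = c("forestgreen", "firebrick"), border = NA,
                        xlab = "t (days)", ylab = "size",
                        legend.text = c("tumor C", "metastatic burden M"))
      grDevices::dev.off()
      traj
    },
    invasion = {
      params <- invasion_params(D_C = p$D_C, rho = p$rho, delta = p$delta,
                                gamma = p$gamma, chi = p$chi)
      x <- seq_len(p$grid_size) * p$spacing
      init <- invasion_state(C = as.numeric(x <= p$spacing * p$grid_size / 10),
                             m = numeric(p$grid_size), upsilon = rep(1, p$grid_size),
                             spacing = p$spacing)
      res <- simulate_invasion(init, params, t_end = p$t_end, dt = p$dt)
      write.csv(res$front, put("front.csv"), row.names = FALSE)
      write.csv(data.frame(x = x, C = res$state$C, m = res$state$m,
                           upsilon = res$state$upsilon),
                put("final_state.csv"), row.names = FALSE)
      res
    },
    metastasis = {
      run <- run_metastasis_simulation(
        n = p$n_agents, seed = seed, max_steps = p$max_steps,
        clustering_strength = p$clustering_strength,
        migration_rate = p$migration_rate, noise_sd = p$noise_sd,
        capture_radius = p$capture_radius)
      write.csv(run$summary, put("summary.csv"), row.names = FALSE)
      jsonlite::write_json(run$summary, put("summary.json"), dataframe = "rows")
      run
    },
    fractal = {
      if (is.na(p$image) || is.null(p$image)) stop("fractal analysis needs an 'image' path")
      img <- read_image(p$image)
      aimg <- holder_alpha(img, measure = p$measure)
      spec <- multifractal_spectrum(aimg, n_bins = p$n_bins,
                                    noise_threshold = p$noise_threshold)
      bc <- box_count(img > 0)
      write.csv(bc$counts, put("box_counts.csv"), row.names = FALSE)
      write.csv(as.data.frame(spec), put("spectrum.csv"), row.names = FALSE)
      list(alpha = aimg, spectrum = spec, box = bc)
    },
    fixture = {
      img <- generate_fixture(p$kind, depth = p$depth, size = p$size,
                              seed = seed, ratio = p$ratio, angle = p$angle)
      write_image(img, put(paste0(p$kind, ".png")))
      img
    },
    stop(sprintf("unknown module '%s'", config$module)))

  manifest <- list(module = config$module, seed = config$seed,
                   derived_seed = seed, params = config$params,
                   package = "sclcsim",
                   version = as.character(utils::packageVersion("sclcsim")))
  jsonlite::write_json(manifest, put("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(result = result, files = files))
}
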