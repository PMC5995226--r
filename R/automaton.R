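#' Parameters of the SCLC tumor cellular automaton
#'
#' Bundles the microenvironment-dependent birth/death model of the lattice
#' automaton.  The effective birth rate is `base_birth_rate +
#' birth_rate_increment`; the SCLC parameterization raises the increment to
#' 0.025/h and the oxygen Hill coefficient of viable cells to 4, and adds a 3%
#' contact-necrosis rule for perinecrotic cells.  Rate
#' defaults not fixed by the SCLC parameterization follow the published
#' example values of standard microenvironment-coupled automata and are all
#' overridable.
#'
#' @param base_birth_rate baseline division rate of well-oxygenated,
#'   drug-free cells (1/h).
#' @param birth_rate_increment SCLC adjustment added to the baseline (1/h).
#' @param oxygen_hill_n Hill coefficient of the hypoxic birth-rate ramp
#'   applied to viable cells (dimensionless).
#' @param oxygen_ramp `"hill"` uses `s^n/(1+s^n)` of the normalized oxygen
#'   excess `s = (pO2 - pO2_N)/(pO2_P - pO2_N)`; `"linear"` uses the
#'   piecewise-linear ramp `s` (the `n = 1` Hill ramp saturates at 1/2 and is
#'   not the same thing).
#' @param pO2_P oxygen partial pressure above which division is unconstrained
#'   (mmHg).
#' @param pO2_N oxygen partial pressure at or below which cells become
#'   necrotic (mmHg); must be `< pO2_P`.
#' @param d_N_star necrotic death rate under hypoxia (1/h).
#' @param d_A_star,d_A_max baseline and drug-saturated apoptosis rates (1/h).
#' @param eta drug inhibition strength of division, in `[0, 1]`.
#' @param alpha drug exposure giving the half-maximum response (uM min).
#' @param drug_hill_h Hill coefficient of the exposure-response curve.
#' @param T_D_apoptotic,T_D_necrotic mean persistence of apoptotic and
#'   necrotic bodies before lysis (h).
#' @param perinecrotic_prob contact-necrosis parameter for a viable cell
#'   with at least one necrotic neighbor (3% by default).
#' @param perinecrotic_mode `"hazard"` (default) reads `perinecrotic_prob`
#'   as a rate in 1/h; `"per-step"` reads it as a probability applied each
#'   step.  The hazard reading keeps the contact-necrosis front moving at
#'   0.03 sites/h independent of `dt`, commensurate with rim growth, so the
#'   rule bounds tumor expansion instead of overrunning it.
#' @param mutation_prob probability that a division produces a daughter with
#'   a fresh clone label.
#' @param neighborhood `"moore"` (8 neighbors) or `"von-neumann"` (4).
#' @param dt automaton time step (h).
#' @return An object of class `automaton_params`.
#' @export
automaton_params <- function(base_birth_rate = 0.025,
                             birth_rate_increment = 0.025,
                             oxygen_hill_n = 4,
                             oxygen_ramp = c("hill", "linear"),
                             pO2_P = 10,
                             pO2_N = 5,
                             d_N_star = 0.1,
                             d_A_star = 0.002,
                             d_A_max = 0.1,
                             eta = 1,
                             alpha = 7200,
                             drug_hill_h = 1,
                             T_D_apoptotic = 8.6,
                             T_D_necrotic = 60,
                             perinecrotic_prob = 0.03,
                             perinecrotic_mode = c("hazard", "per-step"),
                             mutation_prob = 0.01,
                             neighborhood = c("moore", "von-neumann"),
                             dt = 0.1) {
  oxygen_ramp <- match.arg(oxygen_ramp)
  perinecrotic_mode <- match.arg(perinecrotic_mode)
  neighborhood <- match.arg(neighborhood)
  rates <- c(base_birth_rate = base_birth_rate,
             birth_rate_increment = birth_rate_increment,
             d_N_star = d_N_star, d_A_star = d_A_star, d_A_max = d_A_max,
             alpha = alpha, oxygen_hill_n = oxygen_hill_n,
             drug_hill_h = drug_hill_h)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("automaton rates must be finite and nonnegative")
  if (alpha <= 0) stop("alpha (half-maximum exposure) must be > 0")
  if (!(pO2_N < pO2_P)) stop("pO2_N must be strictly below pO2_P")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  if (perinecrotic_mode == "per-step" &&
      (perinecrotic_prob < 0 || perinecrotic_prob > 1))
    stop("perinecrotic_prob must be a probability in [0, 1]")
  if (mutation_prob < 0 || mutation_prob > 1)
    stop("mutation_prob must lie in [0, 1]")
  if (T_D_apoptotic <= 0 || T_D_necrotic <= 0)
    stop("death durations T_D must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(
    base_birth_rate = base_birth_rate,
    birth_rate_increment = birth_rate_increment,
    birth_rate = base_birth_rate + birth_rate_increment,
    oxygen_hill_n = oxygen_hill_n, oxygen_ramp = oxygen_ramp,
    pO2_P = pO2_P, pO2_N = pO2_N,
    d_N_star = d_N_star, d_A_star = d_A_star, d_A_max = d_A_max,
    eta = eta, alpha = alpha, drug_hill_h = drug_hill_h,
    T_D_apoptotic = T_D_apoptotic, T_D_necrotic = T_D_necrotic,
    perinecrotic_prob = perinecrotic_prob,
    perinecrotic_mode = perinecrotic_mode,
    mutation_prob = mutation_prob, neighborhood = neighborhood,
    dt = dt), class = "automaton_params")
}

#' Drug exposure-response (Hill curve)
#'
#' `R = E^h / (alpha^h + E^h)`: the saturating response of a cell to its
#' accumulated drug exposure, with `h = 1` by default.
#'
#' @param E accumulated exposure (uM min), `>= 0`.
#' @param alpha exposure at half-maximum response (uM min), `> 0`.
#' @param h Hill coefficient.
#' @return Response in `[0, 1]`; vectorized over `E`.
#' @examples
#' drug_response(c(0, 100, 300), alpha = 100)  # 0, 0.5, 0.75
#' @export
drug_response <- function(E, alpha, h = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a single positive number")
  if (any(E < 0)) stop("exposure E must be nonnegative")
  Eh <- E^h
  Eh / (alpha^h + Eh)
}

#' Accumulate drug exposure over one step
#'
#' Left-endpoint rectangle rule for the exposure integral of the local drug
#' concentration: `E + c_local * dt`.
#'
#' @param E current exposure (uM min).
#' @param c_local local drug concentration (uM), `>= 0`.
#' @param dt step length in minutes.
#' @return Updated exposure.
#' @export
update_exposure <- function(E, c_local, dt) {
  if (any(c_local < 0)) stop("drug concentration must be nonnegative")
  E + c_local * dt
}

#' Microenvironment-dependent birth rate
#'
#' Three-branch birth model: full division rate above the proliferative
#' oxygen threshold, a (Hill-modified) oxygen ramp in the hypoxic band, and
#' zero at or below the necrotic threshold; throughout, division is inhibited
#' by the drug response as `(1 - eta R)`.
#'
#' @param pO2 local oxygen (mmHg), `>= 0`; vectorized.
#' @param R drug response in `[0, 1]`.
#' @param params an [automaton_params()].
#' @return Birth rate(s) in 1/h.
#' @export
birth_rate <- function(pO2, R, params) {
  stopifnot(inherits(params, "automaton_params"))
  if (any(pO2 < 0)) stop("pO2 must be nonnegative")
  if (any(R < 0 | R > 1)) stop("R must lie in [0, 1]")
  bP <- params$birth_rate
  s <- (pO2 - params$pO2_N) / (params$pO2_P - params$pO2_N)
  g <- if (params$oxygen_ramp == "linear") s else {
    sn <- pmax(s, 0)^params$oxygen_hill_n
    sn / (1 + sn)
  }
  out <- bP * (1 - params$eta * R) + 0 * pO2 # recycle to common length
  band <- pO2 <= params$pO2_P & pO2 > params$pO2_N
  out[band] <- (bP * g * (1 - params$eta * R))[band]
  out[pO2 <= params$pO2_N] <- 0
  out
}

#' Microenvironment-dependent death rates
#'
#' Necrotic death switches on at constant rate `d_N_star` when oxygen falls
#' to or below the necrotic threshold; the apoptosis rate interpolates
#' affinely between its baseline and drug-saturated value with the drug
#' response: `d_A = d_A_star + (d_A_max - d_A_star) R`.
#'
#' @inheritParams birth_rate
#' @return A list with components `necrotic` and `apoptotic` (1/h).
#' @export
death_rates <- function(pO2, R, params) {
  stopifnot(inherits(params, "automaton_params"))
  if (any(pO2 < 0)) stop("pO2 must be nonnegative")
  if (any(R < 0 | R > 1)) stop("R must lie in [0, 1]")
  necro <- ifelse(pO2 <= params$pO2_N, params$d_N_star, 0)
  apop <- params$d_A_star + (params$d_A_max - params$d_A_star) * R
  list(necrotic = necro + 0 * R, apoptotic = apop + 0 * pO2)
}

#' Per-step event probability of a Poisson hazard
#'
#' `P = 1 - exp(-rate * dt)`: the probability that at least one event of a
#' constant hazard fires within one step.
#'
#' @param rate hazard (1/h), `>= 0`; vectorized.
#' @param dt step length (h), `> 0`.
#' @return Probability in `[0, 1]`.
#' @examples
#' event_probability(0.01, 0.1)  # ~ rate * dt in the small-hazard limit
#' @export
event_probability <- function(rate, dt) {
  if (any(rate < 0)) stop("rate must be nonnegative")
  if (any(dt <= 0)) stop("dt must be positive")
  1 - exp(-rate * dt)
}

#' Per-step lysis probability of a dead cell
#'
#' `P = 1 - exp(-dt / T_D)` where `T_D` is the mean duration of cell death;
#' a lysed cell ruptures and leaves an empty lattice site.
#'
#' @param T_D mean death duration (h), `> 0`.
#' @param dt step length (h), `>= 0`.
#' @return Probability in `[0, 1]`.
#' @export
lysis_probability <- function(T_D, dt) {
  if (any(T_D <= 0)) stop("T_D must be positive")
  1 - exp(-dt / T_D)
}

#' Create an empty cell lattice
#'
#' @param nrow,ncol lattice dimensions.
#' @param seed_cell place one viable founder cell at the lattice center?
#' @return A `cell_lattice`: list of congruent matrices `state` (codes 0
#'   empty, 1 viable, 2 apoptotic, 3 necrotic), `exposure` (uM min) and
#'   `clone_id` (integer labels, NA on empty sites), plus the clone counter
#'   `next_clone_id` (the highest label assigned so far).
#' @export
cell_lattice <- function(nrow, ncol = nrow, seed_cell = TRUE) {
  state <- matrix(CELL_EMPTY, nrow, ncol)
  exposure <- matrix(0, nrow, ncol)
  clone_id <- matrix(NA_integer_, nrow, ncol)
  if (seed_cell) {
    ci <- (nrow + 1L) %/% 2L; cj <- (ncol + 1L) %/% 2L
    state[ci, cj] <- CELL_VIABLE
    clone_id[ci, cj] <- 1L
  }
  structure(list(state = state, exposure = exposure, clone_id = clone_id,
                 next_clone_id = 1L), class = "cell_lattice")
}

#' Advance the cell lattice by one automaton step
#'
#' For each viable cell (decisions taken against the state at step entry):
#' hypoxic necrosis is tested first, then perinecrotic contact necrosis, then
#' apoptosis, then division into a uniformly chosen empty neighbor (skipped
#' when none is free).  Dead cells are tested for lysis.  Exposures are
#' updated from the local drug concentration, and daughters inherit the
#' parental clone label unless a mutation event relabels them.
#'
#' @param lattice a [cell_lattice()].
#' @param oxygen,drug [scalar_field()]s congruent with the lattice (mmHg, uM).
#' @param params an [automaton_params()]; `params$dt` is the step in hours.
#' @param log_events keep a per-event log? (type 1 = division, 2 = apoptosis,
#'   3 = necrosis, 4 = lysis, with 1-based lattice coordinates).
#' @return A list: `lattice` (advanced, including its clone counter),
#'   `events` (data.frame or `NULL`).
#' @export
step_lattice <- function(lattice, oxygen, drug, params, log_events = TRUE) {
  stopifnot(inherits(lattice, "cell_lattice"), inherits(params, "automaton_params"))
  ox <- if (inherits(oxygen, "scalar_field")) oxygen$values else oxygen
  dr <- if (inherits(drug, "scalar_field")) drug$values else drug
  if (!identical(dim(ox), dim(lattice$state)) || !identical(dim(dr), dim(lattice$state)))
    stop("oxygen/drug grids are not congruent with the lattice")
  # defensive copies: the compiled stepper updates its arguments in place
  lattice$state <- lattice$state + 0L
  lattice$exposure <- lattice$exposure + 0
  lattice$clone_id <- lattice$clone_id + 0L
  par <- unclass(params)
  par$next_clone_id <- lattice$next_clone_id
  res <- ca_step_cpp(lattice$state, lattice$exposure, lattice$clone_id,
                     ox, dr, par, t = 0, log_events = log_events)
  lattice$next_clone_id <- res$next_clone_id
  events <- NULL
  if (log_events) {
    ev <- res$events
    events <- data.frame(type = ev$type, i = ev$i, j = ev$j, clone_id = ev$clone_id)
  }
  list(lattice = lattice, events = events)
}

#' Run the coupled tumor-microenvironment simulation
#'
#' Starts from a single viable cell at the lattice center at `t = 0`, and at
#' every automaton step equilibrates the oxygen and drug fields (with uptake
#' at viable-cell sites) before applying the stochastic cell rules.  Because
#' substrate diffusion relaxes within minutes while the automaton advances
#' in 6-minute steps, the fields are solved quasi-statically by default
#' ([solve_steady_field()], warm-started from the previous step);
#' `field_mode = "transient"` time-steps them with [step_substrate()]
#' instead.
#' At `drug_time` the drug's far-field boundary value is raised to
#' `drug_value` and the drug diffuses in.  The run records state and clone
#' counts over time and the first time any cell turns necrotic.
#'
#' @param n lattice side (the lattice is `n x n`).
#' @param spacing lattice spacing (um).
#' @param t_end end time (h).
#' @param params an [automaton_params()].
#' @param oxygen_params,drug_params [substrate_params()] for the two fields;
#'   drug uptake/decay default to the oxygen solver's example values with a
#'   zero far-field until `drug_time`.
#' @param drug_time time at which drug treatment starts (h); default 528 h
#'   (day 22).
#' @param drug_value drug far-field concentration from `drug_time` on (uM).
#' @param field_mode `"quasi-static"` (default) or `"transient"` substrate
#'   handling.
#' @param seed RNG seed (one seed drives the whole run).
#' @param snapshot_every interval (h) at which lattice/oxygen snapshots are
#'   retained, or `NULL` for none.
#' @param stop_at_first_necrosis end the run as soon as a necrotic cell
#'   appears (used for necrosis-onset measurements).
#' @param log_events keep the full per-event log (memory heavy on long runs).
#' @return A `tumor_run` list: `time_series` data.frame (t, counts by state,
#'   wild-type/mutant viable counts), `first_necrosis_time` (h, `NA` if
#'   never), `snapshots`, final `lattice`, `oxygen`, `drug`, `events`.
#' @export
run_tumor_simulation <- function(n = 200, spacing = 20, t_end = 720,
                                 params = automaton_params(),
                                 oxygen_params = substrate_params(),
                                 drug_params = substrate_params(
                                   D = 1e5, lambda = 0.01, uptake = 10,
                                   dirichlet_value = 0),
                                 drug_time = 528, drug_value = 5,
                                 field_mode = c("quasi-static", "transient"),
                                 seed = NULL,
                                 snapshot_every = NULL,
                                 stop_at_first_necrosis = FALSE,
                                 log_events = FALSE) {
  field_mode <- match.arg(field_mode)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(params, "automaton_params"))
  lattice <- cell_lattice(n, n, seed_cell = TRUE)
  oxygen <- scalar_field(matrix(oxygen_params$dirichlet_value, n, n),
                         spacing = spacing, boundary = "dirichlet")
  drug <- scalar_field(matrix(0, n, n), spacing = spacing, boundary = "dirichlet")

  dt <- params$dt
  nsteps <- ceiling(t_end / dt)
  times <- numeric(0); cnt <- list()
  first_necrosis <- NA_real_
  snapshots <- list()
  events <- if (log_events) vector("list", 0) else NULL
  next_snapshot <- if (is.null(snapshot_every)) Inf else 0

  record <- function(t, state, clone_id) {
    k <- ca_counts_cpp(state)
    viable <- state == CELL_VIABLE
    wt <- sum(viable & clone_id == 1L, na.rm = TRUE)
    data.frame(t = t, n_viable = k[2], n_apoptotic = k[3], n_necrotic = k[4],
               n_wildtype = wt, n_mutant = k[2] - wt)
  }
  ts <- list(record(0, lattice$state, lattice$clone_id))

  drug_on <- FALSE
  par <- unclass(params)
  for (step in seq_len(nsteps)) {
    t <- step * dt
    if (!drug_on && t >= drug_time) {
      drug_params$dirichlet_value <- drug_value
      drug_on <- TRUE
    }
    occ <- lattice$state == CELL_VIABLE
    if (field_mode == "quasi-static") {
      oxygen <- solve_steady_field(oxygen, oxygen_params, occ, tol = 1e-7)
      if (drug_on) drug <- solve_steady_field(drug, drug_params, occ, tol = 1e-7)
    } else {
      oxygen <- step_substrate(oxygen, oxygen_params, occ, dt * 60)
      if (drug_on || any(drug$values > 0))
        drug <- step_substrate(drug, drug_params, occ, dt * 60)
    }
    par$next_clone_id <- lattice$next_clone_id
    res <- ca_step_cpp(lattice$state, lattice$exposure, lattice$clone_id,
                       oxygen$values, drug$values, par,
                       t = t, log_events = log_events)
    lattice$next_clone_id <- res$next_clone_id
    if (log_events && length(res$events$type) > 0)
      events[[length(events) + 1L]] <- data.frame(
        t = t, type = res$events$type, i = res$events$i, j = res$events$j,
        clone_id = res$events$clone_id)
    row <- record(t, lattice$state, lattice$clone_id)
    ts[[length(ts) + 1L]] <- row
    if (is.na(first_necrosis) && row$n_necrotic > 0) {
      first_necrosis <- t
      if (stop_at_first_necrosis) break
    }
    if (t >= next_snapshot) {
      snapshots[[length(snapshots) + 1L]] <-
        list(t = t, state = lattice$state + 0L, oxygen = oxygen$values)
      next_snapshot <- next_snapshot + snapshot_every
    }
  }
  structure(list(
    time_series = do.call(rbind, ts),
    first_necrosis_time = first_necrosis,
    snapshots = snapshots,
    lattice = lattice, oxygen = oxygen, drug = drug,
    events = if (log_events) do.call(rbind, events) else NULL,
    params = params), class = "tumor_run")
}

#' @export
print.tumor_run <- function(x, ...) {
  last <- tail(x$time_series, 1)
  cat("<tumor_run> ", nrow(x$time_series) - 1, " steps to t = ", last$t, " h\n",
      "  viable ", last$n_viable, ", apoptotic ", last$n_apoptotic,
      ", necrotic ", last$n_necrotic, "\n",
      "  first necrosis at t = ", x$first_necrosis_time, " h\n", sep = "")
  invisible(x)
}

#' Median time of first necrosis over several seeds
#'
#' Runs the coupled tumor simulation repeatedly from a single founder cell
#' and reports the per-seed time at which the first necrotic cell appears,
#' plus the median.  Runs stop at first necrosis.
#'
#' @param seeds integer vector of RNG seeds (one run each).
#' @param ... passed to [run_tumor_simulation()].
#' @return List with `times` (h, per seed) and `median` (h).
#' @export
first_necrosis_times <- function(seeds, ...) {
  times <- vapply(seeds, function(s) {
    run <- run_tumor_simulation(seed = s, stop_at_first_necrosis = TRUE, ...)
    run$first_necrosis_time
  }, numeric(1))
  list(times = times, median = median(times))
}

#' Write an event log as JSON lines
#'
#' One JSON object per event (`t`, `type`, `i`, `j`, `clone_id`), with type
#' codes 1 = division, 2 = apoptosis, 3 = necrosis, 4 = lysis.
#'
#' @param events event data.frame from [step_lattice()] or
#'   [run_tumor_simulation()] (with `log_events = TRUE`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(events) && nrow(events) > 0)
    for (r in seq_len(nrow(events)))
      writeLines(jsonlite::toJSON(as.list(events[r, ]), auto_unbox = TRUE), con)
  invisible(path)
}

#' Save a lattice snapshot as a color PNG
#'
#' Red = viable, green = apoptotic, blue = necrotic, white = empty.
#'
#' @param state integer state matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_state_png <- function(state, path) {
  nr <- nrow(state); nc <- ncol(state)
  img <- array(1, c(nr, nc, 3))
  img[, , 1][state == CELL_APOPTOTIC | state == CELL_NECROTIC] <- 0
  img[, , 2][state == CELL_VIABLE | state == CELL_NECROTIC] <- 0
  img[, , 3][state == CELL_VIABLE | state == CELL_APOPTOTIC] <- 0
  png::writePNG(img, path)
  invisible(path)
}
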