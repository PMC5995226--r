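test_that("drug response is the Hill curve of accumulated exposure", {
  expect_equal(drug_response(0, alpha = 100), 0)
  expect_equal(drug_response(100, alpha = 100), 0.5)
  expect_equal(drug_response(300, alpha = 100), 0.75)
  expect_equal(drug_response(c(0, 50, 150), alpha = 50), c(0, 0.5, 0.75))
  expect_error(drug_response(10, alpha = 0), "positive")
  expect_error(drug_response(-1, alpha = 10), "nonnegative")
})

test_that("exposure accumulates by the rectangle rule and approaches fine quadrature", {
  expect_equal(update_exposure(0, 0, 10), 0)
  expect_equal(update_exposure(0, 5, 60), 300)
  # piecewise-constant concentration: coarse rectangle sum vs fine-step oracle
  conc <- c(2, 5, 1); dt <- 30
  E_coarse <- Reduce(function(E, cc) update_exposure(E, cc, dt), conc, accumulate = FALSE, init = 0)
  tfine <- seq(0, 90 - 0.01, by = 0.01)
  cfine <- conc[pmin(floor(tfine / dt) + 1, 3)]
  E_fine <- sum(cfine * 0.01)
  expect_equal(E_coarse, E_fine, tolerance = 1e-6)
})

test_that("birth rate follows the three oxygen branches with drug inhibition", {
  p <- automaton_params(oxygen_ramp = "linear", oxygen_hill_n = 1)
  bP <- p$birth_rate
  expect_equal(bP, 0.05) # baseline plus the SCLC increment
  expect_equal(birth_rate(38, 0, p), bP)
  expect_equal(birth_rate(3, 0.9, p), 0)   # at/below necrotic threshold: no division
  expect_equal(birth_rate(5, 0, p), 0)
  mid <- (p$pO2_P + p$pO2_N) / 2
  expect_equal(birth_rate(mid, 0, p), bP / 2) # linear ramp midpoint
  expect_equal(birth_rate(38, 1, p), 0)       # full drug response, eta = 1
  expect_equal(birth_rate(38, 0.5, automaton_params(eta = 0.6)), bP * 0.7)
  # Hill-modified ramp suppresses the hypoxic band more strongly than linear
  ph <- automaton_params(oxygen_ramp = "hill", oxygen_hill_n = 4)
  s <- (mid - ph$pO2_N) / (ph$pO2_P - ph$pO2_N)
  expect_equal(birth_rate(mid, 0, ph), bP * s^4 / (1 + s^4))
  expect_lt(birth_rate(mid, 0, ph), birth_rate(mid, 0, p))
})

test_that("death rates: necrosis switches at the threshold, apoptosis is affine in the response", {
  p <- automaton_params()
  d0 <- death_rates(20, 0, p)
  expect_equal(d0$necrotic, 0)
  expect_equal(d0$apoptotic, p$d_A_star)
  d1 <- death_rates(4, 1, p)
  expect_equal(d1$necrotic, p$d_N_star)
  expect_equal(d1$apoptotic, p$d_A_max)
  dm <- death_rates(20, 0.5, p)
  expect_equal(dm$apoptotic, (p$d_A_star + p$d_A_max) / 2)
})

test_that("event and lysis probabilities are exponential hazards", {
  expect_equal(event_probability(0, 1), 0)
  expect_equal(event_probability(1e9, 1), 1)
  expect_equal(event_probability(0.01, 0.1), 1 - exp(-0.001))
  expect_error(event_probability(-0.1, 1), "nonnegative")
  expect_equal(lysis_probability(10, 0), 0)
  expect_equal(lysis_probability(10, 10), 1 - exp(-1))
  expect_error(lysis_probability(0, 1), "positive")
  # monotone in both arguments
  expect_true(all(diff(event_probability(seq(0, 2, by = 0.1), 0.5)) > 0))
  expect_true(all(diff(event_probability(0.3, seq(0.1, 2, by = 0.1))) > 0))
})

test_that("mean persistence of dead cells recovers T_D (Monte Carlo vs geometric oracle)", {
  set.seed(301)
  T_D <- 8; dt <- 0.4
  p_lys <- lysis_probability(T_D, dt)
  dwell <- dt * (rgeom(10000, p_lys) + 1)
  # geometric dwell mean is dt/p = T_D + dt/2 + O(dt^2)
  expect_equal(mean(dwell), T_D, tolerance = 0.05)
  expect_equal(dt / p_lys, T_D + dt / 2, tolerance = 0.01)
})

test_that("an empty lattice is a fixed point and hypoxia stops all division", {
  p <- automaton_params()
  lat <- cell_lattice(12, seed_cell = FALSE)
  ox <- matrix(38, 12, 12); dr <- matrix(0, 12, 12)
  set.seed(1)
  res <- step_lattice(lat, ox, dr, p)
  expect_identical(res$lattice$state, lat$state)
  expect_equal(nrow(res$events), 0)

  # pO2 at the necrotic threshold everywhere: never a division
  lat2 <- cell_lattice(12, seed_cell = TRUE)
  oxlow <- matrix(4, 12, 12)
  set.seed(2)
  divisions <- 0
  for (i in 1:50) {
    r <- step_lattice(lat2, oxlow, dr, p)
    lat2 <- r$lattice
    divisions <- divisions + sum(r$events$type == 1)
  }
  expect_equal(divisions, 0)
})

test_that("population growth from one cell recovers the birth rate within 5%", {
  p <- automaton_params(dt = 0.05, d_A_star = 0, mutation_prob = 0)
  ox <- matrix(38, 20, 20); dr <- matrix(0, 20, 20)
  set.seed(77)
  finals <- replicate(400, {
    lat <- cell_lattice(20, seed_cell = TRUE)
    for (s in 1:40) lat <- step_lattice(lat, ox, dr, p, log_events = FALSE)$lattice
    sum(lat$state == 1L)
  })
  b_hat <- log(mean(finals)) / 2 # E N(t) = exp(b t), t = 2 h
  expect_equal(b_hat, p$birth_rate, tolerance = 0.05)
})

test_that("sampled event frequency matches the small-hazard limit within 3 Monte Carlo SE", {
  # apoptosis hazard on a fully occupied lattice: d_A * dt = 1e-3
  p <- automaton_params(dt = 0.1, d_A_star = 0.01, mutation_prob = 0)
  n <- 350
  lat <- cell_lattice(n, seed_cell = FALSE)
  lat$state[] <- 1L; lat$clone_id[] <- 1L
  ox <- matrix(38, n, n); dr <- matrix(0, n, n)
  set.seed(5)
  res <- step_lattice(lat, ox, dr, p)
  n_apop <- sum(res$events$type == 2)
  ntrials <- n * n
  p_target <- p$d_A_star * p$dt
  se <- sqrt(p_target * (1 - p_target) / ntrials)
  expect_lt(abs(n_apop / ntrials - p_target), 3 * se + p_target^2)
})

test_that("state transitions respect the allowed graph and sites stay exclusive", {
  p <- automaton_params(dt = 0.2, d_A_star = 0.05)
  n <- 25
  ox <- matrix(8, n, n) # hypoxic band: some necrosis, some division
  dr <- matrix(0, n, n)
  set.seed(9)
  lat <- cell_lattice(n, seed_cell = TRUE)
  prev <- lat$state
  allowed <- list(`0` = c(0L, 1L), `1` = c(1L, 2L, 3L), `2` = c(2L, 0L), `3` = c(3L, 0L))
  for (i in 1:200) {
    lat <- step_lattice(lat, ox, dr, p, log_events = FALSE)$lattice
    for (from in 0:3) {
      idx <- prev == from
      expect_true(all(lat$state[idx] %in% allowed[[as.character(from)]]))
    }
    # exactly one cell record per occupied site: clone ids defined iff occupied
    expect_true(all(is.na(lat$clone_id[lat$state == 0L])))
    expect_true(all(!is.na(lat$clone_id[lat$state != 0L])))
    prev <- lat$state
  }
})

test_that("perinecrotic contact necrosis fires at the configured per-step probability", {
  p <- automaton_params(dt = 0.1, d_A_star = 0, base_birth_rate = 0,
                        birth_rate_increment = 0, perinecrotic_prob = 0.03,
                        perinecrotic_mode = "per-step")
  ox <- matrix(38, 3, 3); dr <- matrix(0, 3, 3)
  set.seed(12)
  hits <- replicate(5000, {
    lat <- cell_lattice(3, seed_cell = FALSE)
    lat$state[2, 2] <- 1L; lat$clone_id[2, 2] <- 1L
    lat$state[2, 3] <- 3L; lat$clone_id[2, 3] <- 1L
    r <- step_lattice(lat, ox, dr, p, log_events = FALSE)
    r$lattice$state[2, 2] == 3L
  })
  se <- sqrt(0.03 * 0.97 / 5000)
  expect_lt(abs(mean(hits) - 0.03), 3 * se)
})

test_that("clone tagging: no mutations means one clone, certain mutation relabels every daughter", {
  ox <- matrix(38, 15, 15); dr <- matrix(0, 15, 15)
  run_clones <- function(mut) {
    p <- automaton_params(dt = 0.2, mutation_prob = mut, d_A_star = 0)
    set.seed(33)
    lat <- cell_lattice(15, seed_cell = TRUE)
    for (i in 1:350) lat <- step_lattice(lat, ox, dr, p, log_events = FALSE)$lattice
    unique(lat$clone_id[lat$state == 1L])
  }
  expect_identical(run_clones(0), 1L)
  clones <- run_clones(1)
  n_cells <- length(clones)
  expect_gt(n_cells, 3)
  expect_equal(length(unique(clones)), n_cells) # every division made a fresh label
})

test_that("runs are bit-reproducible under a fixed seed", {
  p <- automaton_params(dt = 0.2)
  ox <- matrix(9, 15, 15); dr <- matrix(0.5, 15, 15)
  go <- function() {
    set.seed(123)
    lat <- cell_lattice(15, seed_cell = TRUE)
    logs <- list()
    for (i in 1:60) {
      r <- step_lattice(lat, ox, dr, p)
      lat <- r$lattice
      logs[[i]] <- r$events
    }
    list(lat = lat, logs = logs)
  }
  a <- go(); b <- go()
  expect_identical(a$lat, b$lat)
  expect_identical(a$logs, b$logs)
})

test_that("coupled run grows a hypoxic core: necrosis is interior-enriched and oxygen dips centrally", {
  run <- run_tumor_simulation(n = 120, t_end = 400, seed = 42,
                              stop_at_first_necrosis = FALSE,
                              params = automaton_params())
  expect_false(is.na(run$first_necrosis_time))
  st <- run$lattice$state
  necro <- which(st == 3L, arr.ind = TRUE)
  viable <- which(st == 1L, arr.ind = TRUE)
  expect_gt(nrow(necro), 5)
  cen <- colMeans(rbind(necro, viable))
  dist_to <- function(m) sqrt((m[, 1] - cen[1])^2 + (m[, 2] - cen[2])^2)
  expect_lt(mean(dist_to(necro)), mean(dist_to(viable)))
  # radially averaged oxygen is lowest in the innermost shell
  ox <- run$oxygen$values
  ij <- expand.grid(i = 1:120, j = 1:120)
  rr <- sqrt((ij$i - cen[1])^2 + (ij$j - cen[2])^2)
  shell <- cut(rr, breaks = seq(0, 60, by = 6))
  prof <- tapply(as.vector(ox), shell, mean)
  prof <- prof[!is.na(prof)]
  expect_equal(which.min(prof), 1L, ignore_attr = TRUE)
  expect_lt(prof[1], prof[length(prof)])
})
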