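test_that("both homogeneous steady states have zero RHS and are preserved by the stepper", {
  p <- invasion_params()
  invaded <- invasion_state(C = rep(1, 60), m = rep(1, 60), upsilon = rep(0, 60))
  healthy <- invasion_state(C = rep(0, 60), m = rep(0, 60), upsilon = rep(1, 60))
  for (st in list(invaded, healthy)) {
    r <- invasion_rhs(st, p)
    expect_equal(max(abs(c(r$dC, r$dm, r$dupsilon))), 0)
    out <- simulate_invasion(st, p, t_end = 1, dt = 0.2)
    expect_identical(out$state$C, st$C)
    expect_identical(out$state$m, st$m)
    expect_identical(out$state$upsilon, st$upsilon)
  }
})

test_that("uniform matrix decay relaxes to max(0, 1 - gamma), matching a stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  for (gam in c(0.4, 2)) {
    p <- invasion_params(D_C = 0, rho = 0, delta = 0, gamma = gam)
    st <- invasion_state(C = rep(1, 10), m = rep(1, 10), upsilon = rep(0.6, 10))
    out <- simulate_invasion(st, p, t_end = 40, dt = 0.05)
    target <- max(0, 1 - gam)
    expect_equal(unname(out$state$upsilon[5]), target, tolerance = 0.02)
    sol <- deSolve::lsoda(c(u = 0.6), times = c(0, 40),
                          function(t, y, pp) list(y * (1 - y) - gam * y), NULL)
    expect_equal(unname(out$state$upsilon[5]), unname(sol[2, "u"]), tolerance = 0.02)
  }
})

test_that("with no proliferation and no diffusion the tumor field is static", {
  p <- invasion_params(D_C = 0, rho = 0, delta = 1, gamma = 1)
  C0 <- c(rep(1, 20), rep(0, 40))
  st <- invasion_state(C = C0, m = numeric(60), upsilon = rep(1, 60))
  out <- simulate_invasion(st, p, t_end = 5, dt = 0.1)
  expect_equal(as.vector(out$state$C), C0, tolerance = 1e-12)
})

test_that("Fisher-limit front speed approaches 2 sqrt(rho D) within 5%", {
  n <- 2000; h <- 0.25
  p <- invasion_params(D_C = 1, rho = 1, delta = 0, gamma = 0, chi = 0)
  init <- invasion_state(C = as.numeric(seq_len(n) <= 40), m = numeric(n),
                         upsilon = numeric(n), spacing = h)
  res <- simulate_invasion(init, p, t_end = 150, dt = 0.03, sample_every = 1e9)
  expect_equal(res$front_speed, 2, tolerance = 0.05)
})

test_that("a hypocellular gap opens at the invasion front only for gamma > 1", {
  gap_depth <- function(gam) {
    n <- 400
    init <- invasion_state(C = as.numeric(seq_len(n) <= 40), m = numeric(n),
                           upsilon = rep(1, n), spacing = 1)
    p <- invasion_params(D_C = 4e-5, rho = 1, delta = 1, gamma = gam)
    res <- simulate_invasion(init, p, t_end = 60, dt = 0.2, sample_every = 1e9)
    s <- res$state
    tot <- s$C + s$upsilon
    fr <- max(which(s$C >= 0.5))
    hr <- min(which(s$upsilon >= 0.9 * max(s$upsilon)))
    min(tot[fr:max(fr, hr)]) / min(tot[10], tot[n - 10])
  }
  expect_gt(gap_depth(0.5), 0.8)  # no real gap in the weak-degradation regime
  expect_lt(gap_depth(2), 0.8)
  expect_lt(gap_depth(5), 0.3)    # deeper gap at stronger matrix degradation
})

test_that("stability violations report the admissible step", {
  init <- invasion_state(C = rep(0.5, 50), m = rep(0, 50), upsilon = rep(1, 50))
  expect_error(simulate_invasion(init, invasion_params(), t_end = 1, dt = 10),
               "admissible bound")
  expect_error(invasion_state(C = rep(2, 5), m = rep(0, 5), upsilon = rep(0, 5)),
               "\\[0, 1\\]")
})

test_that("walk probabilities: unbiased on flat matrix, exact stencil bias on a ramp", {
  p <- invasion_params(D_C = 0.5, chi = 2)
  flat <- walk_probabilities(c(0.4, 0.4, 0.4, 0.4, 0.4), p, dt = 0.1, spacing = 1)
  expect_equal(sum(flat), 1)
  expect_equal(unname(flat["left"]), unname(flat["right"]))
  expect_equal(unname(flat["up"]), unname(flat["down"]))
  expect_equal(unname(flat["left"]), 0.05) # D dt / h^2

  # chi = 0: probabilities ignore the matrix neighborhood entirely
  p0 <- invasion_params(D_C = 0.5, chi = 0)
  a <- walk_probabilities(c(0.1, 0.9, 0.2), p0, dt = 0.1, spacing = 1)
  b <- walk_probabilities(c(0.7, 0.0, 0.5), p0, dt = 0.1, spacing = 1)
  expect_equal(a, b)

  # linear ramp: up-gradient minus down-gradient equals chi dt grad(upsilon) / h
  h <- 0.5; dt <- 0.02
  u <- c(0.5, 0.45, 0.55) # gradient 0.1/(2h) = 0.1
  pr <- walk_probabilities(u, p, dt, h)
  expect_equal(unname(pr["right"] - pr["left"]), 2 * dt * 0.1 / h, tolerance = 1e-12)
  # reflection symmetry: mirroring the neighborhood swaps the move labels
  pr_m <- walk_probabilities(u[c(1, 3, 2)], p, dt, h)
  expect_equal(unname(pr_m["left"]), unname(pr["right"]))
  expect_equal(unname(pr_m["right"]), unname(pr["left"]))
  expect_error(walk_probabilities(c(0, 0, 0), p, dt = 10, spacing = 1),
               "too large")
})

test_that("an ensemble of walkers reproduces the PDE stencil density within 3 sigma", {
  set.seed(42)
  n <- 81; h <- 1; dt <- 0.2
  ups <- seq(0, 0.8, length.out = n)
  p <- invasion_params(D_C = 1, rho = 0, delta = 0, gamma = 0, chi = 1)
  nw <- 1e5
  pos <- simulate_walkers(nw, 41L, ups, p, t_end = 4, dt = dt)
  dens <- numeric(n); dens[41] <- 1
  for (s in 1:20) {
    nd <- dens
    for (i in 1:n) {
      um <- ups[max(i - 1, 1)]; up <- ups[min(i + 1, n)]
      w <- walk_probabilities(c(ups[i], um, up), p, dt, h)
      nd[i] <- nd[i] - (w["left"] + w["right"]) * dens[i]
      if (i > 1) nd[i - 1] <- nd[i - 1] + w["left"] * dens[i]
      if (i < n) nd[i + 1] <- nd[i + 1] + w["right"] * dens[i]
    }
    dens <- nd
  }
  emp <- tabulate(pos, n) / nw
  se <- pmax(sqrt(dens * (1 - dens) / nw), 1e-9)
  occupied <- dens > 1e-4
  n_out <- sum(abs(emp - dens)[occupied] > 3 * se[occupied])
  expect_lte(n_out, 1) # multiple comparisons: allow a single 3-sigma excursion
  # drift matches the PDE mean displacement (haptotaxis up the ramp)
  expect_gt(mean(pos - 41), 0)
  expect_equal(mean(pos - 41), sum((seq_len(n) - 41) * dens), tolerance = 0.3)
})
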