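#' Parameters of the acid-mediated invasion model
#'
#' Nondimensional parameters of the three-field tumor/acid/matrix system
#' \deqn{\partial C/\partial t = \nabla\cdot(D_C (1-\upsilon) \nabla C) + \rho C (1 - C)}
#' \deqn{\partial m/\partial t = \nabla^2 m + \delta (C - m)}
#' \deqn{\partial \upsilon/\partial t = \upsilon(1-\upsilon) - \gamma m \upsilon}
#' plus an optional haptotaxis strength `chi` used by the single-cell random
#' walk (and by the C-equation as `-chi grad.(C grad upsilon)` when nonzero;
#' the default `chi = 0` reproduces the plain system).
#'
#' @param D_C tumor diffusion coefficient (dimensionless).
#' @param rho tumor proliferation rate.
#' @param delta acid production/decay rate.
#' @param gamma matrix degradation rate; a hypocellular interstitial gap
#'   opens for `gamma > 1`.
#' @param chi haptotaxis strength (default 0).
#' @return An object of class `invasion_params`.
#' @export
invasion_params <- function(D_C = 4e-5, rho = 1, delta = 1, gamma = 2, chi = 0) {
  v <- c(D_C = D_C, rho = rho, delta = delta, gamma = gamma, chi = chi)
  if (any(!is.finite(v)) || any(v < 0))
    stop("invasion parameters must be finite and nonnegative")
  structure(as.list(v), class = "invasion_params")
}

#' State of the invasion system
#'
#' @param C tumor density in `[0, 1]` (numeric vector for 1D or matrix for 2D).
#' @param m acid concentration, `>= 0`, congruent with `C`.
#' @param upsilon extracellular-matrix density in `[0, 1]`, congruent with `C`.
#' @param spacing grid spacing (nondimensional).
#' @param t current time.
#' @return An object of class `invasion_state`.
#' @export
invasion_state <- function(C, m, upsilon, spacing = 1, t = 0) {
  C <- as.array(C); m <- as.array(m); upsilon <- as.array(upsilon)
  if (!identical(dim(C), dim(m)) || !identical(dim(C), dim(upsilon)))
    stop("C, m and upsilon grids must be congruent")
  if (any(C < 0 | C > 1)) stop("C must lie in [0, 1]")
  if (any(upsilon < 0 | upsilon > 1)) stop("upsilon must lie in [0, 1]")
  if (any(m < 0)) stop("m must be nonnegative")
  structure(list(C = C, m = m, upsilon = upsilon, spacing = spacing, t = t),
            class = "invasion_state")
}

# conservative divergence of D (1 - upsilon) grad C along one dimension,
# no-flux ends; face coefficients are arithmetic means of (1 - upsilon)
.degenerate_diffusion <- function(C, upsilon, D, h) {
  dims <- dim(C); nd <- length(dims)
  out <- array(0, dims)
  for (d in seq_len(nd)) {
    Cp <- .shift_along(C, d, 1L, 0L, 0)   # i+1
    Cm <- .shift_along(C, d, -1L, 0L, 0)  # i-1
    up <- .shift_along(upsilon, d, 1L, 0L, 0)
    um <- .shift_along(upsilon, d, -1L, 0L, 0)
    ap <- D * (1 - (upsilon + up) / 2)    # face i+1/2
    am <- D * (1 - (upsilon + um) / 2)    # face i-1/2
    out <- out + (ap * (Cp - C) - am * (C - Cm)) / h^2
  }
  out
}

#' Right-hand side of the invasion system
#'
#' Returns the three time derivatives with the degenerate tumor diffusion
#' flux `D_C (1 - upsilon) grad C` discretized conservatively (arithmetic
#' face averages, no-flux boundaries).
#'
#' @param state an [invasion_state()].
#' @param params an [invasion_params()].
#' @return List of arrays `dC`, `dm`, `dupsilon` congruent with the state.
#' @export
invasion_rhs <- function(state, params) {
  stopifnot(inherits(state, "invasion_state"), inherits(params, "invasion_params"))
  C <- state$C; m <- state$m; u <- state$upsilon; h <- state$spacing
  dC <- .degenerate_diffusion(C, u, params$D_C, h) + params$rho * C * (1 - C)
  if (params$chi > 0) {
    # haptotaxis flux -chi C grad(upsilon), conservative form
    dims <- dim(C)
    for (d in seq_along(dims)) {
      Cp <- .shift_along(C, d, 1L, 0L, 0); Cm <- .shift_along(C, d, -1L, 0L, 0)
      up <- .shift_along(u, d, 1L, 0L, 0); um <- .shift_along(u, d, -1L, 0L, 0)
      fp <- params$chi * (C + Cp) / 2 * (up - u)
      fm <- params$chi * (C + Cm) / 2 * (u - um)
      dC <- dC - (fp - fm) / h^2
    }
  }
  dm <- .laplacian(m, 0L, 0) / h^2 + params$delta * (C - m)
  du <- u * (1 - u) - params$gamma * m * u
  list(dC = dC, dm = dm, dupsilon = du)
}

#' Simulate the invasion system
#'
#' Explicit Euler stepping with the conservative degenerate-diffusion flux.
#' The admissible step is bounded by the fastest diffuser (the acid field has
#' unit diffusivity): `dt <= h^2 / (2 ndim max(D_C, 1))`.  After each step
#' `C` and `upsilon` are clipped to `[0, 1]` and `m` to `>= 0` (protection
#' against roundoff only; the scheme respects the bounds for admissible dt).
#' In 1D the tumor front is tracked as the rightmost grid point with
#' `C >= 0.5`, and the asymptotic front speed is the least-squares slope of
#' front position against time over the last third of the run.
#'
#' @param initial an [invasion_state()].
#' @param params an [invasion_params()].
#' @param t_end end time, `> 0`.
#' @param dt time step; must satisfy the stability bound.
#' @param sample_every sampling interval for stored states.
#' @return A list: `state` (final), `front` (data.frame t, position; 1D
#'   only), `front_speed` (1D only), `states` (sampled snapshots).
#' @export
simulate_invasion <- function(initial, params, t_end, dt, sample_every = t_end / 50) {
  stopifnot(inherits(initial, "invasion_state"), inherits(params, "invasion_params"))
  nd <- length(dim(initial$C))
  h <- initial$spacing
  dmax <- max(params$D_C, 1)
  dt_max <- h^2 / (2 * nd * dmax)
  if (dt > dt_max)
    stop(sprintf("explicit scheme unstable: dt = %g exceeds the admissible bound %g", dt, dt_max))
  st <- initial
  nstep <- ceiling(t_end / dt)
  is1d <- nd == 1
  front_t <- front_x <- numeric(0)
  states <- list()
  next_sample <- 0
  x <- seq_len(length(st$C)) * h
  for (step in seq_len(nstep)) {
    rhs <- invasion_rhs(st, params)
    st$C <- pmin(pmax(st$C + dt * rhs$dC, 0), 1)
    st$m <- pmax(st$m + dt * rhs$dm, 0)
    st$upsilon <- pmin(pmax(st$upsilon + dt * rhs$dupsilon, 0), 1)
    st$t <- step * dt
    if (is1d) {
      idx <- which(st$C >= 0.5)
      front_t <- c(front_t, st$t)
      front_x <- c(front_x, if (length(idx)) x[max(idx)] else NA_real_)
    }
    if (st$t >= next_sample) {
      states[[length(states) + 1L]] <- st
      next_sample <- next_sample + sample_every
    }
  }
  out <- list(state = st, states = states)
  if (is1d) {
    out$front <- data.frame(t = front_t, position = front_x)
    tail_idx <- front_t >= (2 / 3) * t_end & !is.na(front_x)
    out$front_speed <- if (sum(tail_idx) >= 2)
      unname(coef(lm(front_x[tail_idx] ~ front_t[tail_idx]))[2]) else NA_real_
  }
  out
}

#' Movement probabilities of the discretized single-cell walk
#'
#' Maps the 5-point explicit discretization of
#' `dC/dt = D_C lap(C) - chi div(C grad upsilon)` onto the movement
#' probabilities of a biased random walker: each move carries probability
#' `dt/h^2 (D_C + chi/4 (upsilon_ahead - upsilon_behind))` and the stay
#' probability absorbs the remainder, so the set always sums to one.  On a
#' flat matrix field all moves are equally likely; a matrix gradient biases
#' the walker up-gradient (haptotaxis).
#'
#' @param upsilon_neighborhood numeric vector of the local matrix density:
#'   `c(here, left, right)` in 1D or `c(here, left, right, down, up)` in 2D.
#' @param params an [invasion_params()].
#' @param dt time step.
#' @param spacing grid spacing.
#' @return Named numeric vector of probabilities (`stay`, then one entry per
#'   move direction), summing to 1.
#' @export
walk_probabilities <- function(upsilon_neighborhood, params, dt, spacing) {
  stopifnot(inherits(params, "invasion_params"))
  u <- upsilon_neighborhood
  if (!length(u) %in% c(3L, 5L))
    stop("upsilon_neighborhood must have 3 (1D) or 5 (2D) entries: center first")
  r <- dt / spacing^2
  if (length(u) == 3L) {
    p <- c(left = r * (params$D_C + params$chi / 4 * (u[2] - u[3])),
           right = r * (params$D_C + params$chi / 4 * (u[3] - u[2])))
  } else {
    p <- c(left = r * (params$D_C + params$chi / 4 * (u[2] - u[3])),
           right = r * (params$D_C + params$chi / 4 * (u[3] - u[2])),
           down = r * (params$D_C + params$chi / 4 * (u[4] - u[5])),
           up = r * (params$D_C + params$chi / 4 * (u[5] - u[4])))
  }
  stay <- 1 - sum(p)
  if (any(p < 0) || stay < 0)
    stop(sprintf("dt = %g too large for well-defined walk probabilities (reduce dt below ~%g)",
                 dt, spacing^2 / (2 * length(p) * max(params$D_C, 1e-12))))
  c(stay = stay, p)
}

#' Simulate an ensemble of biased random walkers
#'
#' Advances independent walkers on a 1D lattice with a frozen matrix profile
#' using [walk_probabilities()] at each site.  Used to check the
#' discrete-walk/PDE correspondence.
#'
#' @param n_walkers number of walkers.
#' @param start_index starting lattice index for all walkers.
#' @param upsilon frozen matrix profile (numeric vector).
#' @param params an [invasion_params()].
#' @param t_end,dt time horizon and step.
#' @param spacing grid spacing.
#' @return Integer vector of final lattice indices.
#' @export
simulate_walkers <- function(n_walkers, start_index, upsilon, params, t_end, dt,
                             spacing = 1) {
  n <- length(upsilon)
  # per-site move probabilities (reflecting ends)
  pl <- pr <- numeric(n)
  for (i in seq_len(n)) {
    um <- upsilon[max(i - 1, 1)]; up <- upsilon[min(i + 1, n)]
    pr_i <- walk_probabilities(c(upsilon[i], um, up), params, dt, spacing)
    pl[i] <- pr_i["left"]; pr[i] <- pr_i["right"]
  }
  pos <- rep.int(start_index, n_walkers)
  nstep <- round(t_end / dt)
  for (s in seq_len(nstep)) {
    u <- runif(n_walkers)
    left <- u < pl[pos]
    right <- !left & u < (pl + pr)[pos]
    pos <- pos - left + right
    pos[pos < 1L] <- 1L
    pos[pos > n] <- n
  }
  pos
}
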