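#' Parameters of the dynamic-carrying-capacity growth model
#'
#' Gompertz growth of the primary tumor, `dC/dt = lambda C ln(K/C)`, coupled
#' to an angiogenesis-driven carrying capacity `dK/dt = phi_stim C -
#' phi_inhib C^(2/3)` (literal form) or `dK/dt = phi_stim C - phi_inhib K
#' C^(2/3)` (the canonical K-multiplied inhibition), plus a simple
#' metastatic-emission companion model.  The default rate constants are
#' `lambda = 0.192`/day with stimulation 0.00873 and inhibition 5.85.
#'
#' The metastatic companion is a deliberately simple stand-in: new lesions
#' are emitted at rate `mu C^theta` per day and each grows by the same
#' Gompertz law from size 1 toward the fixed-point capacity; the burden `M`
#' is their summed size.
#'
#' @param lambda intrinsic Gompertz growth rate (1/day).
#' @param phi_stim angiogenesis stimulation rate.
#' @param phi_inhib angiogenesis inhibition rate.
#' @param C0,K0 initial tumor size and carrying capacity (`> 0`; units are
#'   whatever the user's C is measured in - cells or mm^3).
#' @param mu metastatic emission rate coefficient (lesions per day per
#'   `C^theta`); `0` disables the companion model.
#' @param theta metastatic emission exponent (2/3 = surface-shedding).
#' @param form `"literal"` or `"hahnfeldt"` (K-multiplied inhibition).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(lambda = 0.192, phi_stim = 0.00873, phi_inhib = 5.85,
                          C0 = 1e6, K0 = 1e6, mu = 0, theta = 2 / 3,
                          form = c("literal", "hahnfeldt")) {
  form <- match.arg(form)
  pos <- c(phi_stim = phi_stim, phi_inhib = phi_inhib, C0 = C0, K0 = K0)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("phi_stim, phi_inhib, C0 and K0 must all be positive")
  if (!is.finite(lambda) || lambda < 0)
    stop("lambda must be a positive growth rate (0 allowed for degenerate runs)")
  if (mu < 0) stop("emission rate mu must be nonnegative")
  structure(list(lambda = lambda, phi_stim = phi_stim, phi_inhib = phi_inhib,
                 C0 = C0, K0 = K0, mu = mu, theta = theta, form = form),
            class = "growth_params")
}

#' Classify the tumor growth regime from dividing/dying fractions
#'
#' With `alpha` the fraction of dividing cells and `beta` the fraction of
#' dying cells, the tumor is quiescent when `alpha == beta`, proliferative
#' when `alpha > beta` and depleting when `alpha < beta`.
#'
#' @param alpha dividing fraction in `[0, 1]`.
#' @param beta dying fraction in `[0, 1]`.
#' @return One of `"quiescent"`, `"proliferative"`, `"depleting"`.
#' @examples
#' classify_regime(0.3, 0.3)
#' classify_regime(0.5, 0.2)
#' @export
classify_regime <- function(alpha, beta) {
  if (any(c(alpha, beta) < 0) || any(c(alpha, beta) > 1))
    stop("alpha and beta must be fractions in [0, 1]")
  d <- alpha - beta
  if (d == 0) "quiescent" else if (d > 0) "proliferative" else "depleting"
}

#' Right-hand side of the carrying-capacity ODE
#'
#' Literal form: `dK/dt = phi_stim C - phi_inhib C^(2/3)`, which vanishes at
#' the fixed point `C* = (phi_inhib/phi_stim)^3` and is negative below it.
#' The `"hahnfeldt"` form multiplies the inhibition term by K.
#'
#' @param C tumor size, `>= 0`; vectorized.
#' @param params a [growth_params()].
#' @param K carrying capacity (needed by the `"hahnfeldt"` form).
#' @return `dK/dt`.
#' @export
carrying_capacity_rhs <- function(C, params, K = NULL) {
  stopifnot(inherits(params, "growth_params"))
  if (any(C < 0)) stop("C must be nonnegative")
  if (params$form == "literal")
    params$phi_stim * C - params$phi_inhib * C^(2 / 3)
  else {
    if (is.null(K)) stop("the hahnfeldt form needs the current K")
    params$phi_stim * C - params$phi_inhib * K * C^(2 / 3)
  }
}

# joint RHS of (C, K); M is handled by the closed-form cohort sum
.growth_rhs <- function(C, K, params) {
  dC <- if (C > 0 && K > 0) params$lambda * C * log(K / C) else 0
  dK <- carrying_capacity_rhs(C, params, K)
  c(dC, dK)
}

#' Simulate tumor growth with dynamic carrying capacity
#'
#' Integrates the Gompertz/carrying-capacity system with a classical
#' fixed-step 4th-order Runge-Kutta scheme (default `dt = 0.01` day), and
#' accumulates the metastatic burden from emitted lesion cohorts: a cohort of
#' `mu C^theta dt` lesions is created per step, and each lesion grows from
#' size 1 by the closed-form constant-capacity Gompertz solution toward the
#' fixed-point capacity `C* = (phi_inhib/phi_stim)^3`.
#'
#' @param params a [growth_params()].
#' @param t_end end time (days), `> 0`.
#' @param dt integrator step (days).
#' @param sample_every sample the trajectory every this many days.
#' @return A data.frame with columns `t`, `C`, `K`, `M` and, when `mu > 0`,
#'   `emission_rate` (lesions/day).
#' @examples
#' p <- growth_params(C0 = (5.85 / 0.00873)^3, K0 = (5.85 / 0.00873)^3)
#' traj <- simulate_growth(p, t_end = 1, dt = 0.01)
#' range(traj$C)  # joint fixed point: constant
#' @export
simulate_growth <- function(params, t_end, dt = 0.01, sample_every = max(dt, t_end / 1000)) {
  stopifnot(inherits(params, "growth_params"))
  if (t_end <= 0) stop("t_end must be positive")
  if (dt <= 0 || dt > t_end) stop("dt must lie in (0, t_end]")
  C <- params$C0; K <- params$K0
  nstep <- ceiling(t_end / dt)
  Kstar <- (params$phi_inhib / params$phi_stim)^3
  lam <- params$lambda

  # emission cohorts: times and sizes (number of lesions)
  em_t <- numeric(0); em_n <- numeric(0)
  sample_steps <- unique(c(0, seq(0, nstep, by = max(1, round(sample_every / dt))), nstep))
  out_t <- out_C <- out_K <- out_M <- out_E <- numeric(0)

  burden <- function(t) {
    if (length(em_t) == 0) return(0)
    age <- t - em_t
    sum(em_n * Kstar^(1 - exp(-lam * age)))
  }
  push <- function(step, t) {
    out_t <<- c(out_t, t); out_C <<- c(out_C, C); out_K <<- c(out_K, K)
    out_M <<- c(out_M, burden(t))
    out_E <<- c(out_E, params$mu * C^params$theta)
  }
  push(0, 0)
  for (step in seq_len(nstep)) {
    t0 <- (step - 1) * dt
    k1 <- .growth_rhs(C, K, params)
    k2 <- .growth_rhs(C + dt / 2 * k1[1], K + dt / 2 * k1[2], params)
    k3 <- .growth_rhs(C + dt / 2 * k2[1], K + dt / 2 * k2[2], params)
    k4 <- .growth_rhs(C + dt * k3[1], K + dt * k3[2], params)
    C <- C + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    K <- K + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    C <- max(C, 0); K <- max(K, 0)
    if (params$mu > 0) {
      em_t <- c(em_t, t0 + dt)
      em_n <- c(em_n, params$mu * C^params$theta * dt)
    }
    if (step %in% sample_steps) push(step, step * dt)
  }
  out <- data.frame(t = out_t, C = out_C, K = out_K, M = out_M)
  if (params$mu > 0) out$emission_rate <- out_E
  out
}
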