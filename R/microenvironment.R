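#' Scalar concentration field on a regular lattice
#'
#' A `scalar_field` holds a nonnegative concentration (oxygen in mmHg, drug in
#' uM) sampled on a regular 1D/2D/3D lattice, together with the lattice
#' spacing and the boundary condition used by the diffusion solver.
#'
#' @param values numeric vector, matrix or array of nonnegative concentrations.
#' @param spacing lattice spacing in micrometers (one number; the lattice is
#'   isotropic).
#' @param boundary `"no-flux"` (reflecting) or `"dirichlet"` (fixed far-field
#'   value, taken from the substrate parameters at solve time).
#' @return An object of class `scalar_field`.
#' @examples
#' f <- scalar_field(matrix(38, 50, 50), spacing = 20, boundary = "dirichlet")
#' total_mass(f)
#' @export
scalar_field <- function(values, spacing = 1, boundary = c("no-flux", "dirichlet")) {
  boundary <- match.arg(boundary)
  values <- as.array(values)
  if (!is.numeric(values)) stop("field values must be numeric")
  if (any(!is.finite(values))) stop("field values must be finite")
  if (any(values < 0)) stop("field values must be nonnegative")
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a single positive number")
  structure(list(values = values, spacing = spacing, boundary = boundary),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat("<scalar_field> ", paste(dim(x$values), collapse = " x "),
      " grid, spacing ", x$spacing, ", boundary ", x$boundary, "\n",
      "  range [", format(min(x$values)), ", ", format(max(x$values)), "]\n",
      sep = "")
  invisible(x)
}

#' Substrate transport parameters
#'
#' Diffusion, decay and per-cell uptake rates of one diffusible substrate.
#' Defaults correspond to oxygen in tissue as used by standard
#' microenvironment solvers: fast diffusion (1e5 um^2/min), a small background
#' tissue decay, an uptake of 10/min inside occupied sites, and a far-field
#' partial pressure of 38 mmHg.
#'
#' @param D diffusion coefficient (um^2/min), `>= 0`.
#' @param lambda first-order decay rate (1/min), `>= 0`.
#' @param uptake per-cell uptake rate applied at occupied lattice sites
#'   (1/min), `>= 0`.
#' @param dirichlet_value boundary concentration used when the field has a
#'   Dirichlet boundary.
#' @return An object of class `substrate_params`.
#' @export
substrate_params <- function(D = 1e5, lambda = 0.01, uptake = 10,
                             dirichlet_value = 38) {
  for (nm in c("D", "lambda", "uptake")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || !is.finite(v))
      stop(sprintf("substrate parameter '%s' must be a single nonnegative number", nm))
  }
  structure(list(D = D, lambda = lambda, uptake = uptake,
                 dirichlet_value = dirichlet_value),
            class = "substrate_params")
}

# apply the batched implicit 1D diffusion solve along dimension d of array a;
# sink (or NULL) is the congruent per-site implicit reaction term
.diffuse_along <- function(a, d, r, boundary_code, g, sink = NULL) {
  dims <- dim(a)
  nd <- length(dims)
  none <- matrix(0, 0, 0)
  if (nd == 1L) {
    s <- if (is.null(sink)) none else matrix(sink, ncol = 1L)
    m <- tridiag_diffuse(matrix(a, ncol = 1L), r, boundary_code, g, s)
    return(array(m, dims))
  }
  perm <- c(d, seq_len(nd)[-d])
  m <- matrix(aperm(a, perm), nrow = dims[d])
  s <- if (is.null(sink)) none else matrix(aperm(sink, perm), nrow = dims[d])
  m <- tridiag_diffuse(m, r, boundary_code, g, s)
  out <- array(m, dims[perm])
  aperm(out, order(perm))
}

# explicit Laplacian with ghost cells (no-flux mirrors, Dirichlet value g)
.laplacian <- function(a, boundary_code, g) {
  dims <- dim(a)
  nd <- length(dims)
  lap <- array(0, dims)
  for (d in seq_len(nd)) {
    up <- .shift_along(a, d, 1L, boundary_code, g)
    dn <- .shift_along(a, d, -1L, boundary_code, g)
    lap <- lap + up + dn - 2 * a
  }
  lap
}

# shift array a by `by` along dim d, filling the exposed edge with the ghost
.shift_along <- function(a, d, by, boundary_code, g) {
  dims <- dim(a)
  n <- dims[d]
  idx <- seq_len(n) + by
  edge <- if (by > 0) n else 1L
  idx[idx < 1L] <- if (boundary_code == 0L) 1L else NA_integer_
  idx[idx > n] <- if (boundary_code == 0L) n else NA_integer_
  args <- rep(list(quote(expr = )), length(dims))
  args[[d]] <- idx
  out <- do.call(`[`, c(list(a), args, list(drop = FALSE)))
  if (boundary_code == 1L) out[is.na(out)] <- g
  array(out, dims)
}

#' Advance a substrate field by one time step
#'
#' Integrates one step of the uptake-coupled reaction-diffusion equation
#' \deqn{\partial u/\partial t = D \nabla^2 u - \lambda u - \sum_i U_i u}
#' where the per-cell uptake sink acts only at lattice sites flagged occupied.
#' The default scheme is backward Euler with dimension-wise operator splitting
#' (one tridiagonal solve per grid line); the decay/uptake reaction is folded
#' implicitly into the diagonal of the first directional solve so that even
#' stiff per-cell uptake (`dt * U >> 1`) stays balanced against diffusive
#' resupply within the step.  The scheme is unconditionally stable and
#' positivity preserving.  `method = "explicit"` selects a forward Euler
#' cross-check scheme which enforces the stability bound
#' `dt <= h^2 / (2 * ndim * D)`.
#'
#' @param field a [scalar_field()].
#' @param params a [substrate_params()].
#' @param occupancy optional logical/0-1 array congruent with the field; sites
#'   where it is 1 take up substrate at rate `params$uptake`.  `NULL` means no
#'   uptake anywhere.
#' @param dt time step in minutes (`> 0`).
#' @param method `"implicit"` (default) or `"explicit"`.
#' @return The advanced `scalar_field`.
#' @examples
#' f <- scalar_field(rep(1, 100), spacing = 1)
#' f2 <- step_substrate(f, substrate_params(D = 10, lambda = 0, uptake = 0), dt = 1)
#' max(abs(f2$values - f$values))  # uniform field is a fixed point
#' @export
step_substrate <- function(field, params, occupancy = NULL, dt,
                           method = c("implicit", "explicit")) {
  method <- match.arg(method)
  stopifnot(inherits(field, "scalar_field"), inherits(params, "substrate_params"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be a single positive number")
  u <- field$values
  dims <- dim(u)
  if (is.null(occupancy)) {
    occ <- 0
  } else {
    occ <- as.array(occupancy) * 1
    if (!identical(dim(occ), dims))
      stop(sprintf("occupancy grid (%s) is not congruent with the field (%s)",
                   paste(dim(occ), collapse = "x"), paste(dims, collapse = "x")))
  }
  h <- field$spacing
  bcode <- if (field$boundary == "dirichlet") 1L else 0L
  g <- params$dirichlet_value
  nd <- length(dims)
  if (method == "implicit") {
    r <- params$D * dt / h^2
    sink <- dt * (params$lambda + params$uptake * occ)
    if (length(sink) == 1) sink <- array(sink, dims)
    # reaction folded into the first directional solve (keeps strong uptake
    # coupled to diffusive resupply); remaining dimensions diffuse plainly
    u <- .diffuse_along(u, 1L, r, bcode, g, sink)
    if (nd > 1 && r > 0)
      for (d in 2:nd) u <- .diffuse_along(u, d, r, bcode, g)
  } else {
    if (params$D > 0) {
      dt_max <- h^2 / (2 * nd * params$D)
      if (dt > dt_max)
        stop(sprintf("explicit scheme unstable: dt = %g exceeds the admissible bound %g min",
                     dt, dt_max))
    }
    u <- u + dt * (params$D / h^2) * .laplacian(u, bcode, g) -
      dt * (params$lambda + params$uptake * occ) * u
    u[u < 0] <- 0
  }
  field$values <- u
  field
}

#' Solve a substrate field to its quasi-static steady state
#'
#' Solves `(lambda + U occ) u = D lap(u)` (with the field's boundary
#' condition) by warm-started red-black successive over-relaxation, starting
#' from the field's current values.  In the coupled tumor simulation the
#' substrate fields relax within minutes while the automaton advances in
#' 6-minute steps, so the fields are equilibrated quasi-statically rather
#' than time-stepped.  2D grids only.
#'
#' @inheritParams step_substrate
#' @param omega SOR relaxation factor in `(0, 2)`.
#' @param tol convergence tolerance on the maximum update, relative to the
#'   boundary value.
#' @param max_sweeps sweep budget.
#' @return The equilibrated `scalar_field`, with attributes `sweeps` and
#'   `max_change` on the values.
#' @export
solve_steady_field <- function(field, params, occupancy = NULL,
                               omega = 1.9, tol = 1e-8, max_sweeps = 10000) {
  stopifnot(inherits(field, "scalar_field"), inherits(params, "substrate_params"))
  dims <- dim(field$values)
  if (length(dims) != 2) stop("steady-state solve supports 2D grids only")
  occ <- if (is.null(occupancy)) matrix(0, dims[1], dims[2]) else {
    o <- as.matrix(occupancy) * 1
    if (!identical(dim(o), dims)) stop("occupancy grid is not congruent with the field")
    o
  }
  bcode <- if (field$boundary == "dirichlet") 1L else 0L
  res <- sor_steady_cpp(field$values, occ, params$D / field$spacing^2,
                        params$lambda, params$uptake, bcode,
                        params$dirichlet_value, omega, tol, max_sweeps)
  field$values <- res$values
  attr(field$values, "sweeps") <- res$sweeps
  attr(field$values, "max_change") <- res$max_change
  field
}

#' Total substrate mass of a field
#'
#' Sum of all concentrations times the lattice cell volume `spacing^ndim`.
#'
#' @param field a [scalar_field()].
#' @return A single number.
#' @export
total_mass <- function(field) {
  stopifnot(inherits(field, "scalar_field"))
  sum(field$values) * field$spacing^length(dim(field$values))
}

#' Write a 2D field as CSV (columns x, y, value)
#'
#' @param field a [scalar_field()] with a 2D grid.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  v <- field$values
  if (length(dim(v)) != 2) stop("CSV export expects a 2D field")
  df <- data.frame(x = rep(seq_len(nrow(v)), times = ncol(v)),
                   y = rep(seq_len(ncol(v)), each = nrow(v)),
                   value = as.vector(v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 2D field written by [write_field_csv()]
#'
#' @param path CSV file path.
#' @param spacing,boundary passed to [scalar_field()].
#' @return A `scalar_field`.
#' @export
read_field_csv <- function(path, spacing = 1, boundary = "no-flux") {
  df <- read.csv(path)
  nr <- max(df$x); nc <- max(df$y)
  v <- matrix(NA_real_, nr, nc)
  v[cbind(df$x, df$y)] <- df$value
  scalar_field(v, spacing = spacing, boundary = boundary)
}

#' Write a 2D field as a normalized grayscale TIFF
#'
#' Intensities are rescaled to `[0, 1]` by the field maximum (recorded in the
#' return value); the CSV writer is the lossless serialization.
#'
#' @param field a [scalar_field()] with a 2D grid.
#' @param path output file path.
#' @return The scale factor used, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "scalar_field"))
  v <- field$values
  if (length(dim(v)) != 2) stop("TIFF export expects a 2D field")
  mx <- max(v)
  tiff::writeTIFF(if (mx > 0) v / mx else v, path)
  invisible(mx)
}
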