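#' Organ-target table for the metastasis simulation
#'
#' The default table carries the organ-involvement percentages of the SCLC
#' autopsy cohort the simulation endpoint is constrained to: liver 20.3%,
#' bone 18.3%, brain 15.5%, lung 10.0%, adrenal 6.0%; the residual 29.9%
#' stays at the primary site.  Anchor coordinates are schematic layout data
#' for the planar simulation, not science.
#'
#' @param organs character vector of organ names.
#' @param fractions target involvement in percent, `>= 0`; together with the
#'   primary residual they must total 100.
#' @param x,y planar anchor coordinates, one per organ.
#' @param add_primary_residual add a `primary` row absorbing `100 -
#'   sum(fractions)`?
#' @return A data.frame of class `organ_table` with columns `organ`,
#'   `fraction`, `x`, `y`.
#' @examples
#' organ_table()
#' @export
organ_table <- function(organs = c("liver", "bone", "brain", "lung", "adrenal"),
                        fractions = c(20.3, 18.3, 15.5, 10.0, 6.0),
                        x = c(8, -8, 0, 6, -6),
                        y = c(4, 4, 10, -6, -6),
                        add_primary_residual = TRUE) {
  if (length(organs) == 0) stop("organ table must have at least one entry")
  if (length(fractions) != length(organs)) stop("one fraction per organ required")
  if (any(fractions < 0)) stop("fractions must be nonnegative")
  tab <- data.frame(organ = as.character(organs), fraction = fractions,
                    x = x, y = y, stringsAsFactors = FALSE)
  if (add_primary_residual) {
    resid <- 100 - sum(fractions)
    if (resid < -1e-9) stop("fractions exceed 100%")
    tab <- rbind(tab, data.frame(organ = "primary", fraction = resid, x = 0, y = 0))
  }
  if (abs(sum(tab$fraction) - 100) > 1e-9)
    stop("fractions (with residual) must sum to 100")
  class(tab) <- c("organ_table", "data.frame")
  tab
}

#' Read or write an organ table as CSV (columns organ, fraction, x, y)
#'
#' @param path CSV file path.
#' @param table an [organ_table()] (the primary-residual row is written too
#'   and re-derived on read).
#' @return `read_organ_table()`: an `organ_table`; `write_organ_table()`:
#'   `path`, invisibly.
#' @export
read_organ_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$organ != "primary", , drop = FALSE]
  organ_table(df$organ, df$fraction, df$x, df$y)
}

#' @rdname read_organ_table
#' @export
write_organ_table <- function(table, path) {
  stopifnot(inherits(table, "organ_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apportion agents to organs by largest remainder
#'
#' Deterministic largest-remainder apportionment of `n_agents` over the
#' table fractions: every organ gets the floor of `n_agents * fraction /
#' 100`, and remaining agents go to the largest fractional remainders, ties
#' broken by descending fraction and then organ-name order.
#'
#' @param n_agents number of agents, `>= 1`.
#' @param table an [organ_table()].
#' @return Named integer vector of per-organ counts summing to `n_agents`.
#' @examples
#' allocate_phenotypes(1000, organ_table())
#' @export
allocate_phenotypes <- function(n_agents, table = organ_table()) {
  if (!inherits(table, "organ_table") || nrow(table) == 0)
    stop("a nonempty organ_table is required")
  if (n_agents < 1) stop("n_agents must be at least 1")
  quota <- n_agents * table$fraction / 100
  counts <- floor(quota)
  short <- n_agents - sum(counts)
  if (short > 0) {
    rem <- quota - counts
    ord <- order(-rem, -table$fraction, table$organ)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(counts), table$organ)
}

#' Advance metastasis agents by one step
#'
#' Un-arrived agents move by (i) attraction toward the centroid of their
#' phenotype cluster scaled by `clustering_strength`, (ii) drift toward
#' their target-organ anchor scaled by `migration_rate`, and (iii) isotropic
#' Gaussian noise; an agent within `capture_radius` of its anchor arrives
#' and stops.
#'
#' @param agents data.frame with columns `organ`, `x`, `y`, `arrived`.
#' @param table an [organ_table()].
#' @param clustering_strength fraction of the centroid offset applied per
#'   step, `>= 0`.
#' @param migration_rate fraction of the anchor offset applied per step,
#'   `>= 0`.
#' @param noise_sd standard deviation of the positional noise.
#' @param capture_radius arrival distance.
#' @return Updated agents data.frame.
#' @export
step_agents <- function(agents, table, clustering_strength = 0.05,
                        migration_rate = 0.05, noise_sd = 0.2,
                        capture_radius = 1) {
  if (any(c(clustering_strength, migration_rate, noise_sd) < 0))
    stop("step parameters must be nonnegative")
  live <- !agents$arrived
  if (!any(live)) return(agents)
  anchor <- table[match(agents$organ, table$organ), c("x", "y")]
  # phenotype centroids over all agents of the same label
  cx <- tapply(agents$x, agents$organ, mean)[agents$organ]
  cy <- tapply(agents$y, agents$organ, mean)[agents$organ]
  nlive <- sum(live)
  agents$x[live] <- agents$x[live] +
    clustering_strength * (cx[live] - agents$x[live]) +
    migration_rate * (anchor$x[live] - agents$x[live]) +
    if (noise_sd > 0) rnorm(nlive, 0, noise_sd) else 0
  agents$y[live] <- agents$y[live] +
    clustering_strength * (cy[live] - agents$y[live]) +
    migration_rate * (anchor$y[live] - agents$y[live]) +
    if (noise_sd > 0) rnorm(nlive, 0, noise_sd) else 0
  d2 <- (agents$x - anchor$x)^2 + (agents$y - anchor$y)^2
  agents$arrived <- agents$arrived | d2 <= capture_radius^2
  agents
}

#' Run the endpoint-constrained metastasis redistribution simulation
#'
#' All agents start at the primary site; each carries a metastatic phenotype
#' assigned by [allocate_phenotypes()], so the final per-organ fractions are
#' fixed by construction while the intermediate clustering-and-migration
#' dynamics are illustrative.  Agents still in transit after `max_steps` are
#' forcibly placed at their anchor (with a warning).
#'
#' @param n number of agents.
#' @param table an [organ_table()].
#' @param seed RNG seed.
#' @param max_steps step budget.
#' @param record_every keep a trajectory snapshot every this many steps
#'   (`Inf` to keep none).
#' @param ... passed to [step_agents()].
#' @return A `metastasis_run` list: `agents` (final), `summary` (from
#'   [finalize_metastasis()]), `trajectory` (list of agent snapshots),
#'   `table`, `n_steps`.
#' @export
run_metastasis_simulation <- function(n = 1000, table = organ_table(),
                                      seed = NULL, max_steps = 400,
                                      record_every = Inf, ...) {
  if (!is.null(seed)) set.seed(seed)
  counts <- allocate_phenotypes(n, table)
  primary <- table[table$organ == "primary", , drop = FALSE]
  p0 <- if (nrow(primary)) c(primary$x[1], primary$y[1]) else c(0, 0)
  agents <- data.frame(
    organ = rep(names(counts), counts),
    x = p0[1] + rnorm(n, 0, 0.1), y = p0[2] + rnorm(n, 0, 0.1),
    arrived = rep(names(counts), counts) == "primary",
    stringsAsFactors = FALSE)
  trajectory <- list()
  step <- 0L
  while (any(!agents$arrived) && step < max_steps) {
    step <- step + 1L
    agents <- step_agents(agents, table, ...)
    if (step %% record_every == 0)
      trajectory[[length(trajectory) + 1L]] <- agents
  }
  if (any(!agents$arrived)) {
    warning(sprintf("%d agents had not arrived after %d steps; forcing arrival",
                    sum(!agents$arrived), max_steps))
    anchor <- table[match(agents$organ, table$organ), c("x", "y")]
    live <- !agents$arrived
    agents$x[live] <- anchor$x[live]; agents$y[live] <- anchor$y[live]
    agents$arrived <- TRUE
  }
  structure(list(agents = agents, summary = finalize_metastasis(agents, table),
                 trajectory = trajectory, table = table, n_steps = step),
            class = "metastasis_run")
}

#' Final per-organ counts and fractions
#'
#' The endpoint constraint makes the reported fractions equal the
#' apportionment fractions exactly for every seed.
#'
#' @param agents final agents data.frame (all arrived).
#' @param table an [organ_table()].
#' @return data.frame with columns `organ`, `count`, `fraction` (percent),
#'   `target_fraction`.
#' @export
finalize_metastasis <- function(agents, table = organ_table()) {
  counts <- table(factor(agents$organ, levels = table$organ))
  data.frame(organ = table$organ,
             count = as.integer(counts),
             fraction = 100 * as.integer(counts) / nrow(agents),
             target_fraction = table$fraction,
             row.names = NULL)
}

#' @export
print.metastasis_run <- function(x, ...) {
  cat("<metastasis_run> ", nrow(x$agents), " agents, ", x$n_steps, " steps\n", sep = "")
  print(x$summary)
  invisible(x)
}

# round to one decimal, ties away from zero (half-up), as clinical tables do
.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort distant-metastasis rate
#'
#' Percentage of patients with distant metastases in a cohort, rounded
#' half-up to one decimal: with the default counts (152 of 251) this is
#' 60.6%.
#'
#' @param n_metastatic number of patients with distant metastases.
#' @param n_total cohort size.
#' @return Percentage (one decimal).
#' @examples
#' cohort_involvement_rate()  # 60.6
#' @export
cohort_involvement_rate <- function(n_metastatic = 152, n_total = 251) {
  if (n_total <= 0 || n_metastatic < 0 || n_metastatic > n_total)
    stop("need 0 <= n_metastatic <= n_total with n_total > 0")
  .round_half_up(100 * n_metastatic / n_total, 1)
}

#' Mean within-phenotype pairwise distance
#'
#' Clustering statistic used to characterize the transient dynamics: the
#' mean over phenotypes of the mean pairwise distance between agents of that
#' phenotype.
#'
#' @param agents agents data.frame.
#' @return A single number.
#' @export
within_phenotype_distance <- function(agents) {
  groups <- split(seq_len(nrow(agents)), agents$organ)
  d <- vapply(groups, function(idx) {
    if (length(idx) < 2) return(NA_real_)
    mean(stats::dist(cbind(agents$x[idx], agents$y[idx])))
  }, numeric(1))
  mean(d, na.rm = TRUE)
}
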