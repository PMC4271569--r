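# Modified multi-parameter sensitivity analysis (m-MPSA).
#
# For each parameter of a decoupled sub-problem: sample candidate values
# uniformly in its range, substitute them one at a time into an anchor
# solution, split the candidates into acceptable/unacceptable by the Cr rule
# (Cr = cr_multiplier x best fitness), and score the parameter by the Pearson
# correlation of the acceptable and unacceptable cumulative-frequency curves.
# Low scores mean the split separates the curves, i.e. the parameter is
# influential ("sensitive").

#' m-MPSA settings
#'
#' @param n_samples Uniform samples drawn per parameter (default 500).
#' @param cr_multiplier Acceptability threshold multiplier: a candidate is
#'   acceptable when its fitness is at most `cr_multiplier` times the best
#'   sampled fitness (default 3).
#' @param ccr_initial Sensitivity-classification threshold. `NULL` (default)
#'   sets it from the first report as the 25th percentile of the sensitivity
#'   distribution; a number fixes it absolutely.
#' @param epsilon Increment added to CCR after each identification phase
#'   (default 0.01); CCR is capped at 1 since sensitivities are correlations.
#' @param mode `"one_at_a_time"` (default: vary one parameter, others held at
#'   the anchor) or `"joint"` (classic MPSA: all parameters resampled
#'   jointly).
#' @return A list of class `sensitivity_config`.
#' @export
sensitivity_config <- function(n_samples = 500, cr_multiplier = 3,
                               ccr_initial = NULL, epsilon = 0.01,
                               mode = c("one_at_a_time", "joint")) {
  stopifnot(n_samples >= 2, cr_multiplier > 1, epsilon > 0,
            is.null(ccr_initial) || (ccr_initial >= -1 && ccr_initial <= 1))
  structure(list(n_samples = as.integer(n_samples),
                 cr_multiplier = cr_multiplier, ccr_initial = ccr_initial,
                 epsilon = epsilon, mode = match.arg(mode)),
            class = "sensitivity_config")
}

#' Uniform parameter sampling
#'
#' @param range Length-2 interval `c(lo, hi)` with `lo <= hi`.
#' @param n Number of draws.
#' @param seed Optional seed for deterministic draws.
#' @return `n` i.i.d. uniform values; a degenerate interval (`lo == hi`)
#'   returns `n` copies of the point with attribute `degenerate = TRUE`.
#' @export
sample_parameter <- function(range, n, seed = NULL) {
  stopifnot(length(range) == 2, range[1] <= range[2], n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (range[1] == range[2])
    return(structure(rep(range[1], n), degenerate = TRUE))
  runif(n, range[1], range[2])
}

#' Split sampled candidates into acceptable and unacceptable sets
#'
#' The acceptability threshold is `Cr = cr_multiplier * min(fitnesses)`; a
#' candidate is acceptable when its fitness is `<= Cr`, so the best candidate
#' is always acceptable.
#'
#' @param fitnesses Non-negative finite fitness values.
#' @param cr_multiplier Multiplier (> 1) on the best fitness.
#' @return A list with logical `acceptable` mask and the threshold `cr`.
#' @export
split_acceptable <- function(fitnesses, cr_multiplier = 3) {
  stopifnot(length(fitnesses) >= 1, all(is.finite(fitnesses)),
            all(fitnesses >= 0), cr_multiplier > 1)
  cr <- cr_multiplier * min(fitnesses)
  list(acceptable = fitnesses <= cr, cr = cr)
}

#' Sensitivity score of one parameter from its acceptable/unacceptable split
#'
#' Builds the common grid of all sampled values and the cumulative-frequency
#' curves `CF_acc(v)` (fraction of acceptable samples <= v) and `CF_unacc(v)`;
#' the score is the Pearson correlation of the two curves over the grid.
#' Near-identical curves (score near 1) mean the parameter's value does not
#' decide acceptability, i.e. the parameter is insensitive. Degenerate splits
#' (all candidates acceptable or unacceptable, or a zero-variance curve)
#' score the defined insensitive value 1.
#'
#' @param values Sampled parameter values.
#' @param mask Logical acceptability mask of the same length.
#' @return Sensitivity score in \[-1, 1\].
#' @export
sensitivity_of_parameter <- function(values, mask) {
  stopifnot(length(values) == length(mask), length(values) >= 2)
  n_acc <- sum(mask)
  if (n_acc == 0L || n_acc == length(values)) return(1)
  grid <- sort(values)
  cf_acc <- ecdf(values[mask])(grid)
  cf_un <- ecdf(values[!mask])(grid)
  if (sd(cf_acc) == 0 || sd(cf_un) == 0) return(1)
  cor(cf_acc, cf_un)
}

#' Classify parameters as sensitive or insensitive
#'
#' A parameter is sensitive iff its sensitivity score is at most `ccr`;
#' raising `ccr` can only move parameters into the sensitive class.
#'
#' @param report A `sensitivity_report` (or numeric vector of scores).
#' @param ccr Classification threshold.
#' @return Logical vector, `TRUE` = sensitive, named by parameter.
#' @export
classify_parameters <- function(report, ccr) {
  scores <- if (inherits(report, "sensitivity_report"))
    report$sensitivity else report
  setNames(scores <= ccr, names(scores))
}

#' Increment the CCR classification threshold
#'
#' `CCR` grows by `epsilon` after every identification phase so that all
#' parameters are eventually classified sensitive; it is capped at 1, the
#' maximum attainable sensitivity score.
#'
#' @param ccr Current threshold.
#' @param epsilon Increment (default 0.01).
#' @return `min(ccr + epsilon, 1)`.
#' @export
update_ccr <- function(ccr, epsilon = 0.01) min(ccr + epsilon, 1)

#' Run m-MPSA on a decoupled sub-problem
#'
#' For each parameter of the sub-problem (alpha, beta, g1..gN, h1..hN):
#' draw `cfg$n_samples` uniform values in its sampling range, substitute each
#' into the anchor vector (one at a time by default), evaluate the candidate
#' fitnesses via the sub-problem objective, split by the Cr rule and score by
#' [sensitivity_of_parameter()]. Candidates whose simulation diverges are
#' assigned the worst finite sampled fitness.
#'
#' @param problem A [decoupled_problem()].
#' @param anchor Feasible parameter vector of length 2 + 2N (normally the
#'   optimizer's current global best).
#' @param cfg A [sensitivity_config()].
#' @param seed Seed making the report deterministic.
#' @param ranges Optional 2 x P matrix of per-parameter sampling intervals
#'   (defaults to the legal ranges).
#' @param ccr Classification threshold; `NULL` uses `cfg$ccr_initial`, or the
#'   25th percentile of this report's scores when that is also `NULL`.
#' @return A `sensitivity_report`: data frame with one row per parameter
#'   (`parameter`, `role`, `target`, `source`, `sensitivity`, `rank`,
#'   `sensitive`) plus attribute `ccr_used`.
#' @export
mpsa <- function(problem, anchor, cfg = sensitivity_config(), seed = 1L,
                 ranges = NULL, ccr = NULL) {
  P <- length(anchor)
  stopifnot(P == 2 + 2 * problem$N)
  if (is.null(ranges)) ranges <- problem$legal_ranges
  stopifnot(ncol(ranges) == P)
  if (!is.null(seed)) set.seed(seed)
  scores <- numeric(P)
  for (p in seq_len(P)) {
    vals <- runif(cfg$n_samples, ranges[1, p], ranges[2, p])
    cand <- matrix(rep(anchor, each = cfg$n_samples), nrow = cfg$n_samples)
    if (cfg$mode == "joint")
      for (q in seq_len(P))
        cand[, q] <- runif(cfg$n_samples, ranges[1, q], ranges[2, q])
    cand[, p] <- vals
    fit <- problem$eval(cand)
    bad <- !is.finite(fit)
    if (any(bad)) fit[bad] <- max(fit[!bad], 0)
    sp <- split_acceptable(fit, cfg$cr_multiplier)
    scores[p] <- sensitivity_of_parameter(vals, sp$acceptable)
  }
  if (is.null(ccr)) ccr <- cfg$ccr_initial
  if (is.null(ccr)) ccr <- unname(quantile(scores, 0.25))
  report <- data.frame(
    parameter = param_names(problem$N, problem$gene),
    role = param_roles(problem$N),
    target = problem$gene,
    source = param_sources(problem$N),
    sensitivity = scores,
    rank = rank(scores, ties.method = "first"),
    sensitive = scores <= ccr
  )
  attr(report, "ccr_used") <- ccr
  class(report) <- c("sensitivity_report", class(report))
  report
}

# Parameter vector layout of a sub-problem: c(alpha, beta, g[1..N], h[1..N]).
param_roles <- function(N) c("alpha", "beta", rep("g", N), rep("h", N))
param_sources <- function(N) c(NA, NA, seq_len(N), seq_len(N))
param_names <- function(N, gene) {
  c(paste0("alpha", gene), paste0("beta", gene),
    paste0("g", gene, ",", seq_len(N)), paste0("h", gene, ",", seq_len(N)))
}

#' Mean sensitivity of a report
#'
#' @param report A `sensitivity_report`.
#' @return Mean of the per-parameter sensitivity scores.
#' @export
mean_sensitivity <- function(report) mean(report$sensitivity)
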