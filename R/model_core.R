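# S-system model representation, simulation and objective functions.
#
# Each gene i of an N-gene S-system obeys
#   dXi/dt = alpha_i * prod_j Xj^g_ij  -  beta_i * prod_j Xj^h_ij
# with rate constants alpha, beta in [0, 10] and kinetic orders g, h in
# [-3, 3]. The sign of a kinetic order encodes activation/repression; a zero
# kinetic order means no interaction.

ALPHA_RANGE <- c(0, 10)
KINETIC_RANGE <- c(-3, 3)

#' Per-gene S-system parameters
#'
#' Bundles the synthesis/degradation rate constants and kinetic-order vectors
#' of one gene in an N-gene S-system. Ranges are enforced at construction:
#' rate constants must lie in \[0, 10\] and kinetic orders in \[-3, 3\].
#'
#' @param alpha,beta Non-negative rate constants of the synthesis and
#'   degradation power-law terms, each in \[0, 10\].
#' @param g,h Numeric vectors of length N of kinetic orders (exponents) of
#'   the synthesis and degradation terms, each entry in \[-3, 3\].
#' @param gene_index 1-based index of the gene within its network.
#' @param check_ranges Enforce the canonical search ranges at construction
#'   (default). Disable only for reference systems whose published rate
#'   constants exceed the search range (the 5-gene benchmark's first
#'   synthesis rate is 15).
#' @return An object of class `gene_parameters`.
#' @examples
#' gp <- gene_parameters(alpha = 10, beta = 10, g = c(0, 2), h = c(0, 1),
#'                       gene_index = 2)
#' gene_derivative(gp, state = c(1, 0.5))
#' @export
gene_parameters <- function(alpha, beta, g, h, gene_index = 1L,
                            check_ranges = TRUE) {
  stopifnot(length(alpha) == 1L, length(beta) == 1L,
            length(g) == length(h), length(g) >= 1L)
  if (!is.finite(alpha) || !is.finite(beta) || alpha < 0 || beta < 0)
    stop("rate constants must be finite and non-negative")
  if (any(!is.finite(g)) || any(!is.finite(h)))
    stop("kinetic orders must be finite")
  if (check_ranges) {
    if (alpha > ALPHA_RANGE[2] || beta > ALPHA_RANGE[2])
      stop("rate constants must lie in [", ALPHA_RANGE[1], ", ",
           ALPHA_RANGE[2], "]")
    if (any(g < KINETIC_RANGE[1] | g > KINETIC_RANGE[2]) ||
        any(h < KINETIC_RANGE[1] | h > KINETIC_RANGE[2]))
      stop("kinetic orders must lie in [", KINETIC_RANGE[1], ", ",
           KINETIC_RANGE[2], "]")
  }
  structure(list(gene_index = as.integer(gene_index),
                 alpha = as.numeric(alpha), beta = as.numeric(beta),
                 g = as.numeric(g), h = as.numeric(h)),
            class = "gene_parameters")
}

#' Assemble an S-system network from per-gene parameters
#'
#' @param genes List of N [gene_parameters()] objects, all of dimension N,
#'   ordered by gene index.
#' @param names Character vector of N gene labels (default `X1..XN`).
#' @return An object of class `ssystem` storing `alpha`/`beta` vectors and
#'   the N x N kinetic-order matrices `G` and `H` (row i = regulators of
#'   gene i).
#' @export
s_system <- function(genes, names = NULL) {
  N <- length(genes)
  stopifnot(N >= 1L, all(vapply(genes, inherits, TRUE, "gene_parameters")))
  if (any(vapply(genes, function(gp) length(gp$g), 1L) != N))
    stop("every gene must have kinetic-order vectors of length N = ", N)
  idx <- vapply(genes, `[[`, 1L, "gene_index")
  if (!identical(sort(idx), seq_len(N)))
    stop("gene_index values must be 1..N without gaps")
  genes <- genes[order(idx)]
  if (is.null(names)) names <- paste0("X", seq_len(N))
  stopifnot(length(names) == N)
  net <- list(
    names = as.character(names),
    alpha = vapply(genes, `[[`, 1, "alpha"),
    beta = vapply(genes, `[[`, 1, "beta"),
    G = do.call(rbind, lapply(genes, `[[`, "g")),
    H = do.call(rbind, lapply(genes, `[[`, "h"))
  )
  dimnames(net$G) <- dimnames(net$H) <- list(net$names, net$names)
  structure(net, class = "ssystem")
}

#' @export
print.ssystem <- function(x, ...) {
  cat("S-system network with", length(x$names), "genes\n")
  cat(format_equations(x), sep = "\n")
  invisible(x)
}

n_genes <- function(net) length(net$names)

#' Extract one gene's parameters from a network
#'
#' @param net An `ssystem` network.
#' @param i Gene index.
#' @return A [gene_parameters()] object.
#' @export
network_gene <- function(net, i) {
  gene_parameters(net$alpha[i], net$beta[i], net$G[i, ], net$H[i, ],
                  gene_index = i, check_ranges = FALSE)
}

#' Render a network as power-law rate equations
#'
#' Produces one string per gene, e.g.
#' `"X1' = 15.0*X3*X5^-0.1 - 10.0*X1^2.0"`. Zero kinetic orders are omitted;
#' unit exponents are written without `^`.
#'
#' @param net An `ssystem` network.
#' @param digits Number of decimal places for coefficients and exponents.
#' @return Character vector of N equations.
#' @export
format_equations <- function(net, digits = 1) {
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  term <- function(rate, orders) {
    if (rate == 0) return("0")
    parts <- fmt(rate)
    for (j in which(orders != 0)) {
      e <- orders[j]
      parts <- c(parts,
                 if (e == 1) net$names[j]
                 else paste0(net$names[j], "^", fmt(e)))
    }
    paste(parts, collapse = "*")
  }
  vapply(seq_along(net$names), function(i) {
    paste0(net$names[i], "' = ", term(net$alpha[i], net$G[i, ]),
           " - ", term(net$beta[i], net$H[i, ]))
  }, character(1))
}

#' Time-series expression profile
#'
#' A T x N matrix of non-negative gene concentrations with strictly
#' increasing time stamps; the container consumed by all decoupled
#' estimation routines.
#'
#' @param values Numeric T x N matrix, all entries >= 0, T >= 2.
#' @param times Strictly increasing numeric vector of T time stamps.
#' @param names N gene labels (defaults to the matrix column names or
#'   `X1..XN`).
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(values, times, names = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("a profile needs at least 2 time points")
  if (length(times) != nrow(values))
    stop("times must have one entry per profile row")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  if (is.null(names))
    names <- if (!is.null(colnames(values))) colnames(values)
             else paste0("X", seq_len(ncol(values)))
  stopifnot(length(names) == ncol(values))
  colnames(values) <- names
  structure(list(values = values, times = as.numeric(times),
                 names = as.character(names)),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("Expression profile:", nrow(x$values), "time points x",
      ncol(x$values), "genes, t in [", x$times[1], ",",
      x$times[length(x$times)], "]\n")
  print(head(x$values, 3))
  invisible(x)
}

#' @export
plot.expression_profile <- function(x, ...) {
  graphics::matplot(x$times, x$values, type = "l", lty = 1,
                    xlab = "time", ylab = "concentration", ...)
  graphics::legend("topright", legend = x$names, lty = 1,
                   col = seq_along(x$names), cex = 0.8, bty = "n")
  invisible(x)
}

#' Integration settings for the fixed-step simulator
#'
#' The package integrates S-systems with a fixed-step 4th-order Runge-Kutta
#' scheme. States are clamped from below at `state_floor` before the power
#' laws are applied (negative bases with fractional exponents are undefined)
#' and a state above `overflow_ceiling` signals divergence.
#'
#' @param dt Internal RK4 step size (time units).
#' @param state_floor Lower clamp applied to states before power laws.
#' @param overflow_ceiling State magnitude treated as divergence.
#' @return A list of class `sim_control`.
#' @export
sim_control <- function(dt = 0.01, state_floor = 1e-6,
                        overflow_ceiling = 1e6) {
  stopifnot(dt > 0, state_floor > 0, overflow_ceiling > state_floor)
  structure(list(dt = dt, state_floor = state_floor,
                 overflow_ceiling = overflow_ceiling),
            class = "sim_control")
}

#' S-system rate of change for one gene
#'
#' Evaluates `alpha * prod_j state[j]^g[j] - beta * prod_j state[j]^h[j]`.
#'
#' @param params A [gene_parameters()] object.
#' @param state Numeric vector of N current concentrations (clamped from
#'   below at `state_floor`).
#' @param state_floor Lower clamp for the power-law bases.
#' @return The scalar derivative dXi/dt.
#' @export
gene_derivative <- function(params, state, state_floor = 1e-6) {
  stopifnot(length(state) == length(params$g))
  x <- pmax(state, state_floor)
  rate <- params$alpha * prod(x^params$g) - params$beta * prod(x^params$h)
  if (!is.finite(rate))
    stop("numeric overflow evaluating the rate of gene ", params$gene_index)
  rate
}

# Build times of the recorded samples for a steps/dt specification.
sample_times <- function(n_steps, dt_sample) seq(0, n_steps * dt_sample,
                                                 by = dt_sample)

#' Simulate a coupled S-system network
#'
#' Fixed-step RK4 integration of the full N-gene system, recording the state
#' at each requested sampling time (the internal step subdivides each
#' sampling interval).
#'
#' @param net An `ssystem` network.
#' @param x0 Positive initial state vector of length N.
#' @param n_steps Number of recorded steps after the initial state; the
#'   returned profile has `n_steps + 1` rows.
#' @param dt_sample Spacing of recorded samples (time units).
#' @param control A [sim_control()] list.
#' @return An [expression_profile()].
#' @export
simulate_network <- function(net, x0, n_steps = 30, dt_sample = 0.1,
                             control = sim_control()) {
  stopifnot(inherits(net, "ssystem"), length(x0) == n_genes(net),
            all(x0 > 0), n_steps >= 1)
  times <- sample_times(n_steps, dt_sample)
  vals <- cpp_simulate_network(net$alpha, net$beta, net$G, net$H,
                               as.numeric(x0), times, control$dt,
                               control$state_floor, control$overflow_ceiling)
  expression_profile(vals, times, net$names)
}

# Precompute the decoupled integration grid for gene `gene` of `observed`:
# log off-target states interpolated on the half-step refinement of the
# internal RK4 grid. Shared by every candidate evaluation of a sub-problem.
decoupled_grid <- function(observed, control = sim_control()) {
  times <- observed$times
  T <- length(times)
  spans <- diff(times)
  m <- pmax(1L, as.integer(ceiling(spans / control$dt - 1e-9)))
  hsteps <- spans / m
  # stage times: start, mid, end of each substep; consecutive substeps share
  # endpoints, so each substep contributes rows (2s, 2s+1, 2s+2) of the grid
  grid_times <- unlist(lapply(seq_len(T - 1L), function(k) {
    t0 <- times[k]
    seq(0L, 2L * m[k] - 1L) * (hsteps[k] / 2) + t0
  }))
  grid_times <- c(grid_times, times[T])
  vals <- apply(observed$values, 2L, function(col)
    approx(times, col, xout = grid_times, rule = 2)$y)
  L <- log(pmax(vals, control$state_floor))
  list(L = L, m = m, hsteps = hsteps)
}

#' Simulate one gene with the others clamped to observations (decoupling)
#'
#' Integrates only gene `gene_index`'s ODE with RK4; at every integration
#' stage the other genes' concentrations are taken from the observed profile,
#' linearly interpolated between samples. The predicted trajectory starts at
#' the observed initial value.
#'
#' @param params [gene_parameters()] for the target gene.
#' @param observed An [expression_profile()] covering all N genes.
#' @param gene_index Index of the target gene.
#' @param control A [sim_control()] list.
#' @return Numeric vector of T predicted concentrations of the target gene.
#' @export
simulate_gene_decoupled <- function(params, observed, gene_index,
                                    control = sim_control()) {
  stopifnot(inherits(observed, "expression_profile"),
            length(params$g) == ncol(observed$values),
            gene_index >= 1, gene_index <= ncol(observed$values))
  grid <- decoupled_grid(observed, control)
  theta <- c(params$alpha, params$beta, params$g, params$h)
  cpp_decoupled_traj(theta, grid$L, grid$m, grid$hsteps,
                     observed$values[, gene_index], gene_index - 1L,
                     control$state_floor, control$overflow_ceiling)
}

#' Relative mean-squared-error fitness
#'
#' The per-gene behaviour objective: the sum over time points of the squared
#' relative deviation `((predicted - observed) / observed)^2`. Observed
#' values below `floor` are replaced by `floor` in the denominator.
#'
#' @param predicted,observed Equal-length numeric trajectories.
#' @param floor Positive denominator guard.
#' @return Non-negative scalar; 0 iff `predicted == observed`.
#' @export
mse_fitness <- function(predicted, observed, floor = 1e-6) {
  if (length(predicted) != length(observed))
    stop("predicted and observed trajectories differ in length")
  stopifnot(floor > 0, all(observed >= 0))
  sum(((predicted - observed) / pmax(observed, floor))^2)
}

#' Prior structure annotation
#'
#' Per-slot prior knowledge about the kinetic-order matrices: `"zero"` (no
#' interaction), `"nonzero"` (interaction present) or `"unknown"`.
#'
#' @param g_known,h_known N x N character matrices with entries in
#'   `c("zero", "nonzero", "unknown")`.
#' @return An object of class `prior_structure`.
#' @export
prior_structure <- function(g_known, h_known) {
  g_known <- as.matrix(g_known); h_known <- as.matrix(h_known)
  stopifnot(identical(dim(g_known), dim(h_known)),
            nrow(g_known) == ncol(g_known))
  ok <- c("zero", "nonzero", "unknown")
  if (!all(g_known %in% ok) || !all(h_known %in% ok))
    stop("prior entries must be one of ", paste(ok, collapse = ", "))
  structure(list(g_known = g_known, h_known = h_known),
            class = "prior_structure")
}

#' Derive the prior structure implied by a reference network
#'
#' Marks each kinetic-order slot `"zero"` or `"nonzero"` according to the
#' reference network's topology (`|value| < zero_threshold` counts as zero).
#'
#' @param net An `ssystem` network.
#' @param zero_threshold Magnitude below which a kinetic order is zero.
#' @return A [prior_structure()].
#' @export
prior_from_network <- function(net, zero_threshold = 0.1) {
  lab <- function(M) ifelse(abs(M) < zero_threshold, "zero", "nonzero")
  prior_structure(lab(net$G), lab(net$H))
}

#' Structure-consistency score of one gene against prior knowledge
#'
#' Counts, over gene i's 2N kinetic orders, the disagreements with the prior:
#' `nzp` slots inferred non-zero where the prior says zero and `zp` slots
#' inferred zero where the prior says non-zero. The ratios
#' `sp1 = nzp / zPK` and `sp2 = zp / nzPK` (0 when a denominator is 0) both
#' lie in \[0, 1\]; slots marked `"unknown"` are ignored.
#'
#' @param params [gene_parameters()] of the gene under scoring.
#' @param prior A [prior_structure()].
#' @param zero_threshold Magnitude below which an inferred order counts as 0.
#' @return A list of class `structure_score` with `nzp`, `zp`, `sp1`, `sp2`.
#' @export
structure_priority <- function(params, prior, zero_threshold = 0.1) {
  i <- params$gene_index
  inferred_zero <- c(abs(params$g) < zero_threshold,
                     abs(params$h) < zero_threshold)
  known <- c(prior$g_known[i, ], prior$h_known[i, ])
  zPK <- sum(known == "zero")
  nzPK <- sum(known == "nonzero")
  nzp <- sum(known == "zero" & !inferred_zero)
  zp <- sum(known == "nonzero" & inferred_zero)
  structure(list(nzp = nzp, zp = zp,
                 sp1 = if (zPK > 0) nzp / zPK else 0,
                 sp2 = if (nzPK > 0) zp / nzPK else 0),
            class = "structure_score")
}

#' Objective-function settings
#'
#' @param weight_alpha Weight in \[0, 1\] on the behaviour (MSE) term; the
#'   structure-priority penalty gets `1 - weight_alpha`. 1 = behaviour only.
#' @param zero_threshold Magnitude below which a kinetic order counts as 0.
#' @param mse_floor Denominator guard of [mse_fitness()].
#' @return A list of class `fitness_config`.
#' @export
fitness_config <- function(weight_alpha = 1, zero_threshold = 0.1,
                           mse_floor = 1e-6) {
  stopifnot(weight_alpha >= 0, weight_alpha <= 1, zero_threshold > 0,
            mse_floor > 0)
  structure(list(weight_alpha = weight_alpha, zero_threshold = zero_threshold,
                 mse_floor = mse_floor),
            class = "fitness_config")
}

#' Combined behaviour + structure objective
#'
#' `weight_alpha * mse + (1 - weight_alpha) * (sp1 + sp2) / 2`. The structure
#' penalty `(sp1 + sp2) / 2` is normalised to \[0, 1\] so it is commensurate
#' with a per-gene MSE; with `weight_alpha = 1` the value is the MSE exactly.
#'
#' @param mse Behaviour score from [mse_fitness()].
#' @param score A `structure_score` from [structure_priority()].
#' @param cfg A [fitness_config()].
#' @return Scalar objective value (to be minimised).
#' @export
combined_fitness <- function(mse, score, cfg = fitness_config()) {
  cfg$weight_alpha * mse +
    (1 - cfg$weight_alpha) * (score$sp1 + score$sp2) / 2
}
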