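# Hybrid GA-PSO search and the integrated parameter identification and
# optimization (PIO) loop.
#
# Each generation the population is ranked and split: the best (1-r) fraction
# is refined by a PSO velocity/position update, the remaining r fraction is
# replaced by tournament-selected, crossed-over and mutated offspring.
# Periodically the m-MPSA identification phase classifies parameters as
# sensitive/insensitive and re-centres their search bounds around the global
# best (tight for sensitive, loose for insensitive), and an exploration phase
# re-seeds all but the top 1% of particles to preserve diversity.

FAIL_FITNESS <- 1e12

#' Decoupled per-gene estimation sub-problem
#'
#' Packages everything needed to score candidate parameter vectors
#' `c(alpha, beta, g1..gN, h1..hN)` for one target gene: the observed
#' profile (off-target genes are interpolated onto the integration grid once,
#' here), the objective settings and the optional structure prior. The
#' returned object's `eval(candidates)` scores a matrix of candidate rows;
#' diverging candidates receive the worst-case fitness instead of aborting.
#'
#' @param profile An [expression_profile()] covering all N genes.
#' @param gene Index of the target gene.
#' @param fit_cfg A [fitness_config()]; with `weight_alpha < 1` a `prior` is
#'   required and the combined behaviour + structure objective is used.
#' @param prior Optional [prior_structure()].
#' @param control A [sim_control()] list.
#' @return A list of class `decoupled_problem` with elements `N`, `gene`,
#'   `legal_ranges` (2 x P matrix) and `eval`.
#' @export
decoupled_problem <- function(profile, gene, fit_cfg = fitness_config(),
                              prior = NULL, control = sim_control()) {
  stopifnot(inherits(profile, "expression_profile"))
  N <- ncol(profile$values)
  stopifnot(gene >= 1, gene <= N)
  if (fit_cfg$weight_alpha < 1 && is.null(prior))
    stop("a structure prior is required when weight_alpha < 1")
  grid <- decoupled_grid(profile, control)
  obs <- profile$values[, gene]
  legal <- cbind(matrix(ALPHA_RANGE, 2, 2), matrix(KINETIC_RANGE, 2, 2 * N))
  colnames(legal) <- param_names(N, gene)

  w <- fit_cfg$weight_alpha
  str_penalty <- NULL
  if (w < 1) {
    known <- c(prior$g_known[gene, ], prior$h_known[gene, ])
    zero_slots <- known == "zero"
    nonzero_slots <- known == "nonzero"
    zPK <- sum(zero_slots); nzPK <- sum(nonzero_slots)
    str_penalty <- function(cand) {
      ko <- abs(cand[, -(1:2), drop = FALSE]) < fit_cfg$zero_threshold
      nzp <- if (zPK > 0)
        rowSums(!ko[, zero_slots, drop = FALSE]) / zPK else 0
      zp <- if (nzPK > 0)
        rowSums(ko[, nonzero_slots, drop = FALSE]) / nzPK else 0
      (nzp + zp) / 2
    }
  }

  eval_fun <- function(cand) {
    cand <- if (is.matrix(cand)) cand else matrix(cand, nrow = 1)
    mse <- cpp_decoupled_fitness(cand, grid$L, grid$m, grid$hsteps, obs,
                                 gene - 1L, control$state_floor,
                                 control$overflow_ceiling, fit_cfg$mse_floor,
                                 FAIL_FITNESS)
    if (w < 1) w * mse + (1 - w) * str_penalty(cand) else mse
  }

  structure(list(N = N, gene = gene, profile = profile, fit_cfg = fit_cfg,
                 prior = prior, control = control, legal_ranges = legal,
                 eval = eval_fun),
            class = "decoupled_problem")
}

#' Search bounds of a sub-problem
#'
#' @param legal_ranges 2 x P matrix of legal parameter ranges.
#' @param lower,upper Current per-parameter bounds (default: legal ranges).
#' @param velocity_bound Per-parameter PSO velocity clamp; defaults to 2.0
#'   for the rate constants and 1.0 for the kinetic orders.
#' @return A list of class `bounds_set`.
#' @export
bounds_set <- function(legal_ranges, lower = NULL, upper = NULL,
                       velocity_bound = NULL) {
  P <- ncol(legal_ranges)
  if (is.null(lower)) lower <- legal_ranges[1, ]
  if (is.null(upper)) upper <- legal_ranges[2, ]
  if (is.null(velocity_bound)) velocity_bound <- c(2, 2, rep(1, P - 2))
  stopifnot(length(lower) == P, length(upper) == P, all(lower < upper),
            all(velocity_bound > 0))
  structure(list(lower = lower, upper = upper,
                 velocity_bound = velocity_bound, legal = legal_ranges),
            class = "bounds_set")
}

#' PIO run configuration
#'
#' @param max_gen Generations of the GA-PSO cycle (default 5000: ten
#'   identification and five exploration phases at the default cadence).
#' @param pop_size Particles in the population (default 200).
#' @param r Randomness rate: fraction of the ranked population handed to the
#'   GA part each generation; the best `1 - r` fraction goes to PSO.
#' @param identification_interval Generations between m-MPSA identification
#'   phases (default 500); `NA` or `Inf` disables identification.
#' @param exploration_interval Generations between exploration phases
#'   (default 1000); `NA` or `Inf` disables exploration.
#' @param elite_keep_fraction Fraction of top particles spared by the
#'   exploration phase (default 0.01, ceiling rounding).
#' @param inertia,cognitive,social Standard PSO update coefficients.
#' @param tournament_size GA parent-selection tournament size.
#' @param blx_alpha Blend-crossover expansion factor.
#' @param mutation_rate Per-dimension Gaussian mutation probability.
#' @param mutation_sd_frac Mutation standard deviation as a fraction of the
#'   legal range width.
#' @param tight_factor,loose_factor Multiples of the velocity bound defining
#'   the re-centred search interval of sensitive/insensitive parameters.
#' @param sensitivity_track_interval Generations between diagnostic
#'   sensitivity measurements of the current global best (over the full
#'   legal ranges, so the series is comparable across configurations and
#'   across phases); `NA` (default) disables tracking.
#' @param sa_cfg A [sensitivity_config()].
#' @param fit_cfg A [fitness_config()].
#' @param seed Master RNG seed of the run.
#' @return A list of class `pio_config`.
#' @export
pio_config <- function(max_gen = 5000, pop_size = 200, r = 0.5,
                       identification_interval = 500,
                       exploration_interval = 1000,
                       elite_keep_fraction = 0.01, inertia = 0.7,
                       cognitive = 1.5, social = 1.5, tournament_size = 2,
                       blx_alpha = 0.5, mutation_rate = 0.05,
                       mutation_sd_frac = 0.05, tight_factor = 2,
                       loose_factor = 5,
                       sensitivity_track_interval = NA,
                       sa_cfg = sensitivity_config(),
                       fit_cfg = fitness_config(), seed = 1L) {
  stopifnot(max_gen >= 1, pop_size >= 2, r > 0, r < 1,
            elite_keep_fraction > 0, elite_keep_fraction < 1,
            tournament_size >= 1, tight_factor > 0,
            loose_factor >= tight_factor)
  structure(list(max_gen = max_gen, pop_size = pop_size, r = r,
                 identification_interval = identification_interval,
                 exploration_interval = exploration_interval,
                 elite_keep_fraction = elite_keep_fraction,
                 inertia = inertia, cognitive = cognitive, social = social,
                 tournament_size = tournament_size, blx_alpha = blx_alpha,
                 mutation_rate = mutation_rate,
                 mutation_sd_frac = mutation_sd_frac,
                 tight_factor = tight_factor, loose_factor = loose_factor,
                 sensitivity_track_interval = sensitivity_track_interval,
                 sa_cfg = sa_cfg, fit_cfg = fit_cfg, seed = as.integer(seed)),
            class = "pio_config")
}

interval_active <- function(interval, gen) {
  !is.null(interval) && !is.na(interval) && is.finite(interval) &&
    gen %% interval == 0
}

runif_matrix <- function(n, lower, upper) {
  P <- length(lower)
  matrix(runif(n * P, rep(lower, each = n), rep(upper, each = n)), nrow = n)
}

#' Initialize a random population
#'
#' Positions are uniform within the bounds, velocities uniform within the
#' velocity clamp, local bests start at the initial positions and the global
#' best is the fittest initial particle.
#'
#' @param n Population size.
#' @param bounds A [bounds_set()].
#' @param problem A [decoupled_problem()].
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @return A list of class `population`.
#' @export
init_population <- function(n, bounds, problem, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- runif_matrix(n, bounds$lower, bounds$upper)
  vel <- runif_matrix(n, -bounds$velocity_bound, bounds$velocity_bound)
  fit <- problem$eval(pos)
  b <- which.min(fit)
  structure(list(pos = pos, vel = vel, fit = fit,
                 lbest_pos = pos, lbest_fit = fit,
                 gbest_pos = pos[b, ], gbest_fit = fit[b], generation = 0L),
            class = "population")
}

#' Rank particles and split into elite and pending sets
#'
#' Particles are sorted ascending by fitness (stable, ties broken by index);
#' the best `ceiling((1 - r) * n)` form the elite (PSO) set, the rest are
#' pending (GA replacement).
#'
#' @param pop A `population`.
#' @param r Randomness rate in (0, 1).
#' @return List with integer index vectors `elite` and `pending`.
#' @export
rank_and_split <- function(pop, r = 0.5) {
  n <- length(pop$fit)
  ord <- order(pop$fit)           # stable: ties keep index order
  n_elite <- ceiling((1 - r) * n)
  list(elite = ord[seq_len(n_elite)], pending = ord[-seq_len(n_elite)])
}

# update local/global bests of particles `idx` after their fitness changed
update_bests <- function(pop, idx) {
  better <- pop$fit[idx] < pop$lbest_fit[idx]
  if (any(better)) {
    ib <- idx[better]
    pop$lbest_pos[ib, ] <- pop$pos[ib, , drop = FALSE]
    pop$lbest_fit[ib] <- pop$fit[ib]
  }
  b <- idx[which.min(pop$fit[idx])]
  if (pop$fit[b] < pop$gbest_fit) {
    pop$gbest_fit <- pop$fit[b]
    pop$gbest_pos <- pop$pos[b, ]
  }
  pop
}

#' PSO refinement step for the elite set
#'
#' Standard inertia + cognitive + social velocity update with per-parameter
#' velocity clamping and position clipping into the bounds; local and global
#' bests are updated when improved, so the global best never worsens.
#'
#' @param pop A `population`.
#' @param elite Integer indices of the particles to update.
#' @param bounds A [bounds_set()].
#' @param cfg A [pio_config()].
#' @param problem A [decoupled_problem()].
#' @return The updated `population`.
#' @export
pso_step <- function(pop, elite, bounds, cfg, problem) {
  ne <- length(elite)
  if (ne == 0L) return(pop)
  P <- ncol(pop$pos)
  x <- pop$pos[elite, , drop = FALSE]
  v <- pop$vel[elite, , drop = FALSE]
  r1 <- matrix(runif(ne * P), ne)
  r2 <- matrix(runif(ne * P), ne)
  gb <- matrix(pop$gbest_pos, ne, P, byrow = TRUE)
  v <- cfg$inertia * v +
    cfg$cognitive * r1 * (pop$lbest_pos[elite, , drop = FALSE] - x) +
    cfg$social * r2 * (gb - x)
  vb <- matrix(bounds$velocity_bound, ne, P, byrow = TRUE)
  v <- pmin(pmax(v, -vb), vb)
  x <- x + v
  x <- pmin(pmax(x, matrix(bounds$lower, ne, P, byrow = TRUE)),
            matrix(bounds$upper, ne, P, byrow = TRUE))
  pop$pos[elite, ] <- x
  pop$vel[elite, ] <- v
  pop$fit[elite] <- problem$eval(x)
  update_bests(pop, elite)
}

# tournament-select one parent index per draw from the whole population
tournament_select <- function(fit, n_draws, size) {
  idx <- matrix(sample.int(length(fit), n_draws * size, replace = TRUE),
                nrow = n_draws)
  picks <- idx[, 1]
  if (size > 1)
    for (k in 2:size) {
      challenger <- idx[, k]
      swap <- fit[challenger] < fit[picks]
      picks[swap] <- challenger[swap]
    }
  picks
}

#' GA replacement step for the pending set
#'
#' Each pending slot is refilled by a child of two tournament-selected
#' parents: blend (BLX-alpha) crossover followed by bounded Gaussian
#' mutation. Replacements get fresh uniform velocities and local bests equal
#' to their own positions.
#'
#' @param pop A `population`.
#' @param pending Integer indices of the particles to replace.
#' @param bounds A [bounds_set()].
#' @param cfg A [pio_config()].
#' @param problem A [decoupled_problem()].
#' @return The updated `population`.
#' @export
ga_step <- function(pop, pending, bounds, cfg, problem) {
  np <- length(pending)
  if (np == 0L) return(pop)
  P <- ncol(pop$pos)
  p1 <- pop$pos[tournament_select(pop$fit, np, cfg$tournament_size), ,
                drop = FALSE]
  p2 <- pop$pos[tournament_select(pop$fit, np, cfg$tournament_size), ,
                drop = FALSE]
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  span <- hi - lo
  child <- lo - cfg$blx_alpha * span +
    matrix(runif(np * P), np) * (1 + 2 * cfg$blx_alpha) * span
  mut <- matrix(runif(np * P) < cfg$mutation_rate, np)
  if (any(mut)) {
    sdv <- cfg$mutation_sd_frac * (bounds$legal[2, ] - bounds$legal[1, ])
    noise <- matrix(rnorm(np * P, sd = rep(sdv, each = np)), np)
    child[mut] <- child[mut] + noise[mut]
  }
  child <- pmin(pmax(child, matrix(bounds$lower, np, P, byrow = TRUE)),
                matrix(bounds$upper, np, P, byrow = TRUE))
  pop$pos[pending, ] <- child
  pop$vel[pending, ] <- runif_matrix(np, -bounds$velocity_bound,
                                     bounds$velocity_bound)
  pop$fit[pending] <- problem$eval(child)
  pop$lbest_pos[pending, ] <- child
  pop$lbest_fit[pending] <- pop$fit[pending]
  b <- pending[which.min(pop$fit[pending])]
  if (pop$fit[b] < pop$gbest_fit) {
    pop$gbest_fit <- pop$fit[b]
    pop$gbest_pos <- pop$pos[b, ]
  }
  pop
}

#' Re-centre search bounds after a sensitivity classification
#'
#' Sensitive parameters get tight intervals `gbest_i +/- tight_factor * vb_i`
#' and insensitive ones loose intervals with `loose_factor`, both clipped to
#' the legal ranges (an interval collapsing under clipping is widened to a
#' minimal width around its clipped centre). Every particle's value of every
#' parameter is regenerated uniformly inside the new interval.
#'
#' @param classification Logical vector (`TRUE` = sensitive) over parameters.
#' @param gbest_position Current global-best parameter vector.
#' @param bounds A [bounds_set()].
#' @param n_particles Number of particle positions to regenerate.
#' @param tight_factor,loose_factor Interval half-width multipliers.
#' @return List with the new `bounds` and the regenerated `positions`.
#' @export
assign_bounds <- function(classification, gbest_position, bounds,
                          n_particles, tight_factor = 2, loose_factor = 5) {
  P <- length(gbest_position)
  stopifnot(length(classification) == P)
  factor <- ifelse(classification, tight_factor, loose_factor)
  half <- factor * bounds$velocity_bound
  lo <- pmax(gbest_position - half, bounds$legal[1, ])
  hi <- pmin(gbest_position + half, bounds$legal[2, ])
  degenerate <- hi - lo < 1e-8
  if (any(degenerate)) {
    centre <- (lo + hi) / 2
    lo[degenerate] <- pmax(centre[degenerate] - 5e-4, bounds$legal[1, ][degenerate])
    hi[degenerate] <- pmin(centre[degenerate] + 5e-4, bounds$legal[2, ][degenerate])
  }
  new_bounds <- bounds_set(bounds$legal, lo, hi, bounds$velocity_bound)
  list(bounds = new_bounds,
       positions = runif_matrix(n_particles, lo, hi))
}

#' Exploration phase: re-seed all but the top particles
#'
#' Every particle outside the top `ceiling(elite_keep_fraction * n)` by
#' fitness has all parameters and its velocity regenerated uniformly within
#' the current bounds and its local best reset to the regenerated position;
#' the global best is updated only if improved.
#'
#' @param pop A `population`.
#' @param bounds A [bounds_set()].
#' @param elite_keep_fraction Fraction of particles left untouched.
#' @param problem A [decoupled_problem()].
#' @return The updated `population`.
#' @export
exploration_phase <- function(pop, bounds, elite_keep_fraction, problem) {
  n <- length(pop$fit)
  keep <- ceiling(elite_keep_fraction * n)
  ord <- order(pop$fit)
  redo <- ord[-seq_len(keep)]
  if (length(redo) == 0L) return(pop)
  fresh <- runif_matrix(length(redo), bounds$lower, bounds$upper)
  pop$pos[redo, ] <- fresh
  pop$vel[redo, ] <- runif_matrix(length(redo), -bounds$velocity_bound,
                                  bounds$velocity_bound)
  pop$fit[redo] <- problem$eval(fresh)
  pop$lbest_pos[redo, ] <- fresh
  pop$lbest_fit[redo] <- pop$fit[redo]
  b <- redo[which.min(pop$fit[redo])]
  if (pop$fit[b] < pop$gbest_fit) {
    pop$gbest_fit <- pop$fit[b]
    pop$gbest_pos <- pop$pos[b, ]
  }
  pop
}

#' Run the integrated parameter identification and optimization loop
#'
#' Runs `cfg$max_gen` generations of the hybrid GA-PSO cycle on one decoupled
#' sub-problem. Every `identification_interval` generations the m-MPSA phase
#' (anchored at the current global best) classifies parameters against the
#' CCR threshold and re-centres the search bounds ([assign_bounds()]); CCR
#' then grows by epsilon. Every `exploration_interval` generations the
#' exploration phase re-seeds all but the top 1% of particles. Disabling both
#' intervals reduces the loop to the plain hybrid GA-PSO.
#'
#' @param problem A [decoupled_problem()].
#' @param cfg A [pio_config()].
#' @param final_sensitivity Compute an m-MPSA report at the final global best
#'   even when identification is disabled (for robustness comparisons).
#' @return A list of class `pio_result`: `params` (the global-best
#'   [gene_parameters()]), `position`, `fitness`, `history` (per-generation
#'   `gbest` vector and per-phase `sensitivity` data frame), `ccr_final`,
#'   and optionally `final_report`.
#' @export
run_pio <- function(problem, cfg = pio_config(), final_sensitivity = FALSE) {
  set.seed(cfg$seed)
  bounds <- bounds_set(problem$legal_ranges)
  pop <- init_population(cfg$pop_size, bounds, problem)
  ccr <- cfg$sa_cfg$ccr_initial
  gbest_hist <- numeric(cfg$max_gen)
  sens_hist <- list()
  track_hist <- list()

  for (gen in seq_len(cfg$max_gen)) {
    if (interval_active(cfg$sensitivity_track_interval, gen)) {
      # diagnostic only: restore the RNG state afterwards so tracking never
      # perturbs the search (a tracked run equals an untracked one)
      rng_state <- .Random.seed
      trk <- mpsa(problem, pop$gbest_pos, cfg$sa_cfg, seed = NULL,
                  ranges = problem$legal_ranges, ccr = ccr)
      assign(".Random.seed", rng_state, envir = globalenv())
      track_hist[[length(track_hist) + 1L]] <-
        data.frame(generation = gen,
                   mean_sensitivity = mean_sensitivity(trk))
    }
    if (interval_active(cfg$identification_interval, gen)) {
      report <- mpsa(problem, pop$gbest_pos, cfg$sa_cfg, seed = NULL,
                     ranges = rbind(bounds$lower, bounds$upper), ccr = ccr)
      ccr_used <- attr(report, "ccr_used")
      ab <- assign_bounds(report$sensitive, pop$gbest_pos, bounds,
                          cfg$pop_size, cfg$tight_factor, cfg$loose_factor)
      bounds <- ab$bounds
      pop$pos <- ab$positions
      pop$fit <- problem$eval(pop$pos)
      pop$lbest_pos <- pop$pos
      pop$lbest_fit <- pop$fit
      pop$vel <- runif_matrix(cfg$pop_size, -bounds$velocity_bound,
                              bounds$velocity_bound)
      b <- which.min(pop$fit)
      if (pop$fit[b] < pop$gbest_fit) {
        pop$gbest_fit <- pop$fit[b]
        pop$gbest_pos <- pop$pos[b, ]
      }
      ccr <- update_ccr(ccr_used, cfg$sa_cfg$epsilon)
      sens_hist[[length(sens_hist) + 1L]] <-
        data.frame(generation = gen, mean_sensitivity = mean_sensitivity(report),
                   ccr = ccr_used, n_sensitive = sum(report$sensitive))
    }
    if (interval_active(cfg$exploration_interval, gen))
      pop <- exploration_phase(pop, bounds, cfg$elite_keep_fraction, problem)

    split <- rank_and_split(pop, cfg$r)
    pop <- pso_step(pop, split$elite, bounds, cfg, problem)
    pop <- ga_step(pop, split$pending, bounds, cfg, problem)
    pop$generation <- gen
    gbest_hist[gen] <- pop$gbest_fit
  }

  # robustness diagnostic of the final solution: always sampled over the
  # full legal ranges so reports are comparable across configurations
  # (identification phases, by contrast, sample the current bounds)
  final_report <- NULL
  if (final_sensitivity || length(sens_hist) > 0) {
    final_report <- mpsa(problem, pop$gbest_pos, cfg$sa_cfg, seed = NULL,
                         ranges = problem$legal_ranges, ccr = ccr)
  }

  theta <- pop$gbest_pos
  N <- problem$N
  structure(list(
    params = gene_parameters(
      clamp(theta[1], ALPHA_RANGE), clamp(theta[2], ALPHA_RANGE),
      clamp(theta[3:(2 + N)], KINETIC_RANGE),
      clamp(theta[(3 + N):(2 + 2 * N)], KINETIC_RANGE),
      gene_index = problem$gene),
    position = theta, fitness = pop$gbest_fit,
    history = list(gbest = gbest_hist,
                   sensitivity = if (length(sens_hist))
                     do.call(rbind, sens_hist) else NULL,
                   sensitivity_track = if (length(track_hist))
                     do.call(rbind, track_hist) else NULL),
    ccr_final = ccr, final_report = final_report,
    bounds = bounds), class = "pio_result")
}

clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])
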