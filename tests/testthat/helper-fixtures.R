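# Shared fixtures and independent oracles.

# one-gene exponential decay X' = -X (alpha = 0, beta = 1, h11 = 1)
decay_gene <- function() gene_parameters(0, 1, 0, 1, gene_index = 1L)

decay_network <- function() s_system(list(decay_gene()))

# profile of the decay system sampled analytically (exact, no integrator)
decay_profile <- function(n_steps = 30, dt = 0.1) {
  times <- seq(0, n_steps * dt, by = dt)
  expression_profile(matrix(exp(-times), ncol = 1), times, "X1")
}

# small two-gene cascade used across module tests
toy2_network <- function() {
  s_system(list(
    gene_parameters(4, 8, c(0, 1), c(1.5, 0), 1L),
    gene_parameters(6, 6, c(1, 0), c(0, 2), 2L)
  ))
}

toy2_profile <- function() simulate_network(toy2_network(), c(0.5, 0.8))

# independent brute-force ECDF/PCC oracle for the sensitivity score:
# double loop over the grid, hand-rolled Pearson correlation
brute_sensitivity <- function(values, mask) {
  n_acc <- sum(mask)
  if (n_acc == 0 || n_acc == length(values)) return(1)
  grid <- sort(values)
  acc <- values[mask]; un <- values[!mask]
  cf_a <- cf_u <- numeric(length(grid))
  for (k in seq_along(grid)) {
    cf_a[k] <- sum(acc <= grid[k]) / length(acc)
    cf_u[k] <- sum(un <= grid[k]) / length(un)
  }
  va <- cf_a - mean(cf_a); vu <- cf_u - mean(cf_u)
  den <- sqrt(sum(va^2) * sum(vu^2))
  if (den == 0) return(1)
  sum(va * vu) / den
}

# adaptive-integrator reference trajectory (deSolve::lsoda)
lsoda_profile <- function(net, x0, times, state_floor = 1e-6) {
  deriv <- function(t, x, p) {
    x <- pmax(x, state_floor)
    list(as.numeric(net$alpha * exp(net$G %*% log(x)) -
                    net$beta * exp(net$H %*% log(x))))
  }
  out <- deSolve::lsoda(x0, times, deriv, NULL, rtol = 1e-10, atol = 1e-12)
  unname(out[, -1, drop = FALSE])
}

# fast optimizer settings for unit-scale problems
quick_cfg <- function(seed, max_gen = 120, pop_size = 60, ...) {
  pio_config(max_gen = max_gen, pop_size = pop_size,
             identification_interval = NA, exploration_interval = NA,
             seed = seed, ...)
}
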