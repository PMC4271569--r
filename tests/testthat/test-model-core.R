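test_that("gene_derivative evaluates the power-law difference", {
  # 10-gene benchmark gene 2: X2' = 10 X3 X8 - 10 X2^2
  gp <- network_gene(dataset2_network(), 2)
  state <- rep(1, 10)
  expect_equal(gene_derivative(gp, state), 0) # synthesis == degradation
  state[2] <- 0.5
  expect_equal(gene_derivative(gp, state), 10 - 10 * 0.25)
  expect_equal(gene_derivative(gene_parameters(0, 0, c(0, 0), c(0, 0)),
                               c(2, 3)), 0)
})

test_that("parameter ranges are enforced at construction", {
  expect_error(gene_parameters(11, 1, 0, 1), "rate constants")
  expect_error(gene_parameters(1, -0.5, 0, 1), "non-negative")
  expect_error(gene_parameters(1, 1, 3.5, 1), "kinetic orders")
  expect_error(gene_parameters(1, 1, 0, NaN), "finite")
  expect_silent(gene_parameters(10, 0, 3, -3))
})

test_that("s_system validates dimensions and gene indices", {
  g1 <- gene_parameters(1, 1, c(0, 1), c(1, 0), 1L)
  g2 <- gene_parameters(1, 1, c(1, 0), c(0, 1), 2L)
  expect_silent(s_system(list(g1, g2)))
  expect_error(s_system(list(g1, g1)), "gene_index")
  expect_error(s_system(list(g1, gene_parameters(1, 1, 0, 1, 2L))),
               "length N")
})

test_that("expression_profile rejects malformed inputs", {
  expect_error(expression_profile(matrix(1, 1, 2), 1), "at least 2")
  expect_error(expression_profile(matrix(1, 3, 2), c(0, 1, 1)),
               "strictly increasing")
  expect_error(expression_profile(matrix(-1, 3, 2), 0:2), "non-negative")
})

test_that("zero dynamics give a constant trajectory", {
  net <- s_system(list(gene_parameters(0, 0, c(0, 0), c(0, 0), 1L),
                       gene_parameters(0, 0, c(0, 0), c(0, 0), 2L)))
  prof <- simulate_network(net, c(0.4, 1.2), n_steps = 10)
  expect_equal(nrow(prof$values), 11L)
  expect_true(all(prof$values[, 1] == 0.4))
  expect_true(all(prof$values[, 2] == 1.2))
})

test_that("simulate_network matches the closed-form exponential decay", {
  prof <- simulate_network(decay_network(), 1, n_steps = 30, dt_sample = 0.1)
  expect_equal(prof$values[, 1], exp(-prof$times), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("symmetric genes of the 5-gene benchmark are stationary at equal state", {
  # X2' = 10 (X1^2 - X2^2) and X5' = 10 (X4^2 - X5^2) vanish when all equal
  net <- dataset1_network()
  state <- rep(0.7, 5)
  expect_equal(gene_derivative(network_gene(net, 2), state), 0)
  expect_equal(gene_derivative(network_gene(net, 5), state), 0)
})

test_that("simulation reports divergence with the failing time index", {
  # strong autocatalysis: X' = 10 X^3
  net <- s_system(list(gene_parameters(10, 0, 3, 0, 1L)))
  expect_error(simulate_network(net, 5, n_steps = 30), "diverged")
})

test_that("decoupled simulation is self-consistent on a one-gene problem", {
  prof <- decay_profile()
  pred <- simulate_gene_decoupled(decay_gene(), prof, 1)
  expect_equal(pred[1], unname(prof$values[1, 1]))
  expect_lt(max(abs(pred - exp(-prof$times)) / exp(-prof$times)), 1e-6)
})

test_that("decoupled simulation with zero rates stays at the initial value", {
  prof <- toy2_profile()
  pred <- simulate_gene_decoupled(gene_parameters(0, 0, c(0, 0), c(0, 0), 2L),
                                  prof, 2)
  expect_true(all(pred == prof$values[1, 2]))
})

test_that("decoupled self-consistency is limited only by off-target interpolation", {
  # with the true generating parameters the remaining error comes from the
  # linear interpolation of the other genes between the 31 samples
  net <- dataset1_network()
  prof <- generate_profile(benchmark_spec("dataset1"))
  for (i in 1:5) {
    pred <- simulate_gene_decoupled(network_gene(net, i), prof, i)
    expect_equal(pred[1], unname(prof$values[1, i]))
    expect_lt(mse_fitness(pred, prof$values[, i]), 5e-3)
  }
})

test_that("mse_fitness matches hand-computed cases", {
  expect_equal(mse_fitness(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_fitness(3, 2), 0.25)
  expect_equal(mse_fitness(c(2, 0), c(1, 1)), 2)
  expect_error(mse_fitness(1:3, 1:2), "length")
})

test_that("mse_fitness is scale-invariant and positive off-identity", {
  set.seed(11)
  for (k in 1:20) {
    obs <- runif(10, 0.5, 2)
    pred <- obs + rnorm(10, sd = 0.1)
    m <- mse_fitness(pred, obs)
    expect_gt(m, 0)
    s <- runif(1, 0.1, 10)
    expect_equal(mse_fitness(s * pred, s * obs), m, tolerance = 1e-12)
  }
})

test_that("structure_priority counts mismatches per the sp1/sp2 ratios", {
  # prior: gene 1 of 2 genes; g = (zero, zero), h = (nonzero, zero) plus
  # one more zero -> zPK = 3, nzPK = 1
  prior <- prior_structure(matrix(c("zero", "unknown", "zero", "unknown"), 2),
                           matrix(c("nonzero", "unknown", "zero", "unknown"), 2))
  exact <- gene_parameters(1, 1, c(0, 0), c(1, 0), 1L)
  sc <- structure_priority(exact, prior)
  expect_equal(sc$sp1, 0)
  expect_equal(sc$sp2, 0)
  # one of the three prior-zero slots filled at 0.5
  off <- gene_parameters(1, 1, c(0.5, 0), c(1, 0), 1L)
  expect_equal(structure_priority(off, prior)$sp1, 1 / 3)
  # the single prior-nonzero slot inferred zero
  miss <- gene_parameters(1, 1, c(0, 0), c(0.05, 0), 1L)
  expect_equal(structure_priority(miss, prior)$sp2, 1)
})

test_that("structure_priority ignores unknown slots and handles empty priors", {
  prior <- prior_structure(matrix("unknown", 2, 2), matrix("unknown", 2, 2))
  sc <- structure_priority(gene_parameters(1, 1, c(1, 1), c(1, 1), 1L), prior)
  expect_equal(c(sc$sp1, sc$sp2), c(0, 0))
})

test_that("sp1/sp2 stay in [0,1] for random parameters and priors", {
  set.seed(23)
  for (k in 1:50) {
    N <- sample(2:5, 1)
    gp <- gene_parameters(runif(1, 0, 10), runif(1, 0, 10),
                          runif(N, -3, 3), runif(N, -3, 3), 1L)
    lab <- matrix(sample(c("zero", "nonzero", "unknown"), 2 * N * N,
                         replace = TRUE), N)
    prior <- prior_structure(lab[, 1:N, drop = FALSE],
                             matrix(sample(c("zero", "nonzero", "unknown"),
                                           N * N, TRUE), N))
    sc <- structure_priority(gp, prior)
    expect_true(sc$sp1 >= 0 && sc$sp1 <= 1)
    expect_true(sc$sp2 >= 0 && sc$sp2 <= 1)
  }
})

test_that("combined_fitness weights behaviour and structure as specified", {
  sc <- structure(list(nzp = 1, zp = 0, sp1 = 1, sp2 = 0),
                  class = "structure_score")
  expect_equal(combined_fitness(0.37, sc, fitness_config(weight_alpha = 1)),
               0.37)
  zero <- structure(list(nzp = 0, zp = 0, sp1 = 0, sp2 = 0),
                    class = "structure_score")
  expect_equal(combined_fitness(5, zero, fitness_config(weight_alpha = 0)), 0)
  expect_equal(combined_fitness(0.2, sc, fitness_config(weight_alpha = 0.5)),
               0.35)
})

test_that("combined_fitness is monotone in mse and both structure ratios", {
  cfg <- fitness_config(weight_alpha = 0.3)
  sc <- function(a, b) structure(list(nzp = 0, zp = 0, sp1 = a, sp2 = b),
                                 class = "structure_score")
  expect_lte(combined_fitness(0.1, sc(0.2, 0.4), cfg),
             combined_fitness(0.2, sc(0.2, 0.4), cfg))
  expect_lte(combined_fitness(0.1, sc(0.2, 0.4), cfg),
             combined_fitness(0.1, sc(0.5, 0.4), cfg))
  expect_lte(combined_fitness(0.1, sc(0.2, 0.4), cfg),
             combined_fitness(0.1, sc(0.2, 0.9), cfg))
})
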