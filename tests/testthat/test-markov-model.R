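test_that("rate matrices honor their constraint classes", {
  er <- build_rate_matrix(1, "ER", 2)
  expect_equal(unname(er$Q), matrix(c(-1, 1, 1, -1), 2), tolerance = 1e-12)

  sym <- build_rate_matrix(c(0.3, 0.7, 1.1), "SYM", 3)
  expect_equal(sym$Q["0", "1"], 0.3)
  expect_equal(sym$Q["0", "2"], 0.7)
  expect_equal(sym$Q["1", "2"], 1.1)
  expect_equal(sym$Q, t(sym$Q))

  ard <- build_rate_matrix(1:6, "ARD", 3)
  offd <- ard$Q[row(ard$Q) != col(ard$Q)]
  expect_equal(anyDuplicated(offd), 0L)
  expect_lt(max(abs(rowSums(ard$Q))), 1e-12)

  expect_error(build_rate_matrix(c(1, 2), "ER", 2), "needs 1")
  expect_error(build_rate_matrix(-1, "ER", 2), "positive")
})

test_that("spectral decomposition reconstructs Q and finds known spectra", {
  d <- spectral_decompose(build_rate_matrix(1, "ER", 2))
  expect_equal(sort(d$lambda), c(-2, 0), tolerance = 1e-9)
  expect_true(d$symmetric_transform_used)

  set.seed(5)
  for (s in c(2, 3, 5)) {
    m <- build_rate_matrix(runif(s * (s - 1) / 2, 0.2, 2), "SYM", s)
    d <- spectral_decompose(m)
    recon <- d$U %*% (d$lambda * d$U_inv)
    expect_lt(max(Mod(recon - m$Q)), 1e-9)
    expect_lt(min(abs(d$lambda)), 1e-9)  # one zero eigenvalue
  }
})

test_that("transition probabilities match an independent matrix exponential", {
  skip_if_not_installed("Matrix")
  set.seed(17)
  m5 <- build_rate_matrix(runif(10, 0.1, 1.5), "SYM", 5)
  d5 <- spectral_decompose(m5)
  for (t in c(0.1, 0.7, 2.3))
    expect_lt(max(abs(transition_probabilities(d5, t) - oracle_P(m5$Q, t))),
              1e-9)
  # ARD goes through the general (possibly complex) decomposition
  ard <- build_rate_matrix(runif(6, 0.2, 2), "ARD", 3)
  da <- spectral_decompose(ard)
  for (t in c(0.3, 1.4))
    expect_lt(max(abs(transition_probabilities(da, t) - oracle_P(ard$Q, t))),
              1e-9)
})

test_that("P(t) limits: identity at t = 0, stationary rows at large t", {
  d <- spectral_decompose(build_rate_matrix(1, "ER", 2))
  expect_equal(unname(transition_probabilities(d, 0)), diag(2))
  P50 <- transition_probabilities(d, 50)
  expect_lt(max(abs(P50 - 0.5)), 1e-10)
  P1 <- transition_probabilities(d, 1)
  expect_equal(P1[1, 1], (1 + exp(-2)) / 2, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
  expect_error(transition_probabilities(d, -1), "non-negative")
})

test_that("Chapman-Kolmogorov holds for random models and times", {
  set.seed(23)
  for (rep in 1:5) {
    s <- sample(2:4, 1)
    m <- build_rate_matrix(runif(s * (s - 1) / 2, 0.1, 2), "SYM", s)
    d <- spectral_decompose(m)
    t1 <- runif(1, 0, 2); t2 <- runif(1, 0, 2)
    expect_lt(max(abs(transition_probabilities(d, t1) %*%
                        transition_probabilities(d, t2) -
                        transition_probabilities(d, t1 + t2))), 1e-9)
  }
})

test_that("pruning log-likelihood matches trivial identities", {
  tr <- ape::read.tree(text = "(A:0,B:0);")
  m <- build_rate_matrix(1, "ER", 2)
  both0 <- character_data(c(A = "0", B = "0"), alphabet = c("0", "1"))
  expect_equal(tree_log_likelihood(tr, both0, m), log(0.5), tolerance = 1e-12)

  tr2 <- ape::read.tree(text = "(A:0.6,(B:0.2,C:0.9):0.4);")
  amb <- character_data(c(A = "?", B = "?", C = "?"), alphabet = c("0", "1"))
  expect_equal(tree_log_likelihood(tr2, amb, m), 0, tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on small fixtures", {
  skip_if_not_installed("Matrix")
  for (seed in 1:8) {
    fx <- random_fixture(n_tips = sample(3:6, 1), s = sample(2:3, 1),
                         seed = 100 + seed)
    expect_equal(tree_log_likelihood(fx$tree, fx$data, fx$model),
                 oracle_loglik(fx$tree, fx$data, fx$model),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to permuting the state alphabet", {
  fx <- random_fixture(5, 3, seed = 77)
  ll <- tree_log_likelihood(fx$tree, fx$data, fx$model)
  perm <- c(3L, 1L, 2L)
  states_p <- fx$model$states[perm]
  Qp <- fx$model$Q[perm, perm]
  model_p <- fx$model
  model_p$Q <- Qp; model_p$states <- states_p
  model_p$pi <- fx$model$pi[perm]
  data_p <- fx$data
  data_p$matrix <- fx$data$matrix[, perm]
  data_p$alphabet <- states_p
  expect_equal(tree_log_likelihood(fx$tree, data_p, model_p), ll,
               tolerance = 1e-10)
})

test_that("ML rate estimation: degenerate data drives ER to the bound", {
  tr <- simulate_pure_birth_tree(24, 1, seed = 9)
  inv <- character_data(setNames(rep("0", 24), tr$tip.label),
                        alphabet = c("0", "1"))
  fit <- estimate_mle(tr, inv, "ER")
  bounds <- c(1e-8, 1e3) / mean(tr$edge.length)
  expect_lt(fit$rates, bounds[1] * 1.5)  # pinned at the lower bound
})

test_that("ML estimate beats a 50-point log-spaced rate grid", {
  tr <- simulate_pure_birth_tree(16, 1, seed = 31)
  m <- build_rate_matrix(0.8, "ER", 2)
  h <- simulate_history(tr, m, seed = 32)
  dat <- history_tip_states(h)
  fit <- estimate_mle(tr, dat, "ER")
  grid <- 10^seq(-3, 2, length.out = 50)
  grid_ll <- vapply(grid, function(r)
    tree_log_likelihood(tr, dat, build_rate_matrix(r, "ER", 2)), 0)
  expect_gte(attr(fit, "logLik"), max(grid_ll) - 1e-8)
  expect_equal(attr(fit, "convergence"), 0)
})

test_that("model reports round-trip through the key-value format", {
  m <- build_rate_matrix(c(0.3, 0.7, 1.1), "SYM", 3, pi = "stationary")
  attr(m, "logLik") <- -12.34
  p <- withr::local_tempfile(fileext = ".txt")
  write_model_report(m, p)
  m2 <- read_model_report(p)
  expect_equal(m2$Q, m$Q, tolerance = 1e-12)
  expect_equal(m2$pi, m$pi, tolerance = 1e-12)
  expect_equal(attr(m2, "logLik"), -12.34)
})
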