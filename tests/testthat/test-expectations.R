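test_that("integral factors match closed forms and quadrature", {
  expect_equal(integral_factor_matrix(0, 3), matrix(3, 1, 1))
  expect_equal(integral_factor_matrix(c(0, -2, 1.3), 0), matrix(0, 3, 3))

  lam <- c(0, -2)
  J <- integral_factor_matrix(lam, 1)
  expect_equal(J[1, 2], (1 - exp(-2)) / 2, tolerance = 1e-12)
  quad <- stats::integrate(function(tau) exp(-2 * (1 - tau)), 0, 1,
                           rel.tol = 1e-12)$value
  expect_equal(J[1, 2], quad, tolerance = 1e-10)
  expect_equal(J, t(J), tolerance = 1e-10)
  expect_equal(J[2, 2], 1 * exp(-2), tolerance = 1e-12)  # equal-eigenvalue limit
  expect_true(all(J >= 0))
})

test_that("endpoint-conditioned dwelling times conserve branch length", {
  set.seed(41)
  for (s in 2:4) {
    m <- build_rate_matrix(runif(s * (s - 1) / 2, 0.2, 1.5), "SYM", s)
    d <- spectral_decompose(m)
    T_len <- runif(1, 0.2, 2)
    total <- Reduce(`+`, lapply(seq_len(s), function(i)
      endpoint_conditioned_dwell(d, T_len, i)))
    expect_lt(max(abs(total - T_len)), 1e-8)
  }
})

test_that("short branches concentrate dwelling in the endpoint state", {
  d <- spectral_decompose(build_rate_matrix(1, "ER", 2))
  T_len <- 1e-7
  D0 <- endpoint_conditioned_dwell(d, T_len, 1)
  D1 <- endpoint_conditioned_dwell(d, T_len, 2)
  expect_equal(D0[1, 1], T_len, tolerance = 1e-6)
  expect_lt(D1[1, 1], T_len * 1e-3)
})

test_that("endpoint-conditioned expectations match adaptive quadrature", {
  skip_if_not_installed("Matrix")
  # the documented 2-state closed-form case
  m <- build_rate_matrix(1, "ER", 2)
  d <- spectral_decompose(m)
  D0 <- endpoint_conditioned_dwell(d, 1, 1)
  p00 <- function(t) (1 + exp(-2 * t)) / 2
  q <- stats::integrate(function(tau) p00(tau) * p00(1 - tau), 0, 1,
                        rel.tol = 1e-12)$value / p00(1)
  expect_equal(D0[1, 1], q, tolerance = 1e-8)

  # seeded 2- and 3-state cases against generic quadrature
  set.seed(55)
  for (rep in 1:4) {
    s <- sample(2:3, 1)
    m <- build_rate_matrix(runif(s * (s - 1) / 2, 0.3, 1.8), "SYM", s)
    d <- spectral_decompose(m)
    T_len <- runif(1, 0.3, 1.5)
    a <- sample(s, 1); b <- sample(s, 1); i <- sample(s, 1)
    j <- resample(setdiff(seq_len(s), i))
    Dv <- endpoint_conditioned_dwell(d, T_len, i)[a, b]
    expect_equal(Dv, oracle_dwell_quadrature(m$Q, T_len, i, a, b),
                 tolerance = 1e-8)
    Nv <- endpoint_conditioned_transitions(d, T_len, i, j)[a, b]
    expect_equal(Nv, oracle_trans_quadrature(m$Q, T_len, i, j, a, b),
                 tolerance = 1e-8)
  }
})

test_that("transition expectations respect parity and limits", {
  m <- build_rate_matrix(1, "ER", 2)
  d <- spectral_decompose(m)
  expect_error(endpoint_conditioned_transitions(d, 1, 1, 1), "from == to")
  # short branch, equal endpoints: no transitions expected
  N <- endpoint_conditioned_transitions(d, 1e-8, 1, 2)
  expect_lt(N[1, 1], 1e-6)
  # unequal endpoints force at least one change whatever T
  for (T_len in c(0.05, 0.5, 3)) {
    tot <- endpoint_conditioned_transitions(d, T_len, 1, 2)[1, 2] +
      endpoint_conditioned_transitions(d, T_len, 2, 1)[1, 2]
    expect_gte(tot, 1 - 1e-10)
  }
})

test_that("transition expectation matches endpoint-conditioned simulation", {
  m <- build_rate_matrix(1, "ER", 2)
  d <- spectral_decompose(m)
  sim <- sample_endpoint_conditioned_paths(m, 1, 1, 2, 200000, seed = 99)
  n01 <- sim$pairwise[, 1, 2]
  se <- sd(n01) / sqrt(length(n01))
  expect_lt(abs(mean(n01) - endpoint_conditioned_transitions(d, 1, 1, 2)[1, 2]),
            3 * se)
})

test_that("branch posteriors: no-data and observed-tip identities", {
  tr <- ape::read.tree(text = "((A:0.5,B:0.8):0.4,C:1.1);")
  m <- build_rate_matrix(0.7, "ER", 2)
  amb <- character_data(c(A = "?", B = "?", C = "?"), alphabet = c("0", "1"))
  bp <- branch_posteriors(tr, amb, m)
  d <- spectral_decompose(m)
  for (e in seq_len(nrow(tr$edge))) {
    W <- bp$W[[e]]
    expect_equal(sum(W), 1, tolerance = 1e-10)
    # with no data and uniform pi: W_ab = pi_a P_ab(T)
    Pe <- transition_probabilities(d, tr$edge.length[e])
    expect_lt(max(abs(W - 0.5 * Pe)), 1e-10)
  }

  obs <- character_data(c(A = "0", B = "1", C = "0"), alphabet = c("0", "1"))
  bp2 <- branch_posteriors(tr, obs, m)
  tipA <- which(tr$edge[, 2] == which(tr$tip.label == "A"))
  expect_equal(unname(colSums(bp2$W[[tipA]])), c(1, 0), tolerance = 1e-12)
  tipB <- which(tr$edge[, 2] == which(tr$tip.label == "B"))
  expect_equal(unname(colSums(bp2$W[[tipB]])), c(0, 1), tolerance = 1e-12)
})

test_that("node marginals agree between adjacent branches and enumeration", {
  skip_if_not_installed("Matrix")
  fx <- random_fixture(6, 3, seed = 204)
  bp <- branch_posteriors(fx$tree, fx$data, fx$model)
  marg_oracle <- oracle_node_marginals(fx$tree, fx$data, fx$model)
  n <- ape::Ntip(fx$tree)
  for (e in seq_len(nrow(fx$tree$edge))) {
    ch <- fx$tree$edge[e, 2]
    expect_equal(unname(colSums(bp$W[[e]])), marg_oracle[ch, ],
                 tolerance = 1e-10)
    pa <- fx$tree$edge[e, 1]
    expect_equal(unname(rowSums(bp$W[[e]])), marg_oracle[pa, ],
                 tolerance = 1e-10)
  }
})

test_that("mapping with no data reproduces unconditional CTMC expectations", {
  tr <- simulate_pure_birth_tree(16, 1, seed = 7)
  m <- build_rate_matrix(c(0.4, 0.9, 1.7), "SYM", 3, pi = "stationary")
  amb <- character_data(setNames(rep("?", 16), tr$tip.label),
                        alphabet = c("0", "1", "2"))
  mp <- map_tree(tr, amb, m)
  expect_lt(max(abs(mp$dwell - outer(tr$edge.length, m$pi))), 1e-8)
  expect_lt(max(abs(mp$away - outer(tr$edge.length, m$pi * (-diag(m$Q))))),
            1e-8)
})

test_that("mapping conserves branch lengths and derives away from pairwise", {
  tr <- simulate_pure_birth_tree(16, 1, seed = 7)
  m <- build_rate_matrix(1, "ER", 2)
  dat <- history_tip_states(simulate_history(tr, m, seed = 3))
  mp <- map_tree(tr, dat, m)
  expect_lt(max(abs(rowSums(mp$dwell) - tr$edge.length)), 1e-8)
  expect_true(all(mp$dwell >= 0) && all(mp$pairwise >= 0))
  away_from_pairwise <- apply(mp$pairwise, c(1, 2), sum)
  expect_lt(max(abs(mp$away - away_from_pairwise)), 1e-10)
  expect_equal(unname(mp$totals$dwell), unname(colSums(mp$dwell)))
})

test_that("zero-length branches yield zero expectations", {
  tr <- ape::read.tree(text = "((A:0,B:0.5):0.3,C:0.9);")
  m <- build_rate_matrix(1, "ER", 2)
  dat <- character_data(c(A = "0", B = "0", C = "1"), alphabet = c("0", "1"))
  mp <- map_tree(tr, dat, m)
  e0 <- which(tr$edge.length == 0)
  expect_equal(unname(mp$dwell[e0, ]), c(0, 0))
  expect_equal(unname(mp$away[e0, ]), c(0, 0))
})

test_that("tree-level totals match SIMMAP-style simulation (triangle)", {
  tr <- simulate_pure_birth_tree(16, 1, seed = 7)
  m <- build_rate_matrix(1, "ER", 2)
  dat <- history_tip_states(simulate_history(tr, m, seed = 3))
  mp <- map_tree(tr, dat, m)
  reps <- simulate_mappings(tr, dat, m, 20000, seed = 5)
  for (k in 1:2) {
    se_d <- sd(reps$tree_dwell[, k]) / sqrt(20000)
    expect_lt(abs(mean(reps$tree_dwell[, k]) - mp$totals$dwell[k]), 3 * se_d)
    se_a <- sd(reps$tree_away[, k]) / sqrt(20000)
    expect_lt(abs(mean(reps$tree_away[, k]) - mp$totals$away[k]), 3 * se_a)
  }
})

test_that("treeset mapping is deterministic and honors q_mode", {
  tr <- simulate_pure_birth_tree(10, 1, seed = 71)
  m <- build_rate_matrix(0.6, "ER", 2)
  dat <- history_tip_states(simulate_history(tr, m, seed = 72))
  ts <- as_treeset(list(tr, tr, tr))
  ms <- map_treeset(ts, dat, q_mode = "per-tree", constraint = "ER")
  expect_length(ms, 3L)
  for (k in 2:3) expect_equal(ms[[k]]$dwell, ms[[1]]$dwell, tolerance = 1e-12)

  # user Q: no optimization, result independent of constraint argument
  mu1 <- map_treeset(ts, dat, q_mode = "user", model = m, constraint = "ER")
  mu2 <- map_treeset(ts, dat, q_mode = "user", model = m, constraint = "ARD")
  expect_equal(mu1[[1]]$dwell, mu2[[1]]$dwell, tolerance = 1e-15)
  expect_equal(attr(mu1, "models")[[1]]$rates, m$rates)
})

test_that("mapping TSV serialization round-trips the key columns", {
  tr <- simulate_pure_birth_tree(8, 1, seed = 81)
  m <- build_rate_matrix(1, "ER", 2)
  dat <- history_tip_states(simulate_history(tr, m, seed = 82))
  mp <- map_tree(tr, dat, m)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_mapping_tsv(mp, p)
  tab <- read_mapping_tsv(p)
  expect_equal(nrow(tab), nrow(tr$edge))
  expect_equal(tab$clade, mp$clade)
  expect_equal(tab$dwell_0, unname(mp$dwell[, 1]), tolerance = 1e-10)
  expect_equal(tab$away_1, unname(mp$away[, 2]), tolerance = 1e-10)
})
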