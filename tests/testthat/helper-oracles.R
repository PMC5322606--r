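# Independent oracles used across the suite. These deliberately avoid the
# package's spectral route: matrix exponentials come from Matrix::expm
# (Pade approximation), likelihoods from exhaustive enumeration, and
# endpoint-conditioned expectations from adaptive quadrature.

# Matrix exponential independent of the package's eigendecomposition.
oracle_P <- function(Q, t) unname(as.matrix(Matrix::expm(Q * t)))

# Exhaustive-enumeration likelihood: sum over every assignment of states to
# internal nodes, with tip ambiguity summed inline. Only feasible for tiny
# trees; that is the point.
oracle_loglik <- function(tree, data, model) {
  tipmat <- data$matrix[tree$tip.label, , drop = FALSE]
  s <- ncol(tipmat)
  n <- ape::Ntip(tree)
  Pl <- lapply(tree$edge.length, function(b) oracle_P(model$Q, b))
  internals <- (n + 1L):(n + tree$Nnode)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(s)),
                                             length(internals))))
  tot <- 0
  st <- integer(n + tree$Nnode)
  for (r in seq_len(nrow(grid))) {
    st[internals] <- grid[r, ]
    p <- model$pi[st[n + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      p <- p * if (ch <= n) sum(Pl[[e]][st[pa], ] * tipmat[ch, ])
      else Pl[[e]][st[pa], st[ch]]
    }
    tot <- tot + p
  }
  unname(log(tot))
}

# sample() without the scalar-x expansion trap
resample <- function(x, size = 1L) x[sample.int(length(x), size)]

# Node-state marginal posteriors by the same enumeration.
oracle_node_marginals <- function(tree, data, model) {
  tipmat <- data$matrix[tree$tip.label, , drop = FALSE]
  s <- ncol(tipmat)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  Pl <- lapply(tree$edge.length, function(b) oracle_P(model$Q, b))
  allowed <- lapply(seq_len(nn), function(v)
    if (v <= n) which(tipmat[v, ] > 0) else seq_len(s))
  grid <- as.matrix(do.call(expand.grid, allowed))
  marg <- matrix(0, nn, s)
  for (r in seq_len(nrow(grid))) {
    st <- as.integer(grid[r, ])
    p <- model$pi[st[n + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * Pl[[e]][st[tree$edge[e, 1L]], st[tree$edge[e, 2L]]]
    for (v in seq_len(nn)) marg[v, st[v]] <- marg[v, st[v]] + p
  }
  marg / rowSums(marg)
}

# Random small fixture: rooted tree with uniform branch lengths plus a
# random character over s states (some tips made ambiguous).
random_fixture <- function(n_tips, s, seed, amb_prob = 0.2) {
  set.seed(seed)
  tree <- ape::rtree(n_tips, rooted = TRUE,
                     br = function(k) runif(k, 0.05, 1.2))
  states <- as.character(seq_len(s) - 1L)
  assign <- lapply(seq_len(n_tips), function(i) {
    if (runif(1) < amb_prob) sample(states, resample(2:s))
    else sample(states, 1)
  })
  names(assign) <- tree$tip.label
  rates <- runif(switch("SYM", SYM = s * (s - 1) / 2), 0.2, 2)
  model <- build_rate_matrix(rates, "SYM", s, pi = "uniform")
  list(tree = tree, data = character_data(assign, alphabet = states),
       model = model)
}

# Quadrature value of the endpoint-conditioned dwelling time in state i:
# int_0^T P_ai(tau) P_ib(T - tau) dtau / P_ab(T), via Matrix::expm.
oracle_dwell_quadrature <- function(Q, T_len, i, a, b) {
  f <- Vectorize(function(tau)
    oracle_P(Q, tau)[a, i] * oracle_P(Q, T_len - tau)[i, b])
  stats::integrate(f, 0, T_len, rel.tol = 1e-10)$value /
    oracle_P(Q, T_len)[a, b]
}

# Same for the expected i -> j transition count.
oracle_trans_quadrature <- function(Q, T_len, i, j, a, b) {
  f <- Vectorize(function(tau)
    oracle_P(Q, tau)[a, i] * oracle_P(Q, T_len - tau)[j, b])
  Q[i, j] * stats::integrate(f, 0, T_len, rel.tol = 1e-10)$value /
    oracle_P(Q, T_len)[a, b]
}
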