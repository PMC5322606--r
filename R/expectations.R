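# Analytic per-branch expectations: dwelling times and transition counts
# conditional on tip data, via spectral decomposition and integral factors.

#' Integral factor matrix for a branch
#'
#' For eigenvalues lambda of Q and a branch of length `T`, the factor
#' J_kl = int_0^T exp(lambda_k tau) exp(lambda_l (T - tau)) d tau
#'      = (exp(lambda_k T) - exp(lambda_l T)) / (lambda_k - lambda_l),
#' with the limit T exp(lambda_k T) when lambda_k = lambda_l (equality is
#' declared at tolerance 1e-9 * max(1, |lambda_k|)). These factors carry the
#' time integral in every endpoint-conditioned expectation, so they are
#' computed once per branch and shared by dwelling-time and transition
#' kernels.
#'
#' @param lambda Eigenvalue vector (real or complex).
#' @param T_len Non-negative branch length.
#' @return An s x s (possibly complex) symmetric matrix; all-zero when
#'   `T_len` is 0.
#' @export
integral_factor_matrix <- function(lambda, T_len) {
  if (!is.numeric(T_len) && !is.complex(T_len) || length(T_len) != 1L || Re(T_len) < 0)
    stop_phylomap("T_len must be a single non-negative number")
  s <- length(lambda)
  if (T_len == 0) {
    J <- matrix(if (is.complex(lambda)) 0 + 0i else 0, s, s)
    return(J)
  }
  el <- exp(lambda * T_len)
  num <- outer(el, el, `-`)
  den <- outer(lambda, lambda, `-`)
  eq <- Mod(den) < 1e-9 * pmax(1, outer(Mod(lambda), Mod(lambda), pmax))
  den[eq] <- 1  # placeholder; overwritten by the limit formula below
  J <- num / den
  lim <- T_len * el
  J[eq] <- matrix(lim, s, s)[eq]  # limit T e^{lambda_k T} on (near-)equal pairs
  J
}

# Endpoint-conditioning kernel: H_ij(a,b) = sum_{k,l} U_ak Uinv_ki U_jl
# Uinv_lb J_kl = [U (J * (Uinv[,i] %o% U[j,])) Uinv]_ab, the unconditional
# integral int_0^T P_ai(tau) P_jb(T - tau) dtau.
ec_kernel <- function(decomp, J, i, j) {
  decomp$U %*% (J * (decomp$U_inv[, i] %o% decomp$U[j, ])) %*% decomp$U_inv
}

# Take the real part of an expectation computed through a possibly complex
# eigenbasis, validating that the imaginary part is numerical noise.
real_part <- function(x, scale = 1) {
  if (is.complex(x)) {
    if (max(abs(Im(x))) > 1e-8 * max(1, scale))
      stop_phylomap("non-negligible imaginary part in expectation; ",
                    "defective rate matrix (use the quadrature fallback)")
    x <- Re(x)
  }
  x
}

#' Expected dwelling time in a state, conditioned on branch endpoints
#'
#' D_i(a, b) is the expected time spent in state `i` along a branch of
#' length `T_len`, given that the branch starts in state `a` and ends in
#' state `b`:
#' D_i(a,b) = \[ int_0^T P_ai(tau) P_ib(T - tau) d tau \] / P_ab(T).
#' Endpoint pairs with P_ab(T) = 0 are unreachable and reported as `NA`.
#'
#' @param decomp A `spectral_decomposition`.
#' @param T_len Branch length (>= 0).
#' @param state State index (1-based) or state label.
#' @return s x s matrix D_i indexed \[a, b\].
#' @export
endpoint_conditioned_dwell <- function(decomp, T_len, state) {
  stopifnot(inherits(decomp, "spectral_decomposition"))
  i <- resolve_state(decomp, state)
  s <- length(decomp$lambda)
  J <- integral_factor_matrix(decomp$lambda, T_len)
  num <- real_part(ec_kernel(decomp, J, i, i), scale = max(T_len, 1))
  P <- transition_probabilities(decomp, T_len)
  D <- num / P
  D[P == 0] <- NA_real_
  D[!is.na(D) & D < 0 & D > -1e-10] <- 0
  dimnames(D) <- dimnames(decomp$Q)
  D
}

#' Expected number of i -> j transitions, conditioned on branch endpoints
#'
#' N_ij(a, b) is the expected number of labelled i -> j jumps along a branch
#' of length `T_len` given endpoint states (a, b):
#' N_ij(a,b) = q_ij \[ int_0^T P_ai(tau) P_jb(T - tau) d tau \] / P_ab(T).
#'
#' @param decomp A `spectral_decomposition`.
#' @param T_len Branch length (>= 0).
#' @param from,to Distinct state indices (1-based) or labels.
#' @return s x s matrix N_ij indexed \[a, b\]; `NA` where P_ab(T) = 0.
#' @export
endpoint_conditioned_transitions <- function(decomp, T_len, from, to) {
  stopifnot(inherits(decomp, "spectral_decomposition"))
  i <- resolve_state(decomp, from)
  j <- resolve_state(decomp, to)
  if (i == j)
    stop_phylomap("diagonal transition counts are undefined: from == to")
  J <- integral_factor_matrix(decomp$lambda, T_len)
  num <- decomp$Q[i, j] * real_part(ec_kernel(decomp, J, i, j),
                                    scale = max(T_len, 1))
  P <- transition_probabilities(decomp, T_len)
  N <- num / P
  N[P == 0] <- NA_real_
  N[!is.na(N) & N < 0 & N > -1e-10] <- 0
  dimnames(N) <- dimnames(decomp$Q)
  N
}

resolve_state <- function(decomp, state) {
  states <- colnames(decomp$Q)
  if (is.character(state)) {
    i <- match(state, states)
    if (is.na(i)) stop_phylomap("unknown state label: ", state)
    return(i)
  }
  i <- as.integer(state)
  if (i < 1L || i > length(decomp$lambda))
    stop_phylomap("state index out of range: ", state)
  i
}

# Shared message-passing pass: postorder partials F, preorder outside
# partials A_e (at the top of each branch, siblings folded in), and the
# scaled child partials. All quantities are per-edge in tree$edge order.
# Ratios only are used downstream, so per-node scaling constants cancel.
branch_messages <- function(tree, data, model, decomp = NULL,
                            Plist = NULL) {
  if (!identical(data$alphabet, model$states))
    stop_phylomap("data alphabet does not match model states")
  decomp <- decomp %||% spectral_decompose(model)
  Plist <- Plist %||% edge_P_list(tree, decomp)
  tipmat <- align_tipmat(tree, data)
  s <- length(model$states)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  parts <- postorder_partials(tree, array(tipmat, c(n, s, 1L)), Plist)
  Fs <- matrix(parts$F[, , 1L], nn, s)  # scaled partials per node

  E <- nrow(tree$edge)
  # Down message per edge: Dn_e(a) = sum_b P_e(a,b) Fs_child(b)
  Dn <- matrix(0, E, s)
  for (e in seq_len(E))
    Dn[e, ] <- as.numeric(Plist[[e]] %*% Fs[tree$edge[e, 2L], ])

  children_of <- split(seq_len(E), tree$edge[, 1L])
  G <- matrix(0, nn, s)     # scaled outside partial at each node
  G[root_node(tree), ] <- model$pi
  A <- matrix(0, E, s)      # outside partial at top of each branch
  pre <- rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
  for (e in pre) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sibs <- setdiff(children_of[[as.character(p)]], e)
    a_e <- G[p, ]
    for (u in sibs) a_e <- a_e * Dn[u, ]
    m <- max(a_e)
    if (m > 0) a_e <- a_e / m
    A[e, ] <- a_e
    G[ch, ] <- as.numeric(a_e %*% Plist[[e]])
  }
  list(decomp = decomp, Plist = Plist, A = A, Fs = Fs, G = G,
       loglik = as.numeric(loglik_from_partials(tree, parts, model$pi)))
}

#' Joint endpoint posteriors for every branch
#'
#' For each branch (parent node v, child node c, length T) computes the s x s
#' matrix W with W\[a, b\] = P(state(v) = a, state(c) = b | tip data), via
#' postorder (inside) and preorder (outside) partials:
#' W_ab proportional to A(a) P_ab(T) F_c(b), normalized to sum to 1.
#' Underflow is guarded by per-node scaling; the scaling constants cancel in
#' the normalization.
#'
#' @param tree A rooted `phylo` tree.
#' @param data A `character_data` covering the tips.
#' @param model A `rate_model` with matching states.
#' @return A `branch_posteriors` object: list with `W` (list of s x s
#'   matrices, one per row of `tree$edge`), `edge`, `states`, `loglik`.
#' @export
branch_posteriors <- function(tree, data, model) {
  msg <- branch_messages(tree, data, model)
  E <- nrow(tree$edge)
  W <- vector("list", E)
  for (e in seq_len(E)) {
    w <- (msg$A[e, ] %o% msg$Fs[tree$edge[e, 2L], ]) * msg$Plist[[e]]
    tot <- sum(w)
    if (tot <= 0) stop_phylomap("zero-probability branch endpoint posterior ",
                                "(data impossible under the model)")
    w <- w / tot
    dimnames(w) <- list(model$states, model$states)
    W[[e]] <- w
  }
  structure(list(W = W, edge = tree$edge, states = model$states,
                 loglik = msg$loglik),
            class = "branch_posteriors")
}

#' Analytic stochastic mapping of one tree
#'
#' Computes, for every branch, the expected time spent in each state
#' (dwelling times) and the expected number of transitions between each
#' ordered state pair, conditional on the tip data, by combining
#' endpoint-conditioned expectations with the joint endpoint posteriors.
#' Away-from-state totals are derived from the pairwise matrix. Unreachable
#' endpoint pairs (P_ab(T) = 0) contribute exactly zero weight and are
#' excluded analytically, so no indeterminate terms arise; zero-length
#' branches get all-zero expectations.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param data A `character_data` covering the tips.
#' @param model A `rate_model` with matching states.
#' @return A `mapping_result`: list with per-edge matrices `dwell`
#'   (branch-length units), `dwell_frac` (fractions of branch length),
#'   `away`, `rate` (away counts per unit branch length), array `pairwise`
#'   (edges x s x s), `branch_length`, `clade` (canonical clade IDs), and
#'   `totals` (tree-level sums).
#' @export
map_tree <- function(tree, data, model) {
  msg <- branch_messages(tree, data, model)
  decomp <- msg$decomp
  s <- length(model$states)
  E <- nrow(tree$edge)
  Q <- model$Q
  dwell <- matrix(0, E, s, dimnames = list(NULL, model$states))
  pairwise <- array(0, c(E, s, s),
                    dimnames = list(NULL, model$states, model$states))
  blen <- tree$edge.length
  for (e in seq_len(E)) {
    T_e <- blen[e]
    if (T_e == 0) next
    ch <- tree$edge[e, 2L]
    # Wt = W / P, assembled without dividing by P: unreachable endpoint
    # pairs never enter the sums.
    Z <- as.numeric(msg$A[e, ] %*% msg$Plist[[e]] %*% msg$Fs[ch, ])
    Wt <- (msg$A[e, ] %o% msg$Fs[ch, ]) / Z
    J <- integral_factor_matrix(decomp$lambda, T_e)
    for (i in seq_len(s)) {
      dwell[e, i] <- real_part(sum(Wt * ec_kernel(decomp, J, i, i)),
                               scale = T_e)
      for (j in seq_len(s)) {
        if (i == j) next
        pairwise[e, i, j] <- Q[i, j] *
          real_part(sum(Wt * ec_kernel(decomp, J, i, j)), scale = max(T_e, 1))
      }
    }
  }
  dwell[dwell < 0] <- 0
  pairwise[pairwise < 0] <- 0
  away <- apply(pairwise, c(1L, 2L), sum)
  dimnames(away) <- list(NULL, model$states)
  dwell_frac <- dwell / ifelse(blen > 0, blen, 1)
  dwell_frac[blen == 0, ] <- 0
  rate <- away / ifelse(blen > 0, blen, 1)
  rate[blen == 0, ] <- 0
  structure(list(tree = tree, states = model$states,
                 clade = clade_ids(tree),
                 branch_length = blen,
                 dwell = dwell, dwell_frac = dwell_frac,
                 away = away, rate = rate, pairwise = pairwise,
                 loglik = msg$loglik,
                 totals = list(dwell = colSums(dwell),
                               away = colSums(away),
                               pairwise = apply(pairwise, c(2L, 3L), sum))),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat("mapping_result:", length(x$branch_length), "branches,",
      length(x$states), "states\n")
  cat("tree-level expected dwelling times:\n")
  print(round(x$totals$dwell, 4))
  cat("tree-level expected transitions away from each state:\n")
  print(round(x$totals$away, 4))
  invisible(x)
}

#' Analytic stochastic mapping over a set of trees
#'
#' Runs [map_tree()] on every tree of a posterior sample. The rate matrix is
#' either re-estimated per tree (`q_mode = "per-tree"`), estimated once on
#' the first tree and reused (`"pooled"`), or supplied by the user
#' (`"user"`, no optimization).
#'
#' @param trees A `treeset` / `multiPhylo` (shared taxon namespace).
#' @param data A `character_data` covering the namespace.
#' @param q_mode `"per-tree"`, `"pooled"`, or `"user"`.
#' @param model A `rate_model`; required when `q_mode = "user"`.
#' @param constraint Constraint class for estimation modes.
#' @param pi Root prior specification (see [build_rate_matrix()]).
#' @param starts Multistarts for each estimation.
#' @param on_error `"stop"` (default, fail fast naming the tree) or
#'   `"skip"` (replace the failing tree's result with `NULL` and warn).
#' @return A `mapping_set`: list of `mapping_result` in input order, with
#'   attribute `models` (the `rate_model` used for each tree).
#' @export
map_treeset <- function(trees, data, q_mode = c("per-tree", "pooled", "user"),
                        model = NULL, constraint = "ER", pi = "uniform",
                        starts = 3L, on_error = c("stop", "skip")) {
  q_mode <- match.arg(q_mode)
  on_error <- match.arg(on_error)
  trees <- as_treeset(trees)
  if (q_mode == "user" && is.null(model))
    stop_phylomap("q_mode = 'user' requires a rate_model")
  if (q_mode == "pooled")
    model <- estimate_mle(trees[[1L]], data, constraint = constraint,
                          pi = pi, starts = starts)
  results <- vector("list", length(trees))
  models <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    res <- tryCatch({
      mi <- if (q_mode == "per-tree")
        estimate_mle(trees[[i]], data, constraint = constraint,
                     pi = pi, starts = starts)
      else model
      list(mapping = map_tree(trees[[i]], data, mi), model = mi)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "stop")
        stop_phylomap("mapping failed on tree ", i, ": ",
                      conditionMessage(res))
      warning("mapping failed on tree ", i, ": ", conditionMessage(res))
      results[i] <- list(NULL); models[i] <- list(NULL)
    } else {
      results[[i]] <- res$mapping
      models[[i]] <- res$model
    }
  }
  structure(results, models = models, class = "mapping_set")
}

#' Write / read per-branch mapping results as TSV
#'
#' One row per (tree index, branch clade ID) with the branch length, the
#' expected dwelling time in each state (absolute and as a fraction of
#' branch length) and the expected number of transitions away from each
#' state.
#'
#' @param mappings A `mapping_result` or `mapping_set`.
#' @param path Output TSV path.
#' @export
write_mapping_tsv <- function(mappings, path) {
  if (inherits(mappings, "mapping_result")) mappings <- list(mappings)
  rows <- lapply(seq_along(mappings), function(i) {
    m <- mappings[[i]]
    if (is.null(m)) return(NULL)
    df <- data.frame(tree = i, clade = m$clade,
                     branch_length = m$branch_length,
                     check.names = FALSE)
    for (k in seq_along(m$states)) {
      df[[paste0("dwell_", m$states[k])]] <- m$dwell[, k]
      df[[paste0("dwell_frac_", m$states[k])]] <- m$dwell_frac[, k]
      df[[paste0("away_", m$states[k])]] <- m$away[, k]
    }
    df
  })
  out <- do.call(rbind, rows)
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping_tsv
#' @return `read_mapping_tsv()` returns the table as a data frame.
#' @export
read_mapping_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = NA)
}
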