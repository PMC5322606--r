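# Simulators: pure-birth trees, exact character histories, and
# endpoint-conditioned path sampling. These provide fixtures with known
# per-branch truth and the simulation side of the analytic-vs-simulation
# cross-validation.

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Constant-rate speciation-only branching: starting from a single stem
#' lineage, waiting times between successive births are exponential with
#' rate `k * birth_rate` while `k` lineages are alive, each birth splits a
#' uniformly chosen lineage, and the process is observed at the moment the
#' `n`-th lineage appears. All tips therefore end at the same time
#' (ultrametric). The stem interval (origin to first split) is retained as
#' `root.edge`, so the total depth including the stem has expectation
#' sum_{k=1}^{n-1} 1 / (k * birth_rate).
#'
#' @param n Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return An ultrametric rooted bifurcating `phylo` with tips
#'   `t1 ... tn` and `root.edge` set.
#' @export
simulate_pure_birth_tree <- function(n, birth_rate = 1, seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop_phylomap("need n >= 2 tips")
  if (birth_rate <= 0) stop_phylomap("birth_rate must be positive")
  with_seed(seed, {
    wait <- stats::rexp(n - 1L, rate = birth_rate * seq_len(n - 1L))
    t_ev <- cumsum(wait)
    depth <- t_ev[n - 1L]
    nlin <- 2L * n - 1L            # stem + 2 per split
    birth <- numeric(nlin)
    parent_lin <- integer(nlin)    # lineage whose split created this one
    split_of <- integer(nlin)      # event index at which lineage splits (0 = tip)
    alive <- 1L
    made <- 1L
    for (k in seq_len(n - 1L)) {
      L <- alive[sample.int(length(alive), 1L)]
      split_of[L] <- k
      kids <- made + 1:2
      birth[kids] <- t_ev[k]
      parent_lin[kids] <- L
      made <- made + 2L
      alive <- c(alive[alive != L], kids)
    }
    # Lineage -> node numbers: tips 1..n (in lineage order among survivors),
    # splits n+1 .. 2n-1 in chronological order (root = first split = n+1).
    node_of <- integer(nlin)
    tip_ids <- sort(alive)
    node_of[tip_ids] <- seq_len(n)
    splitters <- which(split_of > 0L)
    node_of[splitters] <- n + split_of[splitters]
    edge <- matrix(0L, 2L * (n - 1L), 2L)
    elen <- numeric(nrow(edge))
    r <- 0L
    for (L in seq_len(nlin)[-1L]) {      # every lineage but the stem is an edge
      if (L > made) break
      r <- r + 1L
      edge[r, ] <- c(n + split_of[parent_lin[L]], node_of[L])
      end_t <- if (split_of[L] > 0L) t_ev[split_of[L]] else depth
      elen[r] <- end_t - birth[L]
    }
    tree <- structure(list(edge = edge[seq_len(r), , drop = FALSE],
                           edge.length = elen[seq_len(r)],
                           tip.label = paste0("t", seq_len(n)),
                           Nnode = n - 1L,
                           root.edge = wait[1L]),
                      class = "phylo", order = "cladewise")
    ape::reorder.phylo(tree)
  })
}

#' Simulate an exact character history on a tree
#'
#' Forward simulation of the CTMC: the root state is drawn from the model's
#' root prior (or fixed), then each branch is traversed root-to-tip with
#' exponential waiting times (rate -q_ii) and jumps proportional to the
#' off-diagonal rates. The realized history carries per-branch
#' (state, duration) segments, realized dwelling times, realized pairwise
#' and away-from-state transition counts, and the implied tip states.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param model A `rate_model`.
#' @param seed Optional integer seed.
#' @param root_state Optional fixed root state (label or index).
#' @return A `true_history` object.
#' @export
simulate_history <- function(tree, model, seed = NULL, root_state = NULL) {
  stopifnot(inherits(model, "rate_model"))
  s <- length(model$states)
  Q <- model$Q
  with_seed(seed, {
    E <- nrow(tree$edge)
    nn <- ape::Ntip(tree) + tree$Nnode
    node_state <- integer(nn)
    node_state[root_node(tree)] <- if (is.null(root_state))
      sample.int(s, 1L, prob = model$pi)
    else resolve_state(structure(list(Q = Q, lambda = numeric(s)),
                                 class = "spectral_decomposition"), root_state)
    segments <- vector("list", E)
    dwell <- matrix(0, E, s, dimnames = list(NULL, model$states))
    pairwise <- array(0, c(E, s, s),
                      dimnames = list(NULL, model$states, model$states))
    pre <- rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
    for (e in pre) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      T_e <- tree$edge.length[e]
      cur <- node_state[p]
      st <- integer(0); du <- numeric(0)
      left <- T_e
      repeat {
        r_out <- -Q[cur, cur]
        dt <- if (r_out > 0) stats::rexp(1L, r_out) else Inf
        if (dt >= left) { st <- c(st, cur); du <- c(du, left); break }
        st <- c(st, cur); du <- c(du, dt); left <- left - dt
        others <- setdiff(seq_len(s), cur)
        cur <- others[sample.int(length(others), 1L, prob = Q[cur, others])]
      }
      segments[[e]] <- data.frame(state = model$states[st], duration = du)
      node_state[ch] <- cur
      for (k in seq_along(st)) dwell[e, st[k]] <- dwell[e, st[k]] + du[k]
      if (length(st) > 1L)
        for (k in 2:length(st))
          pairwise[e, st[k - 1L], st[k]] <- pairwise[e, st[k - 1L], st[k]] + 1
    }
    away <- apply(pairwise, c(1L, 2L), sum)
    dimnames(away) <- list(NULL, model$states)
    tips <- stats::setNames(model$states[node_state[seq_len(ape::Ntip(tree))]],
                            tree$tip.label)
    structure(list(tree = tree, states = model$states, segments = segments,
                   node_states = model$states[node_state],
                   tip_states = tips,
                   dwell = dwell, pairwise = pairwise, away = away,
                   totals = list(dwell = colSums(dwell),
                                 away = colSums(away),
                                 transitions = sum(pairwise)),
                   seed = seed),
              class = "true_history")
  })
}

#' @export
print.true_history <- function(x, ...) {
  cat("true_history:", nrow(x$dwell), "branches;",
      x$totals$transitions, "realized transitions\n")
  cat("realized dwelling times:", paste(signif(x$totals$dwell, 5),
                                        collapse = " "), "\n")
  invisible(x)
}

#' Tip states of a history as character data
#'
#' @param history A `true_history`.
#' @return A [character_data()] over the model's full alphabet.
#' @export
history_tip_states <- function(history) {
  stopifnot(inherits(history, "true_history"))
  character_data(history$tip_states, alphabet = history$states)
}

#' Sample one endpoint-conditioned CTMC path
#'
#' Draws a path of the chain on a single branch of length `T_len`,
#' conditioned to start in state `a` and end in state `b`, from the exact
#' conditional law. Uniformization (a dominating Poisson process at rate
#' mu = max_i |q_ii| with self-jumps allowed) is used unless the expected
#' number of auxiliary events mu * T exceeds 1e4, in which case rejection
#' sampling of unconditional forward paths is used; the method is recorded
#' in the `method` attribute.
#'
#' @param model A `rate_model` (or bare rate matrix Q).
#' @param T_len Branch length.
#' @param a,b Endpoint states (labels or 1-based indices).
#' @param seed Optional integer seed.
#' @return A data frame of (state, duration) segments; consecutive segments
#'   have distinct states and durations sum to `T_len`.
#' @export
sample_endpoint_conditioned_path <- function(model, T_len, a, b, seed = NULL) {
  Q <- if (inherits(model, "rate_model")) model$Q else validate_rate_matrix(model)
  states <- colnames(Q) %||% as.character(seq_len(nrow(Q)) - 1L)
  fake <- structure(list(Q = Q, lambda = numeric(nrow(Q))),
                    class = "spectral_decomposition")
  ai <- resolve_state(fake, a); bi <- resolve_state(fake, b)
  mu <- max(-diag(Q))
  with_seed(seed, {
    if (mu * T_len > 1e4) {
      segs <- rejection_sample_path(Q, T_len, ai, bi)
      attr(segs, "method") <- "rejection"
    } else {
      s <- nrow(Q)
      Rmat <- diag(s) + Q / max(mu, .Machine$double.eps)
      res <- ec_sample_path_cpp(Rmat, mu, T_len, ai - 1L, bi - 1L)
      segs <- data.frame(state = states[res$state + 1L],
                         duration = res$duration)
      attr(segs, "method") <- "uniformization"
    }
    segs
  })
}

# Rejection fallback: forward-simulate from a until a path ending in b at
# time T is found.
rejection_sample_path <- function(Q, T_len, ai, bi, max_tries = 1e6) {
  s <- nrow(Q)
  states <- colnames(Q) %||% as.character(seq_len(s) - 1L)
  for (try in seq_len(max_tries)) {
    cur <- ai; left <- T_len
    st <- integer(0); du <- numeric(0)
    repeat {
      r_out <- -Q[cur, cur]
      dt <- if (r_out > 0) stats::rexp(1L, r_out) else Inf
      if (dt >= left) { st <- c(st, cur); du <- c(du, left); break }
      st <- c(st, cur); du <- c(du, dt); left <- left - dt
      others <- setdiff(seq_len(s), cur)
      cur <- others[sample.int(length(others), 1L, prob = Q[cur, others])]
    }
    if (cur == bi)
      return(data.frame(state = states[st], duration = du))
  }
  stop_phylomap("rejection sampling failed to hit endpoint ", bi,
                " in ", max_tries, " tries")
}

#' Sample many endpoint-conditioned paths in bulk
#'
#' Replicated version of [sample_endpoint_conditioned_path()] returning
#' realized summaries instead of segment lists: per-replicate dwelling
#' times per state and pairwise transition counts.
#'
#' @inheritParams sample_endpoint_conditioned_path
#' @param n Number of replicate paths.
#' @return List with `dwell` (n x s matrix) and `pairwise`
#'   (n x s x s array of counts).
#' @export
sample_endpoint_conditioned_paths <- function(model, T_len, a, b, n,
                                              seed = NULL) {
  Q <- if (inherits(model, "rate_model")) model$Q else validate_rate_matrix(model)
  states <- colnames(Q) %||% as.character(seq_len(nrow(Q)) - 1L)
  s <- nrow(Q)
  fake <- structure(list(Q = Q, lambda = numeric(s)),
                    class = "spectral_decomposition")
  ai <- resolve_state(fake, a); bi <- resolve_state(fake, b)
  mu <- max(-diag(Q))
  Rmat <- diag(s) + Q / max(mu, .Machine$double.eps)
  res <- with_seed(seed,
    ec_sample_bulk_cpp(Rmat, mu, T_len, ai - 1L, bi - 1L, as.integer(n)))
  dwell <- res$dwell
  colnames(dwell) <- states
  # C++ packs pair (i, j) at 0-based column i * s + j (i = from-state).
  pairwise <- array(0L, c(n, s, s), dimnames = list(NULL, states, states))
  for (i in seq_len(s)) for (j in seq_len(s))
    pairwise[, i, j] <- res$trans[, (i - 1L) * s + j]
  list(dwell = dwell, pairwise = pairwise)
}

#' SIMMAP-style simulation-based stochastic mapping
#'
#' The classical simulation route the analytic expectations replace: node
#' states are drawn jointly from their conditional posterior given the tip
#' data (postorder partials, then preorder sampling), and each branch is
#' filled in with an endpoint-conditioned path. Replicate means of
#' dwelling-time and transition totals converge to the [map_tree()]
#' expectations as `n_reps` grows.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param data A `character_data` covering the tips.
#' @param model A `rate_model` with matching states.
#' @param n_reps Number of replicate mappings (>= 1).
#' @param seed Optional integer seed.
#' @param keep_paths If `TRUE`, also return full per-replicate
#'   `true_history`-style segment lists (intended for small `n_reps`).
#' @return A `mapping_replicates` object: `dwell` (n_reps x branches x s),
#'   `pairwise` (n_reps x branches x s x s counts), `tree_dwell`,
#'   `tree_away` (n_reps x s totals), and optionally `paths`.
#' @export
simulate_mappings <- function(tree, data, model, n_reps, seed = NULL,
                              keep_paths = FALSE) {
  stopifnot(inherits(model, "rate_model"), n_reps >= 1L)
  n_reps <- as.integer(n_reps)
  s <- length(model$states)
  E <- nrow(tree$edge)
  decomp <- spectral_decompose(model)
  Plist <- edge_P_list(tree, decomp)
  tipmat <- align_tipmat(tree, data)
  n <- ape::Ntip(tree)
  parts <- postorder_partials(tree, array(tipmat, c(n, s, 1L)), Plist)
  Fs <- matrix(parts$F[, , 1L], n + tree$Nnode, s)
  mu <- max(-diag(model$Q))
  Rmat <- diag(s) + model$Q / max(mu, .Machine$double.eps)
  pre <- rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))

  with_seed(seed, {
    # 1. Joint node-state sample for every replicate.
    node_states <- matrix(0L, n_reps, n + tree$Nnode)
    pr <- model$pi * Fs[root_node(tree), ]
    node_states[, root_node(tree)] <-
      sample.int(s, n_reps, replace = TRUE, prob = pr)
    for (e in pre) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      cond <- Plist[[e]] * rep(Fs[ch, ], each = s)  # rows: parent state
      ps <- node_states[, p]
      cs <- integer(n_reps)
      for (a in seq_len(s)) {
        idx <- which(ps == a)
        if (length(idx))
          cs[idx] <- sample.int(s, length(idx), replace = TRUE,
                                prob = cond[a, ])
      }
      node_states[, ch] <- cs
    }
    # 2. Endpoint-conditioned path summaries per branch, grouped by (a, b).
    dwell <- array(0, c(n_reps, E, s))
    pairwise <- array(0L, c(n_reps, E, s, s))
    tree_dwell <- matrix(0, n_reps, s, dimnames = list(NULL, model$states))
    tree_away <- matrix(0, n_reps, s, dimnames = list(NULL, model$states))
    for (e in seq_len(E)) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      T_e <- tree$edge.length[e]
      key <- (node_states[, p] - 1L) * s + node_states[, ch]
      for (k in sort(unique(key))) {
        idx <- which(key == k)
        a <- (k - 1L) %/% s + 1L; b <- (k - 1L) %% s + 1L
        res <- ec_sample_bulk_cpp(Rmat, mu, T_e, a - 1L, b - 1L,
                                  length(idx))
        dwell[idx, e, ] <- res$dwell
        # C++ packs pair (i, j) at 0-based column i * s + j.
        for (i in seq_len(s)) {
          cols <- (i - 1L) * s + seq_len(s)
          for (j in seq_len(s))
            pairwise[idx, e, i, j] <- res$trans[, cols[j]]
          tree_away[idx, i] <- tree_away[idx, i] +
            rowSums(res$trans[, cols, drop = FALSE])
        }
        tree_dwell[idx, ] <- tree_dwell[idx, , drop = FALSE] + res$dwell
      }
    }
    out <- list(dwell = dwell, pairwise = pairwise,
                tree_dwell = tree_dwell, tree_away = tree_away,
                states = model$states, edge = tree$edge,
                node_states = node_states, seed = seed)
    if (keep_paths) {
      paths <- vector("list", n_reps)
      for (r in seq_len(n_reps)) {
        segs <- vector("list", E)
        for (e in seq_len(E)) {
          a <- node_states[r, tree$edge[e, 1L]]
          b <- node_states[r, tree$edge[e, 2L]]
          res <- ec_sample_path_cpp(Rmat, mu, tree$edge.length[e],
                                    a - 1L, b - 1L)
          segs[[e]] <- data.frame(state = model$states[res$state + 1L],
                                  duration = res$duration)
        }
        paths[[r]] <- segs
      }
      out$paths <- paths
    }
    structure(out, class = "mapping_replicates")
  })
}

#' @export
print.mapping_replicates <- function(x, ...) {
  cat("mapping_replicates:", nrow(x$tree_dwell), "replicates,",
      dim(x$dwell)[2L], "branches\n")
  cat("mean tree-level dwelling:",
      paste(signif(colMeans(x$tree_dwell), 5), collapse = " "), "\n")
  cat("mean tree-level transitions away:",
      paste(signif(colMeans(x$tree_away), 5), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a true history's segments as TSV
#'
#' One row per segment: edge index, clade ID of the branch's child node,
#' segment order, state, duration.
#'
#' @param history A `true_history`.
#' @param path Output TSV path.
#' @export
write_history_tsv <- function(history, path) {
  stopifnot(inherits(history, "true_history"))
  ids <- clade_ids(history$tree)
  rows <- lapply(seq_along(history$segments), function(e) {
    seg <- history$segments[[e]]
    data.frame(edge = e, clade = ids[e], segment = seq_len(nrow(seg)),
               state = seg$state, duration = seg$duration)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
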