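# Felsenstein pruning and ML estimation of the rate matrix.

# Align a character_data matrix to a tree's tip order; validates coverage.
align_tipmat <- function(tree, data) {
  stopifnot(inherits(data, "character_data"))
  missing <- setdiff(tree$tip.label, rownames(data$matrix))
  if (length(missing))
    stop_phylomap("taxa without state assignments: ",
                  paste(missing, collapse = ", "))
  data$matrix[tree$tip.label, , drop = FALSE]
}

# Per-edge transition matrices for a tree under one decomposition.
edge_P_list <- function(tree, decomp) {
  lapply(tree$edge.length, function(b) transition_probabilities(decomp, b))
}

# Scaled postorder partial likelihoods for C characters at once.
# tipF: n x s x C array of tip indicators. Returns F (nn x s x C) and
# per-node accumulated log scaling factors (nn x C).
postorder_partials <- function(tree, tipF, Plist) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  s <- dim(tipF)[2L]
  C <- dim(tipF)[3L]
  Fm <- array(1, c(nn, s, C))
  Fm[seq_len(n), , ] <- tipF
  logsc <- matrix(0, nn, C)
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  for (e in po) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    msg <- Plist[[e]] %*% matrix(Fm[ch, , ], s, C)
    m <- apply(msg, 2L, max)
    m[m <= 0] <- 1  # zero-likelihood character: keep zeros, avoid log(0) here
    Fm[p, , ] <- matrix(Fm[p, , ], s, C) * sweep(msg, 2L, m, "/")
    logsc[p, ] <- logsc[p, ] + log(m) + logsc[ch, ]
  }
  list(F = Fm, logsc = logsc, po = po)
}

# Log-likelihood(s) from precomputed pieces; returns length-C vector.
loglik_from_partials <- function(tree, parts, pi) {
  r <- root_node(tree)
  s <- length(pi)
  C <- dim(parts$F)[3L]
  lik <- colSums(pi * matrix(parts$F[r, , ], s, C))
  log(lik) + parts$logsc[r, ]
}

#' Log-likelihood of tip data under a CTMC on a tree
#'
#' Felsenstein's pruning algorithm with per-node scaling: a postorder dynamic
#' program over partial likelihoods, returning
#' log( sum_a pi_a F_root(a) ).
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param data A [character_data()] object covering the tree's tips; its
#'   alphabet must match the model's states.
#' @param model A `rate_model`.
#' @return The log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(tree, data, model) {
  stopifnot(inherits(model, "rate_model"))
  if (!identical(data$alphabet, model$states))
    stop_phylomap("data alphabet (", paste(data$alphabet, collapse = ","),
                  ") does not match model states (",
                  paste(model$states, collapse = ","), ")")
  tipmat <- align_tipmat(tree, data)
  decomp <- spectral_decompose(model)
  Plist <- edge_P_list(tree, decomp)
  tipF <- array(tipmat, c(dim(tipmat), 1L))
  parts <- postorder_partials(tree, tipF, Plist)
  as.numeric(loglik_from_partials(tree, parts, model$pi))
}

#' Maximum-likelihood estimation of the rate matrix
#'
#' Fits the free rates of Q under the given constraint by bounded
#' quasi-Newton optimization (via [stats::nlminb()]) in log-rate space, with
#' multiple starting points spread across orders of magnitude. When `data`
#' is a list of `character_data` objects the characters are treated as
#' independent realizations of the same chain and their log-likelihoods are
#' summed (a pooled fit).
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param data A `character_data`, or a list of them (shared alphabet).
#' @param constraint `"ER"`, `"SYM"`, or `"ARD"`.
#' @param bounds Length-2 positive rate interval; default
#'   `c(1e-8, 1e3) / mean(branch lengths)`.
#' @param starts Number of multistarts (>= 1); starting rates are spread
#'   log-uniformly around 1 / mean branch length.
#' @param pi Root prior passed to [build_rate_matrix()].
#' @return The best `rate_model` found, with attributes `logLik`,
#'   `convergence` (nlminb convergence code of the best start) and `starts`
#'   (per-start objective values).
#' @export
estimate_mle <- function(tree, data, constraint = c("ER", "SYM", "ARD"),
                         bounds = NULL, starts = 3L, pi = "uniform") {
  constraint <- match.arg(constraint)
  if (inherits(data, "character_data")) data <- list(data)
  stopifnot(length(data) >= 1L, starts >= 1L)
  alph <- data[[1L]]$alphabet
  for (d in data)
    if (!identical(d$alphabet, alph))
      stop_phylomap("all characters must share one state alphabet")
  s <- length(alph)
  npar <- switch(constraint, ER = 1L, SYM = (s * (s - 1L)) %/% 2L,
                 ARD = s * (s - 1L))
  mean_bl <- mean(tree$edge.length)
  if (!is.finite(mean_bl) || mean_bl <= 0)
    stop_phylomap("tree must have positive branch lengths for estimation")
  bounds <- bounds %||% (c(1e-8, 1e3) / mean_bl)
  if (length(bounds) != 2L || any(bounds <= 0) || bounds[1L] >= bounds[2L])
    stop_phylomap("bounds must be an increasing positive interval")

  n <- ape::Ntip(tree)
  C <- length(data)
  tipF <- array(0, c(n, s, C))
  for (k in seq_len(C)) tipF[, , k] <- align_tipmat(tree, data[[k]])

  negll <- function(logr) {
    model <- tryCatch(
      build_rate_matrix(exp(logr), constraint, s, states = alph, pi = pi),
      error = function(e) NULL)
    if (is.null(model)) return(1e10)
    val <- tryCatch({
      decomp <- spectral_decompose(model)
      Plist <- edge_P_list(tree, decomp)
      parts <- postorder_partials(tree, tipF, Plist)
      -sum(loglik_from_partials(tree, parts, model$pi))
    }, error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }

  r0 <- 1 / mean_bl
  factors <- 10^seq(-1, 1, length.out = max(starts, 2L))[seq_len(starts)]
  if (starts == 1L) factors <- 1
  fits <- vector("list", starts)
  for (i in seq_len(starts)) {
    start_rate <- min(max(r0 * factors[i], bounds[1L] * 1.01), bounds[2L] * 0.99)
    fits[[i]] <- tryCatch(
      stats::nlminb(rep(log(start_rate), npar), negll,
                    lower = log(bounds[1L]), upper = log(bounds[2L]),
                    control = list(rel.tol = 1e-10, iter.max = 500L)),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok))
    stop_phylomap("all optimization starts failed for constraint ", constraint)
  objs <- vapply(fits, function(f) if (is.null(f)) Inf else f$objective, 0)
  best <- fits[[which.min(objs)]]
  model <- build_rate_matrix(exp(best$par), constraint, s, states = alph, pi = pi)
  attr(model, "logLik") <- -best$objective
  attr(model, "convergence") <- best$convergence
  attr(model, "starts") <- objs
  model
}

#' Serialize / parse a model report
#'
#' A tagged key-value text format recording the constraint, fitted rates,
#' root prior, full Q, and fit diagnostics; [read_model_report()] restores a
#' usable `rate_model` from it (e.g. as a user-supplied Q).
#'
#' @param model A `rate_model`.
#' @param path Output path.
#' @export
write_model_report <- function(model, path) {
  stopifnot(inherits(model, "rate_model"))
  lines <- c(
    paste0("constraint\t", model$constraint),
    paste0("states\t", paste(model$states, collapse = ",")),
    paste0("rates\t", paste(format(model$rates, digits = 17), collapse = ",")),
    paste0("pi_mode\t", model$pi_mode),
    paste0("pi\t", paste(format(model$pi, digits = 17), collapse = ",")),
    paste0("logLik\t", format(attr(model, "logLik") %||% NA, digits = 17)),
    paste0("convergence\t", attr(model, "convergence") %||% NA))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_report
#' @param path Path to a model report written by [write_model_report()].
#' @return A `rate_model`.
#' @export
read_model_report <- function(path) {
  kv <- strsplit(readLines(path), "\t", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  states <- strsplit(vals[["states"]], ",", fixed = TRUE)[[1L]]
  rates <- as.numeric(strsplit(vals[["rates"]], ",", fixed = TRUE)[[1L]])
  pi <- as.numeric(strsplit(vals[["pi"]], ",", fixed = TRUE)[[1L]])
  model <- build_rate_matrix(rates, vals[["constraint"]], length(states),
                             states = states, pi = pi / sum(pi))
  if (!is.na(vals[["logLik"]]))
    attr(model, "logLik") <- as.numeric(vals[["logLik"]])
  model
}
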