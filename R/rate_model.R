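#' Build a CTMC rate matrix under a symmetry constraint
#'
#' Constructs the instantaneous rate matrix Q of a continuous-time Markov
#' chain over `s` states, parameterized by positive rates under one of the
#' standard constraint classes: `ER` (equal rates, 1 free rate), `SYM`
#' (symmetric, s(s-1)/2 free rates filling the upper triangle row-wise and
#' mirrored), or `ARD` (all rates different, s(s-1) free rates filling
#' off-diagonals row-wise). Diagonals are set so every row sums to zero.
#'
#' @param rates Numeric vector of positive rates, length matching the
#'   constraint (see above).
#' @param constraint `"ER"`, `"SYM"`, or `"ARD"`.
#' @param s Number of states (>= 2).
#' @param states Optional state labels (default `"0", "1", ...`).
#' @param pi Root prior: `"uniform"` (default), `"stationary"` (stationary
#'   distribution of Q), or a numeric probability vector of length `s`.
#' @return A `rate_model` object: list with `Q`, `constraint`, `pi`,
#'   `pi_mode`, `rates`, `states`.
#' @export
build_rate_matrix <- function(rates, constraint = c("ER", "SYM", "ARD"),
                              s, states = NULL, pi = "uniform") {
  constraint <- match.arg(constraint)
  s <- as.integer(s)
  if (s < 2L) stop_phylomap("need at least 2 states")
  npar <- switch(constraint, ER = 1L, SYM = (s * (s - 1L)) %/% 2L,
                 ARD = s * (s - 1L))
  if (length(rates) != npar)
    stop_phylomap(constraint, " with s=", s, " needs ", npar,
                  " rates, got ", length(rates))
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop_phylomap("all rates must be positive and finite")
  states <- as.character(states %||% (seq_len(s) - 1L))
  stopifnot(length(states) == s)
  Q <- matrix(0, s, s, dimnames = list(states, states))
  if (constraint == "ER") {
    Q[] <- rates[1L]
  } else if (constraint == "SYM") {
    k <- 1L
    for (i in 1:(s - 1L)) for (j in (i + 1L):s) {
      Q[i, j] <- Q[j, i] <- rates[k]; k <- k + 1L
    }
  } else {
    k <- 1L
    for (i in 1:s) for (j in 1:s) if (i != j) {
      Q[i, j] <- rates[k]; k <- k + 1L
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  pi_mode <- if (is.character(pi)) match.arg(pi, c("uniform", "stationary")) else "user"
  piv <- switch(pi_mode,
                uniform = rep(1 / s, s),
                stationary = stationary_distribution(Q),
                user = {
                  pi <- as.numeric(pi)
                  if (length(pi) != s || any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
                    stop_phylomap("pi must be a length-", s, " probability vector")
                  pi / sum(pi)
                })
  names(piv) <- states
  structure(list(Q = Q, constraint = constraint, pi = piv, pi_mode = pi_mode,
                 rates = as.numeric(rates), states = states),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("rate_model (", x$constraint, ", ", length(x$states), " states)\n", sep = "")
  print(round(x$Q, 6))
  cat("root prior (", x$pi_mode, "): ",
      paste(signif(x$pi, 4), collapse = " "), "\n", sep = "")
  if (!is.null(attr(x, "logLik")))
    cat("logLik:", format(attr(x, "logLik")), "\n")
  invisible(x)
}

#' Stationary distribution of a rate matrix
#'
#' Solves pi Q = 0 subject to sum(pi) = 1.
#'
#' @param Q A valid s x s rate matrix (rows sum to zero).
#' @return Numeric probability vector of length s.
#' @export
stationary_distribution <- function(Q) {
  s <- nrow(Q)
  A <- rbind(t(Q), rep(1, s))
  pi <- qr.solve(A, c(rep(0, s), 1))
  pi[pi < 0 & pi > -1e-12] <- 0
  if (any(pi < 0)) stop_phylomap("negative stationary probability; invalid Q")
  stats::setNames(pi / sum(pi), colnames(Q))
}

validate_rate_matrix <- function(Q, tol = 1e-12) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop_phylomap("Q must be a square matrix")
  offd <- Q; diag(offd) <- 0
  if (any(offd < -tol)) stop_phylomap("negative off-diagonal rate in Q")
  if (any(abs(rowSums(Q)) > 1e-8 * max(1, max(abs(Q)))))
    stop_phylomap("rows of Q must sum to zero")
  invisible(Q)
}

#' Spectral decomposition of a rate matrix
#'
#' Decomposes Q = U diag(lambda) U^-1. For a reversible chain (detected via
#' detailed balance against the stationary distribution) the decomposition
#' goes through a similarity transform to a symmetric matrix, guaranteeing
#' real eigenvalues and an orthogonally-derived, well-conditioned basis. For
#' general (ARD) matrices a plain eigendecomposition is used, possibly with
#' complex eigenvalues; downstream computations then run in complex
#' arithmetic and validate that imaginary parts vanish.
#'
#' @param model A `rate_model`, or a bare rate matrix Q.
#' @return A `spectral_decomposition`: list with `U`, `lambda`, `U_inv`,
#'   `Q`, `symmetric_transform_used`.
#' @export
spectral_decompose <- function(model) {
  Q <- if (inherits(model, "rate_model")) model$Q else model
  validate_rate_matrix(Q)
  s <- nrow(Q)
  pi <- tryCatch(stationary_distribution(Q), error = function(e) NULL)
  reversible <- !is.null(pi) && all(pi > 1e-12) &&
    max(abs(pi * Q - t(pi * Q))) < 1e-10 * max(1, max(abs(Q)))
  if (reversible) {
    d <- sqrt(pi)
    B <- (d %o% (1 / d)) * Q          # B = D Q D^-1 is symmetric
    B <- (B + t(B)) / 2
    eb <- eigen(B, symmetric = TRUE)
    U <- eb$vectors / d               # diag(1/d) %*% V
    U_inv <- t(eb$vectors * d)        # t(V) %*% diag(d)
    lambda <- eb$values
    sym <- TRUE
  } else {
    eg <- eigen(Q)
    U <- eg$vectors
    lambda <- eg$values
    sv <- tryCatch(svd(U, nu = 0, nv = 0)$d, error = function(e) c(1, 0))
    kap <- sv[1L] / sv[length(sv)]
    if (!is.finite(kap) || kap > 1e10)
      stop_phylomap("rate matrix is numerically non-diagonalizable ",
                    "(ill-conditioned eigenbasis); use the quadrature ",
                    "fallback for expectations",
                    class = "phylomap_defective_Q")
    U_inv <- solve(U)
    sym <- FALSE
  }
  recon <- U %*% (lambda * U_inv)
  if (max(Mod(recon - Q)) > 1e-9 * max(1, max(abs(Q))))
    stop_phylomap("spectral decomposition failed to reconstruct Q")
  structure(list(U = U, lambda = lambda, U_inv = U_inv, Q = Q,
                 symmetric_transform_used = sym),
            class = "spectral_decomposition")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from a precomputed spectral decomposition as
#' U diag(exp(lambda t)) U^-1. Tiny negative entries (above -1e-12) arising
#' from round-off are clamped to 0 and entries are clipped to \[0, 1\].
#'
#' @param decomp A `spectral_decomposition` (or a `rate_model`, decomposed on
#'   the fly).
#' @param t Non-negative elapsed time (branch length).
#' @return An s x s row-stochastic matrix.
#' @export
transition_probabilities <- function(decomp, t) {
  if (inherits(decomp, "rate_model")) decomp <- spectral_decompose(decomp)
  stopifnot(inherits(decomp, "spectral_decomposition"))
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop_phylomap("t must be a single non-negative number")
  P <- decomp$U %*% (exp(decomp$lambda * t) * decomp$U_inv)
  if (is.complex(P)) {
    if (max(abs(Im(P))) > 1e-8)
      stop_phylomap("non-negligible imaginary part in P(t); defective Q")
    P <- Re(P)
  }
  P[P < 0 & P > -1e-12] <- 0
  P[P > 1] <- 1
  P[P < 0] <- 0
  dimnames(P) <- dimnames(decomp$Q)
  P
}
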