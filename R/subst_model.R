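#' Construct an amino-acid substitution model
#'
#' Builds a time-reversible rate matrix from symmetric exchangeabilities and
#' stationary frequencies: off-diagonal rates are `Q[i,j] = S[i,j] * pi[j]`,
#' the diagonal makes rows sum to zero, and the matrix is scaled so the
#' expected rate at stationarity, `-sum(pi * diag(Q))`, equals one
#' substitution per site per unit branch length. Among-site rate variation
#' is a discretized gamma with `n_categories` equal-probability categories
#' (disabled when `n_categories = 1`).
#'
#' The eigendecomposition of the symmetrized generator is precomputed so
#' transition matrices `exp(Q t)` are cheap for many branch lengths.
#'
#' @param exchangeabilities symmetric non-negative 20x20 matrix, zero
#'   diagonal, rows/cols in PAML amino-acid order (ARNDCQEGHILKMFPSTWYV).
#' @param freqs stationary frequencies: 20 positive values summing to 1.
#' @param gamma_shape shape of the among-site gamma distribution (its rate
#'   parameter is set equal so the mean rate is 1); ignored when
#'   `n_categories = 1`.
#' @param n_categories number of discrete gamma categories (>= 1).
#' @return an object of class `subst_model`.
#' @export
substitution_model <- function(exchangeabilities, freqs, gamma_shape = 1,
                               n_categories = 1L) {
  S <- as.matrix(exchangeabilities)
  if (!all(dim(S) == c(20L, 20L))) stop("exchangeabilities must be 20x20")
  if (max(abs(S - t(S))) > 1e-10) stop("exchangeabilities must be symmetric")
  if (any(S < 0)) stop("exchangeabilities must be non-negative")
  pi <- as.numeric(freqs)
  if (length(pi) != 20L || any(pi <= 0)) stop("freqs must be 20 positive values")
  if (abs(sum(pi) - 1) > 1e-8) stop("freqs must sum to 1")
  pi <- pi / sum(pi)
  if (!is.numeric(gamma_shape) || gamma_shape <= 0) stop("gamma_shape must be > 0")
  n_categories <- as.integer(n_categories)
  if (n_categories < 1L) stop("n_categories must be >= 1")

  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # symmetrized generator B = D^{1/2} Q D^{-1/2} shares Q's eigenvalues
  sq <- sqrt(pi)
  B <- (sq %o% (1 / sq)) * Q
  B <- (B + t(B)) / 2  # exact symmetry against rounding
  eig <- eigen(B, symmetric = TRUE)
  structure(list(
    S = S, pi = pi, Q = Q,
    eig_values = eig$values,
    # P(t) = left %*% diag(exp(values t)) %*% right
    left = (1 / sq) * eig$vectors,
    right = t(eig$vectors * sq),
    gamma_shape = gamma_shape,
    n_categories = n_categories,
    gamma_rates = if (n_categories > 1L)
      discretize_gamma(gamma_shape, gamma_shape, n_categories) else 1
  ), class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model: 20-state reversible; gamma shape %.3g, %d categories\n",
              x$gamma_shape, x$n_categories))
  invisible(x)
}

#' Update the among-site gamma of a model
#' @param model a `subst_model`.
#' @param gamma_shape new shape (= rate) parameter.
#' @param n_categories number of categories; defaults to the model's.
#' @return a new `subst_model`.
#' @export
set_gamma <- function(model, gamma_shape, n_categories = model$n_categories) {
  substitution_model(model$S, model$pi, gamma_shape, n_categories)
}

#' Replace the stationary frequencies of a model
#'
#' Keeps the exchangeabilities, rebuilding the generator with new
#' frequencies (used for the ordered/disordered substitution regimes).
#' @param model a `subst_model`.
#' @param freqs new stationary frequencies.
#' @return a new `subst_model`.
#' @export
set_frequencies <- function(model, freqs) {
  substitution_model(model$S, freqs, model$gamma_shape, model$n_categories)
}

#' Transition probability matrix exp(Q t)
#' @param model a `subst_model`.
#' @param t branch length (substitutions/site), >= 0.
#' @return 20x20 stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  if (!is.finite(t) || t < 0) stop("t must be finite and >= 0")
  P <- model$left %*% (exp(model$eig_values * t) * model$right)
  # clip tiny negative entries from rounding
  P[P < 0] <- 0
  P
}

#' Read a PAML-style amino-acid rate matrix file
#'
#' Parses the plain-text format used by PAML `.dat` files: 190 values of
#' the lower triangle of the exchangeability matrix (rows 2..20), followed
#' by 20 stationary frequencies. Comment text after the numbers is ignored.
#'
#' @param path file path.
#' @return list with `exchangeabilities` (20x20 symmetric) and `freqs`.
#' @export
read_rate_matrix <- function(path) {
  txt <- readLines(path, warn = FALSE)
  tokens <- unlist(strsplit(paste(txt, collapse = " "), "[ \t]+"))
  tokens <- tokens[nzchar(tokens)]
  vals <- suppressWarnings(as.numeric(tokens))
  vals <- vals[!is.na(vals)]
  if (length(vals) < 210L) stop("rate matrix file needs 190 exchangeabilities + 20 frequencies")
  S <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  k <- 0L
  for (i in 2:20) for (j in 1:(i - 1L)) {
    k <- k + 1L
    S[i, j] <- vals[k]
  }
  S <- S + t(S)
  freqs <- vals[191:210]
  list(exchangeabilities = S, freqs = freqs / sum(freqs))
}

#' The WAG substitution model
#'
#' Loads the WAG exchangeabilities and stationary frequencies shipped with
#' the package (Whelan-and-Goldman general matrix) and builds a
#' [substitution_model()].
#'
#' @inheritParams substitution_model
#' @param freqs optional replacement stationary frequencies (e.g. a
#'   disordered-region composition); defaults to the WAG frequencies.
#' @return a `subst_model`.
#' @export
wag_model <- function(gamma_shape = 1, n_categories = 1L, freqs = NULL) {
  dat <- read_rate_matrix(system.file("extdata", "wag.dat", package = "slimdiv",
                                      mustWork = TRUE))
  substitution_model(dat$exchangeabilities,
                     if (is.null(freqs)) dat$freqs else freqs,
                     gamma_shape, n_categories)
}

#' Equal-probability discretized gamma rates
#'
#' Divides a Gamma(shape, rate) distribution into `k` equal-probability
#' bins and represents each bin by its conditional mean, the standard
#' discretization for among-site rate variation. When `rate = shape` the
#' category means average to 1.
#'
#' @param shape,rate gamma parameters (> 0).
#' @param k number of categories (>= 1).
#' @return increasing numeric vector of `k` category rates.
#' @export
discretize_gamma <- function(shape, rate, k) {
  if (!is.numeric(shape) || shape <= 0 || !is.numeric(rate) || rate <= 0) {
    stop("shape and rate must be positive")
  }
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(shape / rate)
  breaks <- qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = rate)
  # E[X | a < X <= b] via the shape+1 identity, times k for equal bins
  mass <- pgamma(breaks, shape = shape + 1, rate = rate)
  (shape / rate) * k * diff(mass)
}
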