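# Modified Storey false-discovery-rate procedure. Zero-LRT tests produce a
# point mass of p-values at exactly 1, so the null proportion is estimated
# from a high-p window where the p-value density of the true nulls is
# uniform, rather than from the usual tail above a single lambda.

#' Estimate the proportion of true null hypotheses
#'
#' Counts p-values inside an open/closed window `(w_lo, w_hi]` where the
#' null density is assumed uniform and rescales by the window width:
#' `pi0 = #\{w_lo < p <= w_hi\} / (N (w_hi - w_lo))`. The point mass of
#' p = 1 tests stays outside the window but inside `N`.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param window `c(w_lo, w_hi)` with `0 < w_lo < w_hi < 1`.
#' @return the raw pi0 estimate (may exceed 1 on pathological input).
#' @export
estimate_pi0 <- function(pvalues, window = c(0.6, 0.95)) {
  if (length(pvalues) == 0L) stop("no p-values supplied")
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (!(window[1L] > 0 && window[1L] < window[2L] && window[2L] < 1)) {
    stop("window must satisfy 0 < w_lo < w_hi < 1")
  }
  m <- sum(pvalues > window[1L] & pvalues <= window[2L])
  m / (length(pvalues) * (window[2L] - window[1L]))
}

#' Estimated false discovery rate at a p-value threshold
#'
#' Returns `pi0 t N / #\{p <= t\}` (pi0 capped at 1). When no p-value is at
#' or below `t` there are no calls to make and `NA` is returned.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param t threshold in (0, 1].
#' @param pi0 estimated null proportion.
#' @return the FDR estimate, or `NA_real_` if no p-value <= t.
#' @export
fdr_at_threshold <- function(pvalues, t, pi0) {
  if (t <= 0 || t > 1) stop("t must be in (0, 1]")
  n_le <- sum(pvalues <= t)
  if (n_le == 0L) return(NA_real_)
  min(pi0, 1) * t * length(pvalues) / n_le
}

#' Call significant tests at a target false discovery rate
#'
#' Estimates pi0 from the high-p window, evaluates the FDR at every distinct
#' observed p-value, takes the largest threshold with FDR strictly below the
#' target, and flags all p-values at or below it. If no threshold qualifies,
#' nothing is called.
#'
#' @inheritParams estimate_pi0
#' @param target FDR target (default 0.05).
#' @return an object of class `fdr_summary`: list with `n_tests`, `window`,
#'   `m_window`, `pi0` (raw), `degenerate` (window empty, pi0 = 1 used),
#'   `threshold` (`NA` when no calls), `fdr_at_threshold`, `target` and
#'   logical `calls` aligned with the input.
#' @export
call_significant <- function(pvalues, target = 0.05, window = c(0.6, 0.95)) {
  pi0 <- estimate_pi0(pvalues, window)
  # an empty window means the uniform-null assumption cannot be checked;
  # fall back to the conservative pi0 = 1 rather than calling everything
  degenerate <- pi0 == 0
  pi0_used <- if (degenerate) 1 else pi0
  cand <- sort(unique(pvalues))
  cand <- cand[cand > 0]
  fdr <- vapply(cand, function(t) fdr_at_threshold(pvalues, t, pi0_used), numeric(1))
  ok <- which(!is.na(fdr) & fdr < target)
  if (length(ok)) {
    thr <- cand[max(ok)]
    calls <- pvalues <= thr
    fdr_thr <- fdr[max(ok)]
  } else {
    thr <- NA_real_
    calls <- rep(FALSE, length(pvalues))
    fdr_thr <- NA_real_
  }
  structure(list(n_tests = length(pvalues), window = window,
                 m_window = sum(pvalues > window[1L] & pvalues <= window[2L]),
                 pi0 = pi0, degenerate = degenerate, threshold = thr,
                 fdr_at_threshold = fdr_thr, target = target, calls = calls),
            class = "fdr_summary")
}

#' @export
print.fdr_summary <- function(x, ...) {
  cat(sprintf(
    "fdr_summary: %d tests, pi0 = %.4f (window %.2f-%.2f), %d called at FDR < %g%s\n",
    x$n_tests, x$pi0, x$window[1L], x$window[2L], sum(x$calls), x$target,
    if (is.na(x$threshold)) "" else sprintf(" (t* = %.3g)", x$threshold)))
  invisible(x)
}
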