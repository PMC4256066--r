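# Clade-rate likelihood-ratio test with a data-dependent non-central
# chi-squared null calibrated through the Kullback-Leibler divergence of the
# background (whole-protein) evolutionary process from the single-rate model.

#' Clade-rate likelihood-ratio test on an alignment segment
#'
#' Compares H0 (all branches share their given lengths, every clade
#' multiplier = 1) with H1 (the tested post-duplication clade gets a free
#' branch-length multiplier, fitted by maximum likelihood). The statistic is
#' `LRT = max(0, 2 (lnL1 - lnL0))` with one degree of freedom.
#'
#' Segments in which no amino-acid differences are observed carry no
#' information about rate changes (under a clock re-fit both hypotheses
#' collapse to zero branch lengths), so they are reported with `LRT = 0`,
#' `alpha_hat = 1` and flagged `zero_information`; their p-value is 1.
#'
#' @inheritParams segment_loglik
#' @param clade_label the post-duplication clade to test (`POST_WGD_1` or
#'   `POST_WGD_2`), present in the tree.
#' @param site_scale optional overall rate scale applied to all branches.
#' @return an object of class `lrt_record`: list with `lnL0`, `lnL1`,
#'   `lrt`, `alpha_hat`, `clade`, `L` (number of columns), `df`,
#'   `zero_information` and `converged`.
#' @export
clade_lrt <- function(aln, interval, tree, model, clade_label,
                      site_scale = 1) {
  check_taxa_match(aln, tree)
  interval <- check_interval(interval, aln$ncol)
  if (!clade_label %in% tree$clades) {
    stop("clade ", clade_label, " absent from tree (has: ",
         paste(tree$clades, collapse = ", "), ")")
  }
  slice <- aln_slice(aln, interval)
  L <- ncol(slice)
  base <- rate_assignment(setNames(rep(1, length(tree$clades)), tree$clades))
  if (segment_invariant(slice)) {
    ll <- segment_loglik(aln, interval, tree, model, base, site_scale)$loglik
    return(structure(list(lnL0 = ll, lnL1 = ll, lrt = 0, alpha_hat = 1,
                          clade = clade_label, L = L, df = 1L,
                          zero_information = TRUE, converged = TRUE),
                     class = "lrt_record"))
  }
  codes <- aln_codes(slice)
  pt <- prepare_tree(tree, aln$taxa)
  lnL0 <- sum(column_logliks(codes, pt, model, base, site_scale))
  fit <- fit_rates_impl(codes, pt, model, clade_label, base, site_scale)
  lrt <- max(0, 2 * (fit$loglik - lnL0))
  structure(list(lnL0 = lnL0, lnL1 = max(fit$loglik, lnL0),
                 lrt = lrt, alpha_hat = unname(fit$rates$rates[clade_label]),
                 clade = clade_label, L = L, df = 1L,
                 zero_information = FALSE, converged = fit$converged),
            class = "lrt_record")
}

# no observable amino-acid differences: every column has at most one
# distinct observed residue
segment_invariant <- function(mat) {
  for (j in seq_len(ncol(mat))) {
    obs <- mat[, j]
    obs <- obs[!obs %in% MISSING_CHARS]
    if (length(unique(obs)) > 1L) return(FALSE)
  }
  TRUE
}

#' @export
print.lrt_record <- function(x, ...) {
  cat(sprintf("lrt_record [%s]: LRT = %.4g, alpha_hat = %.4g, L = %d%s\n",
              x$clade, x$lrt, x$alpha_hat, x$L,
              if (x$zero_information) " (zero information)" else ""))
  invisible(x)
}

#' Per-protein Kullback-Leibler divergence from a whole-protein LRT
#'
#' Under a shared heterogeneous background process the whole-protein LRT has
#' expectation `k + 2 L D_KL`, so the per-column divergence is estimated by
#' moment matching: `D_KL = (LRT_protein - k) / (2 L)`. When the protein LRT
#' does not exceed `k` (the divergence estimate would be non-positive) the
#' proteome-wide divergence is used instead and `fallback_used` is set.
#'
#' @param protein_record an `lrt_record` computed on the whole protein
#'   alignment for the same clade.
#' @param genome_dkl the proteome-wide divergence (per column).
#' @param k degrees of freedom of the test (1).
#' @return an object of class `kl_params`: list with `dkl_protein`,
#'   `dkl_genome`, `L_protein` and `fallback_used`.
#' @export
estimate_dkl <- function(protein_record, genome_dkl, k = 1) {
  if (!is.finite(genome_dkl) || genome_dkl < 0) stop("genome_dkl must be >= 0")
  if (protein_record$L < 1L) stop("protein record must cover >= 1 column")
  if (protein_record$lrt > k) {
    dkl <- (protein_record$lrt - k) / (2 * protein_record$L)
    fallback <- FALSE
  } else {
    dkl <- genome_dkl
    fallback <- TRUE
  }
  structure(list(dkl_protein = dkl, dkl_genome = genome_dkl,
                 L_protein = protein_record$L, fallback_used = fallback),
            class = "kl_params")
}

#' Pooled proteome-wide Kullback-Leibler divergence
#'
#' Pools whole-protein LRTs over many families:
#' `max(0, (sum(LRT_i) - N k) / (2 sum(L_i)))`, the moment-matching
#' estimate of the shared per-column background divergence.
#'
#' @param protein_records list of `lrt_record`s (one per protein and clade).
#' @param k degrees of freedom per test.
#' @return a single non-negative number.
#' @export
estimate_genome_dkl <- function(protein_records, k = 1) {
  if (length(protein_records) == 0L) stop("need at least one protein record")
  lrt_sum <- sum(vapply(protein_records, `[[`, numeric(1), "lrt"))
  L_sum <- sum(vapply(protein_records, `[[`, numeric(1), "L"))
  max(0, (lrt_sum - length(protein_records) * k) / (2 * L_sum))
}

#' Survival function of the non-central chi-squared with one degree of freedom
#'
#' Uses the closed form of the df = 1 non-central chi-squared CDF,
#' `F(x; 1, lambda) = Phi(sqrt(x) - sqrt(lambda)) + Phi(sqrt(x) + sqrt(lambda)) - 1`
#' (equivalently the erf form), and returns `1 - F`. At `lambda = 0` this
#' reduces to the central chi-squared survival function.
#'
#' @param x quantile(s), >= 0.
#' @param lam non-centrality parameter(s), >= 0.
#' @return p-value(s) in \[0, 1\]. Vectorized with recycling.
#' @export
noncentral_chisq_sf <- function(x, lam) {
  if (any(!is.finite(x)) || any(x < 0)) stop("x must be finite and >= 0")
  if (any(!is.finite(lam)) || any(lam < 0)) stop("lam must be finite and >= 0")
  sx <- sqrt(x)
  sl <- sqrt(lam)
  pnorm(sl - sx) + pnorm(-sl - sx)
}

#' Calibrated p-value for a segment LRT
#'
#' The segment's non-centrality is `lambda_m = 2 L_m max(D_KL_protein,
#' D_KL_genome)` — the larger of the protein-level and proteome-wide
#' divergences, which yields the larger (more conservative) p-value — and
#' the p-value is the non-central chi-squared (df = 1) survival function at
#' the segment LRT. The corrected p-value is always at least the central
#' chi-squared p-value for the same statistic.
#'
#' @param seg_record an `lrt_record` for the segment (its `L` is the
#'   segment length in columns).
#' @param kl a `kl_params` from [estimate_dkl()].
#' @return list with `lambda`, `pvalue`, `pvalue_central` and `dkl_used`.
#' @export
segment_pvalue <- function(seg_record, kl) {
  dkl <- max(kl$dkl_protein, kl$dkl_genome)
  lambda <- 2 * seg_record$L * dkl
  p <- noncentral_chisq_sf(seg_record$lrt, lambda)
  list(lambda = lambda, pvalue = p,
       pvalue_central = pchisq(seg_record$lrt, df = seg_record$df,
                               lower.tail = FALSE),
       dkl_used = dkl)
}
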