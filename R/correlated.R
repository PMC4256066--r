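# Lineage-bias (correlated evolution) test: do significant constraint
# changes within a paralog pair concentrate on one of the two lineages?

#' Merge nearby same-lineage motif events for one paralog pair
#'
#' Motifs significant on the same lineage whose intervals are within
#' `distance` columns of each other (nearest edges, inclusive) are chained
#' into a single event — a guard against bipartite motifs split in two by
#' the predictor. Motifs on different lineages never merge.
#'
#' @param calls data.frame of significant MOTIF calls for one pair, with
#'   columns `clade` (`POST_WGD_1` / `POST_WGD_2`), `start`, `end`
#'   (full-alignment, 0-based half-open).
#' @param distance merge distance in columns (35).
#' @param pair_id identifier carried through to the output.
#' @return an object of class `pair_events`: list with `pair_id`, `n1`,
#'   `n2` (merged event counts per lineage) and `events` (per-lineage
#'   merged intervals).
#' @export
merge_events <- function(calls, distance = 35L, pair_id = "pair") {
  stopifnot(all(c("clade", "start", "end") %in% names(calls)))
  events <- list()
  counts <- c(POST_WGD_1 = 0L, POST_WGD_2 = 0L)
  for (lab in c("POST_WGD_1", "POST_WGD_2")) {
    sub <- calls[calls$clade == lab, , drop = FALSE]
    if (nrow(sub) == 0L) next
    sub <- sub[order(sub$start), , drop = FALSE]
    merged <- sub[1L, c("start", "end"), drop = FALSE]
    if (nrow(sub) > 1L) for (i in 2:nrow(sub)) {
      k <- nrow(merged)
      if (sub$start[i] - merged$end[k] <= distance) {
        merged$end[k] <- max(merged$end[k], sub$end[i])
      } else {
        merged <- rbind(merged, sub[i, c("start", "end")])
      }
    }
    events[[lab]] <- merged
    counts[lab] <- nrow(merged)
  }
  structure(list(pair_id = pair_id, n1 = unname(counts["POST_WGD_1"]),
                 n2 = unname(counts["POST_WGD_2"]), events = events),
            class = "pair_events")
}

#' Permutation test for lineage bias across paralog pairs
#'
#' The observed statistic is `T = sum over pairs of |n1 - n2|`, the total
#' lineage imbalance in merged constraint-change events. Under the null
#' each merged event lands on either lineage with probability one half,
#' independently; the permutation p-value uses the add-one convention
#' `p = (1 + #\{T_perm >= T_obs\}) / (n_perm + 1)` for a one-tailed test.
#'
#' @param pairs list of `pair_events` (each with `n1 + n2 >= 1`).
#' @param n_perm number of permutations (>= 1000).
#' @param seed RNG seed; runs are reproducible bit-for-bit.
#' @return list with `T_obs`, `pvalue`, `n_perm`, `seed` and the permuted
#'   statistics `T_perm`.
#' @export
lineage_bias_test <- function(pairs, n_perm = 10000L, seed = 1L) {
  if (length(pairs) == 0L) stop("no pairs supplied")
  totals <- vapply(pairs, function(p) p$n1 + p$n2, numeric(1))
  if (any(totals < 1L)) stop("each pair must have at least one event")
  T_obs <- sum(vapply(pairs, function(p) abs(p$n1 - p$n2), numeric(1)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  T_perm <- vapply(seq_len(n_perm), function(b) {
    n1 <- rbinom(length(totals), size = totals, prob = 0.5)
    sum(abs(2 * n1 - totals))
  }, numeric(1))
  p <- (1 + sum(T_perm >= T_obs)) / (n_perm + 1)
  list(T_obs = T_obs, pvalue = p, n_perm = n_perm, seed = seed,
       T_perm = T_perm)
}
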