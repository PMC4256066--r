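# Phylo-HMM prediction of conserved short segments (candidate short linear
# motifs) in disordered regions of the pre-duplication sub-alignment.

#' Parameters of the conserved-segment phylo-HMM
#'
#' @param gamma_shape,gamma_rate gamma parameters of the conserved-state
#'   rate-scale mixture (defaults 0.6 / 0.6, a wide prior concentrated on
#'   slow rates).
#' @param n_categories number of discretized gamma categories (8).
#' @param window background-rate window in alignment columns (odd, 31).
#' @param p_enter probability of entering the conserved state.
#' @param p_stay probability of remaining in the conserved state.
#' @param posterior_threshold posterior probability above which a column is
#'   decoded as conserved.
#' @param max_length structural filter: conserved runs longer than this many
#'   columns are considered structured regions and discarded (35).
#' @param gap_trim_fraction terminal columns with a gap fraction above this
#'   are trimmed; segments above it overall are dropped (0.5).
#' @param flank_width width of the flanking control segments (5 columns).
#' @param rate_floor minimum background rate scale.
#'
#' The transition probabilities are not fixed by the underlying science;
#' the defaults target conserved runs of roughly 2-35 columns and should be
#' revisited for data with very different background rates.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(gamma_shape = 0.6, gamma_rate = 0.6, n_categories = 8L,
                       window = 31L, p_enter = 0.002, p_stay = 0.9,
                       posterior_threshold = 0.5, max_length = 35L,
                       gap_trim_fraction = 0.5, flank_width = 5L,
                       rate_floor = 1e-4) {
  stopifnot(gamma_shape > 0, gamma_rate > 0, n_categories >= 1,
            window >= 3L, window %% 2L == 1L,
            p_enter > 0, p_enter < 1, p_stay > 0, p_stay < 1,
            posterior_threshold > 0, posterior_threshold < 1,
            max_length >= 1L, gap_trim_fraction > 0, gap_trim_fraction < 1,
            flank_width >= 1L, rate_floor > 0)
  structure(list(gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 n_categories = as.integer(n_categories),
                 window = as.integer(window), p_enter = p_enter,
                 p_stay = p_stay, posterior_threshold = posterior_threshold,
                 max_length = as.integer(max_length),
                 gap_trim_fraction = gap_trim_fraction,
                 flank_width = as.integer(flank_width),
                 rate_floor = rate_floor),
            class = "hmm_params")
}

#' Extract the pre-duplication sub-alignment
#'
#' Removes the post-duplication taxa, drops columns left with no residues,
#' and prunes the tree accordingly. The returned column map is the bijection
#' from kept sub-alignment columns to full-alignment columns (0-based).
#'
#' @param aln a [protein_alignment].
#' @param tree a [clade_tree()] matching the alignment.
#' @return list with `sub_aln` (a `protein_alignment`), `map` (integer
#'   vector, sub column i+1 -> full column `map[i+1]`, 0-based values) and
#'   `sub_tree` (pruned `clade_tree`, all branches PRE_WGD).
#' @export
extract_prewgd <- function(aln, tree) {
  check_taxa_match(aln, tree)
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  post_tips <- phy$edge[tree$edge_label != "PRE_WGD" & phy$edge[, 2L] <= ntip, 2L]
  pre_taxa <- setdiff(phy$tip.label, phy$tip.label[post_tips])
  if (length(pre_taxa) == 0L) stop("no PRE_WGD taxa in tree")
  mat <- aln$mat[pre_taxa, , drop = FALSE]
  keep <- which(colSums(mat != GAP_CHAR) > 0L)
  if (length(keep) == 0L) stop("pre-WGD sub-alignment is empty")
  sub <- protein_alignment(apply(mat[, keep, drop = FALSE], 1L, paste, collapse = ""),
                           family_id = aln$family_id)
  sub_phy <- ape::keep.tip(phy, pre_taxa)
  list(sub_aln = sub, map = keep - 1L, sub_tree = clade_tree(sub_phy))
}

#' Map a sub-alignment interval into full-alignment coordinates
#' @param interval 0-based half-open interval in sub-alignment columns.
#' @param map column map from [extract_prewgd()].
#' @return 0-based half-open interval in full-alignment columns.
#' @export
map_interval_to_full <- function(interval, map) {
  c(map[interval[1L] + 1L], map[interval[2L]] + 1L)
}

#' Per-column background evolutionary rate
#'
#' For each column, the maximum-likelihood rate scale over a window of
#' `W` columns centred on it (clipped at the alignment ends), found by
#' Newton-Raphson on the log scale with a floor at `rate_floor`; columns
#' whose windows are invariant sit at the floor. Bisection on the gradient
#' is used as a fallback when Newton-Raphson fails to converge.
#'
#' @param sub_aln pre-duplication sub-alignment.
#' @param sub_tree matching tree (single-rate).
#' @param model a [substitution_model()] (no gamma mixture is applied here;
#'   the window plays that role).
#' @param params an [hmm_params()].
#' @return numeric vector of per-column rate scales.
#' @export
background_rates <- function(sub_aln, sub_tree, model, params = hmm_params()) {
  check_taxa_match(sub_aln, sub_tree)
  codes <- aln_codes(sub_aln$mat)
  pt <- prepare_tree(sub_tree, sub_aln$taxa)
  base <- rate_assignment(setNames(rep(1, length(sub_tree$clades)), sub_tree$clades))
  edge_scale_base <- base$rates[pt$edge_label]
  L <- ncol(codes)
  half <- (params$window - 1L) %/% 2L
  floor_log <- log(params$rate_floor)
  upper_log <- log(1e3)

  win_loglik <- function(cols, log_s) {
    sum(prune_loglik(codes[, cols, drop = FALSE], pt, model,
                     edge_scale_base * exp(log_s)))
  }
  out <- numeric(L)
  prev <- 0  # warm start at log scale 0
  h <- 1e-3
  for (i in seq_len(L)) {
    cols <- max(1L, i - half):min(L, i + half)
    f <- function(ls) win_loglik(cols, ls)
    x <- prev
    converged <- FALSE
    for (iter in 1:30) {
      f0 <- f(x); fp <- f(x + h); fm <- f(x - h)
      g <- (fp - fm) / (2 * h)
      hess <- (fp - 2 * f0 + fm) / (h * h)
      if (!is.finite(g) || !is.finite(hess) || hess >= 0) break
      step <- g / hess
      step <- max(min(step, 2), -2)  # damp long steps
      x_new <- min(max(x - step, floor_log), upper_log)
      if (abs(x_new - x) < 1e-6) {
        x <- x_new
        converged <- TRUE
        break
      }
      x <- x_new
    }
    if (!converged && !(x <= floor_log + 1e-6)) {
      # bisection on the derivative sign
      lo <- floor_log; hi <- upper_log
      g_lo <- (f(lo + h) - f(lo - h)) / (2 * h)
      if (g_lo <= 0) {
        x <- floor_log
      } else {
        for (iter in 1:60) {
          mid <- (lo + hi) / 2
          g_mid <- (f(mid + h) - f(mid - h)) / (2 * h)
          if (g_mid > 0) lo <- mid else hi <- mid
          if (hi - lo < 1e-6) break
        }
        x <- (lo + hi) / 2
      }
    }
    out[i] <- max(exp(x), params$rate_floor)
    prev <- log(out[i])
  }
  out
}

#' Decode conserved segments with a two-state phylo-HMM
#'
#' Runs a background/conserved HMM over each disordered stretch. The
#' background state emits each column at its local background rate; the
#' conserved state emits an equal-weight mixture over the discretized
#' Gamma(0.6, 0.6) rate categories multiplied by the local background rate.
#' Columns whose conserved-state posterior exceeds the threshold form
#' maximal runs, reported as candidate motif segments (sub-alignment
#' coordinates).
#'
#' @inheritParams background_rates
#' @param disorder_intervals matrix of 0-based half-open intervals of
#'   disordered columns (sub-alignment coordinates); stretches shorter than
#'   2 columns are skipped.
#' @param bg_rates per-column background scales from [background_rates()].
#' @return data.frame with columns `start`, `end` (0-based half-open, sub
#'   coordinates) and `mean_posterior`.
#' @export
decode_motifs <- function(sub_aln, sub_tree, model, disorder_intervals,
                          bg_rates, params = hmm_params()) {
  check_taxa_match(sub_aln, sub_tree)
  if (length(bg_rates) != sub_aln$ncol) stop("bg_rates must cover every column")
  codes <- aln_codes(sub_aln$mat)
  pt <- prepare_tree(sub_tree, sub_aln$taxa)
  base <- rate_assignment(setNames(rep(1, length(sub_tree$clades)), sub_tree$clades))
  edge_base <- base$rates[pt$edge_label]
  g <- discretize_gamma(params$gamma_shape, params$gamma_rate, params$n_categories)
  disorder_intervals <- normalize_intervals(disorder_intervals)

  segs <- list()
  for (r in seq_len(nrow(disorder_intervals))) {
    s <- disorder_intervals[r, 1L]
    e <- disorder_intervals[r, 2L]
    if (e - s < 2L) next
    cols <- (s + 1L):e
    n <- length(cols)
    # emissions: background at local scale; conserved = gamma mixture
    log_bg <- vapply(seq_len(n), function(j) {
      prune_loglik(codes[, cols[j], drop = FALSE], pt, model,
                   edge_base * bg_rates[cols[j]])
    }, numeric(1))
    log_cons <- vapply(seq_len(n), function(j) {
      per_cat <- vapply(g, function(gr) {
        prune_loglik(codes[, cols[j], drop = FALSE], pt, model,
                     edge_base * bg_rates[cols[j]] * gr)
      }, numeric(1))
      mx <- max(per_cat)
      mx + log(mean(exp(per_cat - mx)))
    }, numeric(1))
    post <- two_state_posterior(log_bg, log_cons, params$p_enter, params$p_stay)
    conserved <- post > params$posterior_threshold
    runs <- rle(conserved)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      segs[[length(segs) + 1L]] <- data.frame(
        start = s + starts[k] - 1L, end = s + ends[k],
        mean_posterior = mean(post[starts[k]:ends[k]]))
    }
  }
  if (length(segs) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean_posterior = numeric(0)))
  }
  out <- do.call(rbind, segs)
  out[order(out$start), , drop = FALSE]
}

# forward-backward posterior of the conserved state (state 2) for a
# two-state chain started at its stationary distribution
two_state_posterior <- function(log_e1, log_e2, p_enter, p_stay) {
  n <- length(log_e1)
  logA <- log(matrix(c(1 - p_enter, p_enter,
                       1 - p_stay, p_stay), 2L, 2L, byrow = TRUE))
  p_cons <- p_enter / (p_enter + (1 - p_stay))
  log_init <- log(c(1 - p_cons, p_cons))
  logsumexp2 <- function(a, b) {
    m <- pmax(a, b)
    m + log1p(exp(pmin(a, b) - m))
  }
  fwd <- matrix(-Inf, n, 2L)
  fwd[1L, ] <- log_init + c(log_e1[1L], log_e2[1L])
  if (n > 1L) for (t in 2:n) {
    for (j in 1:2) {
      fwd[t, j] <- logsumexp2(fwd[t - 1L, 1L] + logA[1L, j],
                              fwd[t - 1L, 2L] + logA[2L, j]) +
        if (j == 1L) log_e1[t] else log_e2[t]
    }
  }
  bwd <- matrix(0, n, 2L)
  if (n > 1L) for (t in (n - 1L):1L) {
    for (j in 1:2) {
      bwd[t, j] <- logsumexp2(logA[j, 1L] + log_e1[t + 1L] + bwd[t + 1L, 1L],
                              logA[j, 2L] + log_e2[t + 1L] + bwd[t + 1L, 2L])
    }
  }
  post_un <- fwd + bwd
  1 / (1 + exp(post_un[, 1L] - post_un[, 2L]))
}

#' Trim and filter candidate motif segments
#'
#' Single insertion/deletion events can masquerade as conserved runs, so
#' terminal columns are trimmed while their gap fraction exceeds the trim
#' fraction; a segment whose overall gap fraction then still exceeds the
#' threshold is dropped (strictly "over" the fraction — exactly 50% gaps is
#' kept at the default). Finally segments longer than `max_length` columns
#' are discarded as putative structured regions.
#'
#' @param segments data.frame from [decode_motifs()].
#' @param sub_aln the sub-alignment the segments were decoded on.
#' @param params an [hmm_params()].
#' @return filtered data.frame, same columns as the input.
#' @export
trim_filter <- function(segments, sub_aln, params = hmm_params()) {
  gap_frac <- colMeans(sub_aln$mat == GAP_CHAR)
  keep <- logical(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    s <- segments$start[i]
    e <- segments$end[i]
    while (s < e && gap_frac[s + 1L] > params$gap_trim_fraction) s <- s + 1L
    while (e > s && gap_frac[e] > params$gap_trim_fraction) e <- e - 1L
    if (s >= e) next
    if (mean(gap_frac[(s + 1L):e]) > params$gap_trim_fraction) next
    if (e - s > params$max_length) next
    segments$start[i] <- s
    segments$end[i] <- e
    keep[i] <- TRUE
  }
  segments[keep, , drop = FALSE]
}

#' Flanking control segments for a set of motifs
#'
#' Each motif gets a left flank `[start - w, start)` and a right flank
#' `[end, end + w)` in full-alignment coordinates, clipped at the alignment
#' bounds; flanks never overlap another motif or flank — when two motifs are
#' close, the facing flanks are truncated symmetrically to split the gap.
#' Zero-width flanks are omitted.
#'
#' @param motifs data.frame with `start`, `end` (full-alignment 0-based
#'   half-open), sorted or not.
#' @param ncol number of alignment columns.
#' @param width flank width in columns.
#' @return data.frame with `motif_index`, `side` ("left"/"right"), `start`,
#'   `end`.
#' @export
flank_intervals <- function(motifs, ncol, width = 5L) {
  if (nrow(motifs) == 0L) {
    return(data.frame(motif_index = integer(0), side = character(0),
                      start = integer(0), end = integer(0)))
  }
  ord <- order(motifs$start)
  res <- list()
  for (k in seq_along(ord)) {
    i <- ord[k]
    # left flank: clipped at 0 and at the previous motif's end (+ its share)
    lo_bound <- 0L
    if (k > 1L) {
      prev_end <- motifs$end[ord[k - 1L]]
      gap <- motifs$start[i] - prev_end
      lo_bound <- motifs$start[i] - min(width, gap %/% 2L + gap %% 2L)
      lo_bound <- max(lo_bound, prev_end)
    }
    ls <- max(motifs$start[i] - width, lo_bound, 0L)
    le <- motifs$start[i]
    if (ls < le) {
      res[[length(res) + 1L]] <- data.frame(motif_index = i, side = "left",
                                            start = ls, end = le)
    }
    # right flank: clipped at ncol and at the next motif's start (its share)
    hi_bound <- ncol
    if (k < length(ord)) {
      next_start <- motifs$start[ord[k + 1L]]
      gap <- next_start - motifs$end[i]
      hi_bound <- motifs$end[i] + min(width, gap %/% 2L)
      hi_bound <- min(hi_bound, next_start)
    }
    rs <- motifs$end[i]
    re <- min(motifs$end[i] + width, hi_bound, ncol)
    if (rs < re) {
      res[[length(res) + 1L]] <- data.frame(motif_index = i, side = "right",
                                            start = rs, end = re)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(motif_index = integer(0), side = character(0),
                      start = integer(0), end = integer(0)))
  }
  do.call(rbind, res)
}

#' Predict motifs for one family
#'
#' Convenience wrapper: extracts the pre-duplication sub-alignment, computes
#' background rates, decodes, trims/filters, and maps the surviving
#' segments into full-alignment coordinates.
#'
#' @param aln full [protein_alignment].
#' @param tree [clade_tree()] with post-duplication clades labeled.
#' @param model a [substitution_model()].
#' @param disorder_intervals disordered intervals in FULL alignment
#'   coordinates, or `NULL` to treat the whole protein as disordered.
#' @param params an [hmm_params()].
#' @return data.frame with `sub_start`, `sub_end`, `start`, `end` (full
#'   coordinates) and `mean_posterior`.
#' @export
predict_motifs <- function(aln, tree, model, disorder_intervals = NULL,
                           params = hmm_params()) {
  ex <- extract_prewgd(aln, tree)
  # translate full-coordinate disorder intervals into kept sub columns
  if (is.null(disorder_intervals)) {
    sub_dis <- matrix(c(0L, ex$sub_aln$ncol), 1L, 2L)
  } else {
    disorder_intervals <- normalize_intervals(disorder_intervals)
    full_is_dis <- rep(FALSE, aln$ncol)
    for (r in seq_len(nrow(disorder_intervals))) {
      full_is_dis[(disorder_intervals[r, 1L] + 1L):disorder_intervals[r, 2L]] <- TRUE
    }
    sub_flags <- full_is_dis[ex$map + 1L]
    if (!any(sub_flags)) {
      return(data.frame(sub_start = integer(0), sub_end = integer(0),
                        start = integer(0), end = integer(0),
                        mean_posterior = numeric(0)))
    }
    runs <- rle(sub_flags)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    sub_dis <- cbind(starts[runs$values] - 1L, ends[runs$values])
  }
  bg <- background_rates(ex$sub_aln, ex$sub_tree, model, params)
  segs <- decode_motifs(ex$sub_aln, ex$sub_tree, model, sub_dis, bg, params)
  segs <- trim_filter(segs, ex$sub_aln, params)
  if (nrow(segs) == 0L) {
    return(data.frame(sub_start = integer(0), sub_end = integer(0),
                      start = integer(0), end = integer(0),
                      mean_posterior = numeric(0)))
  }
  full <- t(vapply(seq_len(nrow(segs)), function(i) {
    map_interval_to_full(c(segs$start[i], segs$end[i]), ex$map)
  }, integer(2)))
  data.frame(sub_start = segs$start, sub_end = segs$end,
             start = full[, 1L], end = full[, 2L],
             mean_posterior = segs$mean_posterior)
}
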