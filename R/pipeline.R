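# End-to-end orchestration: motif prediction on the pre-duplication clade,
# whole-protein LRT and divergence estimation, motif/flank tests, corrected
# p-values, FDR calls and summary counts.

#' Pipeline configuration
#'
#' @param genome_dkl proteome-wide Kullback-Leibler divergence: a number, or
#'   `"estimate"` to pool it from the input family collection.
#' @param fdr_target false-discovery-rate target for significance calls.
#' @param test_flanks also test the 5-column flanking segments (negative
#'   controls).
#' @param gamma_categories among-site gamma categories for the LRTs; the
#'   shape is fitted once per protein when > 1, no mixture when 1.
#' @param min_taxa families with fewer taxa are skipped.
#' @param hmm an [hmm_params()].
#' @param fdr_window high-p window for the null-proportion estimate.
#' @param seed seed recorded in outputs (the test pipeline itself is
#'   deterministic).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_dkl = "estimate", fdr_target = 0.05,
                            test_flanks = TRUE, gamma_categories = 1L,
                            min_taxa = 4L, hmm = hmm_params(),
                            fdr_window = c(0.6, 0.95), seed = 1L) {
  structure(list(genome_dkl = genome_dkl, fdr_target = fdr_target,
                 test_flanks = test_flanks,
                 gamma_categories = as.integer(gamma_categories),
                 min_taxa = as.integer(min_taxa), hmm = hmm,
                 fdr_window = fdr_window, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [pipeline_config()] (unknown keys are
#'   rejected), with `hmm` an optional nested mapping of [hmm_params()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  if (!is.null(raw$hmm)) raw$hmm <- do.call(hmm_params, raw$hmm)
  do.call(pipeline_config, raw)
}

#' Run the motif-divergence tests for one family
#'
#' Predicts motifs on the pre-duplication sub-alignment, maps them back,
#' computes the whole-protein LRT per post-duplication clade (for the
#' divergence estimate) and the per-segment LRTs for every motif (and flank
#' when enabled) against every post-duplication clade. Each motif is thus
#' tested once in single-copy families and twice in retained duplicates.
#' P-values are attached later, once the proteome-wide divergence is known
#' (see [run_pipeline()]).
#'
#' @param aln a [protein_alignment].
#' @param tree a [clade_tree()] with >= 1 post-duplication clade.
#' @param model a [substitution_model()].
#' @param disorder_intervals optional disordered intervals (full-alignment
#'   coordinates); `NULL` treats the whole protein as disordered.
#' @param motifs optional precomputed motif intervals (data.frame with
#'   `start`, `end` in full coordinates); skips the phylo-HMM when given.
#' @param cfg a [pipeline_config()].
#' @return list with `family_id`, `n_post_clades`, `protein` (list of
#'   whole-protein `lrt_record`s keyed by clade), `segments` (data.frame of
#'   per-segment per-clade LRTs) and `skipped` (reason string or `NA`).
#' @export
run_family <- function(aln, tree, model, disorder_intervals = NULL,
                       motifs = NULL, cfg = pipeline_config()) {
  post <- intersect(c("POST_WGD_1", "POST_WGD_2"), tree$clades)
  if (length(aln$taxa) < cfg$min_taxa) {
    return(list(family_id = aln$family_id, n_post_clades = length(post),
                protein = list(), segments = empty_segments(),
                skipped = sprintf("fewer than %d taxa", cfg$min_taxa)))
  }
  if (length(post) == 0L) {
    return(list(family_id = aln$family_id, n_post_clades = 0L,
                protein = list(), segments = empty_segments(),
                skipped = "no post-duplication clade"))
  }
  if (cfg$gamma_categories > 1L) {
    model <- fit_gamma_shape(aln, tree, model, cfg$gamma_categories)$model
  }
  informative <- sum(colSums(!apply(aln$mat, 2L, `%in%`, MISSING_CHARS)) >= 2L)
  protein <- list()
  for (lab in post) {
    rec <- clade_lrt(aln, c(0L, aln$ncol), tree, model, lab)
    rec$L <- max(informative, 1L)  # columns that can inform the test
    protein[[lab]] <- rec
  }
  if (is.null(motifs)) {
    motifs <- predict_motifs(aln, tree, model, disorder_intervals, cfg$hmm)
  }
  segs <- list()
  add_seg <- function(start, end, kind) {
    iv <- c(start, end)
    for (lab in post) {
      rec <- clade_lrt(aln, iv, tree, model, lab)
      segs[[length(segs) + 1L]] <<- data.frame(
        family_id = aln$family_id, start = start, end = end, kind = kind,
        clade = lab, lnL0 = rec$lnL0, lnL1 = rec$lnL1, lrt = rec$lrt,
        alpha_hat = rec$alpha_hat, L = rec$L,
        zero_information = rec$zero_information,
        stringsAsFactors = FALSE)
    }
  }
  n_degenerate <- 0L
  if (nrow(motifs)) {
    for (i in seq_len(nrow(motifs))) {
      sl <- aln_slice(aln, c(motifs$start[i], motifs$end[i]))
      if (all(sl %in% MISSING_CHARS)) {
        n_degenerate <- n_degenerate + 1L
        next
      }
      add_seg(motifs$start[i], motifs$end[i], "MOTIF")
    }
    if (cfg$test_flanks) {
      fl <- flank_intervals(motifs, aln$ncol, cfg$hmm$flank_width)
      for (i in seq_len(nrow(fl))) add_seg(fl$start[i], fl$end[i], "FLANK")
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else empty_segments()
  list(family_id = aln$family_id, n_post_clades = length(post),
       protein = protein, segments = segments,
       n_degenerate_motifs = n_degenerate, skipped = NA_character_)
}

empty_segments <- function() {
  data.frame(family_id = character(0), start = integer(0), end = integer(0),
             kind = character(0), clade = character(0), lnL0 = numeric(0),
             lnL1 = numeric(0), lrt = numeric(0), alpha_hat = numeric(0),
             L = integer(0), zero_information = logical(0),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline over a family collection
#'
#' @param families list of family inputs, each a list with `aln`, `tree`
#'   and optional `disorder_intervals` / `motifs` entries.
#' @param model a [substitution_model()].
#' @param cfg a [pipeline_config()].
#' @return list with `results` (the results table: one row per segment and
#'   clade, with non-centrality, corrected p-value and significance flag),
#'   `fdr` (per-kind `fdr_summary`s), `genome_dkl`, `protein_records` and
#'   `skipped` (named reasons).
#' @export
run_pipeline <- function(families, model, cfg = pipeline_config()) {
  runs <- lapply(families, function(f) {
    run_family(f$aln, f$tree, model,
               disorder_intervals = f$disorder_intervals,
               motifs = f$motifs, cfg = cfg)
  })
  skipped <- vapply(runs, `[[`, character(1), "skipped")
  names(skipped) <- vapply(runs, `[[`, character(1), "family_id")
  protein_records <- unlist(lapply(runs, `[[`, "protein"), recursive = FALSE)
  genome_dkl <- if (identical(cfg$genome_dkl, "estimate")) {
    if (length(protein_records) == 0L) stop("no protein records to pool")
    estimate_genome_dkl(protein_records)
  } else {
    as.numeric(cfg$genome_dkl)
  }
  rows <- list()
  for (run in runs) {
    seg <- run$segments
    if (nrow(seg) == 0L) next
    for (i in seq_len(nrow(seg))) {
      kl <- estimate_dkl(run$protein[[seg$clade[i]]], genome_dkl)
      rec <- list(lrt = seg$lrt[i], L = seg$L[i], df = 1L)
      sp <- segment_pvalue(rec, kl)
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = seg$family_id[i], start = seg$start[i], end = seg$end[i],
        kind = seg$kind[i], clade = seg$clade[i], lnL0 = seg$lnL0[i],
        lnL1 = seg$lnL1[i], lrt = seg$lrt[i], dkl = sp$dkl_used,
        lambda = sp$lambda, pvalue = sp$pvalue,
        pvalue_central = sp$pvalue_central,
        alpha_hat = seg$alpha_hat[i], significant = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else {
    cbind(empty_segments()[, c("family_id", "start", "end", "kind", "clade",
                               "lnL0", "lnL1", "lrt")],
          data.frame(dkl = numeric(0), lambda = numeric(0), pvalue = numeric(0),
                     pvalue_central = numeric(0), alpha_hat = numeric(0),
                     significant = logical(0)))
  }
  fdr <- list()
  for (kind in intersect(c("MOTIF", "FLANK"), unique(results$kind))) {
    idx <- which(results$kind == kind)
    fdr[[kind]] <- call_significant(results$pvalue[idx], cfg$fdr_target,
                                    cfg$fdr_window)
    results$significant[idx] <- fdr[[kind]]$calls
  }
  list(results = results, fdr = fdr, genome_dkl = genome_dkl,
       protein_records = protein_records, skipped = skipped)
}

#' Summarize pipeline results
#'
#' Counts tested and significant motifs separately for single-copy families
#' (one post-duplication clade) and retained duplicates (two), plus the
#' one-copy-only / both-copies split and flank counts, formatted as
#' fraction and percentage.
#'
#' @param results results table from [run_pipeline()].
#' @return an object of class `pipeline_summary` (a list of counts) with a
#'   formatted print method.
#' @export
summarize_results <- function(results) {
  seg_key <- function(df) paste(df$family_id, df$start, df$end)
  fam_clades <- tapply(results$clade, results$family_id,
                       function(x) length(unique(x)))
  dup_fams <- names(fam_clades)[fam_clades == 2L]
  mot <- results[results$kind == "MOTIF", , drop = FALSE]
  fla <- results[results$kind == "FLANK", , drop = FALSE]
  count_class <- function(df) {
    keys <- seg_key(df)
    sig_by_seg <- tapply(df$significant, keys, any)
    both_by_seg <- tapply(seq_len(nrow(df)), keys, function(i) {
      sum(df$significant[i]) == 2L && length(i) == 2L
    })
    list(n_segments = length(unique(keys)), n_tests = nrow(df),
         n_significant = sum(sig_by_seg),
         n_both_copies = sum(both_by_seg))
  }
  mot_single <- count_class(mot[!mot$family_id %in% dup_fams, , drop = FALSE])
  mot_dup <- count_class(mot[mot$family_id %in% dup_fams, , drop = FALSE])
  fla_all <- count_class(fla)
  structure(list(single_copy = mot_single, duplicates = mot_dup,
                 flanks = fla_all), class = "pipeline_summary")
}

fmt_frac <- function(k, n) {
  if (n == 0L) return("0/0 (0%)")
  sprintf("%d/%d (%.1f%%)", k, n, 100 * k / n)
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("Motifs with significant changes in constraints:\n")
  cat("  single-copy families: ",
      fmt_frac(x$single_copy$n_significant, x$single_copy$n_segments), "\n", sep = "")
  cat("  retained duplicates:  ",
      fmt_frac(x$duplicates$n_significant, x$duplicates$n_segments), "\n", sep = "")
  cat("    significant in both copies: ", x$duplicates$n_both_copies, "\n", sep = "")
  cat("  flank controls:       ",
      fmt_frac(x$flanks$n_significant, x$flanks$n_segments), "\n", sep = "")
  invisible(x)
}

#' Read a family manifest
#'
#' The manifest is YAML with a `families` list; each entry has `id`,
#' `alignment` (FASTA path), `tree` (Newick path), optional `mask` (TSV
#' interval file, DISORDER rows are used) and the post-duplication leaf
#' sets `post_wgd_1` / `post_wgd_2`. Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path manifest YAML file.
#' @return list of family inputs suitable for [run_pipeline()].
#' @export
read_family_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$families)) stop("manifest must contain a 'families' list")
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  lapply(man$families, function(f) {
    spec <- list()
    if (!is.null(f$post_wgd_1)) spec$POST_WGD_1 <- f$post_wgd_1
    if (!is.null(f$post_wgd_2)) spec$POST_WGD_2 <- f$post_wgd_2
    aln <- read_alignment(resolve(f$alignment), family_id = f$id)
    tree <- read_clade_tree(resolve(f$tree), spec)
    dis <- NULL
    if (!is.null(f$mask)) {
      mask <- read_mask(resolve(f$mask))
      mask <- mask[mask$family_id == f$id & mask$kind == "DISORDER", , drop = FALSE]
      if (nrow(mask)) dis <- as.matrix(mask[, c("start", "end")])
    }
    list(aln = aln, tree = tree, disorder_intervals = dis)
  })
}
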