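# Protein-evolution simulator: site-specific rates, ordered/disordered
# substitution regimes, indels with rate/region inheritance, protected motif
# intervals, and optional clade-specific rate shifts. Doubles as the
# synthetic-fixture generator for the whole package.

#' Configuration of a simulated protein family
#'
#' @param tree a [clade_tree()] giving topology, branch lengths and clade
#'   labels; leaves become the simulated taxa.
#' @param root_length length of the root sequence (ignored when `root_seq`
#'   is given).
#' @param root_seq optional root amino-acid string (no gaps).
#' @param site_rates per-site rate scales at the root (recycled; default 1).
#' @param regions per-site region labels at the root, `"ORDERED"` or
#'   `"DISORDERED"` (recycled; default all disordered).
#' @param model_ordered,model_disordered [substitution_model()]s sharing
#'   exchangeabilities but with region-specific stationary frequencies;
#'   insertions draw residues from the region's frequencies.
#' @param ins_rate,del_rate insertion/deletion events per site per unit
#'   branch length (defaults 0.02; the literature on yeast disordered
#'   regions motivates rates of this order but no canonical value exists).
#' @param mean_indel_length mean of the geometric indel length distribution.
#' @param protected matrix of 0-based half-open intervals on the root
#'   sequence that receive no indels (ancestral motifs).
#' @param clade_multiplier named numeric of branch-length multipliers per
#'   clade label (e.g. `c(POST_WGD_1 = 2)`), the injected rate shift.
#' @param seed RNG seed; simulation is deterministic given the seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(tree, root_length = 300L, root_seq = NULL,
                       site_rates = 1, regions = "DISORDERED",
                       model_ordered, model_disordered = model_ordered,
                       ins_rate = 0.02, del_rate = 0.02,
                       mean_indel_length = 2,
                       protected = NULL, clade_multiplier = numeric(0),
                       seed = 1L) {
  stopifnot(inherits(tree, "clade_tree"),
            inherits(model_ordered, "subst_model"),
            inherits(model_disordered, "subst_model"),
            ins_rate >= 0, del_rate >= 0, mean_indel_length >= 1)
  if (!is.null(root_seq)) {
    root_codes <- match(strsplit(toupper(root_seq), "")[[1L]], AA_ALPHABET)
    if (anyNA(root_codes)) stop("root_seq must contain amino acids only")
    root_length <- length(root_codes)
  } else {
    root_codes <- NULL
    root_length <- as.integer(root_length)
    if (root_length < 1L) stop("root_length must be >= 1")
  }
  site_rates <- rep_len(site_rates, root_length)
  if (any(site_rates < 0)) stop("site rates must be >= 0")
  regions <- rep_len(regions, root_length)
  if (!all(regions %in% c("ORDERED", "DISORDERED"))) {
    stop("regions must be ORDERED or DISORDERED")
  }
  prot_flag <- rep(FALSE, root_length)
  if (!is.null(protected) && length(protected)) {
    protected <- normalize_intervals(protected)
    if (any(protected[, 2L] > root_length)) stop("protected intervals exceed root length")
    for (r in seq_len(nrow(protected))) {
      prot_flag[(protected[r, 1L] + 1L):protected[r, 2L]] <- TRUE
    }
  }
  extra <- setdiff(names(clade_multiplier), tree$clades)
  if (length(extra)) stop("clade_multiplier names absent from tree: ",
                          paste(extra, collapse = ", "))
  structure(list(tree = tree, root_length = root_length, root_codes = root_codes,
                 site_rates = site_rates, regions = regions,
                 model_ordered = model_ordered,
                 model_disordered = model_disordered,
                 ins_rate = ins_rate, del_rate = del_rate,
                 geom_prob = 1 / mean_indel_length,
                 protected_flag = prot_flag,
                 clade_multiplier = clade_multiplier, seed = as.integer(seed)),
            class = "sim_config")
}

region_model <- function(cfg, region) {
  if (region == "ORDERED") cfg$model_ordered else cfg$model_disordered
}

# one indel length draw: geometric on {1, 2, ...}
rindel_len <- function(cfg) 1L + rgeom(1L, cfg$geom_prob)

#' Evolve a sequence along one branch
#'
#' Applies substitutions (per-site endpoint draws from `exp(Q t_eff)` with
#' `t_eff = t * site_rate * multiplier`), then deletions and insertions as
#' Poisson processes scaled by branch length. Inserted residues are drawn
#' from the stationary frequencies of the creating site's region and
#' inherit its rate and region label; protected sites receive no indels
#' (deletion blocks are truncated at protected-interval boundaries).
#'
#' @param state sequence state: list with integer `id`, `aa` (1..20),
#'   numeric `rate`, character `region`, logical `protected`.
#' @param t branch length (>= 0).
#' @param multiplier clade rate multiplier for this branch.
#' @param cfg a [sim_config()].
#' @param env simulation environment (column registry); created by
#'   [simulate_family()].
#' @return the child state, with attribute `events` counting events.
#' @export
evolve_branch <- function(state, t, multiplier, cfg, env) {
  if (t < 0) stop("branch length must be >= 0")
  n_sub <- 0L
  L0 <- length(state$id)
  if (t > 0 && L0 > 0L) {
    # substitutions, grouped by (region, rate) so each group shares P(t_eff)
    key <- paste(state$region, signif(state$rate, 12))
    for (grp in unique(key)) {
      idx <- which(key == grp)
      r <- state$rate[idx[1L]]
      if (r <= 0) next
      P <- transition_matrix(region_model(cfg, state$region[idx[1L]]),
                             t * multiplier * r)
      par <- state$aa[idx]
      for (a in unique(par)) {
        sel <- idx[par == a]
        draws <- sample.int(20L, length(sel), replace = TRUE, prob = P[a, ])
        n_sub <- n_sub + sum(draws != a)
        state$aa[sel] <- draws
      }
    }
  }
  n_del_ev <- 0L
  n_ins_ev <- 0L
  if (t > 0) {
    # deletions
    n_del <- rpois(1L, cfg$del_rate * t * length(state$id))
    for (d in seq_len(n_del)) {
      free <- which(!state$protected)
      if (length(free) == 0L) break
      start <- free[sample.int(length(free), 1L)]
      len <- rindel_len(cfg)
      block <- start:min(start + len - 1L, length(state$id))
      if (any(state$protected[block])) {
        block <- block[seq_len(which(state$protected[block])[1L] - 1L)]
      }
      if (length(block) == 0L) next
      keep <- setdiff(seq_along(state$id), block)
      state <- lapply(state, `[`, keep)
      n_del_ev <- n_del_ev + 1L
    }
    # insertions
    n_ins <- rpois(1L, cfg$ins_rate * t * length(state$id))
    for (d in seq_len(n_ins)) {
      free <- which(!state$protected)
      if (length(free) == 0L) break
      at <- free[sample.int(length(free), 1L)]
      len <- rindel_len(cfg)
      region <- state$region[at]
      rate <- state$rate[at]
      model <- region_model(cfg, region)
      new_aa <- sample.int(20L, len, replace = TRUE, prob = model$pi)
      new_ids <- env$next_id + seq_len(len) - 1L
      env$next_id <- env$next_id + len
      env$rate_by_id[new_ids] <- rate
      env$region_by_id[new_ids] <- region
      # splice new columns into the global column order after the creator
      pos <- match(state$id[at], env$columns)
      env$columns <- append(env$columns, new_ids, after = pos)
      state <- list(
        id = append(state$id, new_ids, after = at),
        aa = append(state$aa, new_aa, after = at),
        rate = append(state$rate, rep(rate, len), after = at),
        region = append(state$region, rep(region, len), after = at),
        protected = append(state$protected, rep(FALSE, len), after = at))
      n_ins_ev <- n_ins_ev + 1L
    }
  }
  attr(state, "events") <- c(substitutions = n_sub, deletions = n_del_ev,
                             insertions = n_ins_ev)
  state
}

#' Simulate one protein family
#'
#' Evolves a root sequence down the family tree, recording the full indel
#' history so the true alignment (with per-column ground truth) is known
#' exactly. Deterministic given the config's seed.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `simulated_family`: list with `aln` (true
#'   alignment as a [protein_alignment]), `tree`, `col_rates`,
#'   `col_regions`, `protected` (true-alignment intervals),
#'   `leaf_seqs` (ungapped sequences), `events` and `seed`.
#' @export
simulate_family <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  L <- cfg$root_length
  root_aa <- cfg$root_codes
  if (is.null(root_aa)) {
    root_aa <- integer(L)
    for (reg in unique(cfg$regions)) {
      idx <- which(cfg$regions == reg)
      root_aa[idx] <- sample.int(20L, length(idx), replace = TRUE,
                                 prob = region_model(cfg, reg)$pi)
    }
  }
  env <- new.env(parent = emptyenv())
  env$columns <- seq_len(L)
  env$next_id <- L + 1L
  env$rate_by_id <- cfg$site_rates
  env$region_by_id <- cfg$regions

  phy <- cfg$tree$phy
  ntip <- length(phy$tip.label)
  root_state <- list(id = seq_len(L), aa = root_aa, rate = cfg$site_rates,
                     region = cfg$regions, protected = cfg$protected_flag)
  states <- vector("list", ntip + phy$Nnode)
  states[[ntip + 1L]] <- root_state
  events <- c(substitutions = 0L, deletions = 0L, insertions = 0L)
  ord <- ape::reorder.phylo(phy, "cladewise")
  perm <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                paste(phy$edge[, 1], phy$edge[, 2]))
  labels <- cfg$tree$edge_label[perm]
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]
    child <- ord$edge[e, 2L]
    mult <- cfg$clade_multiplier[labels[e]]
    if (is.na(mult) || length(mult) == 0L) mult <- 1
    states[[child]] <- evolve_branch(states[[parent]], ord$edge.length[e],
                                     mult, cfg, env)
    events <- events + attr(states[[child]], "events")
  }

  cols <- env$columns
  nc <- length(cols)
  pos_of_id <- integer(env$next_id - 1L)
  pos_of_id[cols] <- seq_len(nc)
  rows <- character(ntip)
  leaf_seqs <- character(ntip)
  for (i in seq_len(ntip)) {
    st <- states[[i]]
    row <- rep(GAP_CHAR, nc)
    row[pos_of_id[st$id]] <- AA_ALPHABET[st$aa]
    rows[i] <- paste(row, collapse = "")
    leaf_seqs[i] <- paste(AA_ALPHABET[st$aa], collapse = "")
  }
  names(rows) <- phy$tip.label
  names(leaf_seqs) <- phy$tip.label

  prot_cols <- pos_of_id[which(cfg$protected_flag)]
  prot_int <- if (length(prot_cols)) runs_to_intervals(sort(prot_cols)) else
    matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("start", "end")))

  structure(list(
    aln = protein_alignment(rows, family_id = sprintf("sim%d", cfg$seed)),
    tree = cfg$tree,
    col_rates = env$rate_by_id[cols],
    col_regions = env$region_by_id[cols],
    protected = prot_int,
    leaf_seqs = leaf_seqs,
    clade_multiplier = cfg$clade_multiplier,
    events = events, seed = cfg$seed, config = cfg),
    class = "simulated_family")
}

# sorted positions (1-based) -> 0-based half-open intervals
runs_to_intervals <- function(pos) {
  breaks <- which(diff(pos) > 1L)
  starts <- pos[c(1L, breaks + 1L)]
  ends <- pos[c(breaks, length(pos))]
  cbind(start = starts - 1L, end = ends)
}

#' @export
print.simulated_family <- function(x, ...) {
  cat(sprintf("simulated_family (seed %d): %d taxa, %d true-alignment columns, %s\n",
              x$seed, length(x$leaf_seqs), x$aln$ncol,
              paste(sprintf("%s=%d", names(x$events), x$events), collapse = ", ")))
  invisible(x)
}

#' Generate a null benchmark collection
#'
#' Simulates `n_families` families under the template configuration:
#' protein-wide heterogeneity (branch lengths, regimes, indels, any
#' clade-wide multiplier in the template) but no motif-specific rate shift.
#' Used to measure the false-positive rate of the full pipeline. True
#' alignments are used directly (no re-alignment step), which isolates the
#' statistical behaviour of the test from aligner artifacts.
#'
#' @param n_families number of families.
#' @param cfg_template a [sim_config()]; each family reuses it with a fresh
#'   seed derived from `seed`.
#' @param seed master seed.
#' @return list of `simulated_family` objects with attribute
#'   `alignment_mode = "true"`.
#' @export
make_null_benchmark <- function(n_families, cfg_template, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  family_seeds <- sample.int(2147483646L, n_families)
  fams <- lapply(family_seeds, function(s) {
    cfg <- cfg_template
    cfg$seed <- s
    simulate_family(cfg)
  })
  attr(fams, "alignment_mode") <- "true"
  fams
}

#' Write a simulated family to disk
#'
#' Writes the unaligned leaf sequences, the true alignment, and a JSON
#' ground-truth file (per-column rates and regions, protected intervals,
#' injected clade multipliers, seed).
#'
#' @param fam a `simulated_family`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulated_family <- function(fam, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_simulated_family requires the jsonlite package")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- fam$aln$family_id
  seq_path <- file.path(dir, paste0(id, "_sequences.fasta"))
  aln_path <- file.path(dir, paste0(id, "_true_alignment.fasta"))
  truth_path <- file.path(dir, paste0(id, "_truth.json"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(fam$leaf_seqs), seq_path)
  write_alignment(fam$aln, aln_path)
  jsonlite::write_json(list(
    family_id = id, seed = fam$seed,
    col_rates = fam$col_rates, col_regions = fam$col_regions,
    protected = as.data.frame(fam$protected),
    clade_multiplier = as.list(fam$clade_multiplier),
    events = as.list(fam$events)), truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(seq_path, aln_path, truth_path))
}
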