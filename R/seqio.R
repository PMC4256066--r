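#' @importFrom stats optimize pchisq pgamma pnorm qgamma rbinom rgeom rpois runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Amino acids in PAML order; '-' and 'X' are treated as missing data.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP_CHAR <- "-"
MISSING_CHARS <- c("-", "X")

#' Clade partition labels
#'
#' Branch partitions used throughout the package: `PRE_WGD` covers the
#' lineages that diverged before the whole-genome duplication, and
#' `POST_WGD_1` / `POST_WGD_2` the one or two post-duplication clades.
#' @export
CLADE_LABELS <- c("PRE_WGD", "POST_WGD_1", "POST_WGD_2")

#' Construct a protein alignment
#'
#' A `protein_alignment` holds the gapped amino-acid rows of one ortholog
#' family. Rows must be equal length and drawn from the 20 amino acids plus
#' `-` (gap) and `X` (ambiguous); gaps and `X` are treated as missing data
#' in all likelihood computations.
#'
#' @param rows named character vector of gapped sequences (one per taxon).
#' @param family_id identifier of the family.
#' @return an object of class `protein_alignment` with fields `family_id`,
#'   `taxa`, `mat` (character matrix, taxa x columns) and `ncol`.
#' @export
protein_alignment <- function(rows, family_id = "family") {
  if (length(rows) < 1L) stop("alignment must contain at least one sequence")
  taxa <- names(rows)
  if (is.null(taxa) || any(!nzchar(taxa))) stop("all rows must be named by taxon")
  if (anyDuplicated(taxa)) {
    stop("duplicated taxon names: ", paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    ref <- max(widths)
    bad <- taxa[widths != ref]
    stop("ragged alignment: row(s) ", paste(bad, collapse = ", "),
         " differ in length from the longest row (", ref, " columns)")
  }
  if (widths[1L] < 1L) stop("alignment has zero columns")
  mat <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  rownames(mat) <- taxa
  ok <- mat %in% c(AA_ALPHABET, MISSING_CHARS)
  if (!all(ok)) {
    bad <- unique(mat[!ok])
    stop("invalid characters in alignment: ", paste(bad, collapse = " "),
         " (allowed: 20 amino acids, '-', 'X')")
  }
  structure(list(family_id = family_id, taxa = taxa, mat = mat,
                 ncol = ncol(mat)),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein_alignment '%s': %d taxa, %d columns\n",
              x$family_id, length(x$taxa), x$ncol))
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' @param path FASTA file with >= 2 equal-length gapped records.
#' @param family_id family identifier; defaults to the file stem.
#' @return a [protein_alignment].
#' @export
read_alignment <- function(path, family_id = tools::file_path_sans_ext(basename(path))) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  if (length(aa) < 2L) stop("alignment requires >= 2 records: ", path)
  rows <- as.character(aa)
  names(rows) <- sub("\\s.*$", "", names(aa))
  protein_alignment(rows, family_id = family_id)
}

#' Write a protein alignment to FASTA
#'
#' @param aln a [protein_alignment].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  rows <- apply(aln$mat, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(rows), filepath = path)
  invisible(NULL)
}

#' Map alignment columns to ungapped residue positions
#'
#' @param aln a [protein_alignment].
#' @param taxon taxon name.
#' @return integer vector of length `ncol`: the 1-based residue index of each
#'   alignment column in the ungapped sequence of `taxon`, `NA` at gaps.
#' @export
column_residue_map <- function(aln, taxon) {
  if (!taxon %in% aln$taxa) stop("unknown taxon: ", taxon)
  chars <- aln$mat[taxon, ]
  resid <- chars != GAP_CHAR
  out <- rep(NA_integer_, aln$ncol)
  out[resid] <- seq_len(sum(resid))
  out
}

# subset an alignment to a column interval (0-based, half-open)
aln_slice <- function(aln, interval) {
  interval <- check_interval(interval, aln$ncol)
  aln$mat[, (interval[1L] + 1L):interval[2L], drop = FALSE]
}

check_interval <- function(interval, ncol) {
  if (length(interval) != 2L || any(!is.finite(interval))) {
    stop("interval must be c(start, end)")
  }
  interval <- as.integer(interval)
  if (interval[1L] < 0L || interval[2L] > ncol || interval[1L] >= interval[2L]) {
    stop(sprintf("invalid interval [%d, %d) for %d columns",
                 interval[1L], interval[2L], ncol))
  }
  interval
}

#' Label the branches of a rooted tree by clade
#'
#' Every branch of the rooted tree is assigned exactly one label: branches
#' inside a post-duplication leaf set (including its stem branch) receive
#' that clade's label; all remaining branches are `PRE_WGD`. Each
#' post-duplication leaf set must be monophyletic.
#'
#' @param phy a rooted `ape::phylo` with branch lengths.
#' @param clade_spec named list mapping `POST_WGD_1` / `POST_WGD_2` to leaf
#'   name vectors; an empty list yields a single-rate (all `PRE_WGD`) tree.
#' @return an object of class `clade_tree`: list with `phy`, `edge_label`
#'   (one label per edge row) and `clades` (labels present).
#' @export
clade_tree <- function(phy, clade_spec = list()) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape phylo object")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  bad_labels <- setdiff(names(clade_spec), c("POST_WGD_1", "POST_WGD_2"))
  if (length(bad_labels)) stop("unknown clade labels: ", paste(bad_labels, collapse = ", "))
  edge_label <- rep("PRE_WGD", nrow(phy$edge))
  ntip <- length(phy$tip.label)
  for (lab in names(clade_spec)) {
    leaves <- clade_spec[[lab]]
    missing <- setdiff(leaves, phy$tip.label)
    if (length(missing)) stop("clade ", lab, " names unknown leaves: ",
                              paste(missing, collapse = ", "))
    tips <- match(leaves, phy$tip.label)
    if (length(tips) == 1L) {
      node <- tips
    } else {
      node <- ape::getMRCA(phy, tips)
      desc <- phy$tip.label[intersect(descendant_nodes(phy, node), seq_len(ntip))]
      extra <- setdiff(desc, leaves)
      if (length(extra)) {
        stop("clade ", lab, " is not monophyletic; the clade spanned by its ",
             "ancestor also contains: ", paste(extra, collapse = ", "))
      }
    }
    in_clade <- c(node, descendant_nodes(phy, node))
    sel <- phy$edge[, 2L] %in% in_clade
    if (any(edge_label[sel] != "PRE_WGD")) stop("overlapping clade specifications")
    edge_label[sel] <- lab
  }
  structure(list(phy = phy, edge_label = edge_label,
                 clades = unique(c("PRE_WGD", names(clade_spec)))),
            class = "clade_tree")
}

# all nodes strictly below `node` (tips and internals)
descendant_nodes <- function(phy, node) {
  out <- integer(0)
  todo <- phy$edge[phy$edge[, 1L] == node, 2L]
  while (length(todo)) {
    out <- c(out, todo)
    todo <- phy$edge[phy$edge[, 1L] %in% todo, 2L]
  }
  out
}

#' Read a Newick tree and label its branches by clade
#'
#' @param path Newick file with branch lengths.
#' @param clade_spec as in [clade_tree()].
#' @return a `clade_tree`.
#' @export
read_clade_tree <- function(path, clade_spec = list()) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file: ", path)
  clade_tree(phy, clade_spec)
}

#' @export
print.clade_tree <- function(x, ...) {
  tab <- table(x$edge_label)
  cat(sprintf("clade_tree: %d leaves; branches: %s\n", length(x$phy$tip.label),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# check that alignment taxa and tree leaves match one-to-one
check_taxa_match <- function(aln, tree) {
  leaves <- tree$phy$tip.label
  if (!setequal(aln$taxa, leaves) || length(aln$taxa) != length(leaves)) {
    stop("alignment taxa and tree leaves do not match; alignment-only: ",
         paste(setdiff(aln$taxa, leaves), collapse = ", "), "; tree-only: ",
         paste(setdiff(leaves, aln$taxa), collapse = ", "))
  }
  invisible(TRUE)
}

#' Normalize a set of intervals
#'
#' Sorts 0-based half-open intervals and merges overlapping or abutting
#' ones. Idempotent.
#'
#' @param intervals two-column matrix or data.frame (start, end).
#' @return matrix with columns `start`, `end`, sorted and non-overlapping.
#' @export
normalize_intervals <- function(intervals) {
  m <- as.matrix(intervals)
  if (length(m) == 0L) return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("start", "end"))))
  if (ncol(m) != 2L) stop("intervals must have two columns (start, end)")
  storage.mode(m) <- "integer"
  if (any(m[, 1L] < 0L) || any(m[, 1L] >= m[, 2L])) {
    stop("intervals must satisfy 0 <= start < end")
  }
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) for (i in 2:nrow(m)) {
    k <- nrow(out)
    if (m[i, 1L] <= out[k, 2L]) {
      out[k, 2L] <- max(out[k, 2L], m[i, 2L])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Read an interval mask file
#'
#' Mask files are TSV with columns `family_id`, `start`, `end`, `kind`
#' (0-based half-open alignment-column intervals; kind one of DISORDER,
#' MOTIF, FLANK). Intervals are normalized per family and kind.
#'
#' @param path TSV file.
#' @return data.frame with the four columns, normalized.
#' @export
read_mask <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "start", "end", "kind")
  if (!all(need %in% names(df))) {
    stop("mask file must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$kind %in% c("DISORDER", "MOTIF", "FLANK"))) {
    stop("mask kind must be DISORDER, MOTIF or FLANK")
  }
  parts <- split(df, list(df$family_id, df$kind), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(p) {
    m <- normalize_intervals(p[, c("start", "end")])
    data.frame(family_id = p$family_id[1L], start = m[, 1L], end = m[, 2L],
               kind = p$kind[1L], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$family_id, out$kind, out$start), , drop = FALSE]
}

#' Write an interval mask file
#' @param mask data.frame as returned by [read_mask()].
#' @param path output TSV path.
#' @export
write_mask <- function(mask, path) {
  write.table(mask, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

RESULTS_COLUMNS <- c("family_id", "start", "end", "kind", "clade",
                     "lnL0", "lnL1", "lrt", "dkl", "lambda", "pvalue",
                     "alpha_hat", "significant")

#' Write a results table
#'
#' Writes one row per likelihood-ratio test as TSV with a fixed column
#' order, floats at 6 significant digits, and deterministic row order
#' (family, segment start, clade).
#'
#' @param table data.frame with the columns listed in `RESULTS_COLUMNS`.
#' @param path output TSV path.
#' @export
write_results <- function(table, path) {
  miss <- setdiff(RESULTS_COLUMNS, names(table))
  if (length(miss)) stop("results table missing columns: ", paste(miss, collapse = ", "))
  tab <- table[, RESULTS_COLUMNS, drop = FALSE]
  if (nrow(tab)) {
    tab <- tab[order(tab$family_id, tab$start, tab$clade), , drop = FALSE]
    for (col in c("lnL0", "lnL1", "lrt", "dkl", "lambda", "pvalue", "alpha_hat")) {
      tab[[col]] <- signif(tab[[col]], 6L)
    }
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a results table written by [write_results()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
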