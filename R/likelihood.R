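# Phylogenetic likelihood core: Felsenstein pruning over alignment columns,
# vectorized across columns, with per-branch rate multipliers.

#' Construct a rate assignment
#'
#' Maps each clade label to a branch-length multiplier. Exactly one label is
#' the reference, fixed at 1; under the null every label is at 1, under the
#' alternative the tested clade's multiplier is free.
#'
#' @param rates named numeric vector of multipliers (>= 0), one per clade
#'   label present in the tree.
#' @param reference the reference label (multiplier forced to 1).
#' @return an object of class `rate_assignment`.
#' @export
rate_assignment <- function(rates = c(PRE_WGD = 1), reference = "PRE_WGD") {
  if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
    stop("rates must be a named vector of clade labels")
  }
  if (!reference %in% names(rates)) stop("reference label missing from rates")
  if (any(!is.finite(rates)) || any(rates < 0)) stop("rates must be finite and >= 0")
  rates[reference] <- 1
  structure(list(rates = rates, reference = reference), class = "rate_assignment")
}

# Preprocess a clade_tree for pruning: postorder edges, tip indices.
prepare_tree <- function(tree, taxa) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  # reorder() permutes edges only; match labels through the original rows
  perm <- match(paste(po$edge[, 1], po$edge[, 2]),
                paste(phy$edge[, 1], phy$edge[, 2]))
  list(
    edge = po$edge,
    edge_length = po$edge.length,
    edge_label = tree$edge_label[perm],
    ntip = ntip,
    nnode = phy$Nnode,
    root = ntip + 1L,
    tip_row = match(phy$tip.label, taxa)  # row of codes matrix per tip number
  )
}

# Integer codes for an alignment slice: 1..20 in PAML order, NA = missing.
aln_codes <- function(mat) {
  codes <- match(mat, AA_ALPHABET)
  dim(codes) <- dim(mat)
  rownames(codes) <- rownames(mat)
  codes
}

# Core pruning pass. codes: taxa x L integer matrix (NA = missing data);
# pt: prepare_tree() output; edge_scale: per-edge multiplier (already
# includes clade rates, the site scale, and the gamma-category rate).
# Returns per-column log-likelihood (length L).
prune_loglik <- function(codes, pt, model, edge_scale) {
  L <- ncol(codes)
  nnodes <- pt$ntip + pt$nnode
  partial <- vector("list", nnodes)
  logscale <- numeric(L)
  edge <- pt$edge
  t_eff <- pt$edge_length * edge_scale
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1L]
    child <- edge[e, 2L]
    if (child <= pt$ntip) {
      cw <- codes[pt$tip_row[child], ]
      down <- matrix(0, 20L, L)
      obs <- which(!is.na(cw))
      if (length(obs)) down[cbind(cw[obs], obs)] <- 1
      if (length(obs) < L) down[, setdiff(seq_len(L), obs)] <- 1
    } else {
      down <- partial[[child]]
      partial[child] <- list(NULL)  # free memory without shifting indices
    }
    P <- model$left %*% (exp(model$eig_values * t_eff[e]) * model$right)
    up <- P %*% down
    up[up < 0] <- 0
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- up
    } else {
      prod <- partial[[parent]] * up
      # rescale per column to avoid underflow on larger trees
      mx <- apply(prod, 2L, max)
      mx[mx == 0] <- 1
      logscale <- logscale + log(mx)
      partial[[parent]] <- prod / rep(mx, each = 20L)
    }
  }
  lik <- colSums(model$pi * partial[[pt$root]])
  log(lik) + logscale
}

# all-ones assignment over the labels present in a tree
unit_rates <- function(tree) {
  labs <- unique(tree$edge_label)
  ref <- if ("PRE_WGD" %in% labs) "PRE_WGD" else labs[1L]
  rate_assignment(setNames(rep(1, length(labs)), labs), reference = ref)
}

# Per-column log-likelihood for all columns, mixing over gamma categories
# (equal prior weights) if the model has > 1 category.
column_logliks <- function(codes, pt, model, rates, site_scale = 1) {
  miss <- setdiff(unique(pt$edge_label), names(rates$rates))
  if (length(miss)) stop("rate assignment lacks labels: ",
                         paste(miss, collapse = ", "))
  edge_scale <- rates$rates[pt$edge_label] * site_scale
  g <- model$gamma_rates
  if (length(g) == 1L) {
    return(prune_loglik(codes, pt, model, edge_scale * g))
  }
  per_cat <- vapply(g, function(r) prune_loglik(codes, pt, model, edge_scale * r),
                    numeric(ncol(codes)))
  if (ncol(codes) == 1L) per_cat <- matrix(per_cat, nrow = 1L)
  mx <- apply(per_cat, 1L, max)
  mx + log(rowMeans(exp(per_cat - mx)))
}

#' Log-likelihood of a single alignment column
#'
#' Computes the probability of one column under the pruning algorithm with
#' branch lengths multiplied by the clade rates in `rates` and by
#' `site_scale`. Gaps and `X` are missing data; an all-missing column has
#' log-likelihood 0.
#'
#' @param aln a [protein_alignment].
#' @param col 0-based column index.
#' @param tree a [clade_tree()] whose leaves match the alignment taxa.
#' @param model a [substitution_model()].
#' @param rates a [rate_assignment()].
#' @param site_scale additional rate scale applied to every branch.
#' @return the column log-likelihood (a finite scalar).
#' @export
column_loglik <- function(aln, col, tree, model, rates = unit_rates(tree),
                          site_scale = 1) {
  check_taxa_match(aln, tree)
  if (site_scale <= 0 || !is.finite(site_scale)) stop("site_scale must be positive")
  codes <- aln_codes(aln$mat[, col + 1L, drop = FALSE])
  pt <- prepare_tree(tree, aln$taxa)
  as.numeric(column_logliks(codes, pt, model, rates, site_scale))
}

#' Log-likelihood of an alignment segment
#'
#' Sums independent per-column log-likelihoods over a 0-based half-open
#' column interval, mixing each column over the model's discretized gamma
#' categories with equal prior weights.
#'
#' @inheritParams column_loglik
#' @param interval `c(start, end)`, 0-based half-open, within the alignment.
#' @return an object of class `segment_loglik`: list with `loglik`,
#'   `per_column` and `rates`.
#' @export
segment_loglik <- function(aln, interval, tree, model,
                           rates = unit_rates(tree), site_scale = 1) {
  check_taxa_match(aln, tree)
  interval <- check_interval(interval, aln$ncol)
  codes <- aln_codes(aln_slice(aln, interval))
  pt <- prepare_tree(tree, aln$taxa)
  per_col <- column_logliks(codes, pt, model, rates, site_scale)
  structure(list(loglik = sum(per_col), per_column = per_col, rates = rates,
                 converged = TRUE),
            class = "segment_loglik")
}

# Low-level optimizer used by fit_rates and clade_lrt: codes/pt prepared once.
fit_rates_impl <- function(codes, pt, model, free_labels, base_rates,
                           site_scale = 1, bounds = c(1e-6, 1e3), tol = 1e-8,
                           max_cycles = 50L) {
  rates <- base_rates
  obj <- function(r) {
    sum(column_logliks(codes, pt, model, r, site_scale))
  }
  if (length(free_labels) == 0L) {
    ll <- obj(rates)
    return(list(loglik = ll, rates = rates, converged = TRUE))
  }
  log_bounds <- log(bounds)
  ll_old <- obj(rates)
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    for (lab in free_labels) {
      opt <- optimize(function(la) {
        r <- rates
        r$rates[lab] <- exp(la)
        obj(r)
      }, interval = log_bounds, maximum = TRUE, tol = 1e-7)
      rates$rates[lab] <- exp(opt$maximum)
    }
    ll_new <- obj(rates)
    if (abs(ll_new - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  # tie-break toward 1: if fixing a free label at 1 loses nothing, prefer 1
  for (lab in free_labels) {
    r1 <- rates
    r1$rates[lab] <- 1
    if (obj(r1) >= ll_old - tol) {
      rates <- r1
      ll_old <- obj(r1)
    }
  }
  list(loglik = ll_old, rates = rates, converged = converged)
}

#' Maximum-likelihood clade rate multipliers for a segment
#'
#' Maximizes the segment log-likelihood over the multipliers of the
#' `free_labels` clades (Brent's method on the log scale, coordinate-wise
#' when several labels are free), holding the reference label at 1 and
#' branch lengths fixed. With no free labels this returns the fixed-rate
#' likelihood. Ties are broken toward a multiplier of 1.
#'
#' @inheritParams segment_loglik
#' @param free_labels character vector of clade labels to optimize
#'   (must exclude the reference label of `rates`).
#' @param bounds search bounds for each multiplier.
#' @param tol convergence tolerance on the log-likelihood.
#' @return a `segment_loglik` with fitted `rates` and a `converged` flag.
#' @export
fit_rates <- function(aln, interval, tree, model, free_labels = character(0),
                      rates = unit_rates(tree),
                      site_scale = 1, bounds = c(1e-6, 1e3), tol = 1e-8) {
  check_taxa_match(aln, tree)
  interval <- check_interval(interval, aln$ncol)
  if (rates$reference %in% free_labels) stop("free_labels must exclude the reference label")
  missing_lab <- setdiff(free_labels, tree$clades)
  if (length(missing_lab)) stop("labels absent from tree: ",
                                paste(missing_lab, collapse = ", "))
  codes <- aln_codes(aln_slice(aln, interval))
  pt <- prepare_tree(tree, aln$taxa)
  fit <- fit_rates_impl(codes, pt, model, free_labels, rates, site_scale,
                        bounds, tol)
  per_col <- column_logliks(codes, pt, model, fit$rates, site_scale)
  structure(list(loglik = fit$loglik, per_column = per_col, rates = fit$rates,
                 converged = fit$converged),
            class = "segment_loglik")
}

#' Fit the among-site gamma shape for a whole alignment
#'
#' Estimates the gamma shape (8 categories by default) by maximizing the
#' full-alignment likelihood at fixed branch lengths and unit clade rates;
#' done once per protein and then held fixed for all segment tests.
#'
#' @inheritParams segment_loglik
#' @param n_categories number of gamma categories.
#' @param bounds search interval for the shape.
#' @return list with `shape` and the fitted `model`.
#' @export
fit_gamma_shape <- function(aln, tree, model, n_categories = 8L,
                            bounds = c(0.05, 50)) {
  check_taxa_match(aln, tree)
  codes <- aln_codes(aln$mat)
  pt <- prepare_tree(tree, aln$taxa)
  rates <- unit_rates(tree)
  opt <- optimize(function(ls) {
    m <- set_gamma(model, exp(ls), n_categories)
    sum(column_logliks(codes, pt, m, rates))
  }, interval = log(bounds), maximum = TRUE, tol = 1e-4)
  shape <- exp(opt$maximum)
  list(shape = shape, model = set_gamma(model, shape, n_categories))
}

#' Maximum-likelihood branch lengths for a family
#'
#' Re-estimates the branch lengths of the family tree on the whole protein
#' alignment under the given model (via phangorn), keeping the topology and
#' the clade partition. Used once per family; segment tests then hold these
#' lengths fixed and fit only the clade multiplier.
#'
#' @param aln a [protein_alignment].
#' @param tree a [clade_tree()].
#' @param model a [substitution_model()]; its frequencies and
#'   exchangeabilities are passed to phangorn.
#' @return a `clade_tree` with updated branch lengths.
#' @export
fit_branch_lengths <- function(aln, tree, model) {
  if (!requireNamespace("phangorn", quietly = TRUE)) {
    stop("fit_branch_lengths requires the phangorn package")
  }
  check_taxa_match(aln, tree)
  chars <- aln$mat
  chars[chars == "X"] <- "-"
  dat <- phangorn::phyDat(chars, type = "AA")
  Q <- model$S[lower.tri(model$S)]
  fit <- phangorn::pml(ape::unroot(tree$phy), dat, bf = model$pi, Q = Q)
  fit <- phangorn::optim.pml(fit, optEdge = TRUE, optBf = FALSE, optQ = FALSE,
                             control = phangorn::pml.control(trace = 0))
  newphy <- fit$tree
  # transfer unrooted ML lengths back onto the rooted topology by splitting
  # the root edge evenly between the two root children
  rooted <- tree$phy
  ntip <- length(rooted$tip.label)
  bip_len <- function(phy) {
    out <- list()
    for (e in seq_len(nrow(phy$edge))) {
      child <- phy$edge[e, 2L]
      tips <- if (child <= length(phy$tip.label)) phy$tip.label[child] else
        phy$tip.label[intersect(descendant_nodes(phy, child), seq_len(length(phy$tip.label)))]
      key <- paste(sort(tips), collapse = ";")
      all_t <- sort(phy$tip.label)
      comp <- paste(setdiff(all_t, sort(tips)), collapse = ";")
      out[[min(key, comp)]] <- (out[[min(key, comp)]] %||% 0) + phy$edge.length[e]
    }
    out
  }
  ml <- bip_len(newphy)
  root_children <- rooted$edge[rooted$edge[, 1L] == ntip + 1L, 2L]
  for (e in seq_len(nrow(rooted$edge))) {
    child <- rooted$edge[e, 2L]
    tips <- if (child <= ntip) rooted$tip.label[child] else
      rooted$tip.label[intersect(descendant_nodes(rooted, child), seq_len(ntip))]
    key <- paste(sort(tips), collapse = ";")
    comp <- paste(setdiff(sort(rooted$tip.label), sort(tips)), collapse = ";")
    len <- ml[[min(key, comp)]]
    if (is.null(len)) len <- 0
    if (child %in% root_children && length(root_children) == 2L) len <- len / 2
    rooted$edge.length[e] <- len
  }
  out <- tree
  out$phy <- rooted
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
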