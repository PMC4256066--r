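# Shared fixtures and independent oracles, all built in code.

# 4-leaf tree with one post-duplication clade {c, d}
quartet_tree <- function() {
  phy <- ape::read.tree(text = "((a:0.1,b:0.2):0.15,(c:0.3,d:0.25):0.05):0;")
  clade_tree(phy, list(POST_WGD_1 = c("c", "d")))
}

# 8-leaf yeast-like tree: 4 pre-WGD taxa and a 4-taxon post-WGD clade,
# branch lengths of the order seen in budding-yeast protein trees
eight_taxon_tree <- function() {
  txt <- paste0("(((a:0.25,b:0.25):0.15,(c:0.2,d:0.3):0.1):0.1,",
                "((e:0.15,f:0.2):0.2,(g:0.25,h:0.2):0.15):0.1):0;")
  clade_tree(ape::read.tree(text = txt), list(POST_WGD_1 = c("e", "f", "g", "h")))
}

# 10-leaf duplicate-family tree: two post-WGD clades
duplicate_tree <- function() {
  txt <- paste0("(((a:0.25,b:0.25):0.15,(c:0.2,d:0.3):0.1):0.1,",
                "(((e:0.15,f:0.2):0.2,(g:0.25,h:0.2):0.15):0.15,",
                "(i:0.3,j:0.25):0.2):0.1):0;")
  clade_tree(ape::read.tree(text = txt),
             list(POST_WGD_1 = c("e", "f", "g", "h"), POST_WGD_2 = c("i", "j")))
}

# random reversible substitution model (random exchangeabilities and
# Dirichlet-ish frequencies)
random_model <- function(seed) {
  set.seed(seed)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- runif(190, 0.05, 2)
  S <- S + t(S)
  pi <- rgamma(20, shape = 2)
  pi <- pi / sum(pi)
  substitution_model(S, pi)
}

# random gapped column over a set of taxa
random_column <- function(taxa, seed, p_gap = 0.15) {
  set.seed(seed)
  chars <- sample(c(slimdiv:::AA_ALPHABET, "-"), length(taxa), replace = TRUE,
                  prob = c(rep((1 - p_gap) / 20, 20), p_gap))
  rows <- setNames(chars, taxa)
  protein_alignment(rows, family_id = paste0("col", seed))
}

# Exhaustive-enumeration likelihood oracle: sums over all internal-node
# states; independent of the pruning implementation.
brute_force_col_loglik <- function(aln, col, ct, model, rates = NULL) {
  phy <- ct$phy
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  if (is.null(rates)) {
    rates <- setNames(rep(1, length(unique(ct$edge_label))),
                      unique(ct$edge_label))
  }
  codes <- match(aln$mat[phy$tip.label, col + 1L], slimdiv:::AA_ALPHABET)
  states <- as.matrix(expand.grid(rep(list(1:20), nint)))
  state_of <- function(node) {
    if (node <= ntip) rep(codes[node], nrow(states)) else states[, node - ntip]
  }
  pr <- model$pi[states[, 1L]]  # root = ntip + 1 is the first internal node
  for (e in seq_len(nrow(phy$edge))) {
    i <- state_of(phy$edge[e, 1L])
    j <- state_of(phy$edge[e, 2L])
    if (anyNA(j)) next  # missing tip: marginalizes to 1
    P <- transition_matrix(model, phy$edge.length[e] * rates[ct$edge_label[e]])
    pr <- pr * P[cbind(i, j)]
  }
  log(sum(pr))
}

# simulate a family with an injected clade rate shift, no indels
shifted_family <- function(tree, L, multiplier, seed, model = wag_model()) {
  cfg <- sim_config(tree, root_length = L, model_ordered = model,
                    ins_rate = 0, del_rate = 0,
                    clade_multiplier = c(POST_WGD_1 = multiplier), seed = seed)
  simulate_family(cfg)
}

# density of the chi-squared(df = 1, ncp = lam), written from the
# (Z + sqrt(lam))^2 representation; used only as an integration oracle
ncx2_density_df1 <- function(x, lam) {
  s <- sqrt(x)
  (dnorm(s - sqrt(lam)) + dnorm(s + sqrt(lam))) / (2 * s)
}

# numerically integrated survival function oracle
ncx2_sf_oracle <- function(x, lam) {
  if (x == 0) return(1)
  1 - integrate(ncx2_density_df1, lower = 0, upper = x, lam = lam,
                rel.tol = 1e-11, abs.tol = 1e-12)$value
}

# exact null distribution of the lineage-bias statistic by enumeration of
# all fair-coin event assignments (feasible for <= 12 total events)
exact_bias_pvalue <- function(totals, T_obs) {
  grids <- lapply(totals, function(t) 0:t)
  combos <- expand.grid(grids)
  prob <- rep(1, nrow(combos))
  Tval <- rep(0, nrow(combos))
  for (k in seq_along(totals)) {
    n1 <- combos[[k]]
    prob <- prob * choose(totals[k], n1) / 2^totals[k]
    Tval <- Tval + abs(2 * n1 - totals[k])
  }
  sum(prob[Tval >= T_obs])
}
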