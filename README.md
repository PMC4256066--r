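# slimdiv

Detecting functional divergence of short linear motifs after gene
duplication.

## The problem

Short linear motifs (SLiMs) — phosphosites, docking and localization
signals of 2–15 residues, mostly in disordered protein regions — carry much
of a protein's posttranslational regulation. After a whole-genome
duplication (WGD), such as the one in budding yeast, a motif may keep its
function in one paralog and degenerate in the other (type I functional
divergence). `slimdiv` detects this as a lineage-specific change in
evolutionary rate of a motif-sized alignment segment.

The naive approach — a likelihood-ratio test of "one rate on the whole
tree" against "an extra rate on the post-duplication clade" — is badly
miscalibrated on real alignments: whole-protein rate shifts, alignment
errors and non-stationary evolution are all partially absorbed by the extra
rate parameter, so the central χ²₁ null rejects far too often. `slimdiv`
implements a calibrated version of the test plus everything needed to run
and validate it genome-wide.

## The statistic

For a segment of `L` columns and a post-duplication clade with
branch-length multiplier α (α = 1 for all other branches, branch lengths
fixed from the whole-protein fit):

    LRT = 2 (ln L₁ − ln L₀),   with α̂ fitted by maximum likelihood in H₁.

Under a *shared heterogeneous background process*, the LRT follows a
non-central chi-squared χ²(k = 1, λ) with

    λ = 2 · L · D_KL(P‖Q),

where `D_KL` is the per-column Kullback–Leibler divergence of the true
background process from the single-rate null. `D_KL` is estimated by moment
matching from the whole-protein LRT (`E[LRT] = k + λ` implies
`D_KL = (LRT_protein − k) / (2 L_protein)`), with a proteome-wide pooled
estimate as a fallback; each motif uses the *larger* of the two
divergences, so corrected p-values are always more conservative than the
central χ²₁ p-values. The df = 1 survival function has a closed form in
terms of the normal CDF, used directly.

Significance is then called with a modified Storey FDR procedure: because
zero-information segments produce a point mass of p = 1, the null
proportion π₀ is estimated from the density of p-values in the window
(0.6, 0.95], and `FDR(t) = π₀ t N / #{p ≤ t}`.

Around the core test, the package provides:

* a phylo-HMM that predicts candidate motifs as conserved segments inside
  disordered regions of the pre-WGD sub-alignment (background rate from a
  31-column window via Newton–Raphson; conserved state an 8-category
  Gamma(0.6, 0.6) rate mixture; gap trimming and a structural length
  filter),
* a permutation test for lineage bias of constraint changes within paralog
  pairs (events merged within 35 columns),
* an amino-acid evolution simulator with indels, ordered/disordered
  substitution regimes, rate inheritance through insertions, protected
  motif intervals and injected clade shifts, used to validate calibration,
* a Felsenstein-pruning likelihood engine (WAG by default, any
  PAML-format rate matrix accepted) with clade-rate fitting.

## Worked example

Simulate a duplicate family (4 pre-WGD species, two 4-species post-WGD
clades) in which a 12-column motif evolves six times faster in one copy,
then test two motifs in both copies:

```r
library(slimdiv)
library(ape)

tree <- clade_tree(
  read.tree(text = paste0("(((a:0.25,b:0.25):0.15,(c:0.2,d:0.3):0.1):0.1,",
                          "(((e:0.15,f:0.2):0.2,(g:0.25,h:0.2):0.15):0.15,",
                          "((i:0.2,j:0.15):0.2,(k:0.25,l:0.2):0.1):0.15):0.1):0;")),
  list(POST_WGD_1 = c("e", "f", "g", "h"), POST_WGD_2 = c("i", "j", "k", "l")))
model <- wag_model()

cfg <- sim_config(tree, root_length = 200, model_ordered = model,
                  ins_rate = 0, del_rate = 0, seed = 42)
fam <- simulate_family(cfg)
cfg_shift <- sim_config(tree, root_length = 200, model_ordered = model,
                        ins_rate = 0, del_rate = 0,
                        clade_multiplier = c(POST_WGD_1 = 6), seed = 42)
fam_s <- simulate_family(cfg_shift)
mat <- fam$aln$mat
mat[, 81:92] <- fam_s$aln$mat[, 81:92]     # lineage-specific motif shift
aln <- protein_alignment(apply(mat, 1, paste, collapse = ""), "demo")

out <- run_pipeline(
  list(list(aln = aln, tree = tree,
            motifs = data.frame(start = c(80L, 150L), end = c(92L, 160L)))),
  model, pipeline_config(genome_dkl = 0.014552523, test_flanks = FALSE))
out$results[, c("start", "end", "clade", "lrt", "lambda", "pvalue",
                "alpha_hat", "significant")]
```

Output:

```
  start end      clade    lrt lambda   pvalue alpha_hat significant
1    80  92 POST_WGD_1 66.915  0.413 2.39e-14     7.007        TRUE
2    80  92 POST_WGD_2  0.326  0.349 6.31e-01     1.173       FALSE
3   150 160 POST_WGD_1  0.178  0.344 7.22e-01     0.869       FALSE
4   150 160 POST_WGD_2  1.374  0.291 3.07e-01     1.412       FALSE
```

The shifted motif is recovered in the right copy (α̂ ≈ 7 against a true
multiplier of 6, p = 2.4 × 10⁻¹⁴ against the non-central null with
λ = 2 × 12 × D_KL), while the same motif in the other copy and the
untouched control motif stay quiet in both lineages.

A thin command-line front end over these functions is provided in
`inst/scripts/slimdiv.R` with subcommands `predict-motifs`,
`test-divergence`, `fdr`, `lineage-bias`, `simulate-benchmark` and
`run-all`, driven by a YAML family manifest and config.

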