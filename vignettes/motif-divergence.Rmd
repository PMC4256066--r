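---
title: "Detecting changes in constraint in short linear motifs after gene duplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting changes in constraint in short linear motifs after gene duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimdiv)
```

## The model and its assumptions

`slimdiv` asks, for a short alignment segment (a candidate short linear
motif) in a family that went through a whole-genome duplication, whether
the segment's rate of evolution changed on one post-duplication lineage.

The test is a local molecular clock likelihood-ratio test. The data are the
segment's alignment columns, assumed independent; the substitution process
is a reversible 20-state amino-acid model (WAG by default), with the
generator built as exchangeabilities times stationary frequencies and
scaled to one expected substitution per site per unit branch length. Under
the null hypothesis every branch keeps its given length; under the
alternative, the branches of the tested post-duplication clade are
multiplied by a free rate factor $\alpha$, estimated by maximum likelihood
(Brent search on $\log\alpha$ in $[10^{-6}, 10^{3}]$). The statistic is
$\mathrm{LRT} = 2(\ln L_1 - \ln L_0)$, one degree of freedom. Families
with two retained copies are tested twice, once per post-duplication
clade; gaps and `X` are missing data throughout.

Branch lengths are estimated once per family on the whole protein (via
`fit_branch_lengths()`, or supplied) and then held fixed for every segment
test: a motif of ten columns cannot identify node times, only the clade
multiplier. The whole-protein divergence estimate described next is
computed under the identical procedure, which keeps the test
self-consistent. This is a deliberate design choice; re-fitting a full
clock per segment would change the degrees of freedom story without adding
identifiable parameters at motif scale.

## Why the central chi-squared fails, and the correction

Real protein alignments violate the null model as a whole: expression-level
rate shifts after duplication, lineage-specific composition changes and
alignment errors all make the extra clade-rate parameter useful even when
the motif itself has not changed. The free parameter "fits" part of this
background heterogeneity, inflating the LRT and the false-rejection rate
of the central $\chi^2_1$ null.

If (i) most tests are truly null and (ii) the background deviation acts
uniformly across the protein's columns, the LRT converges instead to a
*non-central* chi-squared with non-centrality

$$\lambda = 2\,L\,D_{KL}(P\|Q),$$

where $L$ is the number of columns in the segment and $D_{KL}$ is the
per-column Kullback-Leibler divergence of the true background process from
the single-rate null. Because $E[\mathrm{LRT}] = k + \lambda$ under the
background process, the whole protein provides a moment-matching estimate
$\hat D_{KL} = (\mathrm{LRT}_{\text{protein}} - k) / (2 L_{\text{protein}})$.
Three practical rules complete the procedure:

* when the protein LRT does not exceed $k$ the estimate is unusable and a
  proteome-wide pooled divergence is substituted
  (`estimate_genome_dkl()`, or a configured constant);
* each motif uses the *larger* of the protein-level and proteome-wide
  divergences, choosing the larger p-value; no extra multiple-testing
  penalty is applied for this maximum since only one test per motif is
  reported;
* the df = 1 survival function is evaluated in closed form,
  $1 - F(x; 1, \lambda)
  = \Phi(\sqrt{\lambda}-\sqrt{x}) + \Phi(-\sqrt{\lambda}-\sqrt{x})$,
  which reduces to the central case at $\lambda = 0$ and makes the
  corrected p-value strictly larger than the central one whenever
  $\lambda > 0$.

For duplicate families the protein-level LRT, and hence $D_{KL}$, is
computed separately per tested clade and each motif test uses its own
clade's estimate. Whether to share one divergence per protein instead is a
genuinely open choice; per-clade is the default because the two copies'
backgrounds can differ (that is the phenomenon under study), and the
pooled fallback bounds the cost when a per-clade estimate is noisy.

Segments with no observed amino-acid differences carry no information
about rates — a clock re-fit would send every branch length to zero under
both hypotheses — so they are reported as LRT = 0, $\hat\alpha = 1$,
p = 1, and flagged. This mass of p = 1 tests motivates the FDR procedure
below.

## False-discovery-rate calling

The null proportion $\pi_0$ is estimated from the p-value density in the
window $(0.6, 0.95]$ (open below, closed above, a convention fixed so the
counting arithmetic is exact), where null p-values are expected uniform
and the p = 1 point mass cannot intrude:
$\hat\pi_0 = \#\{w_{lo} < p \le w_{hi}\} / (N\,(w_{hi}-w_{lo}))$. The FDR
at threshold $t$ is $\hat\pi_0\, t\, N / \#\{p \le t\}$ ($\hat\pi_0$
capped at 1; raw value reported), the significance threshold is the
largest observed p with FDR strictly below the target, and an empty
window (all p-values at 1, say) falls back to the conservative
$\pi_0 = 1$ rather than calling everything. No smoothing over a window
grid is attempted — one fixed window, as the procedure's heterogeneous
p = 1 mass requires.

## Motif prediction (phylo-HMM)

Candidate motifs are predicted on the pre-duplication sub-alignment only
(post-WGD rows removed, all-gap columns dropped with a recorded column
map), so that predictions are not biased by the very divergence being
tested. A two-state hidden Markov model runs over each disordered stretch:

* the background state emits a column at its local background rate — the
  ML rate scale of a 31-column window centred on the column, found by
  Newton-Raphson on the log scale (floor $10^{-4}$, bisection on the
  gradient as fallback);
* the conserved state emits an equal-weight mixture over eight
  discretized Gamma(0.6, 0.6) rate categories multiplied by the same
  local background rate. The 0.6/0.6 shape keeps most mass well below
  the background rate while tolerating a few fast columns inside a
  conserved run.

Posterior decoding at threshold 0.5 gives per-column confidence; maximal
runs above threshold become segments. Transition probabilities are not
dictated by the underlying theory; the defaults (enter-conserved 0.002,
stay-conserved 0.9) target runs of roughly 2-35 columns and are exposed in
`hmm_params()` — they are the parameters most worth revisiting on new
data. Decoded segments are trimmed while a terminal column exceeds 50%
gaps, dropped if still over 50% gaps overall (exactly 50% is kept: the
rule is strictly "over"), and dropped when longer than 35 columns — long
conserved runs are taken to be structured regions, not motifs; the filter
is applied after trimming. Each surviving motif contributes two 5-column
flanking segments as negative controls, clipped at alignment bounds and
truncated symmetrically so flanks never overlap a neighbouring motif.

## The simulator

`sim_config()`/`simulate_family()` evolve a root sequence down the family
tree with: per-site rate scales (inherited by descent), ordered/disordered
region labels selecting between two stationary-frequency regimes over
shared exchangeabilities, endpoint-conditioned substitution draws from
$e^{Qt}$ (exact for the homogeneous model — no event-by-event Gillespie
needed), Poisson indels with geometric lengths (defaults: rate 0.02 per
site per unit branch length each for insertions and deletions, mean length
2 — chosen as a realistic order of magnitude for disordered yeast
proteins; no canonical published value exists), insertions drawing
residues from the creating site's regional frequencies and inheriting its
rate and region, protected intervals that receive no indels (deletion
blocks truncate at their boundaries), and an optional clade-wide branch
multiplier. The full indel history is kept, so the true alignment and
per-column ground truth are exact.

What the simulator does *not* emulate: alignment error (benchmarks use
true alignments, isolating the statistics from aligner artifacts),
site-specific selection changes, codon-level effects, and heterotachy
beyond the injected clade shifts. Passing calibration on these benchmarks
therefore shows the statistical machinery is sound under the model's own
assumptions plus indels and composition regimes — not that real alignments
cannot add further heterogeneity; the proteome-wide fallback divergence
exists precisely for that.

## Numerical choices

* Matrix exponentials by symmetric eigendecomposition of
  $\Pi^{1/2} Q\, \Pi^{-1/2}$ (valid by reversibility); tiny negative
  entries from rounding are clipped at zero.
* Pruning is vectorized across columns with per-node rescaling, so
  likelihoods stay finite on deep trees.
* LRTs are clamped at zero (optimizer noise can leave
  $\ln L_1 < \ln L_0$ by $<10^{-6}$; the models are nested).
* Rate fits break ties toward $\alpha = 1$: if fixing the free multiplier
  at 1 loses no likelihood, 1 is reported.
* Discretized gamma categories are equal-probability bins represented by
  conditional means (computed via the shape+1 identity), so the mean rate
  is conserved exactly.
* The lineage-bias permutation test reassigns each merged event to a
  lineage with probability one half within its pair, uses
  $T=\sum_{\text{pairs}}|n_1-n_2|$ (the absolute difference makes the
  one-tailed test well-defined), and the add-one p-value convention, so
  $p \in (0, 1]$ and seeded runs are bit-reproducible.

## Validation scale

The shipped tests and the acceptance script validate at desk scale, chosen
to exercise every code path with tight statistical bounds: calibration on
250 simulated families (500 null motif tests) with a clade-wide two-fold
shift and indels; parameter recovery at 2000 columns over 20 seeds;
pruning vs exhaustive enumeration on 100 random 4-5-leaf instances;
10^6-draw Monte-Carlo checks of the closed-form survival function; and a
12-taxon tree for motif decoding, comparable in information depth to the
15-25-species pre-WGD clades of real yeast families. Genome-scale runs
(thousands of families, 20+ species) use the same code paths; only the
collection size differs.

## Limitations

The test detects changes in *rate* on a pre-specified clade; it cannot see
motifs gained after the duplication (prediction is pre-WGD only), changes
within structured regions (filtered out by design), or divergence that
leaves the substitution rate unchanged. The divergence correction assumes
the background heterogeneity acts uniformly over columns — recombination
within a gene, for instance, violates it. Disorder masks are inputs: the
package does not predict disorder, coiled-coils or low-complexity regions.
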