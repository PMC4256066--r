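# fixed 12-taxon pre-WGD-style tree: the pre-duplication clade of real
# yeast families has 15-25 species, so conserved-segment detection is
# exercised at a comparable information depth
pre_tree <- function() {
  txt <- paste0(
    "((((t11:0.356,(t2:0.267,t3:0.401):0.342):0.267,t1:0.253):0.108,",
    "((t5:0.135,t8:0.211):0.125,(t12:0.332,(t6:0.42,t10:0.203):0.242):0.282):0.186):0.376,",
    "(t9:0.216,(t4:0.19,t7:0.267):0.328):0.261):0;")
  clade_tree(ape::read.tree(text = txt))
}

# simulate a disordered protein with a slow (conserved) interior interval
conserved_family <- function(seed, L = 60, slow = c(25, 35), scale = 0.1,
                             tree = pre_tree()) {
  rates <- rep(1, L)
  rates[(slow[1] + 1):slow[2]] <- scale
  cfg <- sim_config(tree, root_length = L, site_rates = rates,
                    model_ordered = wag_model(), ins_rate = 0, del_rate = 0,
                    seed = seed)
  simulate_family(cfg)
}

test_that("pre-WGD extraction drops post taxa and maps columns bijectively", {
  ct <- eight_taxon_tree()
  fam <- shifted_family(ct, 50, 1, seed = 21)
  ex <- extract_prewgd(fam$aln, ct)
  expect_setequal(ex$sub_aln$taxa, c("a", "b", "c", "d"))
  expect_true(all(ex$sub_tree$edge_label == "PRE_WGD"))
  # no all-gap columns created here (no indels): identity map
  expect_equal(ex$map, 0:(fam$aln$ncol - 1L))

  # force a column gapped in all pre-WGD rows
  mat <- fam$aln$mat
  mat[c("a", "b", "c", "d"), 10] <- "-"
  aln2 <- protein_alignment(apply(mat, 1, paste, collapse = ""), "f")
  ex2 <- extract_prewgd(aln2, ct)
  expect_equal(ex2$sub_aln$ncol, fam$aln$ncol - 1L)
  expect_false(9L %in% ex2$map)
  # round trip: map an interval back and forth across the dropped column
  full <- map_interval_to_full(c(5, 12), ex2$map)
  expect_equal(full, c(5, 13))
})

test_that("background rates floor on invariant windows and track branch scaling", {
  tr <- pre_tree()
  m <- wag_model()
  params <- hmm_params(window = 11L)
  # invariant alignment: ML rate is the floor
  aln_inv <- protein_alignment(setNames(rep(strrep("ARNDKELSTV", 2), 12),
                                        tr$phy$tip.label))
  bg <- background_rates(aln_inv, tr, m, params)
  expect_true(all(bg <= params$rate_floor + 1e-9))

  fam <- conserved_family(9, L = 40, slow = c(0, 1), scale = 1)
  bg1 <- background_rates(fam$aln, tr, m, params)
  tr2 <- tr
  tr2$phy$edge.length <- tr2$phy$edge.length * 2
  bg2 <- background_rates(fam$aln, tr2, m, params)
  interior <- 6:34
  expect_equal(bg2[interior], bg1[interior] / 2, tolerance = 1e-3)
})

test_that("background rate recovery is unbiased on homogeneous data", {
  tr <- pre_tree()
  cfg <- sim_config(tr, root_length = 120, site_rates = 2.0,
                    model_ordered = wag_model(), ins_rate = 0, del_rate = 0,
                    seed = 4)
  fam <- simulate_family(cfg)
  bg <- background_rates(fam$aln, tr, wag_model(), hmm_params(window = 31L))
  expect_gt(median(bg), 1.7)
  expect_lt(median(bg), 2.3)
})

test_that("decoding finds planted conserved segments and respects masks", {
  tr <- pre_tree()
  m <- wag_model()
  params <- hmm_params()
  hits <- 0L
  n_rep <- 15L
  for (seed in seq_len(n_rep)) {
    fam <- conserved_family(seed * 11, L = 60, slow = c(25, 35), scale = 0.1)
    bg <- background_rates(fam$aln, tr, m, params)
    segs <- decode_motifs(fam$aln, tr, m, rbind(c(0L, 60L)), bg, params)
    covered <- 0L
    if (nrow(segs)) {
      for (i in seq_len(nrow(segs))) {
        covered <- covered + max(0, min(segs$end[i], 35) - max(segs$start[i], 25))
      }
    }
    if (covered >= 8L) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_rep))

  # same data, but the slow region is inside an ORDERED mask: never reported
  fam <- conserved_family(77, L = 60, slow = c(25, 35), scale = 0.1)
  bg <- background_rates(fam$aln, tr, m, params)
  disorder_only <- rbind(c(0L, 25L), c(35L, 60L))
  segs <- decode_motifs(fam$aln, tr, m, disorder_only, bg, params)
  if (nrow(segs)) {
    expect_true(all(segs$end <= 25 | segs$start >= 35))
  } else {
    succeed()
  }
})

test_that("homogeneous families yield no conserved segments", {
  tr <- pre_tree()
  m <- wag_model()
  params <- hmm_params()
  n_segs <- 0L
  for (seed in c(5, 6, 7)) {
    fam <- conserved_family(seed, L = 60, slow = c(0, 1), scale = 1)
    bg <- background_rates(fam$aln, tr, m, params)
    n_segs <- n_segs + nrow(decode_motifs(fam$aln, tr, m, rbind(c(0L, 60L)),
                                          bg, params))
  }
  expect_equal(n_segs, 0L)
})

test_that("gap trimming and filtering follow the 50% rules exactly", {
  # 10-row alignment, controlled per-column gap fractions
  make_aln <- function(gap_counts, L = length(gap_counts), n = 10) {
    mat <- matrix("A", n, L)
    for (j in seq_len(L)) if (gap_counts[j] > 0) mat[seq_len(gap_counts[j]), j] <- "-"
    protein_alignment(apply(mat, 1, paste, collapse = "") |>
                        setNames(paste0("t", seq_len(n))), "trim")
  }
  params <- hmm_params()
  # terminal columns 60% gaps, interior 10%: both ends trimmed, segment kept
  aln <- make_aln(c(6, 1, 1, 1, 1, 1, 6))
  seg <- data.frame(start = 0L, end = 7L, mean_posterior = 0.9)
  out <- trim_filter(seg, aln, params)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(1L, 6L))
  # 55% gaps overall: dropped
  aln2 <- make_aln(rep(c(6, 5), 5))
  expect_equal(nrow(trim_filter(data.frame(start = 0L, end = 10L,
                                           mean_posterior = 0.9),
                                aln2, params)), 0L)
  # exactly 50% gaps: kept (rule is strictly "over 50%")
  aln3 <- make_aln(rep(5L, 10))
  expect_equal(nrow(trim_filter(data.frame(start = 0L, end = 10L,
                                           mean_posterior = 0.9),
                                aln3, params)), 1L)
  # longer than the structural cutoff: dropped
  aln4 <- make_aln(rep(0L, 40))
  expect_equal(nrow(trim_filter(data.frame(start = 0L, end = 40L,
                                           mean_posterior = 0.9),
                                aln4, params)), 0L)
})

test_that("flanks are constructed, clipped and kept non-overlapping", {
  motifs <- data.frame(start = 100L, end = 110L)
  fl <- flank_intervals(motifs, ncol = 300L, width = 5L)
  expect_equal(fl$start[fl$side == "left"], 95L)
  expect_equal(fl$end[fl$side == "left"], 100L)
  expect_equal(fl$start[fl$side == "right"], 110L)
  expect_equal(fl$end[fl$side == "right"], 115L)

  # motif at the alignment start: left flank omitted
  fl0 <- flank_intervals(data.frame(start = 0L, end = 8L), ncol = 300L)
  expect_false("left" %in% fl0$side)

  # two motifs six columns apart: facing flanks truncated, no overlap
  two <- data.frame(start = c(50L, 66L), end = c(60L, 80L))
  fl2 <- flank_intervals(two, ncol = 300L, width = 5L)
  right1 <- fl2[fl2$motif_index == 1 & fl2$side == "right", ]
  left2 <- fl2[fl2$motif_index == 2 & fl2$side == "left", ]
  expect_lte(right1$end, left2$start)
  expect_lte(right1$end - right1$start, 3L)
  expect_lte(left2$end - left2$start, 3L)
})
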