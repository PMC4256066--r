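test_that("identical alignments give LRT = 0 with alpha reported as 1", {
  ct <- quartet_tree()
  m <- wag_model()
  aln <- protein_alignment(c(a = "ARNDAR", b = "ARNDAR", c = "ARNDAR",
                             d = "ARNDAR"))
  rec <- clade_lrt(aln, c(0, 6), ct, m, "POST_WGD_1")
  expect_equal(rec$lrt, 0)
  expect_equal(rec$alpha_hat, 1)
  expect_true(rec$zero_information)
  # gap-only variation is still zero information
  aln2 <- protein_alignment(c(a = "AR--", b = "ARND", c = "A-ND", d = "ARND"))
  expect_true(clade_lrt(aln2, c(0, 4), ct, m, "POST_WGD_1")$zero_information)
})

test_that("the LRT only responds to the tested clade's data", {
  ct <- duplicate_tree()
  m <- wag_model()
  fam <- shifted_family(ct, 200, 2.5, seed = 13)
  iv <- c(0, fam$aln$ncol)
  r1 <- clade_lrt(fam$aln, iv, ct, m, "POST_WGD_1")
  # relabeling the two post-WGD clades leaves the test of unchanged data intact
  swapped_spec <- list(POST_WGD_2 = c("e", "f", "g", "h"),
                       POST_WGD_1 = c("i", "j"))
  ct_sw <- clade_tree(ct$phy, swapped_spec)
  r1_sw <- clade_lrt(fam$aln, iv, ct_sw, m, "POST_WGD_2")
  expect_equal(r1$lrt, r1_sw$lrt, tolerance = 1e-6)
  expect_equal(r1$alpha_hat, r1_sw$alpha_hat, tolerance = 1e-4)
  expect_error(clade_lrt(fam$aln, iv, ct, m, "POST_WGD_9"), "absent")
})

test_that("clade_lrt recovers an injected multiplier", {
  ct <- eight_taxon_tree()
  m <- wag_model()
  fam <- shifted_family(ct, 1000, 5, seed = 3)
  rec <- clade_lrt(fam$aln, c(0, fam$aln$ncol), ct, m, "POST_WGD_1")
  expect_gt(rec$alpha_hat, 4)
  expect_lt(rec$alpha_hat, 6)
  expect_gt(rec$lrt, 10)
})

test_that("divergence estimation follows the moment-matching rule with fallback", {
  rec <- structure(list(lrt = 21, L = 500L, df = 1L), class = "lrt_record")
  kl <- estimate_dkl(rec, genome_dkl = 0.014552523)
  expect_equal(kl$dkl_protein, 0.02)
  expect_false(kl$fallback_used)

  low <- structure(list(lrt = 0.5, L = 500L, df = 1L), class = "lrt_record")
  kl2 <- estimate_dkl(low, genome_dkl = 0.014552523)
  expect_true(kl2$fallback_used)
  expect_equal(kl2$dkl_protein, 0.014552523)

  eq <- structure(list(lrt = 1, L = 500L, df = 1L), class = "lrt_record")
  expect_true(estimate_dkl(eq, 0.01)$fallback_used)
})

test_that("pooled proteome-wide divergence is additive and null-consistent", {
  one <- structure(list(lrt = 3, L = 100L), class = "lrt_record")
  expect_equal(estimate_genome_dkl(list(one)), 0.01)
  # splitting one protein's columns into two records pools identically
  a <- structure(list(lrt = 2, L = 60L), class = "lrt_record")
  b <- structure(list(lrt = 4, L = 140L), class = "lrt_record")
  whole <- structure(list(lrt = 6 - 1, L = 200L), class = "lrt_record")
  expect_equal(estimate_genome_dkl(list(a, b)),
               (2 + 4 - 2) / (2 * 200))
  expect_equal(estimate_genome_dkl(list(whole)), (5 - 1) / (2 * 200))
  expect_error(estimate_genome_dkl(list()), "at least one")

  # under the exact null the pooled estimate shrinks toward zero:
  # E[LRT] = k, so simulate central chi-squared records
  set.seed(42)
  recs <- lapply(rchisq(200, df = 1), function(x)
    structure(list(lrt = x, L = 300L), class = "lrt_record"))
  expect_lte(estimate_genome_dkl(recs), 0.005)
})

test_that("non-central chi-squared survival function obeys its contracts", {
  expect_equal(noncentral_chisq_sf(0, 0), 1)
  expect_equal(noncentral_chisq_sf(0, 7.3), 1)
  # reduces to the central chi-squared at lambda = 0
  xs <- c(0.1, 1, 3.841459, 10, 30)
  expect_equal(noncentral_chisq_sf(xs, 0),
               pchisq(xs, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(noncentral_chisq_sf(3.841459, 0), 0.05, tolerance = 1e-4)
  # monotone: decreasing in x, increasing in lambda
  lam <- 2
  p_x <- noncentral_chisq_sf(seq(0.1, 20, by = 0.5), lam)
  expect_true(all(diff(p_x) < 0))
  p_l <- noncentral_chisq_sf(5, seq(0, 20, by = 0.5))
  expect_true(all(diff(p_l) > 0))
  expect_error(noncentral_chisq_sf(-1, 0), "x must")
  expect_error(noncentral_chisq_sf(1, -2), "lam must")
})

test_that("segment p-values use the larger divergence and stay conservative", {
  seg <- structure(list(lrt = 4.2, L = 10L, df = 1L), class = "lrt_record")
  kl <- structure(list(dkl_protein = 0.05, dkl_genome = 0.0146,
                       L_protein = 300L, fallback_used = FALSE),
                  class = "kl_params")
  sp <- segment_pvalue(seg, kl)
  expect_equal(sp$lambda, 2 * 10 * 0.05)
  expect_equal(sp$dkl_used, 0.05)
  # genome divergence dominates when the protein's own estimate is smaller
  kl2 <- structure(list(dkl_protein = 0.005, dkl_genome = 0.014552523,
                        L_protein = 300L, fallback_used = FALSE),
                   class = "kl_params")
  expect_equal(segment_pvalue(seg, kl2)$dkl_used, 0.014552523)

  # corrected p exceeds the central p for any positive LRT and lambda
  for (lrt in c(0.5, 2, 6, 15)) for (lam in c(0.2, 1, 5)) {
    rec <- structure(list(lrt = lrt, L = 10L, df = 1L), class = "lrt_record")
    klx <- structure(list(dkl_protein = lam / 20, dkl_genome = 0,
                          L_protein = 100L, fallback_used = FALSE),
                     class = "kl_params")
    spx <- segment_pvalue(rec, klx)
    expect_gt(spx$pvalue, spx$pvalue_central)
  }
})
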