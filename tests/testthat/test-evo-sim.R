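test_that("zero-length branches and zero indel rates are identities", {
  ct <- quartet_tree()
  m <- wag_model()
  cfg <- sim_config(ct, root_length = 50, model_ordered = m, seed = 1)
  env <- new.env()
  env$columns <- 1:50
  env$next_id <- 51L
  env$rate_by_id <- rep(1, 50)
  env$region_by_id <- rep("DISORDERED", 50)
  state <- list(id = 1:50, aa = sample.int(20, 50, replace = TRUE),
                rate = rep(1, 50), region = rep("DISORDERED", 50),
                protected = rep(FALSE, 50))
  child <- evolve_branch(state, 0, 1, cfg, env)
  expect_identical(child$aa, state$aa)
  expect_equal(sum(attr(child, "events")), 0)

  # no indels: every leaf keeps the root length
  fam <- shifted_family(ct, 80, 1, seed = 2)
  expect_true(all(nchar(fam$leaf_seqs) == 80L))
  expect_equal(fam$aln$ncol, 80L)
  expect_true(all(fam$aln$mat != "-"))
})

test_that("protected intervals receive no indels and stay gap-free", {
  ct <- eight_taxon_tree()
  m <- wag_model()
  for (seed in 1:5) {
    cfg <- sim_config(ct, root_length = 120, model_ordered = m,
                      ins_rate = 0.08, del_rate = 0.08,
                      protected = rbind(c(50L, 60L)), seed = seed)
    fam <- simulate_family(cfg)
    expect_equal(nrow(fam$protected), 1L)
    cols <- (fam$protected[1, 1] + 1L):fam$protected[1, 2]
    expect_equal(length(cols), 10L)
    expect_true(all(fam$aln$mat[, cols] != "-"))
    # protected block survives as contiguous original sites
    expect_true(all(diff(cols) == 1L))
  }
})

test_that("simulation is deterministic given the seed", {
  ct <- eight_taxon_tree()
  cfg <- sim_config(ct, root_length = 100, model_ordered = wag_model(),
                    ins_rate = 0.05, del_rate = 0.05,
                    clade_multiplier = c(POST_WGD_1 = 2), seed = 33)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(cfg)
  expect_identical(f1$aln$mat, f2$aln$mat)
  expect_identical(f1$col_rates, f2$col_rates)
  cols <- make_null_benchmark(3, cfg, seed = 9)
  cols2 <- make_null_benchmark(3, cfg, seed = 9)
  expect_identical(lapply(cols, `[[`, "leaf_seqs"),
                   lapply(cols2, `[[`, "leaf_seqs"))
})

test_that("long branches converge to the stationary composition", {
  # one long branch from a disordered-only template
  phy <- ape::read.tree(text = "(a:50,b:50):0;")
  ct <- clade_tree(phy)
  m <- wag_model()
  cfg <- sim_config(ct, root_length = 10000, model_ordered = m,
                    ins_rate = 0, del_rate = 0, seed = 17)
  fam <- simulate_family(cfg)
  counts <- table(factor(strsplit(fam$leaf_seqs[["a"]], "")[[1]],
                         levels = slimdiv:::AA_ALPHABET))
  gof <- chisq.test(as.numeric(counts), p = m$pi)
  expect_gt(gof$p.value, 0.01)
})

test_that("insertions inherit rate and region from the creating site", {
  ct <- quartet_tree()
  m <- wag_model()
  rates <- c(rep(0.25, 30), rep(4, 30))
  regions <- c(rep("ORDERED", 30), rep("DISORDERED", 30))
  cfg <- sim_config(ct, root_length = 60, site_rates = rates,
                    regions = regions, model_ordered = m,
                    model_disordered = set_frequencies(m, rep(0.05, 20)),
                    ins_rate = 0.6, del_rate = 0, seed = 23)
  fam <- simulate_family(cfg)
  expect_gt(fam$aln$ncol, 60L)  # insertions happened
  inserted <- setdiff(seq_len(fam$aln$ncol),
                      which(seq_len(fam$aln$ncol) %in% seq_len(60)))
  # inherited labels must come from the original palette
  expect_true(all(fam$col_rates %in% c(0.25, 4)))
  expect_true(all(fam$col_regions %in% c("ORDERED", "DISORDERED")))
  # rate/region pairs stay linked as at creation
  expect_true(all((fam$col_rates == 0.25) == (fam$col_regions == "ORDERED")))
})

test_that("substitution counts scale with the injected clade multiplier", {
  ct <- eight_taxon_tree()
  ident <- function(fam) {
    post <- c("e", "f", "g", "h")
    pre <- c("a", "b", "c", "d")
    mean_ident <- function(x, y)
      mean(fam$aln$mat[x, ] == fam$aln$mat[y, ])
    c(post = mean_ident(post[1], post[2]), pre = mean_ident(pre[1], pre[2]))
  }
  id_null <- ident(shifted_family(ct, 500, 1, seed = 41))
  id_fast <- ident(shifted_family(ct, 500, 5, seed = 41))
  # the shifted clade diverges more; the pre clade is unaffected
  expect_lt(id_fast[["post"]], id_null[["post"]] - 0.1)
  expect_equal(id_fast[["pre"]], id_null[["pre"]], tolerance = 0.05)
})

test_that("simulated families write to disk with their ground truth", {
  skip_if_not_installed("jsonlite")
  ct <- quartet_tree()
  fam <- shifted_family(ct, 40, 1, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_simulated_family(fam, dir)
  expect_true(all(file.exists(paths)))
  back <- read_alignment(paths[2], family_id = fam$aln$family_id)
  expect_identical(back$mat, fam$aln$mat)
  truth <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_equal(truth$seed, fam$seed)
  expect_equal(truth$col_rates, fam$col_rates)
})
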