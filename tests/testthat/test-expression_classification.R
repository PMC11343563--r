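test_that("the adaptive threshold lands between the expression modes", {
  set.seed(50)
  vals <- c(pmax(rnorm(500, 0.5, 0.3), 0.01), rnorm(500, 8, 1))
  th <- dafs_threshold(vals)
  expect_false(th$fallback)
  expect_gt(th$threshold, 2); expect_lt(th$threshold, 6)
  expect_gt(th$threshold, th$low_mean); expect_lt(th$threshold, th$high_mean)

  # location equivariance: shifting all values shifts the threshold
  th2 <- dafs_threshold(vals + 1)
  expect_equal(th2$threshold, th$threshold + 1, tolerance = 0.15)

  # degenerate single-mode sample falls back to the quantile, flagged
  uni <- rnorm(500, 5, 0.5)
  expect_warning(thf <- dafs_threshold(uni), "fallback")
  expect_true(thf$fallback)
  expect_equal(thf$threshold, unname(quantile(uni[uni > 0], 0.15)), tolerance = 1e-9)

  expect_error(dafs_threshold(rnorm(50)), "100 genes")
  expect_error(dafs_threshold(c(rep(0, 495), rnorm(5, 8))), "nonzero")
})

test_that("morph-specific calls reproduce the replicate-count rule", {
  # 4/5 PP flagged at swimming, LL never: P-specific
  design <- make_design(n_reps = 5)
  flags <- matrix(FALSE, 3, nrow(design), dimnames = list(paste0("g", 1:3), design$sample_id))
  on <- design$sample_id[design$genotype == "PP" & design$stage == "swimming"][1:4]
  flags["g1", on] <- TRUE
  # g2: LL >= 3 at gastrula, PP flagged once anywhere
  flags["g2", design$sample_id[design$genotype == "LL" & design$stage == "gastrula"][1:3]] <- TRUE
  flags["g2", design$sample_id[design$genotype == "PP"][1]] <- TRUE
  # g3: PP >= 3 at a stage but LL flagged twice: neither
  flags["g3", design$sample_id[design$genotype == "PP" & design$stage == "blastula"][1:5]] <- TRUE
  flags["g3", design$sample_id[design$genotype == "LL"][c(1, 9)]] <- TRUE
  ms <- classify_morph_specific(flags, design)
  expect_identical(ms$label, c("P-specific", "L-specific", "neither"))
})

test_that("stages with few replicates scale the on-criterion", {
  design <- make_design(n_reps = 2)
  flags <- matrix(FALSE, 1, nrow(design), dimnames = list("g1", design$sample_id))
  flags["g1", design$sample_id[design$genotype == "PP" & design$stage == "gastrula"]] <- TRUE
  ms <- suppressMessages(classify_morph_specific(flags, design))
  expect_identical(ms$label, "P-specific")  # 2/2 >= ceil(0.6*2)
})

test_that("profile correlation is Pearson on the raw stage means", {
  expect_equal(profile_correlation(1:6, 1:6), 1)
  expect_equal(profile_correlation(1:6, 2 * (1:6)), 1)      # affine invariance
  expect_equal(profile_correlation(1:6, 7 - (1:6)), -1)
  expect_true(is.na(profile_correlation(rep(1, 6), 1:6)))
  set.seed(51)
  for (i in 1:100) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(profile_correlation(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
})

test_that("gene classification follows the documented precedence", {
  genes <- paste0("g", 1:6)
  sig <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  de <- list(blastula = data.frame(gene_id = genes, significant = sig))
  asg <- function(cl) data.frame(gene_id = genes, cluster = cl)
  r <- setNames(c(0.99, 0.5, 0.9, 0.3, 0.2, 0.1), genes)
  ms <- data.frame(gene_id = genes,
                   label = c(rep("neither", 5), "P-specific"))
  cls <- classify_genes(genes, de,
                        assign_P = asg(c(1, 1, 1, 1, NA, 2)),
                        assign_L = asg(c(1, 2, 2, 2, NA, 5)),
                        r = r, ms = ms)
  # g1: DE, same cluster -> heteromorphic
  expect_identical(cls$category[1], "heteromorphic")
  # g2: DE, cluster switch, r = 0.5 -> heterochronic
  expect_identical(cls$category[2], "heterochronic")
  # g3: cluster switch but r = 0.9 -> NOT heterochronic
  expect_identical(cls$category[3], "heteromorphic")
  # g4: cluster switch, low r, but no DE -> conserved
  expect_identical(cls$category[4], "conserved")
  # g5: unclustered without label or filter record -> unclassifiable
  expect_identical(cls$category[5], "unclassifiable")
  # g6: morph-specific label wins over everything
  expect_identical(cls$category[6], "P-specific")
  expect_true(is.na(cls$cluster_P[6]) && is.na(cls$cluster_L[6]))

  # unclusterable genes fall back to heteromorphic-if-DE, flagged
  cls2 <- classify_genes(genes[5], de, asg(NA), asg(NA), r, ms,
                         unclusterable = "g5")
  expect_identical(cls2$category, "heteromorphic")
  expect_identical(cls2$flag, "unclusterable")

  # morph-specific can be made conditional on DE
  ms4 <- data.frame(gene_id = "g4", label = "L-specific")
  c_req <- classify_genes("g4", de, asg(1)[4, ], asg(2)[4, ], r, ms4,
                          require_de_for_morph_specific = TRUE)
  expect_identical(c_req$category, "conserved")
  c_free <- classify_genes("g4", de, asg(1)[4, ], asg(2)[4, ], r, ms4,
                           require_de_for_morph_specific = FALSE)
  expect_identical(c_free$category, "L-specific")
})

test_that("identical expression in both morphs is never heterochronic or morph-specific", {
  for (seed in 1:3) {
    set.seed(seed)
    design <- make_design(n_reps = 4)
    base <- matrix(rnbinom(120 * 24, size = 20, mu = exp(runif(120, 2, 7))),
                   120, 24)
    m <- cbind(base, base)  # LL columns copy PP columns exactly
    dimnames(m) <- list(sprintf("g%03d", 1:120), design$sample_id)
    norm <- normalize_counts(m)
    samples <- read_sample_table(design)
    disp <- estimate_dispersion(norm, interaction(samples$genotype, samples$stage))
    de <- de_by_stage(norm, disp, samples, "LL", "PP")
    prof_P <- stage_profiles(norm, samples, "PP")
    prof_L <- stage_profiles(norm, samples, "LL")
    std_P <- filter_and_standardize(prof_P)
    std_L <- filter_and_standardize(prof_L)
    fit <- fit_fcm(std_P, k = 3, m = 1.8, seed = seed)
    aP <- map_memberships(fit, std_P)
    aL <- map_memberships(fit, std_L)
    r <- sapply(rownames(prof_P), function(g)
      profile_correlation(prof_P[g, ], prof_L[g, ]))
    ef <- expression_flags(norm, samples)
    ms <- classify_morph_specific(ef$flags, samples)
    cls <- classify_genes(rownames(m), de$results, aP, aL, r, ms,
                          unclusterable = union(attr(std_P, "unclusterable"),
                                                attr(std_L, "unclusterable")))
    expect_false(any(cls$category %in%
                       c("heterochronic", "P-specific", "L-specific")))
  }
})

test_that("heterochrony direction orders shifts and flags extremes", {
  ord <- c(1L, 2L, 3L, 4L)  # clusters already early-to-late
  hd <- heterochrony_direction(c(1, 4, 2), c(4, 1, 3), ord)
  expect_identical(hd$direction, c("earlier-in-P", "earlier-in-L", "earlier-in-P"))
  expect_identical(hd$extreme, c(TRUE, TRUE, FALSE))
  # antisymmetry
  hd2 <- heterochrony_direction(c(4, 1, 3), c(1, 4, 2), ord)
  expect_identical(hd2$direction, c("earlier-in-L", "earlier-in-P", "earlier-in-L"))
})
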