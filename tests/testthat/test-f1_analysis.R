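# shared F1 fixture: allele counts with known allelic ratios
make_f1_fixture <- function(n_genes = 150, total = 200, log2_ratio = 2,
                            n_samples = 5, seed = 60, stage = "gastrula") {
  set.seed(seed)
  sids <- sprintf("PL_%s_r%d", stage, seq_len(n_samples))
  samples <- read_sample_table(data.frame(
    sample_id = sids, genotype = "PL", stage = stage,
    replicate = seq_len(n_samples)))
  pr <- 2^log2_ratio / (1 + 2^log2_ratio)
  rows <- list()
  for (s in sids) {
    tot <- rpois(n_genes, total)
    p <- rbinom(n_genes, tot, pr)
    rows[[s]] <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                            sample_id = s, p_count = p, l_count = tot - p)
  }
  list(ac = do.call(rbind, rows), samples = samples)
}

test_that("allelic DE finds imbalance and stays quiet on 50:50 splits", {
  bal <- make_f1_fixture(log2_ratio = 0, seed = 61)
  b <- allelic_de(bal$ac, bal$samples, "gastrula")
  expect_lt(mean(b$significant), 0.05)
  expect_lt(median(abs(b$log2_ratio)), 0.15)

  imb <- make_f1_fixture(log2_ratio = 2, seed = 62)
  a <- allelic_de(imb$ac, imb$samples, "gastrula")
  expect_gte(mean(a$significant & a$log2_ratio > 1.5 & a$log2_ratio < 2.5), 0.95)

  # below the assignable minimum: not testable, excluded from FDR
  low <- imb
  low$ac$p_count[low$ac$gene_id == "g001"] <- 0
  low$ac$l_count[low$ac$gene_id == "g001"] <- 1
  al <- allelic_de(low$ac, low$samples, "gastrula", min_assignable = 10)
  expect_false(al$testable[al$gene_id == "g001"])
  expect_true(is.na(al$q_value[al$gene_id == "g001"]))

  # a single F1 sample is not a paired design
  one <- imb
  one$ac <- one$ac[one$ac$sample_id == one$samples$sample_id[1], ]
  expect_error(allelic_de(one$ac, one$samples, "gastrula"), ">=2")
})

test_that("the interaction test compares parental and allelic ratios", {
  # equal ratios (pure cis): H0 true, mostly non-significant
  pseudo_par <- function(lr, se, genes) {
    data.frame(gene_id = genes, log_ratio = lr, se = se,
               q_value = 0.001, stringsAsFactors = FALSE)
  }
  imb <- make_f1_fixture(log2_ratio = 2, seed = 63)
  al <- allelic_de(imb$ac, imb$samples, "gastrula")
  par_same <- pseudo_par(2 * log(2), 0.08, al$gene_id)
  it_same <- interaction_test(par_same, al)
  expect_lt(mean(it_same$significant), 0.05)

  # parental ratio 2 log2, allelic 0: strongly significant
  bal <- make_f1_fixture(log2_ratio = 0, seed = 64)
  al0 <- allelic_de(bal$ac, bal$samples, "gastrula")
  it_diff <- interaction_test(pseudo_par(2 * log(2), 0.08, al0$gene_id), al0)
  expect_gte(mean(it_diff$significant), 0.95)

  # exploding SE drives the statistic to zero
  it_wide <- interaction_test(pseudo_par(2 * log(2), 1e6, al0$gene_id), al0)
  expect_false(any(it_wide$significant))
})

test_that("the regulatory truth table maps every pattern to exactly one mode", {
  expect_identical(regulatory_mode(TRUE, TRUE, FALSE, 2, 2), "cis")
  expect_identical(regulatory_mode(TRUE, FALSE, TRUE, 2, 0), "trans")
  expect_identical(regulatory_mode(FALSE, TRUE, TRUE, 0, 2), "compensatory")
  expect_identical(regulatory_mode(TRUE, TRUE, TRUE, 2, 1), "cis+trans")
  expect_identical(regulatory_mode(TRUE, TRUE, TRUE, 2, -1), "cisxtrans")
  expect_identical(regulatory_mode(FALSE, FALSE, FALSE, 0.1, 0.1), "conserved")
  expect_identical(regulatory_mode(NA, TRUE, TRUE, 1, 1), "ambiguous")
  # exhaustive: every flag/sign pattern yields exactly one of the seven labels
  grid <- expand.grid(A = c(TRUE, FALSE), B = c(TRUE, FALSE), C = c(TRUE, FALSE),
                      s = c(1, -1))
  modes <- regulatory_mode(grid$A, grid$B, grid$C, rep(1, nrow(grid)), grid$s)
  expect_true(all(modes %in% c("cis", "trans", "cis+trans", "cisxtrans",
                               "compensatory", "conserved", "ambiguous")))
  expect_identical(length(modes), nrow(grid))
})

test_that("inheritance modes follow the parental-interval geometry", {
  set.seed(65)
  design <- rbind(make_design(n_reps = 5),
                  make_design(n_reps = 5, genotypes = "PL"))
  mu_fun <- function(genes, genotype, stage) {
    base <- c(additive = NA, pdom = NA, ldom = NA, over = NA, cons = NA)
    mu <- switch(genotype,
                 PP = c(400, 400, 400, 100, 200),
                 LL = c(80, 80, 80, 20, 200),
                 PL = c(240, 400, 80, 1600, 200))
    rep(mu, length.out = length(genes))
  }
  m <- nb_counts_from_means(mu_fun, design, dispersion = 0.03, n_genes = 5, seed = 66)
  rownames(m) <- c("additive", "pdom", "ldom", "over", "cons")
  norm <- normalize_counts(m, sf = rep(1, ncol(m)))
  samples <- read_sample_table(design)
  disp <- estimate_dispersion(norm, interaction(samples$genotype, samples$stage))
  inh <- inheritance_mode(norm, disp, samples, "gastrula")
  expect_identical(inh$mode[match(c("additive", "pdom", "ldom", "over", "cons"),
                                  inh$gene_id)],
                   c("additive", "P-dominant", "L-dominant", "overdominant",
                     "conserved"))
  # excluded reciprocal-DE genes carry the reason, not a mode
  inh2 <- inheritance_mode(norm, disp, samples, "gastrula", excluded = "additive")
  expect_true(is.na(inh2$mode[inh2$gene_id == "additive"]))
  expect_identical(inh2$reason[inh2$gene_id == "additive"], "reciprocal-DE")
})

test_that("parent-of-origin effects are detected early with direction labels", {
  # 40 of 120 genes carry reciprocal offsets (20 on a conserved background,
  # 20 on a heteromorphic one); the conserved majority anchors normalization
  ds <- simulate_experiment(sim_config(
    n_conserved = 20, n_heteromorphic = 100, n_heterochronic = 0,
    n_p_specific = 0, n_l_specific = 0, parental_effect_genes = 40, seed = 67))
  norm <- normalize_counts(ds$counts)
  samples <- read_sample_table(ds$samples)
  disp <- estimate_dispersion(norm, interaction(samples$genotype, samples$stage))
  de <- suppressMessages(de_by_stage(norm, disp, samples, "LL", "PP"))
  pe <- parental_effect_test(norm, disp, samples, parental_de = de$results)
  truth_pe <- ds$truth$gene_id[ds$truth$parental_effect]
  hits16 <- pe$effects$gene_id[pe$effects$stage == "16-cell"]
  expect_gte(length(intersect(hits16, truth_pe)) / length(truth_pe), 0.9)
  # decayed by gastrula and swimming
  expect_lte(sum(pe$effects$stage != "16-cell"), 2)
  # direction: overlay genes on heteromorphic background match the mother
  dir <- pe$effects[pe$effects$stage == "16-cell", ]
  het_pe <- intersect(truth_pe,
                      ds$truth$gene_id[ds$truth$divergence_category == "heteromorphic"])
  lab <- dir$direction[dir$gene_id %in% het_pe]
  expect_true(all(lab == "maternal-matching"))
  # conserved-background genes cannot be assigned a direction
  con_pe <- intersect(truth_pe,
                      ds$truth$gene_id[ds$truth$divergence_category == "conserved"])
  expect_true(all(dir$direction[dir$gene_id %in% con_pe] == "unassigned"))
})

test_that("modal calls collapse stage-wise assignments sensibly", {
  calls <- data.frame(
    gene_id = c("a", "a", "a", "b", "b", "c"),
    mode = c("cis", "cis", "trans", "ambiguous", "trans", "ambiguous"))
  mc <- modal_call(calls)
  expect_identical(mc$mode[mc$gene_id == "a"], "cis")
  expect_identical(mc$mode[mc$gene_id == "b"], "trans")
  expect_identical(mc$mode[mc$gene_id == "c"], "ambiguous")
})
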