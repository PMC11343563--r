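test_that("stage profiles are replicate means of log2 normalized expression", {
  ds <- small_sim(seed = 14)
  norm <- normalize_counts(ds$counts)
  samples <- read_sample_table(ds$samples)
  prof <- stage_profiles(norm, samples, "PP")
  # direct oracle for a handful of genes/stages
  lg <- log2(norm$values + 1)
  for (st in c("16-cell", "swimming")) {
    j <- samples$sample_id[samples$genotype == "PP" & samples$stage == st]
    expect_equal(prof[, st], rowMeans(lg[, j]), tolerance = 1e-12)
  }
  # single replicate: profile equals that replicate's log values
  one <- samples[samples$genotype == "PP" & samples$replicate == 1, ]
  keep <- c(one$sample_id, samples$sample_id[samples$genotype != "PP"])
  p1 <- stage_profiles(normalize_counts(ds$counts[, keep], norm$size_factors[keep]),
                       samples[samples$sample_id %in% keep, ], "PP")
  expect_equal(unname(p1[5, ]), unname(lg[5, one$sample_id[order(one$stage)]]),
               tolerance = 1e-12)
  # constant gene gives a flat row
  cm <- make_counts(120, nrow(samples), values = 50)
  colnames(cm) <- samples$sample_id
  pc <- stage_profiles(normalize_counts(cm, rep(1, ncol(cm))), samples, "PP")
  expect_true(all(abs(pc - pc[, 1]) < 1e-12))
})

test_that("filtering removes flat rows and standardization is exact", {
  x <- rbind(flat = rep(2, 6), ramp = 1:6, bump = c(1, 4, 9, 4, 1, 1))
  colnames(x) <- STAGES
  std <- filter_and_standardize(x, min_sd = 0.1)
  expect_identical(attr(std, "unclusterable"), "flat")
  expect_equal(unname(rowMeans(std)), rep(0, 2), tolerance = 1e-9)
  expect_equal(unname(apply(std, 1, sd)), rep(1, 2), tolerance = 1e-9)
  expect_equal(unname(std["ramp", ]), ((1:6) - 3.5) / sd(1:6), tolerance = 1e-12)
  expect_error(filter_and_standardize(x[1, , drop = FALSE], 0.1), "all profiles")
})

test_that("the fuzzifier estimate is in range and decreases with data size", {
  ms <- sapply(c(100, 1000, 10000, 1e6), function(n) {
    estimate_fuzzifier(matrix(0, n, 6))
  })
  expect_true(all(ms > 1 & ms < 3))
  expect_true(all(diff(ms) < 0))
  expect_error(estimate_fuzzifier(matrix(0, 100, 1)), "dimensions")
  expect_error(estimate_fuzzifier(matrix(0, 5, 6)), "10 profiles")
})

test_that("fcm separates well-separated groups and is seed-deterministic", {
  set.seed(40)
  a <- matrix(rnorm(25 * 6, 0, 0.1), 25, 6) + rep(c(1, 1, -1, -1, -1, 1), each = 25)
  b <- matrix(rnorm(25 * 6, 0, 0.1), 25, 6) + rep(c(-1, -1, 1, 1, 1, -1), each = 25)
  x <- rbind(a, b)
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  dimnames(x) <- list(paste0("g", 1:50), STAGES)
  fit <- fit_fcm(x, k = 2, m = 1.7, seed = 1)
  own <- apply(fit$memberships, 1, max)
  expect_true(all(own > 0.9))
  grp <- apply(fit$memberships, 1, which.max)
  expect_identical(length(unique(grp[1:25])), 1L)
  expect_identical(length(unique(grp[26:50])), 1L)
  expect_true(grp[1] != grp[26])
  # membership rows sum to one
  expect_equal(unname(rowSums(fit$memberships)), rep(1, 50), tolerance = 1e-9)
  # determinism
  fit2 <- fit_fcm(x, k = 2, m = 1.7, seed = 1)
  expect_identical(fit$centroids, fit2$centroids)

  # hard-clustering limit as m -> 1
  hard <- fit_fcm(x, k = 2, m = 1.05, seed = 1)
  expect_true(all(apply(hard$memberships, 1, max) > 0.999))

  # duplicated rows receive identical memberships
  xx <- rbind(x, x[1, , drop = FALSE])
  rownames(xx)[51] <- "dup"
  fd <- fit_fcm(xx, k = 2, m = 1.7, seed = 2)
  expect_equal(unname(fd$memberships["g1", ]), unname(fd$memberships["dup", ]),
               tolerance = 1e-9)
})

test_that("converged fcm satisfies the fixed-point equations and matches the oracle", {
  set.seed(41)
  x <- rbind(matrix(rnorm(60, 2), 10, 6), matrix(rnorm(60, -2), 10, 6))
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  dimnames(x) <- list(paste0("g", 1:20), STAGES)
  fit <- fit_fcm(x, k = 2, m = 1.6, seed = 3, tol = 1e-14)
  # centroids are membership^m weighted means of the data
  um <- fit$memberships^fit$m
  expect_equal(unname((t(um) %*% x) / colSums(um)), unname(fit$centroids),
               tolerance = 1e-7)
  # independent plain-loop AO from the same converged centers stays put
  orc <- oracle_fcm(x, fit$centroids, m = 1.6)
  expect_equal(unname(orc$centers), unname(fit$centroids), tolerance = 1e-8)
  expect_equal(orc$objective, fit$objective, tolerance = 1e-8)
})

test_that("cluster-number selection stops before correlated centroids", {
  set.seed(43)
  shapes <- rbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 1, 0, 0), c(0, 0, 0, 0, 1, 1))
  x <- shapes[rep(1:3, each = 40), ] + matrix(rnorm(720, 0, 0.05), 120, 6)
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  dimnames(x) <- list(paste0("g", 1:120), STAGES)
  sel <- select_cluster_number(x, m = 1.7, r_max = 0.85, k_range = 2:6, seed = 1)
  expect_identical(sel$k, 3L)
  expect_true(all(sel$max_r[as.character(2:3)] < 0.85))
  expect_gte(sel$max_r[["4"]], 0.85)
  # vacuous ceiling returns the top of the range
  sel2 <- select_cluster_number(x, m = 1.7, r_max = 1, k_range = 2:4, seed = 1)
  expect_identical(sel2$k, 4L)
})

test_that("membership mapping onto fixed centroids behaves like the model", {
  set.seed(44)
  x <- rbind(matrix(rnorm(120, 2, 0.3), 20, 6), matrix(rnorm(120, -2, 0.3), 20, 6))
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  dimnames(x) <- list(paste0("g", 1:40), STAGES)
  fit <- fit_fcm(x, k = 2, m = 1.7, seed = 5)
  # a profile equal to a centroid maps there with membership ~1
  probe <- fit$centroids
  rownames(probe) <- c("c1", "c2")
  mm <- map_memberships(fit, probe)
  expect_identical(mm$cluster, 1:2)
  expect_true(all(mm$max_membership > 0.999))
  # self-consistency: mapping the training data reproduces the fit assignment
  back <- map_memberships(fit, x)
  conf <- apply(fit$memberships, 1, max) > 0.5
  expect_identical(back$cluster[conf], unname(apply(fit$memberships, 1, which.max))[conf])
  # equidistant profile: uniform memberships, tie to lowest index, flagged
  mid <- matrix((fit$centroids[1, ] + fit$centroids[2, ]) / 2, 1,
                dimnames = list("mid", STAGES))
  tie <- map_memberships(fit, mid)
  expect_identical(tie$cluster, 1L)
  expect_true(tie$tie)
  expect_equal(tie$max_membership, 0.5, tolerance = 1e-9)
  # gene-order invariance
  perm <- sample(nrow(x))
  mp <- map_memberships(fit, x[perm, ])
  expect_identical(mp$cluster, back$cluster[perm])
  # stage mismatch is an error
  x2 <- x; colnames(x2) <- rev(STAGES)
  expect_error(map_memberships(fit, x2), "stage")
})

test_that("fcm agrees with the e1071 reference implementation at a fixed point", {
  skip_if_not_installed("e1071")
  set.seed(46)
  for (i in 1:5) {
    x <- rbind(matrix(rnorm(60, 1.5), 10, 6), matrix(rnorm(60, -1.5), 10, 6))
    x <- (x - rowMeans(x)) / apply(x, 1, sd)
    dimnames(x) <- list(paste0("g", 1:20), STAGES)
    fit <- fit_fcm(x, k = 2, m = 1.7, seed = i, tol = 1e-14)
    ref <- e1071::cmeans(x, centers = fit$centroids, m = 1.7, iter.max = 500)
    # same fixed point: match clusters by nearest centroid
    d <- as.matrix(dist(rbind(fit$centroids, ref$centers)))[1:2, 3:4]
    perm <- unname(apply(d, 1, which.min))
    expect_identical(sort(perm), 1:2)
    expect_equal(unname(ref$centers[perm, ]), unname(fit$centroids),
                 tolerance = 1e-5)
  }
})

test_that("cluster ordering runs early to late along the centroid peaks", {
  cent <- rbind(c(2, 1, 0, -1, -1, -1), c(-1, -1, 2, 1, 0, -1), c(-1, -1, -1, 0, 1, 2))
  model <- structure(list(k = 3, m = 1.7, centroids = cent[c(2, 3, 1), ],
                          stage_order = STAGES), class = "fcm")
  expect_identical(cluster_stage_order(model), c(2L, 3L, 1L))
})

test_that("cluster models round-trip through JSON", {
  set.seed(47)
  x <- matrix(rnorm(180), 30, 6, dimnames = list(paste0("g", 1:30), STAGES))
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  fit <- fit_fcm(x, k = 3, m = 1.8, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(fit, path)
  back <- read_cluster_model(path)
  expect_equal(back$centroids, fit$centroids, tolerance = 1e-12)
  expect_identical(back$k, fit$k)
  expect_equal(back$m, fit$m)
  expect_identical(back$stage_order, STAGES)
})
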