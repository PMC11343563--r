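# Synthetic developmental RNA-seq experiments with known per-gene ground
# truth: parental morphs (PP, LL), reciprocal F1s (PL, LP), allele-resolved
# F1 counts, and a truth table covering divergence category, generating
# profile shapes, regulatory mode, inheritance mode and parent-of-origin
# effects. Counts are negative-binomial with per-sample library-size factors.

#' Canonical stage-profile shapes
#'
#' Six relative expression profiles over the six stages: Gaussian bumps
#' peaking at each stage (width `sigma` stages), floored at `floor_frac` of
#' the peak. The stage-1 bump is a monotone maternal-decay shape and the
#' stage-6 bump a monotone post-gastrula rise. All pairwise correlations of
#' the log-scale shapes stay below 0.85, so any two shapes at least two
#' apart form a valid heterochronic pair.
#'
#' @param sigma Bump width in stages (default 0.8).
#' @param floor_frac Baseline floor as a fraction of peak (default 0.05).
#' @return 6 x 6 matrix (shape x stage), rows scaled to max 1.
#' @export
profile_shapes <- function(sigma = 0.8, floor_frac = 0.05) {
  sh <- t(sapply(seq_along(STAGES), function(k) {
    v <- exp(-((seq_along(STAGES) - k)^2) / (2 * sigma^2))
    floor_frac + (1 - floor_frac) * v / max(v)
  }))
  dimnames(sh) <- list(paste0("shape", seq_along(STAGES)), STAGES)
  sh
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic experiment. Defaults define the
#' package's reference benchmark: 600 genes (150 conserved, 150
#' heteromorphic, 150 heterochronic, 75 P-specific, 75 L-specific), five
#' replicates per genotype x stage, effect size 2 log2 units, global NB
#' dispersion 0.05, LP samples only at 16-cell/gastrula/swimming.
#'
#' @param n_conserved,n_heteromorphic,n_heterochronic,n_p_specific,n_l_specific
#'   Gene counts per divergence category.
#' @param n_replicates Replicates per genotype x stage (>= 2).
#' @param nb_dispersion Global NB dispersion alpha (> 0); variance is
#'   `mu + alpha * mu^2`.
#' @param lfc_effect Effect size in log2 units for heteromorphy, parental
#'   divergence and misexpression (default 2, i.e. fourfold).
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   per-gene baseline mean count (natural-log scale).
#' @param lib_size_log_sd Log-normal sd of per-sample library-size factors.
#' @param off_mean Ambient NB mean for the "off" morph of morph-specific
#'   genes (not a structural zero, so thresholding is exercised).
#' @param shapes Shape matrix (see [profile_shapes()]).
#' @param heterochrony_shift Integer vector mapping source shape index to
#'   target shape index for heterochronic genes.
#' @param regulatory_mix Proportions over cis, trans, cis+trans, cisxtrans
#'   (assigned to heteromorphic genes) and compensatory, conserved (assigned
#'   to conserved-divergence genes); each subset is renormalized.
#' @param inheritance_mix Proportions over additive, P-dominant, L-dominant,
#'   overdominant, underdominant for heteromorphic genes.
#' @param assignable_fraction Fraction of F1 reads carrying informative SNPs.
#' @param parental_effect_genes Number of genes with early-stage reciprocal
#'   (PL vs LP) offsets.
#' @param parental_effect_offset Reciprocal offset in log2 units.
#' @param parental_effect_stages Affected stages (subset of 16-cell, blastula).
#' @param lp_stages Stages with LP samples (study design default: 16-cell,
#'   gastrula, swimming).
#' @param r_max Shape-correlation ceiling for heterochronic pairs.
#' @param enforce_shape_divergence Reject heterochronic shape pairs with
#'   log-scale correlation >= r_max (default TRUE).
#' @param seed Integer seed; identical configs give identical datasets.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_conserved = 150, n_heteromorphic = 150,
                       n_heterochronic = 150, n_p_specific = 75,
                       n_l_specific = 75, n_replicates = 5,
                       nb_dispersion = 0.05, lfc_effect = 2,
                       baseline_log_mean = log(300), baseline_log_sd = 0.8,
                       lib_size_log_sd = 0.15, off_mean = 0.5,
                       shapes = profile_shapes(),
                       heterochrony_shift = c(3L, 4L, 5L, 6L, 1L, 2L),
                       regulatory_mix = c(cis = 0.15, trans = 0.35,
                                          `cis+trans` = 0.1, cisxtrans = 0.1,
                                          compensatory = 0.1, conserved = 0.2),
                       inheritance_mix = c(additive = 0.4, `P-dominant` = 0.2,
                                           `L-dominant` = 0.2,
                                           overdominant = 0.1, underdominant = 0.1),
                       assignable_fraction = 0.3,
                       parental_effect_genes = 50, parental_effect_offset = 2,
                       parental_effect_stages = c("16-cell", "blastula"),
                       lp_stages = c("16-cell", "gastrula", "swimming"),
                       r_max = 0.85, enforce_shape_divergence = TRUE,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(nb_dispersion > 0, n_replicates >= 2, lfc_effect > 0,
            assignable_fraction >= 0, assignable_fraction <= 1,
            all(regulatory_mix >= 0), all(inheritance_mix >= 0),
            all(parental_effect_stages %in% c("16-cell", "blastula")))
  counts <- c(n_conserved, n_heteromorphic, n_heterochronic, n_p_specific, n_l_specific)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  structure(cfg, class = "sim_config")
}

#' F1 regulatory/inheritance benchmark configuration
#'
#' Study conditions for benchmarking the allele-specific analyses: 750 genes
#' with a realistic mostly-conserved composition (450 conserved-expression
#' genes, of which 100 carry compensatory regulation; 300 heteromorphic genes
#' carrying the divergent regulatory modes and the inheritance-mode mix),
#' parental divergence of 2 log2 units, and baselines near 670 mean counts so
#' that with the default 0.3 assignable fraction each gene yields about 200
#' allele-assignable reads per F1 sample. A conserved majority keeps
#' median-of-ratios normalization anchored on non-divergent genes, as in real
#' transcriptomes where only a small fraction of genes diverge.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A [sim_config()].
#' @export
f1_benchmark_config <- function(seed = 1, ...) {
  args <- list(
    n_conserved = 450, n_heteromorphic = 300, n_heterochronic = 0,
    n_p_specific = 0, n_l_specific = 0,
    baseline_log_mean = log(670), baseline_log_sd = 0.3,
    regulatory_mix = c(cis = 0.25, trans = 0.25, `cis+trans` = 0.125,
                       cisxtrans = 0.125, compensatory = 0.1, conserved = 0.35),
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Stage-mean vectors for one gene
#'
#' Builds the noiseless per-stage expectation vectors for the two morphs
#' according to the divergence category: conserved genes share one shape;
#' heteromorphic genes share the shape but one morph is scaled by
#' `2^effect` at all stages (amount, not timing); heterochronic genes use
#' two different shapes whose log-scale correlation must fall below `r_max`;
#' morph-specific genes follow a shape in one morph and sit at the ambient
#' `off_mean` in the other.
#'
#' @param category One of conserved, heteromorphic, heterochronic,
#'   P-specific, L-specific.
#' @param shape_idx Source shape index.
#' @param baseline Baseline mean count at the shape peak.
#' @param config A [sim_config()].
#' @param up_morph For heteromorphic genes, which morph is scaled up
#'   ("P" or "L").
#' @return List: `P`, `L` (stage-mean vectors), `shape_P`, `shape_L`
#'   (generating shape indices, NA for the off morph).
#' @export
simulate_gene_means <- function(category, shape_idx, baseline, config,
                                up_morph = "P") {
  sh <- config$shapes
  base_prof <- baseline * sh[shape_idx, ]
  off <- rep(config$off_mean, length(STAGES))
  switch(category,
    conserved = list(P = base_prof, L = base_prof,
                     shape_P = shape_idx, shape_L = shape_idx),
    heteromorphic = {
      f <- 2^config$lfc_effect
      if (up_morph == "P") {
        list(P = base_prof * f, L = base_prof, shape_P = shape_idx, shape_L = shape_idx)
      } else {
        list(P = base_prof, L = base_prof * f, shape_P = shape_idx, shape_L = shape_idx)
      }
    },
    heterochronic = {
      tgt <- config$heterochrony_shift[shape_idx]
      r <- stats::cor(log2(sh[shape_idx, ]), log2(sh[tgt, ]))
      if (config$enforce_shape_divergence && r >= config$r_max) {
        stop(sprintf("heterochronic shape pair (%d -> %d) correlates at r = %.3f >= %.2f",
                     shape_idx, tgt, r, config$r_max))
      }
      list(P = base_prof, L = baseline * sh[tgt, ], shape_P = shape_idx, shape_L = tgt)
    },
    `P-specific` = list(P = base_prof, L = off, shape_P = shape_idx, shape_L = NA_integer_),
    `L-specific` = list(P = off, L = base_prof, shape_P = NA_integer_, shape_L = shape_idx),
    stop("unknown category: ", category)
  )
}

# NB draw with mean mu and dispersion alpha (variance mu + alpha mu^2);
# alpha -> 0 degenerates to Poisson
rnb <- function(n, mu, alpha) {
  if (alpha < 1e-12) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate replicate counts from a mean matrix
#'
#' Draws NB counts for every gene x (genotype x stage) expectation, with
#' `n_replicates` samples per cell and a log-normal library-size factor per
#' sample. Deterministic given `seed`.
#'
#' @param means Gene x cell matrix of expected counts; cell columns must be
#'   named `<genotype>_<stage>`.
#' @param config A [sim_config()] (replicates, dispersion, library spread).
#' @param seed Integer seed.
#' @return List: `counts` (matrix), `samples` (sample table with genotype,
#'   stage, replicate, lib_factor).
#' @export
simulate_counts <- function(means, config, seed = config$seed) {
  stopifnot(config$n_replicates >= 1)
  cells <- colnames(means)
  parts <- strsplit(cells, "_(?=[^_]+$)", perl = TRUE)
  genotype <- vapply(parts, `[`, "", 1)
  stage <- vapply(parts, `[`, "", 2)
  with_local_seed(seed, {
    cols <- list(); meta <- list()
    for (ci in seq_along(cells)) {
      for (r in seq_len(config$n_replicates)) {
        sid <- sprintf("%s_%s_r%d", genotype[ci], stage[ci], r)
        s <- exp(stats::rnorm(1, 0, config$lib_size_log_sd))
        cols[[sid]] <- rnb(nrow(means), s * means[, ci], config$nb_dispersion)
        meta[[sid]] <- data.frame(sample_id = sid, genotype = genotype[ci],
                                  stage = stage[ci], replicate = r,
                                  cross_id = paste0("sim", r),
                                  total_reads = round(s * 3e7),  # emulated depth
                                  lib_factor = s, stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- rownames(means)
    list(counts = counts, samples = do.call(rbind, c(meta, list(make.row.names = FALSE))))
  })
}

#' F1 expectations for one gene
#'
#' Sets the total F1 expectation per stage from the inheritance mode
#' (additive: arithmetic midpoint of the parents; dominant: the matching
#' parent; over/underdominant: outside the parental range by `2^lfc_effect`;
#' conserved: the shared parental value) and the allelic log2 ratio from the
#' regulatory mode (cis: equal to the parental log2 ratio; trans: 0;
#' cis+trans: half the parental ratio, same sign; cisxtrans: minus half the
#' parental ratio; compensatory: `lfc_effect` with equal parents;
#' conserved: 0). Modes inconsistent with the parental divergence (e.g. a
#' trans mode with identical parents, or compensatory with divergent
#' parents) raise an error.
#'
#' @param p_means,l_means Parental stage-mean vectors.
#' @param regulatory_mode One of cis, trans, cis+trans, cisxtrans,
#'   compensatory, conserved, or NA (allelic ratio then tracks the parental
#'   ratio).
#' @param inheritance_mode One of conserved, additive, P-dominant,
#'   L-dominant, overdominant, underdominant.
#' @param config A [sim_config()].
#' @return List: `f1_means` (stage vector), `allelic_log2` (stage vector of
#'   allelic log2 ratios P:L).
#' @export
simulate_f1 <- function(p_means, l_means, regulatory_mode, inheritance_mode,
                        config) {
  parental_log2 <- log2(p_means / l_means)
  diverged <- any(abs(parental_log2) > 1e-8)
  if (!is.na(regulatory_mode)) {
    if (regulatory_mode %in% c("cis", "trans", "cis+trans", "cisxtrans") && !diverged) {
      stop("regulatory mode '", regulatory_mode, "' requires diverged parental expression")
    }
    if (regulatory_mode == "compensatory" && diverged) {
      stop("compensatory regulation requires equal parental expression")
    }
  }
  f1 <- switch(inheritance_mode,
    conserved = (p_means + l_means) / 2,
    additive = (p_means + l_means) / 2,
    `P-dominant` = p_means,
    `L-dominant` = l_means,
    overdominant = pmax(p_means, l_means) * 2^config$lfc_effect,
    underdominant = pmax(pmin(p_means, l_means) / 2^config$lfc_effect, 0.25),
    stop("unknown inheritance mode: ", inheritance_mode)
  )
  allelic <- if (is.na(regulatory_mode)) {
    parental_log2
  } else {
    switch(regulatory_mode,
      cis = parental_log2,
      trans = rep(0, length(p_means)),
      `cis+trans` = parental_log2 / 2,
      cisxtrans = -parental_log2 / 2,
      compensatory = rep(config$lfc_effect, length(p_means)),
      conserved = rep(0, length(p_means))
    )
  }
  list(f1_means = f1, allelic_log2 = allelic)
}

#' Reciprocal (parent-of-origin) expectation multipliers
#'
#' Multipliers applied to the PL and LP expectations so their ratio is
#' `2^offset` at the affected early stages (direction following the maternal
#' morph's parental expression) and 1 elsewhere.
#'
#' @param affected_stages Stages carrying the offset (subset of 16-cell,
#'   blastula).
#' @param offset Reciprocal offset in log2 units (nonzero).
#' @param direction +1 if the P-mothered cross (PL) is the higher one.
#' @return data.frame: `stage`, `pl_mult`, `lp_mult`.
#' @export
simulate_parental_effects <- function(affected_stages, offset, direction = 1) {
  stopifnot(all(affected_stages %in% c("16-cell", "blastula")), offset != 0)
  mult <- ifelse(STAGES %in% affected_stages, 2^(sign(direction) * offset / 2), 1)
  data.frame(stage = STAGES, pl_mult = mult, lp_mult = 1 / mult,
             stringsAsFactors = FALSE)
}

# proportional allocation of n items over a mix (largest-remainder)
.allocate <- function(n, mix) {
  if (n == 0 || sum(mix) == 0) return(stats::setNames(rep(0L, length(mix)), names(mix)))
  p <- mix / sum(mix)
  base <- floor(n * p)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * p - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

#' Simulate a complete experiment
#'
#' Generates parental and reciprocal-F1 count matrices, allele-resolved F1
#' counts, sample metadata, and a per-gene truth table under a
#' [sim_config()]. Heteromorphic genes carry the divergent regulatory modes
#' (cis, trans, cis+trans, cisxtrans) and the non-conserved inheritance
#' modes; conserved-divergence genes carry compensatory or conserved
#' regulation; parent-of-origin offsets are overlaid on the first
#' `parental_effect_genes` conserved/heteromorphic genes.
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_dataset"`: `counts`, `samples`,
#'   `allele_counts`, `truth`, `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  cats <- c(rep("conserved", config$n_conserved),
            rep("heteromorphic", config$n_heteromorphic),
            rep("heterochronic", config$n_heterochronic),
            rep("P-specific", config$n_p_specific),
            rep("L-specific", config$n_l_specific))
  n <- length(cats)
  gene_id <- sprintf("g%04d", seq_len(n))

  # deterministic truth layout, then seeded stochastic draws
  reg <- rep(NA_character_, n)
  het_idx <- which(cats == "heteromorphic")
  reg[het_idx] <- rep(names(.allocate(length(het_idx),
    config$regulatory_mix[c("cis", "trans", "cis+trans", "cisxtrans")])),
    .allocate(length(het_idx),
      config$regulatory_mix[c("cis", "trans", "cis+trans", "cisxtrans")]))
  con_idx <- which(cats == "conserved")
  reg[con_idx] <- rep(names(.allocate(length(con_idx),
    config$regulatory_mix[c("compensatory", "conserved")])),
    .allocate(length(con_idx), config$regulatory_mix[c("compensatory", "conserved")]))
  inh <- rep("conserved", n)
  # diverged parents with a midpoint F1 are additive by construction
  inh[cats %in% c("heterochronic", "P-specific", "L-specific")] <- "additive"
  inh[het_idx] <- rep(names(.allocate(length(het_idx), config$inheritance_mix)),
                      .allocate(length(het_idx), config$inheritance_mix))
  pe_pool <- c(con_idx, het_idx)
  pe_idx <- pe_pool[seq_len(min(config$parental_effect_genes, length(pe_pool)))]
  parental_effect <- seq_len(n) %in% pe_idx

  with_local_seed(config$seed, {
    shape_idx <- sample.int(nrow(config$shapes), n, replace = TRUE)
    baseline <- exp(stats::rnorm(n, config$baseline_log_mean, config$baseline_log_sd))
    up <- sample(c("P", "L"), n, replace = TRUE)

    p_means <- l_means <- matrix(0, n, length(STAGES), dimnames = list(gene_id, STAGES))
    shape_P <- shape_L <- integer(n)
    for (i in seq_len(n)) {
      gm <- simulate_gene_means(cats[i], shape_idx[i], baseline[i], config, up[i])
      p_means[i, ] <- gm$P; l_means[i, ] <- gm$L
      shape_P[i] <- if (is.na(gm$shape_P)) NA_integer_ else gm$shape_P
      shape_L[i] <- if (is.na(gm$shape_L)) NA_integer_ else gm$shape_L
    }

    f1_means <- matrix(0, n, length(STAGES), dimnames = list(gene_id, STAGES))
    allelic_log2 <- matrix(0, n, length(STAGES), dimnames = list(gene_id, STAGES))
    for (i in seq_len(n)) {
      f1 <- simulate_f1(p_means[i, ], l_means[i, ], reg[i], inh[i], config)
      f1_means[i, ] <- f1$f1_means
      allelic_log2[i, ] <- f1$allelic_log2
    }

    pe <- simulate_parental_effects(config$parental_effect_stages,
                                    config$parental_effect_offset)
    pl_means <- lp_means <- f1_means
    for (i in pe_idx) {
      dir_stage <- sign(log2(p_means[i, ] / l_means[i, ]))
      dir_stage[dir_stage == 0] <- 1
      mult <- ifelse(STAGES %in% config$parental_effect_stages,
                     2^(dir_stage * config$parental_effect_offset / 2), 1)
      pl_means[i, ] <- f1_means[i, ] * mult
      lp_means[i, ] <- f1_means[i, ] / mult
    }

    cell_means <- cbind(
      structure(p_means, dimnames = list(gene_id, paste0("PP_", STAGES))),
      structure(l_means, dimnames = list(gene_id, paste0("LL_", STAGES))),
      structure(pl_means, dimnames = list(gene_id, paste0("PL_", STAGES))),
      structure(lp_means[, config$lp_stages, drop = FALSE],
                dimnames = list(gene_id, paste0("LP_", config$lp_stages)))
    )
    sim <- simulate_counts(cell_means, config, seed = config$seed + 1L)

    # allele-resolved counts for all F1 samples
    f1_samp <- sim$samples[sim$samples$genotype %in% c("PL", "LP"), , drop = FALSE]
    ac <- vector("list", nrow(f1_samp))
    for (si in seq_len(nrow(f1_samp))) {
      sid <- f1_samp$sample_id[si]
      st <- f1_samp$stage[si]
      tot <- sim$counts[, sid]
      assignable <- round(config$assignable_fraction * tot)
      pr <- 2^allelic_log2[, st] / (1 + 2^allelic_log2[, st])
      pc <- stats::rbinom(n, assignable, pr)
      ac[[si]] <- data.frame(gene_id = gene_id, sample_id = sid,
                             p_count = pc, l_count = assignable - pc,
                             stringsAsFactors = FALSE)
    }

    truth <- data.frame(
      gene_id = gene_id, divergence_category = cats,
      cluster_P = shape_P, cluster_L = shape_L,
      regulatory_mode = reg, inheritance_mode = inh,
      parental_effect = parental_effect, baseline = baseline,
      stringsAsFactors = FALSE
    )
    structure(list(counts = sim$counts, samples = sim$samples,
                   allele_counts = do.call(rbind, c(ac, list(make.row.names = FALSE))),
                   truth = truth, config = config),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("simulated dataset: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$truth$divergence_category))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `counts.tsv`, `samples.tsv`, `allele_counts.tsv`, `truth.tsv` in
#' `out_dir`.
#'
#' @param dataset A `"sim_dataset"` from [simulate_experiment()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("counts.tsv", "samples.tsv",
                                "allele_counts.tsv", "truth.tsv"))
  write_counts(dataset$counts, paths[1])
  write_sample_table(dataset$samples, paths[2])
  write_allele_counts(dataset$allele_counts, paths[3])
  utils::write.table(dataset$truth, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
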