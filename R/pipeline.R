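# End-to-end orchestration: normalize -> DE -> cluster -> classify -> F1
# analyses, with TSV/JSON outputs and a structured report.

#' Pipeline configuration
#'
#' @param counts,samples,allele_counts Input file paths (TSV) or in-memory
#'   objects; `allele_counts` may be NULL (F1 regulatory section is then
#'   skipped).
#' @param simulation Optional [sim_config()]; when given, inputs are
#'   simulated instead of read.
#' @param out_dir Output directory, or NULL to skip writing files.
#' @param alpha FDR level (default 0.05).
#' @param lfc_min Minimum |log2FC| for the morph DE rule (default 1).
#' @param r_max Correlation ceiling for heterochrony and for cluster-number
#'   selection (default 0.85).
#' @param min_reads QC depth cut (default 2e6).
#' @param min_sd Profile variability filter (default 0.1).
#' @param min_assignable Minimum summed assignable F1 counts (default 10).
#' @param k_range Candidate cluster numbers (default 2:10).
#' @param m Fuzzifier: "estimate" (default) or a number > 1.
#' @param seed Seed for clustering restarts.
#' @param n_restarts FCM restarts (default 10).
#' @param require_de_for_morph_specific See [classify_genes()].
#' @param pool_reciprocal_f1 Pool PL and LP for regulatory/inheritance calls
#'   (default TRUE, the reciprocals behaving alike); FALSE restricts to PL.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(counts = NULL, samples = NULL, allele_counts = NULL,
                            simulation = NULL, out_dir = NULL,
                            alpha = 0.05, lfc_min = 1, r_max = 0.85,
                            min_reads = 2e6, min_sd = 0.1, min_assignable = 10,
                            k_range = 2:10, m = "estimate", seed = 1,
                            n_restarts = 10,
                            require_de_for_morph_specific = TRUE,
                            pool_reciprocal_f1 = TRUE) {
  stopifnot(alpha > 0, alpha < 1, r_max > 0, r_max <= 1, lfc_min >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  basename(path)
}

#' Run the full divergence-classification pipeline
#'
#' Executes QC, normalization, dispersion estimation, per-stage DE between
#' the morphs, profile clustering of the P morph with mapping of L,
#' adaptive-threshold morph-specific calling, gene classification, and - when
#' F1 samples are present - parent-of-origin, inheritance and (when allele
#' counts are given) cis/trans regulatory analyses. All randomness is seeded
#' through the config, so identical configs give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"divergence_report"`: a list with the fitted
#'   pieces (`classification`, `de`, `cluster` (model, assignments),
#'   `morph_specific`, `inheritance`, `regulatory`, `parental_effects`,
#'   `summary`, `config`). Result files are written to `config$out_dir`
#'   when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulation)) {
    ds <- simulate_experiment(config$simulation)
    counts <- ds$counts; samples <- read_sample_table(ds$samples)
    allele_counts <- ds$allele_counts
  } else {
    counts <- if (is.character(config$counts)) read_counts(config$counts) else
      validate_counts(config$counts)
    samples <- read_sample_table(config$samples)
    allele_counts <- if (is.null(config$allele_counts)) NULL else
      read_allele_counts(config$allele_counts, counts = counts, samples = samples)
  }
  qc <- qc_filter_samples(counts, samples, config$min_reads)
  counts <- qc$counts; samples <- qc$samples

  norm <- normalize_counts(counts)
  groups <- interaction(samples$genotype, samples$stage, drop = TRUE)
  disp <- estimate_dispersion(norm, groups)
  tested <- expressed_genes(norm, samples)

  de <- de_by_stage(norm, disp, samples, "LL", "PP",
                    alpha = config$alpha, lfc_min = config$lfc_min,
                    tested = tested)

  prof_P <- stage_profiles(norm, samples, "PP")[tested, , drop = FALSE]
  prof_L <- stage_profiles(norm, samples, "LL")[tested, , drop = FALSE]
  std_P <- filter_and_standardize(prof_P, config$min_sd)
  std_L <- filter_and_standardize(prof_L, config$min_sd)
  m <- if (identical(config$m, "estimate")) estimate_fuzzifier(std_P) else config$m
  sel <- select_cluster_number(std_P, m, r_max = config$r_max,
                               k_range = config$k_range, seed = config$seed,
                               n_restarts = config$n_restarts)
  model <- sel$model
  assign_P <- map_memberships(model, std_P)
  assign_L <- map_memberships(model, std_L)

  common <- intersect(rownames(prof_P), rownames(prof_L))
  r <- vapply(common, function(g) profile_correlation(prof_P[g, ], prof_L[g, ]),
              numeric(1))

  ef <- expression_flags(norm, samples)
  ms <- classify_morph_specific(ef$flags[tested, , drop = FALSE], samples)

  unclust <- union(attr(std_P, "unclusterable"), attr(std_L, "unclusterable"))
  genes <- rownames(norm$values)[tested]
  cls <- classify_genes(genes, de$results, assign_P, assign_L, r, ms,
                        r_max = config$r_max,
                        require_de_for_morph_specific = config$require_de_for_morph_specific,
                        unclusterable = unclust)

  ord <- cluster_stage_order(model)
  het <- cls$category == "heterochronic"
  cls$direction <- NA_character_
  if (any(het)) {
    hd <- heterochrony_direction(cls$cluster_P[het], cls$cluster_L[het], ord)
    cls$direction[het] <- hd$direction
  }
  switch_mat <- matrix(0L, model$k, model$k,
                       dimnames = list(paste0("P_order", seq_len(model$k)),
                                       paste0("L_order", seq_len(model$k))))
  both <- !is.na(cls$cluster_P) & !is.na(cls$cluster_L)
  if (any(both)) {
    tab <- table(factor(ord[cls$cluster_P[both]], levels = seq_len(model$k)),
                 factor(ord[cls$cluster_L[both]], levels = seq_len(model$k)))
    switch_mat[] <- as.integer(tab)
  }

  have_f1 <- any(samples$genotype %in% c("PL", "LP"))
  pe <- inh <- reg <- NULL
  excluded <- character()
  if (have_f1) {
    pe <- parental_effect_test(norm, disp, samples, parental_de = de$results,
                               alpha = config$alpha, lfc_min = config$lfc_min,
                               tested = tested)
    excluded <- unique(pe$effects$gene_id)
    f1_geno <- if (config$pool_reciprocal_f1) c("PL", "LP") else "PL"
    samp_f1 <- samples[samples$genotype %in% c("PP", "LL", f1_geno), , drop = FALSE]
    inh_rows <- list()
    for (st in STAGES) {
      ok <- all(c("PP", "LL") %in% samp_f1$genotype[as.character(samp_f1$stage) == st]) &&
        any(samp_f1$genotype[as.character(samp_f1$stage) == st] %in% c("PL", "LP"))
      if (!ok) next
      inh_rows[[st]] <- inheritance_mode(norm, disp, samp_f1, st,
                                         excluded = excluded,
                                         alpha = config$alpha, tested = tested)
    }
    inh <- do.call(rbind, c(inh_rows, list(make.row.names = FALSE)))
    if (!is.null(allele_counts)) {
      ac <- allele_counts
      if (!config$pool_reciprocal_f1) {
        keep_ids <- samples$sample_id[samples$genotype == "PL"]
        ac <- ac[ac$sample_id %in% keep_ids, , drop = FALSE]
      }
      reg_rows <- list()
      for (st in STAGES) {
        n_f1 <- sum(samples$genotype %in% f1_geno &
                      as.character(samples$stage) == st &
                      samples$sample_id %in% unique(ac$sample_id))
        if (n_f1 < 2 || !st %in% names(de$results)) next
        al <- allelic_de(ac, samples, st, min_assignable = config$min_assignable,
                         alpha = config$alpha)
        it <- interaction_test(de$results[[st]], al, alpha = config$alpha)
        reg_rows[[st]] <- regulatory_calls(de$results[[st]], al, it, st,
                                           alpha = config$alpha)
      }
      reg <- do.call(rbind, c(reg_rows, list(make.row.names = FALSE)))
    }
  }

  cat_tab <- table(factor(cls$category,
                          levels = c("conserved", "heteromorphic", "heterochronic",
                                     "P-specific", "L-specific", "unclassifiable")))
  ms_stage <- NULL
  if (any(cls$category %in% c("P-specific", "L-specific"))) {
    msg <- cls$gene_id[cls$category %in% c("P-specific", "L-specific")]
    i <- match(msg, ms$gene_id)
    ms_stage <- data.frame(gene_id = msg,
                           morph = cls$category[match(msg, cls$gene_id)],
                           stages_on = ifelse(cls$category[match(msg, cls$gene_id)] ==
                                                "P-specific",
                                              ms$pp_stages_on[i], ms$ll_stages_on[i]),
                           stringsAsFactors = FALSE)
  }

  report <- structure(list(
    classification = cls,
    de = de,
    cluster = list(model = model, k = model$k, m = m, max_r = sel$max_r,
                   assignments_P = assign_P, assignments_L = assign_L,
                   order = ord, switch_matrix = switch_mat),
    morph_specific = list(calls = ms, thresholds = ef$thresholds,
                          per_stage = ms_stage),
    correlations = r,
    inheritance = inh,
    regulatory = reg,
    parental_effects = pe,
    summary = list(
      n_genes = nrow(counts), n_tested = sum(tested),
      n_samples = ncol(counts), dropped_samples = qc$dropped,
      de_summary = de$summary, category_counts = cat_tab,
      regulatory_skipped = is.null(reg)
    ),
    config = config,
    samples = samples
  ), class = "divergence_report")

  if (!is.null(config$out_dir)) write_report_files(report, config$out_dir)
  report
}

# write every result table plus report.json and a MANIFEST
write_report_files <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (st in names(report$de$results)) {
    d <- report$de$results[[st]]
    out <- data.frame(gene_id = d$gene_id, log2fc = d$log2_fold_change,
                      p = d$p_value, q = d$q_value, mean_a = d$mean_a,
                      mean_b = d$mean_b, significant = d$significant)
    written <- c(written, .write_tsv(out, file.path(out_dir, paste0("de_", st, ".tsv"))))
  }
  written <- c(written, .write_tsv(report$classification,
                                   file.path(out_dir, "classification.tsv")))
  write_cluster_model(report$cluster$model, file.path(out_dir, "cluster_model.json"))
  written <- c(written, "cluster_model.json")
  asg <- rbind(cbind(report$cluster$assignments_P, genotype = "PP"),
               cbind(report$cluster$assignments_L, genotype = "LL"))
  written <- c(written, .write_tsv(asg[, c("gene_id", "genotype", "cluster", "max_membership")],
                                   file.path(out_dir, "assignments.tsv")))
  written <- c(written, .write_tsv(report$morph_specific$thresholds,
                                   file.path(out_dir, "thresholds.tsv")))
  if (!is.null(report$regulatory)) {
    written <- c(written, .write_tsv(report$regulatory,
                                     file.path(out_dir, "regulatory.tsv")))
  }
  if (!is.null(report$inheritance)) {
    written <- c(written, .write_tsv(report$inheritance,
                                     file.path(out_dir, "inheritance.tsv")))
  }
  if (!is.null(report$parental_effects)) {
    written <- c(written, .write_tsv(report$parental_effects$effects,
                                     file.path(out_dir, "parental_effects.tsv")))
  }
  rep_json <- list(
    seed = report$config$seed,
    package_version = as.character(utils::packageVersion("heterochron")),
    thresholds = report$config[c("alpha", "lfc_min", "r_max", "min_reads",
                                 "min_sd", "min_assignable")],
    k = report$cluster$k, m = report$cluster$m,
    de_summary = report$de$summary,
    category_counts = as.list(report$summary$category_counts),
    regulatory_skipped = report$summary$regulatory_skipped,
    regulatory_by_stage = if (!is.null(report$regulatory)) {
      as.data.frame.matrix(table(report$regulatory$stage, report$regulatory$mode))
    } else "skipped",
    parental_effects_by_stage = if (!is.null(report$parental_effects)) {
      report$parental_effects$summary
    } else "skipped"
  )
  jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  written <- c(written, "report.json")
  manifest <- data.frame(file = written, stringsAsFactors = FALSE)
  .write_tsv(manifest, file.path(out_dir, "MANIFEST.tsv"))
  invisible(written)
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("divergence classification report\n")
  cat(sprintf("  genes: %d total, %d tested\n", x$summary$n_genes, x$summary$n_tested))
  cat(sprintf("  clusters: k = %d (fuzzifier m = %.3f)\n", x$cluster$k, x$cluster$m))
  cat("  categories:\n")
  tab <- x$summary$category_counts
  for (nm in names(tab)) cat(sprintf("    %-15s %d\n", nm, tab[[nm]]))
  if (!is.null(x$summary$de_summary)) {
    cat("  percent DE by stage:\n")
    s <- x$summary$de_summary
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %-12s %5.1f%% (%d genes)\n", s$stage[i], s$percent_de[i], s$n_de[i]))
    }
  }
  if (x$summary$regulatory_skipped) cat("  regulatory section: skipped (no allele counts)\n")
  invisible(x)
}
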