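# Classification of tested genes into conserved / heteromorphic /
# heterochronic / morph-specific, combining DE results, cluster assignments,
# profile correlations, and adaptive per-sample expression thresholds.

#' Adaptive expression threshold for one sample
#'
#' Separates spurious from robust expression in a single sample under the
#' assumption that robustly expressed genes have normally distributed
#' log-expression. Fits a two-component Gaussian mixture (unequal variances)
#' to the nonzero `log2(normalized + 1)` values and returns the value between
#' the component means at which the posterior probability of the high
#' component crosses 0.5. If the mixture degenerates (components closer than
#' `min_sep`, or no crossing between the means), the fallback is the 15th
#' percentile of nonzero values, flagged.
#'
#' @param sample_values Per-gene `log2(normalized + 1)` values for one sample.
#' @param min_sep Minimum separation of component means before the fit is
#'   declared degenerate (default 1 log2 unit).
#' @param fallback_q Fallback quantile of nonzero values (default 0.15).
#' @return List: `threshold`, `low_mean`, `high_mean`, `mixing` (weight of the
#'   high component), `fallback` (logical).
#' @export
dafs_threshold <- function(sample_values, min_sep = 1, fallback_q = 0.15) {
  if (length(sample_values) < 100) stop("need >=100 genes to fit an expression threshold")
  nz <- sample_values[sample_values > 0]
  if (length(nz) < 10) stop("need >=10 nonzero values")
  if (all(nz == nz[1])) stop("all nonzero values identical; cannot threshold")
  fallback <- function() {
    list(threshold = unname(stats::quantile(nz, fallback_q)), low_mean = NA_real_,
         high_mean = NA_real_, mixing = NA_real_, fallback = TRUE)
  }
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(nz, G = 2, modelNames = "V", verbose = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("mixture fit degenerated; using fallback quantile threshold")
    return(fallback())
  }
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, 2)
  pro <- fit$parameters$pro
  lo <- which.min(mu); hi <- which.max(mu)
  if (mu[hi] - mu[lo] < min_sep) {
    warning("mixture components not separated; using fallback quantile threshold")
    return(fallback())
  }
  grid <- seq(mu[lo], mu[hi], length.out = 512)
  post_hi <- pro[hi] * stats::dnorm(grid, mu[hi], sig[hi]) /
    (pro[hi] * stats::dnorm(grid, mu[hi], sig[hi]) +
       pro[lo] * stats::dnorm(grid, mu[lo], sig[lo]))
  cross <- which(post_hi >= 0.5)
  if (!length(cross)) {
    warning("no posterior crossing between component means; using fallback")
    return(fallback())
  }
  list(threshold = grid[cross[1]], low_mean = unname(mu[lo]),
       high_mean = unname(mu[hi]), mixing = unname(pro[hi]), fallback = FALSE)
}

#' Per-sample thresholds and above-threshold flags
#'
#' Applies [dafs_threshold()] to every retained sample and flags each gene x
#' sample pair whose `log2(normalized + 1)` exceeds that sample's threshold.
#'
#' @param norm A `normalized_matrix`.
#' @param samples Sample table aligned to the matrix columns; only PP and LL
#'   samples are thresholded unless `genotypes` says otherwise.
#' @param genotypes Genotypes to threshold (default `c("PP", "LL")`).
#' @return List: `thresholds` (data.frame sample_id, threshold, low_mean,
#'   high_mean, mixing, fallback) and `flags` (gene x sample logical matrix).
#' @export
expression_flags <- function(norm, samples, genotypes = c("PP", "LL")) {
  lg <- log2(norm$values + 1)
  keep <- samples$sample_id[samples$genotype %in% genotypes]
  rows <- list()
  flags <- matrix(FALSE, nrow(lg), length(keep),
                  dimnames = list(rownames(lg), keep))
  for (s in keep) {
    th <- dafs_threshold(lg[, s])
    rows[[s]] <- data.frame(sample_id = s, threshold = th$threshold,
                            low_mean = th$low_mean, high_mean = th$high_mean,
                            mixing = th$mixing, fallback = th$fallback,
                            stringsAsFactors = FALSE)
    flags[, s] <- lg[, s] > th$threshold
  }
  list(thresholds = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       flags = flags)
}

#' Morph-specific expression calls
#'
#' A gene is P-specific when some stage has at least `min_on` PP replicates
#' above threshold while no more than `max_off` LL samples are above
#' threshold across all stages combined (the single-mismatched-replicate
#' allowance); L-specific is symmetric. Stages with fewer than three
#' replicates use `ceiling(0.6 * n_reps)` in place of `min_on`.
#'
#' @param flags Gene x sample logical matrix (above threshold), covering all
#'   PP and LL samples.
#' @param samples Sample table with rows for every flag column.
#' @param min_on Replicates required above threshold at some stage (default 3).
#' @param max_off Total above-threshold samples tolerated in the other morph
#'   across all stages (default 1).
#' @return data.frame: `gene_id`, `label` in {P-specific, L-specific,
#'   neither}, `pp_total`, `ll_total`, `pp_stages_on`, `ll_stages_on`
#'   (numbers of stages meeting the on-criterion).
#' @export
classify_morph_specific <- function(flags, samples, min_on = 3, max_off = 1) {
  count_by_stage <- function(genotype) {
    out <- matrix(0L, nrow(flags), length(STAGES),
                  dimnames = list(rownames(flags), STAGES))
    req <- stats::setNames(integer(length(STAGES)), STAGES)
    for (st in STAGES) {
      ids <- samples$sample_id[samples$genotype == genotype & samples$stage == st]
      ids <- intersect(ids, colnames(flags))
      if (!length(ids)) { req[st] <- NA_integer_; next }
      out[, st] <- as.integer(rowSums(flags[, ids, drop = FALSE]))
      req[st] <- if (length(ids) < 3) {
        message(sprintf("classify_morph_specific: %s/%s has %d replicates; requiring >= %d",
                        genotype, st, length(ids), as.integer(ceiling(0.6 * length(ids)))))
        as.integer(ceiling(0.6 * length(ids)))
      } else min_on
    }
    list(counts = out, required = req)
  }
  pp <- count_by_stage("PP")
  ll <- count_by_stage("LL")
  stage_on <- function(cb) {
    ok <- !is.na(cb$required)
    sweep(cb$counts[, ok, drop = FALSE], 2, cb$required[ok], ">=")
  }
  pp_on <- stage_on(pp); ll_on <- stage_on(ll)
  pp_tot <- rowSums(pp$counts); ll_tot <- rowSums(ll$counts)
  p_spec <- rowSums(pp_on) >= 1 & ll_tot <= max_off
  l_spec <- rowSums(ll_on) >= 1 & pp_tot <= max_off
  label <- rep("neither", nrow(flags))
  label[p_spec] <- "P-specific"
  label[l_spec] <- "L-specific"
  label[p_spec & l_spec] <- "neither"  # degenerate: almost nothing expressed
  data.frame(gene_id = rownames(flags), label = label,
             pp_total = pp_tot, ll_total = ll_tot,
             pp_stages_on = rowSums(pp_on), ll_stages_on = rowSums(ll_on),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation between two stage profiles
#'
#' Correlation of the unstandardized 6-point stage-mean vectors of a gene in
#' the two morphs. Returns NA when either vector is constant (the gene is
#' then judged by cluster switch alone).
#'
#' @param p_profile,l_profile Numeric vectors over the same stages.
#' @return Pearson r in \[-1, 1\], or NA.
#' @export
profile_correlation <- function(p_profile, l_profile) {
  stopifnot(length(p_profile) == length(l_profile))
  if (stats::sd(p_profile) == 0 || stats::sd(l_profile) == 0) return(NA_real_)
  stats::cor(p_profile, l_profile)
}

#' Classify genes into divergence categories
#'
#' Applies the precedence morph-specific > heterochronic > heteromorphic >
#' conserved over the tested gene universe:
#' morph-specific label wins (optionally requiring DE at >=1 stage);
#' otherwise a gene DE at >=1 stage that sits in different clusters in the
#' two morphs with profile correlation below `r_max` (or undefined) is
#' heterochronic; otherwise DE at >=1 stage is heteromorphic; otherwise
#' conserved. Genes unclusterable in either morph fall back to
#' heteromorphic-if-DE (flagged); genes missing from the cluster assignments
#' without being filtered or morph-specific are unclassifiable.
#'
#' @param genes Character vector: the tested gene universe.
#' @param de Named list of per-stage DE data.frames (see [de_by_stage()]).
#' @param assign_P,assign_L Cluster assignments from [map_memberships()].
#' @param r Named numeric vector of per-gene profile correlations.
#' @param ms Morph-specific calls from [classify_morph_specific()].
#' @param r_max Correlation ceiling for heterochrony (default 0.85).
#' @param require_de_for_morph_specific Require DE at >=1 stage for the
#'   morph-specific category (default TRUE).
#' @param unclusterable Character vector of gene ids removed by the
#'   variability filter in either morph.
#' @return data.frame: `gene_id`, `category`, `cluster_P`, `cluster_L`,
#'   `pearson_r`, `de_stages` (comma-separated), `n_de_stages`, `flag`.
#' @export
classify_genes <- function(genes, de, assign_P, assign_L, r, ms,
                           r_max = 0.85, require_de_for_morph_specific = TRUE,
                           unclusterable = character()) {
  de_mat <- sapply(de, function(d) {
    sig <- d$significant[match(genes, d$gene_id)]
    ifelse(is.na(sig), FALSE, sig)
  })
  if (is.null(dim(de_mat))) de_mat <- matrix(de_mat, nrow = length(genes))
  colnames(de_mat) <- names(de)
  de_any <- rowSums(de_mat) > 0
  de_str <- apply(de_mat, 1, function(x) paste(colnames(de_mat)[x], collapse = ","))
  cl_P <- assign_P$cluster[match(genes, assign_P$gene_id)]
  cl_L <- assign_L$cluster[match(genes, assign_L$gene_id)]
  rr <- unname(r[match(genes, names(r))])
  ms_lab <- ms$label[match(genes, ms$gene_id)]
  ms_lab[is.na(ms_lab)] <- "neither"

  category <- character(length(genes))
  flag <- character(length(genes))
  for (i in seq_along(genes)) {
    is_ms <- ms_lab[i] %in% c("P-specific", "L-specific") &&
      (!require_de_for_morph_specific || de_any[i])
    if (is_ms) {
      category[i] <- ms_lab[i]
      next
    }
    clustered <- !is.na(cl_P[i]) && !is.na(cl_L[i])
    if (!clustered) {
      if (genes[i] %in% unclusterable ||
          (!is.na(cl_P[i]) || !is.na(cl_L[i]))) {
        category[i] <- if (de_any[i]) "heteromorphic" else "conserved"
        flag[i] <- "unclusterable"
      } else {
        category[i] <- "unclassifiable"
        flag[i] <- "missing-assignment"
      }
      next
    }
    switch_ok <- cl_P[i] != cl_L[i] && (is.na(rr[i]) || rr[i] < r_max)
    category[i] <- if (de_any[i] && switch_ok) {
      "heterochronic"
    } else if (de_any[i]) "heteromorphic" else "conserved"
    if (is.na(rr[i]) && cl_P[i] != cl_L[i]) flag[i] <- "r-undefined"
  }
  out <- data.frame(
    gene_id = genes, category = category, cluster_P = cl_P, cluster_L = cl_L,
    pearson_r = rr, de_stages = de_str, n_de_stages = rowSums(de_mat),
    flag = flag, stringsAsFactors = FALSE, row.names = NULL
  )
  out$cluster_P[out$category %in% c("P-specific", "L-specific")] <- NA_integer_
  out$cluster_L[out$category %in% c("P-specific", "L-specific")] <- NA_integer_
  out
}

#' Direction of a heterochronic shift
#'
#' Compares the early-to-late order index of a gene's clusters in the two
#' morphs: a gene whose P cluster is earlier than its L cluster is expressed
#' earlier in PP. A switch spanning the full cluster order (maximum
#' off-diagonal distance) is flagged extreme.
#'
#' @param cluster_P,cluster_L Integer cluster labels.
#' @param order_index Early-to-late rank per cluster, from
#'   [cluster_stage_order()].
#' @return data.frame: `direction` in {earlier-in-P, earlier-in-L, lateral},
#'   `order_distance`, `extreme`.
#' @export
heterochrony_direction <- function(cluster_P, cluster_L, order_index) {
  op <- order_index[cluster_P]
  ol <- order_index[cluster_L]
  d <- ol - op  # positive: P peaks earlier
  direction <- ifelse(d > 0, "earlier-in-P", ifelse(d < 0, "earlier-in-L", "lateral"))
  data.frame(direction = direction, order_distance = abs(d),
             extreme = abs(d) == max(order_index) - min(order_index),
             stringsAsFactors = FALSE, row.names = NULL)
}
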