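# Library-size normalization (median-of-ratios), moment/trend dispersion
# estimation, and per-stage two-group negative-binomial Wald tests with
# Benjamini-Hochberg FDR control and a fold-change rule.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over reference genes of
#' `counts[g, j] / geomean_g`, where `geomean_g` is the gene's geometric mean
#' across samples and reference genes are those with a positive geometric mean
#' (i.e. no zero count). Factors are rescaled to geometric mean 1. If no gene
#' is positive in every sample, a positive-counts-only variant is used with a
#' warning (geometric means and medians over positive entries only).
#'
#' @param counts Count matrix (genes x samples).
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- validate_counts(counts)
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (any(use)) {
    ratios <- counts[use, , drop = FALSE] / exp(logg[use])
    ls <- log(apply(ratios, 2, stats::median))
  } else {
    warning("no gene expressed in all samples; using positive-counts-only size factors")
    logg_pos <- apply(counts, 1, function(x) {
      if (!any(x > 0)) return(-Inf)
      sum(log(x[x > 0])) / length(x)
    })
    usep <- is.finite(logg_pos) & rowSums(counts > 0) > 1
    if (!any(usep)) stop("cannot estimate size factors: no usable genes")
    ls <- vapply(seq_len(ncol(counts)), function(j) {
      r <- log(counts[usep, j]) - logg_pos[usep]
      stats::median(r[is.finite(r)])
    }, numeric(1))
  }
  s <- exp(ls - mean(ls))
  names(s) <- colnames(counts)
  s
}

#' Normalize counts by size factors
#'
#' Divides each sample's counts by its size factor. The returned object keeps
#' the factors so that `values[g, s] * size_factors[s]` recovers the counts.
#'
#' @param counts Count matrix.
#' @param sf Optional precomputed size factors; estimated via [size_factors()]
#'   when missing.
#' @return List of class `"normalized_matrix"` with elements `values`
#'   (genes x samples) and `size_factors`.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  counts <- validate_counts(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  stopifnot(all(sf > 0), length(sf) == ncol(counts))
  values <- sweep(counts, 2, sf, "/")
  structure(list(values = values, size_factors = sf), class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("size factor range:", paste(signif(range(x$size_factors), 4), collapse = " - "), "\n")
  invisible(x)
}

#' Per-gene NB dispersion estimates
#'
#' Gene-wise method-of-moments estimates pooled within replicate groups
#' (`alpha = (s^2 - m) / m^2` on normalized counts, with a size-factor
#' correction of the Poisson term), shrunk toward a fitted mean-dispersion
#' trend `a0 + a1/mean` by a weighted average whose weight grows with the
#' pooled replicate degrees of freedom, then floored.
#'
#' @param norm A `normalized_matrix`.
#' @param groups Factor of replicate-group labels (e.g. genotype x stage),
#'   one per sample.
#' @param floor Minimum dispersion (default `1e-8`).
#' @param prior_df Strength of shrinkage toward the trend (default 8).
#' @return data.frame with `gene_id`, `dispersion`, `method`.
#' @export
estimate_dispersion <- function(norm, groups, floor = 1e-8, prior_df = 8) {
  v <- norm$values
  sf <- norm$size_factors
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == ncol(v))
  n_per <- table(groups)
  rep_groups <- names(n_per)[n_per >= 2]
  if (!length(rep_groups)) {
    stop("dispersion estimation requires >=2 replicates in at least one group")
  }
  num <- den <- rep(0, nrow(v))
  mu_all <- rep(0, nrow(v)); wsum <- 0
  for (g in rep_groups) {
    j <- which(groups == g)
    m <- rowMeans(v[, j, drop = FALSE])
    s2 <- apply(v[, j, drop = FALSE], 1, stats::var)
    pois <- m * mean(1 / sf[j])  # Poisson part of Var(normalized counts)
    a <- ifelse(m > 0, (s2 - pois) / m^2, NA_real_)
    w <- length(j) - 1
    ok <- !is.na(a)
    num[ok] <- num[ok] + w * a[ok]
    den[ok] <- den[ok] + w
    mu_all <- mu_all + length(j) * m; wsum <- wsum + length(j)
  }
  mu <- mu_all / wsum
  raw <- ifelse(den > 0, pmax(0, num / den), NA_real_)
  # parametric trend alpha(mu) = a0 + a1/mu, fitted on informative genes
  fit_ok <- !is.na(raw) & raw > 0 & mu > 0
  if (sum(fit_ok) >= 50) {
    tf <- stats::lm(raw[fit_ok] ~ I(1 / mu[fit_ok]))
    a0 <- max(unname(stats::coef(tf)[1]), 1e-6)
    a1 <- max(unname(stats::coef(tf)[2]), 0)
  } else {
    a0 <- stats::median(raw[fit_ok], na.rm = TRUE)
    if (!is.finite(a0)) a0 <- 0.1
    a1 <- 0
  }
  trend <- a0 + ifelse(mu > 0, a1 / mu, 0)
  w <- den / (den + prior_df)
  disp <- ifelse(is.na(raw), trend, w * raw + (1 - w) * trend)
  disp <- pmax(floor, disp)
  method <- ifelse(mu == 0, "floor",
            ifelse(disp <= floor, "floor", "trend-shrunk"))
  disp[mu == 0] <- floor
  data.frame(gene_id = rownames(v), dispersion = disp, method = method,
             mean = mu, raw = raw, stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; values must be finite and in \[0, 1\].
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values (monotone in p-rank, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Fisher-scoring MLE of a per-gene group mean on the normalized scale.
# Solves sum_i (y_i - sf_i q)/(1 + alpha sf_i q) = 0 for eta = log q,
# vectorized across genes. Returns eta, its SE (observed/Fisher information
# of the log-mean), and a flag for all-zero groups (floored at half a count).
nb_group_logmean <- function(y, sf, alpha, max_iter = 50, tol = 1e-10) {
  tot <- rowSums(y)
  zero <- tot == 0
  q0 <- pmax(tot / sum(sf), 0.5 / sum(sf))
  eta <- log(q0)
  for (it in seq_len(max_iter)) {
    mu <- exp(eta) %o% sf
    denom <- 1 + alpha * mu
    score <- rowSums((y - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / info
    step <- pmin(pmax(step, -5), 5)
    eta <- eta + step
    if (max(abs(step)) < tol) break
  }
  eta[zero] <- log(0.5 / sum(sf))
  mu <- exp(eta) %o% sf
  info <- rowSums(mu / (1 + alpha * mu))
  list(eta = eta, se = 1 / sqrt(info), zero = zero)
}

#' Two-group negative-binomial Wald test
#'
#' Per gene, fits group means on the normalized scale by maximum likelihood
#' (log link, per-sample size-factor offsets, fixed per-gene dispersion) and
#' tests the group log-ratio with a Wald statistic. Reported
#' `log2_fold_change` is `log2((mean_b + c)/(mean_a + c))` on normalized
#' means with display pseudocount `c` (the test itself uses none). Genes with
#' zero counts in all samples of both groups, or outside `tested`, are not
#' tested (NA p/q) and are excluded from the FDR denominator.
#'
#' @param norm A `normalized_matrix`.
#' @param dispersions data.frame from [estimate_dispersion()] (or a numeric
#'   vector of per-gene dispersions in gene order).
#' @param group_a,group_b Disjoint character vectors of sample ids; the fold
#'   change is b relative to a.
#' @param alpha FDR level for the significance call (default 0.05).
#' @param lfc_min Minimum |log2FC| for significance (default 1, i.e. twofold).
#' @param pseudocount Display pseudocount `c` (default 0.5 normalized counts).
#' @param tested Optional logical vector (gene order) restricting the tested
#'   universe, e.g. to expressed genes.
#' @return data.frame: `gene_id`, `log2_fold_change`, `log_ratio` (natural-log
#'   MLE), `se` (its standard error), `p_value`, `q_value`, `mean_a`,
#'   `mean_b`, `mean_expression`, `significant`.
#' @export
de_test <- function(norm, dispersions, group_a, group_b, alpha = 0.05,
                    lfc_min = 1, pseudocount = 0.5, tested = NULL) {
  v <- norm$values
  sf <- norm$size_factors
  ja <- match(group_a, colnames(v)); jb <- match(group_b, colnames(v))
  if (anyNA(ja) || anyNA(jb)) stop("unknown sample id in group_a/group_b")
  if (!length(ja) || !length(jb)) stop("both groups must be nonempty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  disp <- if (is.data.frame(dispersions)) dispersions$dispersion else dispersions
  stopifnot(length(disp) == nrow(v))
  ya <- sweep(v[, ja, drop = FALSE], 2, sf[ja], "*")  # raw counts back
  yb <- sweep(v[, jb, drop = FALSE], 2, sf[jb], "*")
  fa <- nb_group_logmean(ya, sf[ja], disp)
  fb <- nb_group_logmean(yb, sf[jb], disp)
  mean_a <- rowMeans(v[, ja, drop = FALSE])
  mean_b <- rowMeans(v[, jb, drop = FALSE])
  lr <- fb$eta - fa$eta
  se <- sqrt(fa$se^2 + fb$se^2)
  z <- lr / se
  p <- 2 * stats::pnorm(-abs(z))
  testable <- !(fa$zero & fb$zero)
  if (!is.null(tested)) testable <- testable & tested
  p[!testable] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[testable] <- bh_adjust(p[testable])
  l2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  sig <- !is.na(q) & q <= alpha & abs(l2fc) >= lfc_min
  data.frame(
    gene_id = rownames(v), log2_fold_change = l2fc, log_ratio = lr, se = se,
    p_value = p, q_value = q, mean_a = mean_a, mean_b = mean_b,
    mean_expression = (mean_a + mean_b) / 2, significant = sig,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Expressed-gene filter
#'
#' A gene is "expressed" (enters the FDR denominator) when its mean normalized
#' count is at least `min_mean` in at least one genotype x stage cell.
#'
#' @param norm A `normalized_matrix`.
#' @param samples Sample table aligned to the matrix columns.
#' @param min_mean Threshold on the cell mean (default 1).
#' @return Logical vector, one per gene.
#' @export
expressed_genes <- function(norm, samples, min_mean = 1) {
  cell <- interaction(samples$genotype, samples$stage, drop = TRUE)
  any_ok <- rep(FALSE, nrow(norm$values))
  for (cl in levels(cell)) {
    j <- which(cell == cl)
    any_ok <- any_ok | rowMeans(norm$values[, j, drop = FALSE]) >= min_mean
  }
  any_ok
}

#' Stage-by-stage differential expression between two genotypes
#'
#' Runs [de_test()] at every stage where both genotypes have samples, and
#' summarizes the per-stage percent of expressed genes called DE and the
#' mean/median |log2FC| among DE genes. Stages missing either genotype are
#' skipped with a message.
#'
#' @param norm A `normalized_matrix`.
#' @param dispersions Output of [estimate_dispersion()].
#' @param samples Sample table aligned to the matrix columns.
#' @param genotype_a,genotype_b Genotype labels to contrast (b relative to a).
#' @param alpha,lfc_min Significance thresholds passed to [de_test()].
#' @param tested Optional expressed-gene filter (see [expressed_genes()]).
#' @return List with `results` (named list of per-stage data.frames) and
#'   `summary` (data.frame: stage, n_tested, n_de, percent_de, mean_abs_lfc,
#'   median_abs_lfc).
#' @export
de_by_stage <- function(norm, dispersions, samples, genotype_a, genotype_b,
                        alpha = 0.05, lfc_min = 1, tested = NULL) {
  results <- list()
  rows <- list()
  for (st in STAGES) {
    ida <- samples$sample_id[samples$genotype == genotype_a & samples$stage == st]
    idb <- samples$sample_id[samples$genotype == genotype_b & samples$stage == st]
    if (!length(ida) || !length(idb)) {
      message(sprintf("de_by_stage: skipping stage '%s' (missing %s)", st,
                      if (!length(ida)) genotype_a else genotype_b))
      next
    }
    de <- de_test(norm, dispersions, ida, idb, alpha = alpha,
                  lfc_min = lfc_min, tested = tested)
    results[[st]] <- de
    n_tested <- sum(!is.na(de$q_value))
    sig <- de$significant
    rows[[st]] <- data.frame(
      stage = st, n_tested = n_tested, n_de = sum(sig),
      percent_de = if (n_tested) 100 * sum(sig) / n_tested else NA_real_,
      mean_abs_lfc = if (any(sig)) mean(abs(de$log2_fold_change[sig])) else NA_real_,
      median_abs_lfc = if (any(sig)) stats::median(abs(de$log2_fold_change[sig])) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  list(results = results, summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
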