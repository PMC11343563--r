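# F1 analyses: allele-specific expression contrasts, cis/trans regulatory
# mode assignment, inheritance-mode classification, and parent-of-origin
# (reciprocal PL vs LP) effects.

# IRLS for a fixed-dispersion NB GLM with log link and arbitrary design.
# Returns coefficients and Fisher-information SEs.
nb_irls <- function(y, X, alpha, max_iter = 50, tol = 1e-10) {
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- NULL
  for (it in seq_len(max_iter)) {
    w <- pmax(mu / (1 + alpha * mu), 1e-10)
    z <- eta + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    beta_new[!is.finite(beta_new)] <- log(0.25)  # empty/degenerate block
    eta <- drop(X %*% beta_new)
    eta <- pmin(pmax(eta, -20), 30)
    mu <- exp(eta)
    if (!is.null(beta) && max(abs(beta_new - beta), na.rm = TRUE) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  w <- mu / (1 + alpha * mu)
  XtWX <- crossprod(X, w * X)
  cov <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  list(beta = beta, se = sqrt(diag(cov)), mu = mu)
}

#' Allele-specific differential expression at one stage
#'
#' Contrasts P-allele to L-allele read counts within F1 samples at one stage
#' using a paired NB Wald test: per gene, a log-link NB GLM with one blocking
#' coefficient per F1 sample and a single allele coefficient (the allelic
#' log-ratio). Per-gene dispersion is a moment estimate from the Poisson fit
#' residuals, shrunk toward the across-gene median. Genes whose summed
#' assignable counts fall below `min_assignable` are not testable and are
#' excluded from the FDR denominator.
#'
#' @param allele_counts Allele count table (gene_id, sample_id, p_count,
#'   l_count).
#' @param samples Sample table (to resolve the stage of each F1 sample).
#' @param stage Stage label.
#' @param min_assignable Minimum summed assignable counts per gene (default 10).
#' @param alpha FDR level for the significance flag (default 0.05).
#' @param prior_df Shrinkage strength for the dispersion moment estimate.
#' @return data.frame: `gene_id`, `log2_ratio` (P:L), `log_ratio`, `se`,
#'   `p_value`, `q_value`, `mean_p`, `mean_l`, `n_assignable`, `testable`,
#'   `significant`.
#' @export
allelic_de <- function(allele_counts, samples, stage, min_assignable = 10,
                       alpha = 0.05, prior_df = 8) {
  sids <- samples$sample_id[samples$genotype %in% c("PL", "LP") &
                              as.character(samples$stage) == stage]
  sids <- intersect(sids, unique(allele_counts$sample_id))
  if (length(sids) < 2) stop("need >=2 F1 samples with allele counts at stage ", stage)
  ac <- allele_counts[allele_counts$sample_id %in% sids, , drop = FALSE]
  genes <- unique(ac$gene_id)
  P <- matrix(0, length(genes), length(sids), dimnames = list(genes, sids))
  L <- P
  P[cbind(match(ac$gene_id, genes), match(ac$sample_id, sids))] <- ac$p_count
  L[cbind(match(ac$gene_id, genes), match(ac$sample_id, sids))] <- ac$l_count
  tot <- rowSums(P) + rowSums(L)
  testable <- tot >= min_assignable

  S <- length(sids)
  # design: sample blocks + allele effect; obs ordered (all P, all L)
  X <- cbind(rbind(diag(S), diag(S)), c(rep(1, S), rep(0, S)))
  colnames(X) <- c(paste0("s", seq_len(S)), "allele")
  lr <- se <- rep(NA_real_, length(genes))
  raw_alpha <- rep(NA_real_, length(genes))
  fits <- vector("list", length(genes))
  for (i in which(testable)) {
    y <- c(P[i, ], L[i, ])
    pois <- nb_irls(y, X, alpha = 0)
    df <- length(y) - ncol(X)
    raw_alpha[i] <- max(0, sum(((y - pois$mu)^2 - pois$mu) / pois$mu^2) / df)
  }
  med_a <- stats::median(raw_alpha, na.rm = TRUE)
  if (!is.finite(med_a)) med_a <- 0.01
  w <- (2 * S - ncol(X)) / (2 * S - ncol(X) + prior_df)
  for (i in which(testable)) {
    a <- max(1e-8, w * raw_alpha[i] + (1 - w) * med_a)
    fit <- nb_irls(c(P[i, ], L[i, ]), X, alpha = a)
    lr[i] <- fit$beta["allele"]
    se[i] <- fit$se[ncol(X)]
  }
  z <- lr / se
  p <- 2 * stats::pnorm(-abs(z))
  q <- rep(NA_real_, length(genes))
  ok <- testable & is.finite(p)
  q[ok] <- bh_adjust(p[ok])
  data.frame(
    gene_id = genes, log2_ratio = lr / log(2), log_ratio = lr, se = se,
    p_value = p, q_value = q, mean_p = rowMeans(P), mean_l = rowMeans(L),
    n_assignable = tot, testable = testable,
    significant = !is.na(q) & q <= alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Parental-ratio vs allelic-ratio interaction test
#'
#' Wald test of H0: parental log-ratio equals allelic log-ratio, using the
#' two independent estimates and their standard errors:
#' `z = (L_A - L_B) / sqrt(SE_A^2 + SE_B^2)`. Genes untestable on either
#' side are untestable here.
#'
#' @param parental_de [de_test()] result for PP vs LL at the stage (fold
#'   change of PP relative to LL, i.e. call with `group_a` = LL samples).
#' @param allelic [allelic_de()] result at the same stage.
#' @param alpha FDR level (default 0.05).
#' @return data.frame: `gene_id`, `delta_log2`, `p_value`, `q_value`,
#'   `testable`, `significant`.
#' @export
interaction_test <- function(parental_de, allelic, alpha = 0.05) {
  i <- match(allelic$gene_id, parental_de$gene_id)
  lrA <- parental_de$log_ratio[i]; seA <- parental_de$se[i]
  okA <- !is.na(parental_de$q_value[i])
  lrB <- allelic$log_ratio; seB <- allelic$se
  okB <- allelic$testable
  testable <- !is.na(okA) & okA & okB & is.finite(seA) & is.finite(seB)
  z <- (lrA - lrB) / sqrt(seA^2 + seB^2)
  p <- 2 * stats::pnorm(-abs(z))
  p[!testable] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[testable] <- bh_adjust(p[testable])
  data.frame(gene_id = allelic$gene_id, delta_log2 = (lrA - lrB) / log(2),
             p_value = p, q_value = q, testable = testable,
             significant = !is.na(q) & q <= alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Regulatory mode from the three-contrast truth table
#'
#' Deterministic map from the significance flags of the parental contrast
#' (A), the allelic contrast (B) and the interaction (C), plus the ratio
#' signs: A,B,not C = cis; A,not B,C = trans; A,B,C same sign = cis+trans;
#' A,B,C opposite sign = cisxtrans; not A,B,C = compensatory; none = conserved;
#' every other pattern = ambiguous. Untestable inputs give ambiguous.
#'
#' @param a_sig,b_sig,c_sig Logical significance flags (NA = untestable).
#' @param parental_ratio,allelic_ratio Signed ratios (any log scale).
#' @return Character vector of modes.
#' @export
regulatory_mode <- function(a_sig, b_sig, c_sig, parental_ratio, allelic_ratio) {
  n <- length(a_sig)
  mode <- rep("ambiguous", n)
  ok <- !is.na(a_sig) & !is.na(b_sig) & !is.na(c_sig)
  same <- sign(parental_ratio) == sign(allelic_ratio)
  A <- a_sig; B <- b_sig; C <- c_sig
  mode[ok & A & B & !C] <- "cis"
  mode[ok & A & !B & C] <- "trans"
  mode[ok & A & B & C & same] <- "cis+trans"
  mode[ok & A & B & C & !same] <- "cisxtrans"
  mode[ok & !A & B & C] <- "compensatory"
  mode[ok & !A & !B & !C] <- "conserved"
  mode
}

#' Per-stage regulatory calls
#'
#' Combines the three contrasts at one stage into a [regulatory_mode()] call
#' per gene. Significance here is the FDR cut alone (`q <= alpha`); the
#' fold-change rule is not applied to the architecture contrasts.
#'
#' @param parental_de,allelic,interaction The three per-stage results
#'   (see [de_test()], [allelic_de()], [interaction_test()]).
#' @param stage Stage label recorded in the output.
#' @param alpha FDR level (default 0.05).
#' @return data.frame: `gene_id`, `stage`, `mode`, `parental_log2ratio`,
#'   `allelic_log2ratio`, `interaction_q`.
#' @export
regulatory_calls <- function(parental_de, allelic, interaction, stage,
                             alpha = 0.05) {
  i <- match(allelic$gene_id, parental_de$gene_id)
  a_sig <- ifelse(is.na(parental_de$q_value[i]), NA, parental_de$q_value[i] <= alpha)
  b_sig <- ifelse(allelic$testable & !is.na(allelic$q_value),
                  allelic$q_value <= alpha, NA)
  c_sig <- ifelse(interaction$testable & !is.na(interaction$q_value),
                  interaction$q_value <= alpha, NA)
  plr <- parental_de$log_ratio[i] / log(2)
  data.frame(
    gene_id = allelic$gene_id, stage = stage,
    mode = regulatory_mode(a_sig, b_sig, c_sig, plr, allelic$log2_ratio),
    parental_log2ratio = plr, allelic_log2ratio = allelic$log2_ratio,
    interaction_q = interaction$q_value,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Inheritance mode at one stage
#'
#' Pairwise NB Wald tests (FDR cut only, no fold-change rule) of F1 vs PP,
#' F1 vs LL and PP vs LL: conserved = none significant; additive = F1
#' differs from both parents with mean strictly between them; P-/L-dominant
#' = F1 indistinguishable from that parent and different from the other;
#' over-/underdominant = F1 differs from both with mean outside the parental
#' range. Genes significantly DE between the reciprocal F1s at any stage
#' (`excluded`) are recorded with reason "reciprocal-DE" and not classified.
#'
#' @param norm A `normalized_matrix` over all genotypes.
#' @param dispersions Output of [estimate_dispersion()].
#' @param samples Sample table aligned to the matrix.
#' @param stage Stage label.
#' @param excluded Character vector of reciprocal-DE gene ids.
#' @param alpha FDR level (default 0.05).
#' @param tested Optional expressed-gene filter.
#' @return data.frame: `gene_id`, `stage`, `mode`, `mean_pp`, `mean_ll`,
#'   `mean_f1`, `reason`.
#' @export
inheritance_mode <- function(norm, dispersions, samples, stage,
                             excluded = character(), alpha = 0.05,
                             tested = NULL) {
  id_pp <- samples$sample_id[samples$genotype == "PP" & as.character(samples$stage) == stage]
  id_ll <- samples$sample_id[samples$genotype == "LL" & as.character(samples$stage) == stage]
  id_f1 <- samples$sample_id[samples$genotype %in% c("PL", "LP") &
                               as.character(samples$stage) == stage]
  if (!length(id_pp) || !length(id_ll) || !length(id_f1)) {
    stop("stage '", stage, "' lacks PP, LL or F1 samples")
  }
  t_pp <- de_test(norm, dispersions, id_pp, id_f1, alpha = alpha, lfc_min = 0, tested = tested)
  t_ll <- de_test(norm, dispersions, id_ll, id_f1, alpha = alpha, lfc_min = 0, tested = tested)
  t_par <- de_test(norm, dispersions, id_ll, id_pp, alpha = alpha, lfc_min = 0, tested = tested)
  sig_pp <- !is.na(t_pp$q_value) & t_pp$q_value <= alpha
  sig_ll <- !is.na(t_ll$q_value) & t_ll$q_value <= alpha
  sig_par <- !is.na(t_par$q_value) & t_par$q_value <= alpha
  m_pp <- t_pp$mean_a; m_f1 <- t_pp$mean_b; m_ll <- t_ll$mean_a
  lo <- pmin(m_pp, m_ll); hi <- pmax(m_pp, m_ll)

  mode <- rep("ambiguous", nrow(t_pp))
  mode[!sig_pp & !sig_ll & !sig_par] <- "conserved"
  both <- sig_pp & sig_ll
  mode[both & m_f1 > lo & m_f1 < hi] <- "additive"
  mode[both & m_f1 > hi] <- "overdominant"
  mode[both & m_f1 < lo] <- "underdominant"
  mode[!sig_pp & sig_ll] <- "P-dominant"
  mode[sig_pp & !sig_ll] <- "L-dominant"
  untested <- is.na(t_pp$q_value) | is.na(t_ll$q_value)
  mode[untested] <- "ambiguous"
  reason <- rep("", nrow(t_pp))
  exc <- t_pp$gene_id %in% excluded
  mode[exc] <- NA_character_
  reason[exc] <- "reciprocal-DE"
  reason[untested & !exc] <- "untestable"
  data.frame(gene_id = t_pp$gene_id, stage = stage, mode = mode,
             mean_pp = m_pp, mean_ll = m_ll, mean_f1 = m_f1, reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Parent-of-origin (reciprocal F1) effects
#'
#' Tests PL vs LP per stage (the study design has both reciprocals at
#' 16-cell, gastrula and swimming). For genes also DE between the parental
#' morphs at that stage, the direction is labelled maternal-matching when
#' the reciprocal difference has the same sign as the parental difference
#' (the cross with the higher-expressing mother is itself higher), else
#' paternal-matching; genes not DE in the parents are unassigned.
#'
#' @param norm A `normalized_matrix`.
#' @param dispersions Output of [estimate_dispersion()].
#' @param samples Sample table aligned to the matrix.
#' @param parental_de Named per-stage list of PP-vs-LL results (fold change
#'   of PP relative to LL), for direction labelling; may be NULL.
#' @param stages Stages to test (default 16-cell, gastrula, swimming).
#' @param alpha,lfc_min Significance thresholds (paper DE rule).
#' @param tested Optional expressed-gene filter.
#' @return List: `results` (per-stage [de_test()] outputs, PL relative to
#'   LP... fold change of PL over LP), `effects` (data.frame gene_id, stage,
#'   log2_fold_change, direction for significant genes), `summary`
#'   (data.frame stage, n_de).
#' @export
parental_effect_test <- function(norm, dispersions, samples, parental_de = NULL,
                                 stages = c("16-cell", "gastrula", "swimming"),
                                 alpha = 0.05, lfc_min = 1, tested = NULL) {
  results <- list(); eff <- list(); rows <- list()
  for (st in stages) {
    id_pl <- samples$sample_id[samples$genotype == "PL" & as.character(samples$stage) == st]
    id_lp <- samples$sample_id[samples$genotype == "LP" & as.character(samples$stage) == st]
    if (!length(id_pl) || !length(id_lp)) {
      message("parental_effect_test: skipping stage '", st, "' (missing a reciprocal)")
      next
    }
    de <- de_test(norm, dispersions, id_lp, id_pl, alpha = alpha,
                  lfc_min = lfc_min, tested = tested)  # b = PL, so log2FC is PL:LP
    results[[st]] <- de
    sig <- which(de$significant)
    direction <- rep("unassigned", length(sig))
    if (!is.null(parental_de) && st %in% names(parental_de)) {
      pd <- parental_de[[st]]
      i <- match(de$gene_id[sig], pd$gene_id)
      par_sig <- !is.na(i) & pd$significant[i]
      same <- sign(de$log2_fold_change[sig]) == sign(pd$log2_fold_change[i])
      direction[par_sig & same] <- "maternal-matching"
      direction[par_sig & !same] <- "paternal-matching"
    }
    if (length(sig)) {
      eff[[st]] <- data.frame(gene_id = de$gene_id[sig], stage = st,
                              log2_fold_change = de$log2_fold_change[sig],
                              direction = direction,
                              stringsAsFactors = FALSE)
    }
    rows[[st]] <- data.frame(stage = st, n_de = length(sig), stringsAsFactors = FALSE)
  }
  list(results = results,
       effects = if (length(eff)) do.call(rbind, c(eff, list(make.row.names = FALSE))) else
         data.frame(gene_id = character(), stage = character(),
                    log2_fold_change = numeric(), direction = character()),
       summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Gene-level modal call across stages
#'
#' Collapses per-stage calls to one call per gene: the most frequent
#' informative mode (ties to the more frequent mode overall, then
#' alphabetical); genes with no informative stage call stay ambiguous.
#'
#' @param calls data.frame with `gene_id` and `mode` columns (per stage).
#' @param uninformative Modes ignored when picking the modal call.
#' @return data.frame: `gene_id`, `mode`.
#' @export
modal_call <- function(calls, uninformative = c("ambiguous", NA)) {
  inf <- calls[!(calls$mode %in% uninformative) & !is.na(calls$mode), , drop = FALSE]
  overall <- sort(table(inf$mode), decreasing = TRUE)
  pick <- function(m) {
    tab <- sort(table(m), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) top <- top[order(-overall[top], top)][1]
    top
  }
  genes <- unique(calls$gene_id)
  mode <- rep("ambiguous", length(genes))
  if (nrow(inf)) {
    got <- tapply(inf$mode, inf$gene_id, pick)
    mode[match(names(got), genes)] <- unlist(got)
  }
  data.frame(gene_id = genes, mode = mode, stringsAsFactors = FALSE, row.names = NULL)
}
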