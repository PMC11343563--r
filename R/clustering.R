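# Standardized stage-mean expression profiles, fuzzy c-means clustering of the
# reference (P) morph, cluster-number selection by centroid correlation, and
# mapping of the other morph onto the fixed centroids.

#' Per-stage mean expression profiles
#'
#' For one genotype, averages `log2(normalized + 1)` across replicates at each
#' stage, yielding one 6-point profile per gene (unstandardized).
#'
#' @param norm A `normalized_matrix`.
#' @param samples Sample table aligned to the matrix columns.
#' @param genotype Genotype label whose replicates are averaged.
#' @return Numeric matrix, genes x stages (columns in [STAGES] order), with
#'   attribute `standardized = FALSE`.
#' @export
stage_profiles <- function(norm, samples, genotype) {
  lg <- log2(norm$values + 1)
  prof <- matrix(NA_real_, nrow(lg), length(STAGES),
                 dimnames = list(rownames(lg), STAGES))
  for (st in STAGES) {
    j <- which(samples$genotype == genotype & samples$stage == st)
    if (!length(j)) stop(sprintf("genotype '%s' has no samples at stage '%s'", genotype, st))
    prof[, st] <- rowMeans(lg[, j, drop = FALSE])
  }
  attr(prof, "standardized") <- FALSE
  prof
}

#' Filter low-variability profiles and z-score the rest
#'
#' Rows with standard deviation below `min_sd` are removed (recorded in the
#' `unclusterable` attribute); remaining rows are standardized to mean 0 and
#' standard deviation 1.
#'
#' @param profiles Profile matrix from [stage_profiles()].
#' @param min_sd Minimum row standard deviation (default 0.1 on the log2
#'   scale; rows below carry no usable shape information).
#' @return Standardized profile matrix with attributes `standardized = TRUE`
#'   and `unclusterable` (character vector of removed gene ids).
#' @export
filter_and_standardize <- function(profiles, min_sd = 0.1) {
  stopifnot(min_sd >= 0)
  sds <- apply(profiles, 1, stats::sd)
  keep <- sds > min_sd & sds > 0
  if (!any(keep)) stop("all profiles removed by the variability filter")
  out <- profiles[keep, , drop = FALSE]
  out <- (out - rowMeans(out)) / apply(out, 1, stats::sd)
  attr(out, "standardized") <- TRUE
  attr(out, "unclusterable") <- rownames(profiles)[!keep]
  out
}

#' Estimate the fuzzy c-means fuzzifier
#'
#' Data-size-based estimator of the fuzzifier exponent m from the number of
#' profiles N and dimensions D (Schwaemmle-Jensen relation), clamped to
#' \[1.05, 3\]. m decreases with N: larger datasets support crisper
#' memberships.
#'
#' @param profiles Profile matrix (or anything with `nrow`/`ncol`).
#' @return Fuzzifier m > 1.
#' @export
estimate_fuzzifier <- function(profiles) {
  N <- nrow(profiles); D <- ncol(profiles)
  if (is.null(D) || D < 2) stop("need at least 2 profile dimensions")
  if (N < 10) stop("need at least 10 profiles to estimate the fuzzifier")
  m <- 1 + (1418 / N + 22.05) * D^(-2) +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
  min(max(m, 1.05), 3)
}

# squared Euclidean distances between profile rows and centroid rows
.sqdist <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
}

# FCM membership update for fixed centroids; zero distances get membership 1
# on the nearest centroid (ties to the lowest cluster index)
.fcm_memberships <- function(d2, m) {
  d2 <- pmax(d2, 0)
  u <- (d2 + 1e-300)^(-1 / (m - 1))
  u <- u / rowSums(u)
  zero <- d2 < 1e-12
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    u[cbind(which(hit), apply(zero[hit, , drop = FALSE], 1, which.max))] <- 1
  }
  u
}

#' Fit fuzzy c-means on standardized profiles
#'
#' Alternating optimization of the fuzzy c-means objective
#' `sum_g sum_j u[g,j]^m ||x_g - c_j||^2` with Euclidean distance: membership
#' update from centroid distances, centroid update as membership^m-weighted
#' means. Runs `n_restarts` random initializations (centroids seeded from
#' distinct profile rows) and keeps the best objective. Deterministic given
#' `seed`.
#'
#' @param profiles Standardized profile matrix.
#' @param k Number of clusters (2 <= k < number of profiles).
#' @param m Fuzzifier (> 1); see [estimate_fuzzifier()].
#' @param seed Integer seed for the restarts.
#' @param n_restarts Number of random restarts (default 10).
#' @param tol Convergence tolerance on the maximum centroid coordinate
#'   change per iteration (default 1e-8).
#' @param max_iter Iteration cap per restart (default 1000).
#' @return Object of class `"fcm"`: list with `k`, `m`, `centroids` (k x D),
#'   `memberships` (genes x k, rows sum to 1), `objective`, `seed`,
#'   `converged`, `stage_order`.
#' @export
fit_fcm <- function(profiles, k, m, seed = 1, n_restarts = 10,
                    tol = 1e-8, max_iter = 1000) {
  x <- unclass(profiles)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < number of profiles")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- x[sample.int(n, k), , drop = FALSE]
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        u <- .fcm_memberships(.sqdist(x, centers), m)
        um <- u^m
        new_centers <- (t(um) %*% x) / colSums(um)
        delta <- max(abs(new_centers - centers))
        centers <- new_centers
        if (delta < tol) {
          converged <- TRUE
          break
        }
      }
      if (!converged) warning("fit_fcm: restart did not converge; best iterate kept")
      d2 <- .sqdist(x, centers)
      obj <- sum(.fcm_memberships(d2, m)^m * pmax(d2, 0))
      if (is.null(best) || obj < best$objective) {
        u <- .fcm_memberships(d2, m)
        best <- list(centers = centers, u = u, objective = obj, converged = converged)
      }
    }
  })
  rownames(best$centers) <- paste0("cluster", seq_len(k))
  colnames(best$centers) <- colnames(x)
  dimnames(best$u) <- list(rownames(x), rownames(best$centers))
  structure(list(k = k, m = m, centroids = best$centers, memberships = best$u,
                 objective = best$objective, seed = seed,
                 converged = best$converged, stage_order = colnames(x)),
            class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("fuzzy c-means model: k = %d, m = %.3f, objective = %.6g\n",
              x$k, x$m, x$objective))
  cat(sprintf("%d profiles over stages: %s\n", nrow(x$memberships),
              paste(x$stage_order, collapse = ", ")))
  invisible(x)
}

#' Select the cluster number by centroid correlation
#'
#' Scans k ascending over `k_range`, fitting an FCM model at each k, and
#' returns the largest k for which no pair of centroids has Pearson
#' correlation at or above `r_max` (the scan stops at the first violating k).
#' If even the smallest k violates, that k is returned with a warning.
#'
#' @param profiles Standardized profile matrix.
#' @param m Fuzzifier.
#' @param r_max Centroid-correlation ceiling (default 0.85).
#' @param k_range Candidate cluster numbers (default 2:10, ascending).
#' @param seed,n_restarts Passed to [fit_fcm()].
#' @return List with `k` (selected), `model` (the fitted model at that k),
#'   and `max_r` (named vector of max pairwise centroid correlation per
#'   scanned k).
#' @export
select_cluster_number <- function(profiles, m, r_max = 0.85, k_range = 2:10,
                                  seed = 1, n_restarts = 10) {
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 2), all(k_range <= 20))
  chosen <- NULL; chosen_model <- NULL
  max_r <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  for (k in k_range) {
    fit <- fit_fcm(profiles, k, m, seed = seed, n_restarts = n_restarts)
    cc <- stats::cor(t(fit$centroids))
    mr <- max(cc[upper.tri(cc)])
    max_r[as.character(k)] <- mr
    if (mr >= r_max) {
      if (is.null(chosen)) {
        warning(sprintf("even k = %d violates the centroid-correlation ceiling", k))
        chosen <- k; chosen_model <- fit
      }
      break
    }
    chosen <- k; chosen_model <- fit
  }
  list(k = chosen, model = chosen_model, max_r = max_r[!is.na(max_r)])
}

#' Map profiles onto a fitted cluster model
#'
#' Computes fuzzy memberships of (new) standardized profiles against the
#' model's fixed centroids using the FCM membership formula with the model's
#' fuzzifier; centroids are not refit. Hard assignment is the membership
#' argmax, ties broken toward the lowest cluster index and flagged.
#'
#' @param model An `"fcm"` object.
#' @param profiles Standardized profile matrix on the same stages.
#' @return data.frame: `gene_id`, `cluster` (integer), `max_membership`,
#'   `tie` (logical); plus a `memberships` attribute (genes x k matrix).
#' @export
map_memberships <- function(model, profiles) {
  if (!identical(colnames(profiles), model$stage_order)) {
    stop("profile stages do not match the model's stage order")
  }
  u <- .fcm_memberships(.sqdist(unclass(profiles), model$centroids), model$m)
  hard <- apply(u, 1, which.max)  # which.max ties -> lowest index
  mx <- u[cbind(seq_len(nrow(u)), hard)]
  tie <- apply(u, 1, function(r) sum(abs(r - max(r)) < 1e-9) > 1)
  out <- data.frame(gene_id = rownames(profiles), cluster = as.integer(hard),
                    max_membership = mx, tie = tie,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "memberships") <- u
  out
}

#' @export
predict.fcm <- function(object, newdata, ...) {
  map_memberships(object, newdata)
}

#' Order clusters by developmental timing
#'
#' Returns the rank of each cluster when clusters are sorted by the stage
#' index at which their centroid peaks (early expression first); used to lay
#' out cluster-switch matrices from early to late.
#'
#' @param model An `"fcm"` object.
#' @return Integer vector: `order_index[j]` is cluster j's early-to-late rank.
#' @export
cluster_stage_order <- function(model) {
  peak <- apply(model$centroids, 1, which.max)
  # tie-break equal peaks by the centroid's center of mass over stages
  w <- model$centroids - apply(model$centroids, 1, min)
  com <- as.numeric(w %*% seq_along(model$stage_order)) / rowSums(w + 1e-12)
  as.integer(rank(peak + 1e-3 * com, ties.method = "first"))
}

#' Serialize / restore a cluster model as JSON
#'
#' @param model An `"fcm"` object.
#' @param path Output JSON path.
#' @return `path` (write) or the restored `"fcm"` object (read). Memberships
#'   are not serialized; re-derive them with [map_memberships()].
#' @export
write_cluster_model <- function(model, path) {
  obj <- list(k = model$k, m = model$m, seed = model$seed,
              centroids = lapply(seq_len(model$k),
                                 function(j) unname(model$centroids[j, ])),
              stage_order = model$stage_order, objective = model$objective)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- if (is.list(obj$centroids)) do.call(rbind, obj$centroids) else
    obj$centroids
  dimnames(centroids) <- list(paste0("cluster", seq_len(obj$k)), obj$stage_order)
  structure(list(k = obj$k, m = obj$m, centroids = centroids,
                 memberships = NULL, objective = obj$objective,
                 seed = obj$seed, converged = NA, stage_order = obj$stage_order),
            class = "fcm")
}
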