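# Independent brute-force reference implementations used as oracles.
# These are written directly from the defining formulas and share no code
# with the package internals.

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} ( p_(j) * n / j ), capped at 1
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# median-of-ratios size factors from the definition, geometric mean 1
oracle_size_factors <- function(counts) {
  geo <- apply(counts, 1, function(x) exp(mean(log(x))))
  use <- geo > 0 & is.finite(geo)
  s <- apply(counts, 2, function(col) median(col[use] / geo[use]))
  s / exp(mean(log(s)))
}

# Pearson correlation from the defining sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# plain-loop fuzzy c-means alternating optimization from the update formulas;
# started from given centers, run to a tight fixed point
oracle_fcm <- function(x, centers, m, iters = 2000, tol = 1e-14) {
  k <- nrow(centers)
  for (it in seq_len(iters)) {
    d2 <- matrix(0, nrow(x), k)
    for (j in seq_len(k)) {
      d2[, j] <- rowSums(sweep(x, 2, centers[j, ])^2)
    }
    u <- matrix(0, nrow(x), k)
    for (g in seq_len(nrow(x))) {
      if (any(d2[g, ] < 1e-12)) {
        u[g, which.min(d2[g, ])] <- 1
      } else {
        for (j in seq_len(k)) {
          u[g, j] <- 1 / sum((d2[g, j] / d2[g, ])^(1 / (m - 1)))
        }
      }
    }
    new_centers <- centers
    for (j in seq_len(k)) {
      w <- u[, j]^m
      new_centers[j, ] <- colSums(w * x) / sum(w)
    }
    if (max(abs(new_centers - centers)) < tol) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  obj <- 0
  d2 <- matrix(0, nrow(x), k)
  for (j in seq_len(k)) d2[, j] <- rowSums(sweep(x, 2, centers[j, ])^2)
  for (g in seq_len(nrow(x))) {
    for (j in seq_len(k)) {
      uu <- if (any(d2[g, ] < 1e-12)) as.numeric(j == which.min(d2[g, ])) else
        1 / sum((d2[g, j] / d2[g, ])^(1 / (m - 1)))
      obj <- obj + uu^m * d2[g, j]
    }
  }
  list(centers = centers, objective = obj, u = u)
}

# direct Table-1 style morph-specific rule on per-stage flag counts:
# >=3 above threshold at some stage in one morph, <=1 total in the other
oracle_morph_specific <- function(pp_counts_by_stage, ll_counts_by_stage) {
  p_on <- any(pp_counts_by_stage >= 3)
  l_on <- any(ll_counts_by_stage >= 3)
  p_quiet <- sum(pp_counts_by_stage) <= 1
  l_quiet <- sum(ll_counts_by_stage) <= 1
  if (p_on && l_quiet && !(l_on && p_quiet)) return("P-specific")
  if (l_on && p_quiet && !(p_on && l_quiet)) return("L-specific")
  "neither"
}
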