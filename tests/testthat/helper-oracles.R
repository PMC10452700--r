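# Independent brute-force / closed-form oracles used to cross-check the
# implementation. These deliberately avoid the code paths they verify.

# O(n^2) KS distance: evaluate both ECDFs at every sample point.
brute_ks_distance <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# Exact Mann-Whitney two-sided p by full enumeration of all C(n1+n2, n1)
# group assignments of the pooled ranks.
enum_mann_whitney <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  splits <- utils::combn(length(r), n1)
  u_dist <- apply(splits, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- min(1, 2 * min(mean(u_dist <= u_obs), mean(u_dist >= u_obs)))
  list(U = u_obs, p = p)
}

# Normal-approximation Mann-Whitney p with midranks, tie-corrected variance
# and continuity correction, written out from the textbook formulas.
normal_mann_whitney_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  2 * stats::pnorm(-z)
}

# Closed-form simple OLS via the normal equations.
ols_closed_form <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope,
       intercept = mean(y) - slope * mean(x),
       r_squared = sxy^2 / (sxx * syy))
}

# Naive per-voxel loops for ROI statistics and threshold classification.
brute_roi_stats <- function(suv, mask) {
  vals <- numeric(0)
  for (i in seq_along(suv)) if (mask[i]) vals <- c(vals, suv[i])
  list(mean = mean(vals), sd = stats::sd(vals), max = max(vals),
       n = length(vals))
}

brute_classify <- function(suv, tumor_mask, threshold) {
  prolif <- logical(length(suv))
  for (i in seq_along(suv)) {
    prolif[i] <- tumor_mask[i] && suv[i] >= threshold
  }
  array(prolif, dim(suv))
}

# A small phantom used by several tests.
small_phantom <- function(seed = 1L, ...) {
  generate_phantom(phantom_spec(seed = seed, grid_shape = c(20L, 20L, 20L),
                                ...))
}
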