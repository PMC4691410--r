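# Independent oracles and small fixture builders used across the suite.

# Exhaustive Holm step-down: sort ascending, reject while p(k) < alpha/(m-k+1),
# stop at the first failure, map flags back to input order.
holm_stepdown_reference <- function(p, alpha = 0.05, m = length(p)) {
  ord <- order(p)
  reject <- logical(length(p))
  for (k in seq_along(ord)) {
    if (p[ord[k]] < alpha / (m - k + 1)) reject[ord[k]] <- TRUE else break
  }
  reject
}

# Direct O(N*K) 2-D convolution of each slice with an explicit truncated,
# unit-sum Gaussian kernel; brute-force double loop over kernel offsets.
blur2d_direct <- function(mask, fwhm_mm, voxel_size_mm, truncate = 4) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(truncate * sigma))
  off <- seq(-r, r)
  k1 <- dnorm(off, sd = sigma); k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  d <- dim(mask)
  out <- array(0, dim = d)
  m <- array(as.numeric(mask != 0), dim = d)
  for (z in seq_len(d[3])) for (i in seq_along(off)) for (j in seq_along(off)) {
    di <- off[i]; dj <- off[j]
    xs <- seq_len(d[1]); ys <- seq_len(d[2])
    xok <- xs + di >= 1 & xs + di <= d[1]
    yok <- ys + dj >= 1 & ys + dj <= d[2]
    out[xs[xok], ys[yok], z] <- out[xs[xok], ys[yok], z] +
      kern[i, j] * m[xs[xok] + di, ys[yok] + dj, z]
  }
  out
}

# Two-region scan-table specs on a reduced region set, handy for fast tests.
tiny_trajectories <- function(regions = c("cuneus", "insula"),
                              residual_sd = c(thickness_mm = 0.1,
                                              cortical_mwf = 0.01,
                                              adjacent_mwf = 0.01)) {
  trajectory_specs(regions = regions, hemispheres = "left",
                   residual_sd = residual_sd)
}

tiny_couplings <- function(regions = c("cuneus", "insula"), ...) {
  coupling_specs(regions = regions, hemispheres = "left", ...)
}

small_cohort_spec <- function(n_children = 40) {
  cohort_spec(n_children = n_children, n_repeat2 = 5, n_repeat3 = 2)
}
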