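## Independent brute-force oracles used across the suite.

## set-definition morphology: a voxel survives erosion iff every
## element offset from it lands on foreground inside the volume;
## dilation marks every in-volume voxel reachable from foreground.
brute_erode <- function(arr, elem) {
  d <- dim(arr)
  out <- array(FALSE, d)
  fg <- which(arr, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    ok <- TRUE
    for (k in seq_len(nrow(elem))) {
      p <- fg[r, ] + elem[k, ]
      if (any(p < 1L) || any(p > d) || !arr[p[1], p[2], p[3]]) {
        ok <- FALSE; break
      }
    }
    out[fg[r, 1], fg[r, 2], fg[r, 3]] <- ok
  }
  out
}

brute_dilate <- function(arr, elem) {
  d <- dim(arr)
  out <- array(FALSE, d)
  fg <- which(arr, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    for (k in seq_len(nrow(elem))) {
      p <- fg[r, ] + elem[k, ]
      if (all(p >= 1L) && all(p <= d)) out[p[1], p[2], p[3]] <- TRUE
    }
  }
  out
}

## exhaustive grid search for the least-squares (delta_chi, chi_iso)
grid_search_ols <- function(theta_deg, chi, centre, half_width = 0.5,
                            step = 0.01) {
  c2 <- cos(theta_deg * pi / 180)^2
  dg <- seq(centre[1] - half_width, centre[1] + half_width, by = step)
  cg <- seq(centre[2] - half_width, centre[2] + half_width, by = step)
  best <- c(NA, NA); best_sse <- Inf
  for (d in dg) {
    r0 <- chi - d * c2
    sse <- colSums((outer(r0, cg, "-"))^2)
    j <- which.min(sse)
    if (sse[j] < best_sse) { best_sse <- sse[j]; best <- c(d, cg[j]) }
  }
  best
}

## tiny study configuration for fast MCMC tests
tiny_config <- function(n_hc = 10, n_ms = 12, voxels = 120, seed = 11,
                        rois = default_roi_params()["OR"]) {
  generator_config(n_hc = n_hc, n_ms = n_ms, voxels_per_roi = voxels,
                   rois = rois, seed = seed)
}

## empirical KS distance against an analytic CDF
ks_distance <- function(x, cdf) {
  x <- sort(x); n <- length(x)
  f <- cdf(x)
  max(abs(f - seq_len(n) / n), abs(f - (seq_len(n) - 1) / n))
}
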