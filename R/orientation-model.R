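#' Apparent susceptibility of a radially symmetric fibre tensor
#'
#' For a fibre whose susceptibility tensor has components `chi_par`
#' along and `chi_perp` across the fibre axis, the apparent (scalar)
#' susceptibility recovered from a single orientation varies with the
#' fibre-to-field angle theta as
#' `(chi_par - chi_perp) * cos^2(theta) + chi0`, where `chi0` subsumes
#' every orientation-independent contribution.
#'
#' @param chi_par,chi_perp tensor components, ppb.
#' @param chi0 orientation-independent offset, ppb.
#' @param theta_deg fibre-to-field angle(s) in degrees, in \[0, 90\].
#' @return Apparent susceptibility in ppb, vectorized over `theta_deg`.
#' @examples
#' apparent_from_tensor(10, 2, -40, c(0, 90))
#' @export
apparent_from_tensor <- function(chi_par, chi_perp, chi0, theta_deg) {
  if (any(theta_deg < 0 | theta_deg > 90))
    stop("'theta_deg' must lie in [0, 90] degrees")
  (chi_par - chi_perp) * cos(theta_deg * pi / 180)^2 + chi0
}

#' Fold an angle into the fibre-to-field range
#'
#' Fibre axes are antipodally symmetric, so any orientation angle in
#' degrees is identified with its mirror images and mapped into
#' \[0, 90\].
#'
#' @param theta_deg angles in degrees (any real values).
#' @return Angles in \[0, 90\] degrees.
#' @export
fold_angle <- function(theta_deg) {
  x <- abs(theta_deg) %% 180
  ifelse(x > 90, 180 - x, x)
}

#' Per-subject estimation of apparent anisotropy and isotropic AMS
#'
#' Ordinary least squares of apparent susceptibility on
#' `cos^2(theta)` with intercept, over one subject's voxels in one
#' tract: the slope is the apparent magnetic susceptibility anisotropy
#' `delta_chi`, the intercept the isotropic component `chi_iso`.
#'
#' @param voxels voxel table for a single subject and ROI with columns
#'   `theta_deg` and `chi_app_ppb` (optional `subject_id`, `roi` are
#'   carried through).
#' @return One-row data frame: `subject_id`, `roi`, `delta_chi`,
#'   `chi_iso`, `n_voxels`, `residual_sd` (`NA` when there are no
#'   residual degrees of freedom).
#' @export
fit_subject_regression <- function(voxels) {
  stopifnot(all(c("theta_deg", "chi_app_ppb") %in% names(voxels)))
  n <- nrow(voxels)
  if (n < 2L) stop("at least 2 voxels are required")
  c2 <- cos(voxels$theta_deg * pi / 180)^2
  if (length(unique(voxels$theta_deg)) < 2L ||
      diff(range(c2)) < .Machine$double.eps^0.5)
    stop("all fibre-to-field angles coincide: delta_chi is not ",
         "estimable from a single angle")
  fit <- lm.fit(cbind(intercept = 1, cos2 = c2), voxels$chi_app_ppb)
  rss <- sum(fit$residuals^2)
  data.frame(
    subject_id = if ("subject_id" %in% names(voxels))
      voxels$subject_id[1] else NA_character_,
    roi = if ("roi" %in% names(voxels)) voxels$roi[1] else NA_character_,
    delta_chi = unname(fit$coefficients["cos2"]),
    chi_iso = unname(fit$coefficients["intercept"]),
    n_voxels = n,
    residual_sd = if (n > 2L) sqrt(rss / (n - 2L)) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Fit every subject-by-ROI cell of a voxel table
#'
#' @param voxels voxel table with `subject_id`, `roi`, `theta_deg`,
#'   `chi_app_ppb`.
#' @return Data frame of [fit_subject_regression()] rows.
#' @export
fit_all_subjects <- function(voxels) {
  stopifnot(all(c("subject_id", "roi") %in% names(voxels)))
  cells <- split(voxels, list(voxels$roi, voxels$subject_id), drop = TRUE)
  out <- do.call(rbind, lapply(cells, fit_subject_regression))
  out <- out[order(out$roi, out$subject_id), ]
  rownames(out) <- NULL
  out
}

#' Equally populated angle-decile bins
#'
#' Partitions one subject's tract voxels into `n_bins` bins of (as
#' near as possible) equal population by the order statistics of
#' theta; remainder voxels go to the lowest bins, and ties are kept in
#' stable sort order. Used for AMS(theta) curves.
#'
#' @param voxels voxel table with `theta_deg`, `chi_app_ppb`.
#' @param n_bins number of bins (default 10, i.e. deciles).
#' @return Data frame with one row per bin: `bin`, `n`, `mean_theta`,
#'   `mean_chi`, `theta_min`, `theta_max`; the theta deciles are
#'   attached as attribute `"bin_edges"`.
#' @export
bin_by_angle_deciles <- function(voxels, n_bins = 10L) {
  stopifnot(all(c("theta_deg", "chi_app_ppb") %in% names(voxels)))
  n <- nrow(voxels)
  if (n < n_bins)
    stop("need at least as many voxels (", n, ") as bins (", n_bins, ")")
  ord <- order(voxels$theta_deg)  # stable
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bin <- rep(seq_len(n_bins), sizes)
  th <- voxels$theta_deg[ord]; ch <- voxels$chi_app_ppb[ord]
  out <- data.frame(
    bin = seq_len(n_bins), n = sizes,
    mean_theta = as.numeric(tapply(th, bin, mean)),
    mean_chi = as.numeric(tapply(ch, bin, mean)),
    theta_min = as.numeric(tapply(th, bin, min)),
    theta_max = as.numeric(tapply(th, bin, max))
  )
  attr(out, "bin_edges") <- unname(quantile(voxels$theta_deg,
                                            seq(0, 1, length.out = n_bins + 1)))
  out
}

#' Standardize apparent susceptibility within each ROI
#'
#' Demeans and scales `chi_app_ppb` by its pooled standard deviation
#' across all subjects, independently per ROI, storing the affine
#' parameters so that model coefficients can be mapped back to ppb.
#'
#' @param voxels voxel table with `roi` and `chi_app_ppb`.
#' @return List: `voxels` (input plus a `chi_app_std` column) and
#'   `params` (data frame `roi`, `mean`, `sd`).
#' @export
standardize_ams <- function(voxels) {
  stopifnot(all(c("roi", "chi_app_ppb") %in% names(voxels)))
  params <- do.call(rbind, lapply(split(voxels$chi_app_ppb, voxels$roi),
    function(x) data.frame(mean = mean(x), sd = sd(x))))
  params <- data.frame(roi = rownames(params), params,
                       stringsAsFactors = FALSE)
  rownames(params) <- NULL
  if (any(!is.finite(params$sd)) || any(params$sd <= 0))
    stop("apparent susceptibility has zero variance in some ROI; ",
         "standardization is undefined")
  i <- match(voxels$roi, params$roi)
  voxels$chi_app_std <- (voxels$chi_app_ppb - params$mean[i]) / params$sd[i]
  list(voxels = voxels, params = params)
}

#' Map standardized-scale coefficients back to ppb
#'
#' Slope-like quantities (anisotropy means and slopes, covariate
#' effects, SDs, noise) scale by the ROI standard deviation;
#' location-like quantities (isotropic means and subject levels)
#' additionally shift by the ROI mean.
#'
#' @param value numeric coefficient(s) on the standardized scale.
#' @param params one row of [standardize_ams()] `params` (or the full
#'   table plus `roi`).
#' @param type `"slope"` (or `"scale"`) for pure rescaling,
#'   `"location"` for rescale-and-shift.
#' @param roi ROI name, required when `params` has several rows.
#' @return Coefficients in ppb.
#' @export
rescale_coefficients <- function(value, params,
                                 type = c("slope", "scale", "location"),
                                 roi = NULL) {
  type <- match.arg(type)
  if (nrow(params) > 1L) {
    if (is.null(roi)) stop("give 'roi' to select a standardization row")
    params <- params[params$roi == roi, , drop = FALSE]
    if (nrow(params) != 1L) stop("unknown ROI: ", roi)
  }
  if (type == "location") value * params$sd + params$mean
  else value * params$sd
}
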