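#' Highest density interval of a sample
#'
#' The narrowest contiguous interval containing `ceiling(mass * n)` of
#' the `n` sorted draws — for unimodal posteriors, the Bayesian
#' analogue of a confidence interval. Width ties are broken toward the
#' lower interval start (the uniform-density edge case is positionally
#' ambiguous).
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param mass probability mass in (0, 1), default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' hdi(rnorm(1e4))
#' @export
hdi <- function(draws, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1)
    stop("'mass' must lie strictly between 0 and 1")
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100L) stop("hdi() needs at least 100 draws")
  s <- sort(draws)
  k <- ceiling(mass * n)
  starts <- seq_len(n - k + 1L)
  widths <- s[starts + k - 1L] - s[starts]
  i <- which.min(widths)  # which.min takes the first (lowest) minimum
  c(lower = s[i], upper = s[i + k - 1L])
}

#' Maximum a posteriori estimate from draws
#'
#' Mode of a Gaussian-kernel density estimate of the marginal draws
#' (Silverman rule-of-thumb bandwidth, 4096-point grid), refined by
#' the vertex of a quadratic fitted to the contiguous top 4% of the
#' density curve around its argmax. The quadratic refinement averages
#' out the argmax jitter of flat-topped densities without widening
#' the kernel (which would bias the mode of skewed ones); if the
#' vertex falls outside the fitted window the raw argmax is returned.
#' Constant draws return the constant.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @return The estimated posterior mode.
#' @export
map_estimate <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100L) stop("map_estimate() needs at least 100 draws")
  if (diff(range(draws)) == 0) return(draws[1])
  d <- density(draws, bw = "nrd0", n = 4096L)
  j <- which.max(d$y)
  i <- which(d$y >= 0.96 * d$y[j])
  runs <- split(i, cumsum(c(1L, diff(i) != 1L)))
  i <- runs[[which(vapply(runs, function(r) j %in% r, TRUE))]]
  if (length(i) < 5L) return(d$x[j])
  xs <- d$x[i]; ys <- d$y[i]
  co <- stats::coef(stats::lm.fit(cbind(1, xs, xs^2), ys))
  vertex <- -co[2] / (2 * co[3])
  if (!is.finite(vertex) || co[3] >= 0 ||
      vertex < min(xs) || vertex > max(xs)) d$x[j] else unname(vertex)
}

#' Posterior probability above zero
#'
#' Proportion of draws strictly greater than zero (draws equal to zero
#' count as not-above).
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @return Fraction in \[0, 1\].
#' @export
prob_above_zero <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100L) stop("prob_above_zero() needs at least 100 draws")
  mean(draws > 0)
}

#' Posterior of the standardized cohort effect size
#'
#' Per posterior draw, the cohort-mean difference scaled by the pooled
#' cohort SD, `eta = (mu_MS - mu_HC) / sqrt((sigma_MS^2 + sigma_HC^2)/2)`,
#' computed jointly for the isotropic component and the apparent
#' anisotropy. Using each joint draw preserves the dependence between
#' means and SDs; the result is invariant under a common rescaling of
#' both cohorts' parameters.
#'
#' @param post an `msa_posterior` with both cohorts (or a draws matrix
#'   with the `mu_*`/`sigma_*` columns).
#' @return Matrix of per-draw effect sizes, columns `eta_iso`,
#'   `eta_dchi`.
#' @export
effect_size_posterior <- function(post) {
  m <- if (is.matrix(post)) post else as_draws_matrix(post)
  need <- c("mu_iso[HC]", "mu_iso[MS]", "sigma_iso[HC]", "sigma_iso[MS]",
            "mu_dchi[HC]", "mu_dchi[MS]", "sigma_dchi[HC]", "sigma_dchi[MS]")
  if (!all(need %in% colnames(m)))
    stop("effect sizes require joint draws of both cohorts' mu and sigma")
  if (any(m[, grepl("^sigma_", colnames(m))] <= 0))
    stop("non-positive sigma draws: upstream invariant violated")
  eta <- function(comp) {
    (m[, sprintf("mu_%s[MS]", comp)] - m[, sprintf("mu_%s[HC]", comp)]) /
      sqrt((m[, sprintf("sigma_%s[MS]", comp)]^2 +
            m[, sprintf("sigma_%s[HC]", comp)]^2) / 2)
  }
  cbind(eta_iso = eta("iso"), eta_dchi = eta("dchi"))
}

#' Summary table of a fitted posterior
#'
#' MAP estimate, HDI, probability above zero and convergence
#' diagnostics for each (by default population-level) parameter, plus
#' the effect-size rows when both cohorts are present.
#'
#' @param post an `msa_posterior`.
#' @param mass HDI probability mass (default 0.95).
#' @param include_subjects also summarize subject-level components.
#' @return Data frame: `roi`, `parameter`, `map`, `hdi_low`,
#'   `hdi_high`, `prob_above_zero`, `rhat`, `ess`.
#' @export
summarize_posterior <- function(post, mass = 0.95,
                                include_subjects = FALSE) {
  stopifnot(inherits(post, "msa_posterior"))
  m <- as_draws_matrix(post)
  keep <- colnames(m)
  if (!include_subjects) keep <- keep[!grepl("_subj\\[", keep)]
  if (length(post$cohorts) == 2L) {
    es <- effect_size_posterior(post)
    m <- cbind(m[, keep, drop = FALSE], es)
    keep <- c(keep, colnames(es))
  } else m <- m[, keep, drop = FALSE]
  dg <- post$diagnostics
  out <- do.call(rbind, lapply(keep, function(p) {
    h <- hdi(m[, p], mass)
    data.frame(roi = post$roi, parameter = p,
               map = map_estimate(m[, p]),
               hdi_low = unname(h[1]), hdi_high = unname(h[2]),
               prob_above_zero = prob_above_zero(m[, p]),
               rhat = if (p %in% dg$parameter)
                 dg$rhat[dg$parameter == p] else NA_real_,
               ess = if (p %in% dg$parameter)
                 dg$ess[dg$parameter == p] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Report bundle: tables and figures for a fitted analysis
#'
#' Writes, per ROI, the subject-level AMS(theta) decile curves, the
#' marginal posterior densities of the population parameters annotated
#' with MAP and HDI, and (when both cohorts are present) the
#' effect-size densities; plus a combined summary table as TSV and
#' JSON. ROIs missing from some input are skipped with a warning.
#'
#' @param fits subject-level OLS fits ([fit_all_subjects()]).
#' @param curves binned decile curves: data frame with `subject_id`,
#'   `roi` and [bin_by_angle_deciles()] columns (see
#'   [binned_curves_table()]).
#' @param posteriors named list of `msa_posterior` objects by ROI.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the summary data frame.
#' @export
render_report <- function(fits, curves, posteriors, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rois <- names(posteriors)
  summaries <- do.call(rbind, lapply(rois, function(roi)
    summarize_posterior(posteriors[[roi]])))
  write.table(summaries, file.path(out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summaries, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (roi in rois) {
    if (!is.null(curves) && !roi %in% curves$roi) {
      warning("no binned curves for ROI ", roi, "; skipping its figure")
    } else if (!is.null(curves)) {
      cc <- curves[curves$roi == roi, ]
      p <- ggplot2::ggplot(cc, ggplot2::aes(x = .data$mean_theta,
                                            y = .data$mean_chi,
                                            group = .data$subject_id,
                                            colour = .data$cohort)) +
        ggplot2::geom_line(alpha = 0.35) +
        ggplot2::labs(x = expression(theta ~ "(deg)"),
                      y = expression(chi[app] ~ "(ppb)"),
                      title = paste0("AMS orientation dependence - ", roi)) +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(out_dir, paste0("curves_", roi, ".png")),
                      p, width = 6, height = 4, dpi = 120)
    }
    ss <- summaries[summaries$roi == roi, ]
    m <- as_draws_matrix(posteriors[[roi]])
    pars <- intersect(ss$parameter, colnames(m))
    dd <- do.call(rbind, lapply(pars, function(pp)
      data.frame(parameter = pp, value = m[, pp])))
    ann <- ss[ss$parameter %in% pars, ]
    p2 <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_density(fill = "grey80") +
      ggplot2::geom_vline(data = ann,
                          ggplot2::aes(xintercept = .data$map),
                          linetype = "dashed") +
      ggplot2::geom_segment(data = ann,
                            ggplot2::aes(x = .data$hdi_low,
                                         xend = .data$hdi_high,
                                         y = 0, yend = 0),
                            linewidth = 1.2) +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = "ppb (effect sizes unitless)", y = NULL,
                    title = paste0("Marginal posteriors - ", roi)) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out_dir, paste0("posterior_", roi, ".png")),
                    p2, width = 9, height = 7, dpi = 120)
  }
  invisible(summaries)
}

#' Binned AMS(theta) curves for every subject and ROI
#'
#' @param voxels voxel table (`subject_id`, `roi`, `theta_deg`,
#'   `chi_app_ppb`).
#' @param n_bins bins per subject curve (default 10).
#' @return Long data frame of [bin_by_angle_deciles()] rows with
#'   `subject_id`, `cohort` (if present) and `roi` attached.
#' @export
binned_curves_table <- function(voxels, n_bins = 10L) {
  cells <- split(voxels, list(voxels$roi, voxels$subject_id), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(v) {
    b <- bin_by_angle_deciles(v, n_bins)
    b$subject_id <- v$subject_id[1]
    b$roi <- v$roi[1]
    if ("cohort" %in% names(v)) b$cohort <- v$cohort[1]
    b
  }))
  rownames(out) <- NULL
  out
}
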