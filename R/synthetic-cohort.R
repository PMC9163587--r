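#' Per-tract generating parameters for the synthetic cohort
#'
#' Holds the generative truth for one tract (region of interest):
#' the fibre-orientation profile, the cohort-level normal distributions
#' of the subject-specific isotropic component (`chi_iso`) and apparent
#' anisotropy (`delta_chi`), the population-level covariate effects,
#' and the lesion-load distribution for patients. All susceptibility
#' values are in ppb.
#'
#' Covariate effects follow the multilevel analysis model: `beta_*` is
#' the shared effect of age (at onset), in ppb per decade of
#' age referenced to 30 years; `tau_*` the patient-cohort effect of
#' disease duration in ppb per decade; `lambda_*` the patient-cohort
#' effect of lesion load in ppb per unit lesion-load fraction (so a
#' value of -30 is -3 ppb per 10% lesion load).
#'
#' @param profile an [angle_profile()].
#' @param mu_iso,mu_dchi named numeric `c(HC=, MS=)` cohort means, ppb.
#' @param sigma_iso,sigma_dchi named numeric `c(HC=, MS=)` cohort SDs,
#'   ppb, `>= 0`.
#' @param beta_iso,beta_dchi age (at onset) effects, ppb per decade.
#' @param tau_iso,tau_dchi disease-duration effects (MS only), ppb per
#'   decade.
#' @param lambda_iso,lambda_dchi lesion-load effects (MS only), ppb per
#'   unit fraction.
#' @param lesion_zero probability of a lesion-free tract in an MS
#'   subject (zero inflation).
#' @param lesion_shape1,lesion_shape2 Beta shape parameters of the
#'   nonzero lesion-load fraction.
#' @return An object of class `roi_params`.
#' @export
roi_params <- function(profile,
                       mu_iso, mu_dchi, sigma_iso, sigma_dchi,
                       beta_iso = 0, beta_dchi = 0,
                       tau_iso = 0, tau_dchi = 0,
                       lambda_iso = 0, lambda_dchi = 0,
                       lesion_zero = 0.3,
                       lesion_shape1 = 1.5, lesion_shape2 = 15) {
  as_cohort <- function(x, what) {
    if (length(x) == 1L) x <- c(HC = unname(x), MS = unname(x))
    if (is.null(names(x)) && length(x) == 2L) names(x) <- c("HC", "MS")
    if (!all(c("HC", "MS") %in% names(x)))
      stop("'", what, "' must be named c(HC=, MS=)")
    x[c("HC", "MS")]
  }
  mu_iso <- as_cohort(mu_iso, "mu_iso")
  mu_dchi <- as_cohort(mu_dchi, "mu_dchi")
  sigma_iso <- as_cohort(sigma_iso, "sigma_iso")
  sigma_dchi <- as_cohort(sigma_dchi, "sigma_dchi")
  if (any(sigma_iso < 0) || any(sigma_dchi < 0))
    stop("cohort SDs must be non-negative")
  stopifnot(inherits(profile, "angle_profile"),
            lesion_zero >= 0, lesion_zero <= 1,
            lesion_shape1 > 0, lesion_shape2 > 0)
  structure(list(profile = profile,
                 mu_iso = mu_iso, mu_dchi = mu_dchi,
                 sigma_iso = sigma_iso, sigma_dchi = sigma_dchi,
                 beta_iso = beta_iso, beta_dchi = beta_dchi,
                 tau_iso = tau_iso, tau_dchi = tau_dchi,
                 lambda_iso = lambda_iso, lambda_dchi = lambda_dchi,
                 lesion_zero = lesion_zero,
                 lesion_shape1 = lesion_shape1,
                 lesion_shape2 = lesion_shape2),
            class = "roi_params")
}

#' Default tract parameters for the three analysed ROIs
#'
#' Study-condition defaults for the optic radiation (OR), splenium of
#' the corpus callosum (SCC) and superior longitudinal fascicle (SLF):
#' a narrow nearly-perpendicular angle profile in SCC, a moderate one
#' in OR and a broad one in SLF; positive apparent anisotropy in OR
#' (27 ppb in controls) and SCC (21 ppb) with the widest subject spread
#' in SCC, and a robustly negative value in SLF (-30 ppb); isotropic
#' components ranked OR < SCC < SLF; the patient OR mean placed 0.6
#' pooled SDs below the control mean; age, disease-duration and
#' lesion-load effects of a few ppb per scaled unit, with the
#' disease-duration effect on anisotropy concentrated in SCC and the
#' lesion-load effect in OR; and the heaviest lesion involvement in OR.
#'
#' @return Named list of [roi_params()] for `OR`, `SCC`, `SLF`.
#' @export
default_roi_params <- function() {
  list(
    OR = roi_params(angle_profile(75, 12),
                    mu_iso = c(HC = -40, MS = -38),
                    mu_dchi = c(HC = 27, MS = 21),
                    sigma_iso = c(HC = 5, MS = 5),
                    sigma_dchi = c(HC = 10, MS = 10),
                    beta_iso = 3, beta_dchi = -2,
                    tau_iso = 1, tau_dchi = 0,
                    lambda_iso = 20, lambda_dchi = -30,
                    lesion_zero = 0.2,
                    lesion_shape1 = 1.5, lesion_shape2 = 12),
    SCC = roi_params(angle_profile(90, 25),
                     mu_iso = c(HC = -35, MS = -33),
                     mu_dchi = c(HC = 21, MS = 12),
                     sigma_iso = c(HC = 5, MS = 5),
                     sigma_dchi = c(HC = 30, MS = 30),
                     beta_iso = 5, beta_dchi = -5,
                     tau_iso = 1, tau_dchi = -10,
                     lambda_iso = -10, lambda_dchi = 5,
                     lesion_zero = 0.5,
                     lesion_shape1 = 1.2, lesion_shape2 = 25),
    SLF = roi_params(angle_profile(40, 5),
                     mu_iso = c(HC = -15, MS = -15),
                     mu_dchi = c(HC = -30, MS = -28),
                     sigma_iso = c(HC = 5, MS = 5),
                     sigma_dchi = c(HC = 10, MS = 10),
                     beta_iso = 1, beta_dchi = 1.5,
                     tau_iso = -1, tau_dchi = 5,
                     lambda_iso = -10, lambda_dchi = 10,
                     lesion_zero = 0.35,
                     lesion_shape1 = 1.3, lesion_shape2 = 20)
  )
}

#' Synthetic cohort generator configuration
#'
#' Study conditions for the synthetic voxel-level dataset: 64 healthy
#' controls and 89 relapsing-remitting MS patients, three tract ROIs,
#' and i.i.d. Gaussian voxel noise added to the cos-squared orientation
#' curve of every subject. Control ages span roughly 24-66 years with
#' median near 30; patient disease durations span 1-32 years with
#' median near 9, and age is age at onset plus duration.
#'
#' @param n_hc,n_ms cohort sizes, `> 0`.
#' @param voxels_per_roi voxels generated per subject and ROI, `> 0`.
#' @param rois named list of [roi_params()].
#' @param voxel_noise_sd SD of the additive voxel noise, ppb, `>= 0`.
#' @param seed master integer seed; the whole dataset is a
#'   deterministic function of the configuration.
#' @return An object of class `generator_config`.
#' @examples
#' cfg <- generator_config(n_hc = 4, n_ms = 4, voxels_per_roi = 50)
#' ds <- generate_cohort_dataset(cfg)
#' head(ds$voxels)
#' @export
generator_config <- function(n_hc = 64, n_ms = 89, voxels_per_roi = 500,
                             rois = default_roi_params(),
                             voxel_noise_sd = 15, seed = 1L) {
  stopifnot(n_hc > 0, n_ms > 0, voxels_per_roi > 0,
            voxel_noise_sd >= 0, length(rois) >= 1)
  if (is.null(names(rois)) || any(names(rois) == ""))
    stop("'rois' must be a named list of roi_params")
  if (!all(vapply(rois, inherits, TRUE, "roi_params")))
    stop("every element of 'rois' must be an roi_params object")
  structure(list(n_hc = as.integer(n_hc), n_ms = as.integer(n_ms),
                 voxels_per_roi = as.integer(voxels_per_roi),
                 rois = rois, voxel_noise_sd = voxel_noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

## truncated samplers used by sample_covariates -----------------------

rtrunc <- function(n, rfun, lo, hi) {
  x <- rfun(n)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rfun(sum(bad))
  x
}

#' Sample subject metadata for both cohorts
#'
#' Draws ages, ages at onset, disease durations and per-ROI lesion-load
#' fractions. Controls have disease duration 0 and lesion load 0 in
#' every ROI by definition; patient age equals age at onset plus
#' disease duration. Durations are gamma-distributed truncated to
#' 1-32 years (median near 9); lesion loads are zero-inflated Beta
#' fractions in \[0, 1\].
#'
#' @param config a [generator_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return Data frame with one row per subject: `subject_id`, `cohort`
#'   (`"HC"`/`"MS"`), `age`, `age_at_onset`, `disease_duration`, and a
#'   `lesion_load.<roi>` column per ROI.
#' @export
sample_covariates <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed(derive_seed(seed, 1L), {
    n_hc <- config$n_hc; n_ms <- config$n_ms
    ## HC ages: shifted gamma, median ~30 y, mean ~34 y, range 24-66
    hc_age <- rtrunc(n_hc, function(n) 24 + rgamma(n, 0.75, scale = 14.7),
                     24, 66)
    ## MS: duration 1-32 y (median ~9); onset ~N(29, 9) in 18-60;
    ## age at examination capped at 65 by joint resampling
    ms_dd <- rtrunc(n_ms, function(n) rgamma(n, 1.5, scale = 7.5), 1, 32)
    ms_ao <- rtrunc(n_ms, function(n) rnorm(n, 29, 9), 18, 60)
    bad <- ms_ao + ms_dd > 65
    while (any(bad)) {
      ms_ao[bad] <- rtrunc(sum(bad), function(n) rnorm(n, 29, 9), 18, 60)
      ms_dd[bad] <- rtrunc(sum(bad), function(n) rgamma(n, 1.5, scale = 7.5),
                           1, 32)
      bad <- ms_ao + ms_dd > 65
    }
    subj <- data.frame(
      subject_id = c(sprintf("HC%03d", seq_len(n_hc)),
                     sprintf("MS%03d", seq_len(n_ms))),
      cohort = rep(c("HC", "MS"), c(n_hc, n_ms)),
      age = c(hc_age, ms_ao + ms_dd),
      age_at_onset = c(hc_age, ms_ao),  # for HCs: age at examination
      disease_duration = c(rep(0, n_hc), ms_dd),
      stringsAsFactors = FALSE
    )
    for (roi in names(config$rois)) {
      rp <- config$rois[[roi]]
      ll <- numeric(n_ms)
      lesioned <- runif(n_ms) >= rp$lesion_zero
      ll[lesioned] <- rbeta(sum(lesioned), rp$lesion_shape1, rp$lesion_shape2)
      subj[[paste0("lesion_load.", roi)]] <- c(rep(0, n_hc), ll)
    }
    subj
  })
}

#' Draw subject-specific tract components from the cohort distributions
#'
#' Adds, per ROI, the subject-specific isotropic component and apparent
#' anisotropy drawn from the cohort-level normal distributions of the
#' generating truth (`chi_iso.<roi>`, `dchi.<roi>` columns, ppb). These
#' are the covariate-adjusted subject levels; covariate effects are
#' applied on top when voxels are generated.
#'
#' @param subjects output of [sample_covariates()].
#' @param config a [generator_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return `subjects` with two extra columns per ROI.
#' @export
sample_subject_effects <- function(subjects, config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) seed <- config$seed
  with_seed(derive_seed(seed, 2L), {
    idx <- match(subjects$cohort, c("HC", "MS"))
    for (roi in names(config$rois)) {
      rp <- config$rois[[roi]]
      n <- nrow(subjects)
      subjects[[paste0("chi_iso.", roi)]] <-
        rnorm(n, rp$mu_iso[idx], rp$sigma_iso[idx])
      subjects[[paste0("dchi.", roi)]] <-
        rnorm(n, rp$mu_dchi[idx], rp$sigma_dchi[idx])
    }
    subjects
  })
}

## effective regression coefficients for one subject row in one ROI
effective_coefficients <- function(subject, rp, roi,
                                   ref_age = 30, age_scale = 10) {
  ao <- (subject$age_at_onset - ref_age) / age_scale
  dd <- subject$disease_duration / 10
  ll <- subject[[paste0("lesion_load.", roi)]]
  list(
    chi_iso_eff = subject[[paste0("chi_iso.", roi)]] +
      rp$beta_iso * ao + rp$tau_iso * dd + rp$lambda_iso * ll,
    dchi_eff = subject[[paste0("dchi.", roi)]] +
      rp$beta_dchi * ao + rp$tau_dchi * dd + rp$lambda_dchi * ll
  )
}

#' Generate the voxel table for one subject
#'
#' Draws fibre-to-field angles from each tract's orientation profile
#' and places every voxel on the subject's effective cos-squared curve
#' plus i.i.d. Gaussian noise:
#' `chi_app = dchi_eff * cos^2(theta) + chi_iso_eff + eps`, where the
#' effective components apply the age-at-onset, disease-duration and
#' lesion-load effects to the subject's covariates. Quality metrics
#' (`fa`, `pq`) are drawn inside the crossing-fibre acceptance region,
#' emulating an already-filtered tract sample.
#'
#' @param subject a single row of [sample_subject_effects()] output.
#' @param config a [generator_config()].
#' @param seed optional integer seed.
#' @return Data frame with columns `subject_id`, `cohort`, `roi`,
#'   `theta_deg`, `chi_app_ppb`, `fa`, `pq`.
#' @export
generate_subject_voxels <- function(subject, config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"), nrow(subject) == 1L)
  need <- paste0("chi_iso.", names(config$rois))
  if (!all(need %in% names(subject)))
    stop("subject row lacks sampled tract components; ",
         "run sample_subject_effects() first")
  with_seed(seed, {
    out <- lapply(names(config$rois), function(roi) {
      rp <- config$rois[[roi]]
      nv <- config$voxels_per_roi
      theta <- sample_fibre_angles(rp$profile, nv)
      eff <- effective_coefficients(subject, rp, roi)
      chi <- eff$dchi_eff * cos(theta * pi / 180)^2 + eff$chi_iso_eff +
        rnorm(nv, 0, config$voxel_noise_sd)
      data.frame(subject_id = subject$subject_id, cohort = subject$cohort,
                 roi = roi, theta_deg = theta, chi_app_ppb = chi,
                 fa = 0.6 + 0.4 * rbeta(nv, 2, 2),
                 pq = 0.3 * rbeta(nv, 1, 3),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Generate a full synthetic cohort dataset
#'
#' Composes covariate sampling, subject-level draws and voxel
#' generation into a three-table dataset. Deterministic given the
#' configuration (which includes the master seed).
#'
#' @param config a [generator_config()].
#' @return List with class `msa_dataset`:
#'   `voxels` (one row per voxel), `subjects` (metadata incl. sampled
#'   subject components), and `truth` (long table of every generating
#'   parameter: cohort means/SDs, covariate effects, noise SD, and the
#'   per-subject effective coefficients), plus the `config`.
#' @export
generate_cohort_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  subjects <- sample_covariates(config)
  subjects <- sample_subject_effects(subjects, config)
  voxels <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    generate_subject_voxels(subjects[i, , drop = FALSE], config,
                            seed = derive_seed(config$seed, 100L + i))
  }))
  rownames(voxels) <- NULL
  truth <- do.call(rbind, lapply(names(config$rois), function(roi) {
    rp <- config$rois[[roi]]
    pop <- data.frame(
      roi = roi, level = "population",
      parameter = c("mu_iso[HC]", "mu_iso[MS]", "mu_dchi[HC]", "mu_dchi[MS]",
                    "sigma_iso[HC]", "sigma_iso[MS]",
                    "sigma_dchi[HC]", "sigma_dchi[MS]",
                    "beta_iso", "beta_dchi", "tau_iso", "tau_dchi",
                    "lambda_iso", "lambda_dchi", "noise_sd"),
      value = c(rp$mu_iso, rp$mu_dchi, rp$sigma_iso, rp$sigma_dchi,
                rp$beta_iso, rp$beta_dchi, rp$tau_iso, rp$tau_dchi,
                rp$lambda_iso, rp$lambda_dchi, config$voxel_noise_sd),
      stringsAsFactors = FALSE)
    eff <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
      e <- effective_coefficients(subjects[i, , drop = FALSE],
                                  rp, roi)
      data.frame(roi = roi, level = "subject",
                 parameter = paste0(c("chi_iso_eff[", "dchi_eff["),
                                    subjects$subject_id[i], "]"),
                 value = c(e$chi_iso_eff, e$dchi_eff),
                 stringsAsFactors = FALSE)
    }))
    rbind(pop, eff)
  }))
  rownames(truth) <- NULL
  structure(list(voxels = voxels, subjects = subjects, truth = truth,
                 config = config),
            class = "msa_dataset")
}

#' Inject a theta-correlated reconstruction artefact
#'
#' Robustness probe emulating structured dipole-inversion artefacts
#' that correlate with fibre orientation. `form = "cos2"` adds
#' `amplitude * cos^2(theta)`, which is collinear with the anisotropy
#' regressor and shifts fitted `delta_chi` by exactly the amplitude;
#' `form = "orthogonal"` adds a `cos(4 theta)` ripple residualized
#' against `(1, cos^2 theta)` over each tract sample (per subject when
#' `subject_id` is present, else pooled per ROI) and scaled to
#' root-mean-square `amplitude`, which leaves the tract regression
#' essentially unchanged — a structured artefact the cos-squared model
#' is blind to.
#'
#' @param voxels a voxel table (`theta_deg`, `chi_app_ppb`, `roi`).
#' @param amplitude artefact amplitude in ppb, `>= 0`.
#' @param form `"cos2"` or `"orthogonal"`.
#' @param seed unused for these deterministic forms; accepted for
#'   interface stability.
#' @return The voxel table with perturbed `chi_app_ppb`.
#' @export
inject_orientation_artifact <- function(voxels, amplitude,
                                        form = c("cos2", "orthogonal"),
                                        seed = NULL) {
  form <- match.arg(form)
  stopifnot(amplitude >= 0, all(c("theta_deg", "chi_app_ppb", "roi")
                                %in% names(voxels)))
  if (amplitude == 0) return(voxels)
  c2 <- cos(voxels$theta_deg * pi / 180)^2
  if (form == "cos2") {
    voxels$chi_app_ppb <- voxels$chi_app_ppb + amplitude * c2
  } else {
    grp <- if ("subject_id" %in% names(voxels))
      paste(voxels$roi, voxels$subject_id) else voxels$roi
    for (g_id in unique(grp)) {
      i <- grp == g_id
      g <- cos(4 * voxels$theta_deg[i] * pi / 180)
      r <- lm.fit(cbind(1, c2[i]), g)$residuals
      rms <- sqrt(mean(r^2))
      if (rms > 0)
        voxels$chi_app_ppb[i] <- voxels$chi_app_ppb[i] + amplitude * r / rms
    }
  }
  voxels
}

#' Write / read a synthetic dataset as plain text
#'
#' Voxel, subject and truth tables as TSV plus the configuration as
#' YAML, in `dir`.
#'
#' @param dataset an `msa_dataset` from [generate_cohort_dataset()].
#' @param dir output directory, created if needed.
#' @return `write_cohort_dataset()` returns the file paths invisibly;
#'   `read_voxel_table()` returns a voxel data frame.
#' @export
write_cohort_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "msa_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("voxels.tsv", "subjects.tsv", "truth.tsv",
                            "config.yaml"))
  wt <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(dataset$voxels, paths[1]); wt(dataset$subjects, paths[2])
  wt(dataset$truth, paths[3])
  cfg <- dataset$config
  yaml::write_yaml(list(
    n_hc = cfg$n_hc, n_ms = cfg$n_ms, voxels_per_roi = cfg$voxels_per_roi,
    voxel_noise_sd = cfg$voxel_noise_sd, seed = cfg$seed,
    rois = lapply(cfg$rois, function(rp) {
      c(list(mean_deg = rp$profile$mean_deg,
             dispersion = rp$profile$dispersion),
        lapply(rp[setdiff(names(rp), "profile")], function(v) {
          if (!is.null(names(v))) as.list(v) else v
        }))
    })), paths[4])
  invisible(paths)
}

#' @param path a voxel TSV written by [write_cohort_dataset()].
#' @rdname write_cohort_dataset
#' @export
read_voxel_table <- function(path) {
  v <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "roi", "theta_deg", "chi_app_ppb")
  if (!all(need %in% names(v)))
    stop("voxel table lacks columns: ",
         paste(setdiff(need, names(v)), collapse = ", "))
  v
}
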