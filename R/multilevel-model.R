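#' Specification of the Bayesian multilevel cohort model
#'
#' The model explains every voxel's apparent susceptibility by the
#' subject's tract-level cos-squared curve, whose intercept and slope
#' combine a subject-specific component, a shared age-at-onset effect,
#' and patient-only disease-duration and lesion-load effects:
#' `chi_app = (chi_iso_subj + beta_iso*AO + tau_iso*DD + lambda_iso*LL)
#'  + (dchi_subj + beta_dchi*AO + tau_dchi*DD + lambda_dchi*LL) *
#'  cos^2(theta) + noise`.
#' Subject components are drawn from cohort-specific normal
#' distributions with means `mu_iso`/`mu_dchi` and SDs
#' `sigma_iso`/`sigma_dchi`. Age (at onset) is referenced to
#' `ref_age` (30 years) and scaled by `age_scale` (10 years); disease
#' duration is in decades and lesion load a fraction, both 0 for
#' controls by definition (so their duration/lesion effects exist only
#' for the patient cohort).
#'
#' Priors are weakly informative on the standardized response scale
#' and symmetric about zero, so negative anisotropy is admissible a
#' priori: Normal(0, 1) for cohort means, Normal(0, 2.5) for covariate
#' effects, and Half-Normal(1) for cohort SDs and the voxel noise SD.
#' The wider covariate scale matters because the effects are coded
#' per unit of covariates with small spread (notably the lesion-load
#' fraction): plausible per-unit effects exceed one standardized unit,
#' and a unit-scale prior visibly shrinks them, biasing the patient
#' cohort mean at the covariate reference point. When
#' `center_covariates` is `TRUE` (default) the sampler works in a
#' within-cohort covariate-centered parameterization (the prior on
#' each cohort mean is placed at the cohort's mean covariates, as in
#' centered-intercept regression samplers) and draws are mapped back
#' to the covariate reference point afterwards.
#'
#' @param prior_scale_mu,prior_scale_beta,prior_scale_tau,prior_scale_lambda
#'   Normal prior SDs for cohort means and covariate effects.
#' @param prior_scale_sigma,prior_scale_noise Half-Normal prior scales
#'   for cohort SDs and voxel noise SD.
#' @param ref_age,age_scale covariate reference (years) and scale.
#' @param chains,warmup,draws MCMC settings: `chains >= 2` Markov
#'   chains, `warmup` adaptation-plus-burn-in iterations and `draws`
#'   retained iterations per chain.
#' @param seed integer seed controlling every chain.
#' @param standardize standardize the response per ROI before sampling
#'   (recommended); coefficients are always reported in ppb.
#' @param center_covariates sample in the within-cohort centered
#'   parameterization (recommended; improves mixing).
#' @param include_covariates include the age/duration/lesion terms;
#'   `FALSE` reduces to the pure two-cohort hierarchy.
#' @param monitor_subjects keep draws of the subject-level components.
#' @param rhat_threshold split-R-hat above which the fit is flagged
#'   as non-converged (with a warning).
#' @param fixed named list of parameters to hold fixed at given values
#'   instead of sampling, e.g.
#'   `list(noise_sd = 1, sigma_dchi = c(HC = 5))`; used for degenerate
#'   conjugate checks.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(prior_scale_mu = 1, prior_scale_sigma = 1,
                       prior_scale_beta = 2.5, prior_scale_tau = 2.5,
                       prior_scale_lambda = 2.5, prior_scale_noise = 1,
                       ref_age = 30, age_scale = 10,
                       chains = 4L, warmup = 1000L, draws = 1000L,
                       seed = 1L, standardize = TRUE,
                       center_covariates = TRUE,
                       include_covariates = TRUE,
                       monitor_subjects = TRUE,
                       rhat_threshold = 1.01,
                       fixed = list()) {
  scales <- c(prior_scale_mu, prior_scale_sigma, prior_scale_beta,
              prior_scale_tau, prior_scale_lambda, prior_scale_noise)
  if (any(scales <= 0)) stop("prior scales must be positive")
  if (chains < 2L) stop("at least 2 chains are required")
  stopifnot(warmup >= 2L, draws >= 2L, age_scale > 0)
  structure(list(prior_scale_mu = prior_scale_mu,
                 prior_scale_sigma = prior_scale_sigma,
                 prior_scale_beta = prior_scale_beta,
                 prior_scale_tau = prior_scale_tau,
                 prior_scale_lambda = prior_scale_lambda,
                 prior_scale_noise = prior_scale_noise,
                 ref_age = ref_age, age_scale = age_scale,
                 chains = as.integer(chains),
                 warmup = as.integer(warmup), draws = as.integer(draws),
                 seed = as.integer(seed), standardize = standardize,
                 center_covariates = center_covariates,
                 include_covariates = include_covariates,
                 monitor_subjects = monitor_subjects,
                 rhat_threshold = rhat_threshold,
                 fixed = fixed),
            class = "model_spec")
}

#' Build the covariate design for one ROI
#'
#' One row per subject: cohort, scaled age (at onset), disease
#' duration in decades, lesion-load fraction for the given ROI.
#' Healthy ageing is ascribed to the age at examination for controls
#' and to the age at onset for patients; both are referenced to
#' `spec$ref_age` and scaled by `spec$age_scale`. Controls have zero
#' duration and lesion load by definition.
#'
#' @param subjects subject metadata (see [sample_covariates()]).
#' @param roi ROI name, used to pick the `lesion_load.<roi>` column.
#' @param spec a [model_spec()].
#' @return Data frame: `subject_id`, `cohort`, `ao_scaled`,
#'   `dd_decades`, `ll_fraction`.
#' @export
build_design_matrix <- function(subjects, roi, spec = model_spec()) {
  need <- c("subject_id", "cohort", "age", "age_at_onset",
            "disease_duration")
  if (!all(need %in% names(subjects)))
    stop("subject table lacks columns: ",
         paste(setdiff(need, names(subjects)), collapse = ", "))
  is_ms <- subjects$cohort == "MS"
  llcol <- paste0("lesion_load.", roi)
  ll <- if (llcol %in% names(subjects)) subjects[[llcol]]
        else if (!any(is_ms)) rep(0, nrow(subjects))
        else stop("missing '", llcol, "' for the MS cohort")
  age_pred <- ifelse(is_ms, subjects$age_at_onset, subjects$age)
  if (anyNA(age_pred) || anyNA(subjects$disease_duration) || anyNA(ll))
    stop("missing covariate values")
  if (any(ll < 0 | ll > 1)) stop("lesion load must lie in [0, 1]")
  out <- data.frame(
    subject_id = subjects$subject_id,
    cohort = subjects$cohort,
    ao_scaled = (age_pred - spec$ref_age) / spec$age_scale,
    dd_decades = ifelse(is_ms, subjects$disease_duration / 10, 0),
    ll_fraction = ifelse(is_ms, ll, 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

## Sufficient statistics of each subject's voxel regression: OLS
## estimate, X'X (and its inverse), residual sum of squares and count.
## The Gaussian voxel likelihood factorizes exactly through these,
## which is what the sampler consumes.
collapse_subject_stats <- function(voxels, design, chi_col) {
  stopifnot(all(c("subject_id", "theta_deg", chi_col) %in% names(voxels)))
  ids <- design$subject_id
  sp <- split(voxels, factor(voxels$subject_id, levels = ids))
  ns <- vapply(sp, nrow, 0L)
  if (any(ns < 3L))
    stop("each subject needs at least 3 voxels in the ROI; offending: ",
         paste(head(ids[ns < 3L]), collapse = ", "))
  bhat <- matrix(0, length(ids), 2)
  XtX <- array(0, c(length(ids), 2, 2))
  XtXinv <- array(0, c(length(ids), 2, 2))
  RSS <- numeric(length(ids))
  for (s in seq_along(ids)) {
    v <- sp[[s]]
    c2 <- cos(v$theta_deg * pi / 180)^2
    if (diff(range(c2)) < .Machine$double.eps^0.5)
      stop("subject ", ids[s], " has a single fibre-to-field angle; ",
           "delta_chi is not estimable")
    X <- cbind(1, c2)
    xtx <- crossprod(X)
    bh <- solve(xtx, crossprod(X, v[[chi_col]]))
    bhat[s, ] <- bh
    XtX[s, , ] <- xtx
    XtXinv[s, , ] <- solve(xtx)
    RSS[s] <- sum((v[[chi_col]] - X %*% bh)^2)
  }
  list(bhat = bhat, XtX = XtX, XtXinv = XtXinv, RSS = RSS, n = ns)
}

## which covariate terms enter the model, given the design
covariate_terms <- function(design, spec) {
  list(ao = isTRUE(spec$include_covariates),
       dd = isTRUE(spec$include_covariates) && any(design$dd_decades > 0),
       ll = isTRUE(spec$include_covariates) && any(design$ll_fraction > 0))
}

## assemble the BUGS model with the subject effects integrated out:
## marginally bhat_s ~ MVN(model mean, sv^2 (X'X)^-1 + diag(sigma^2)),
## which removes the latent-effect/variance coupling that stalls
## single-site Gibbs when subject slopes are weakly identified.
## Parameters named in `fixed` are supplied as data, not sampled.
build_jags_code <- function(terms, fixed) {
  fx <- names(fixed)
  a_terms <- c("mu_iso[coh[s]]",
               if (terms$ao) "beta_iso * AO[s]",
               if (terms$dd) "tau_iso * DD[s]",
               if (terms$ll) "lambda_iso * LL[s]")
  b_terms <- c("mu_dchi[coh[s]]",
               if (terms$ao) "beta_dchi * AO[s]",
               if (terms$dd) "tau_dchi * DD[s]",
               if (terms$ll) "lambda_dchi * LL[s]")
  prior <- function(p, line) if (p %in% fx) NULL else line
  code <- c(
    "model {",
    "  for (s in 1:N) {",
    paste0("    mu2[s,1] <- ", paste(a_terms, collapse = " + ")),
    paste0("    mu2[s,2] <- ", paste(b_terms, collapse = " + ")),
    "    V11[s] <- sv2 * XtXinv[s,1,1] + pow(sigma_iso[coh[s]], 2)",
    "    V12[s] <- sv2 * XtXinv[s,1,2]",
    "    V22[s] <- sv2 * XtXinv[s,2,2] + pow(sigma_dchi[coh[s]], 2)",
    "    Vdet[s] <- V11[s] * V22[s] - V12[s] * V12[s]",
    "    prec2[s,1,1] <- V22[s] / Vdet[s]",
    "    prec2[s,1,2] <- -V12[s] / Vdet[s]",
    "    prec2[s,2,1] <- -V12[s] / Vdet[s]",
    "    prec2[s,2,2] <- V11[s] / Vdet[s]",
    "    bhat[s,1:2] ~ dmnorm(mu2[s,1:2], prec2[s,1:2,1:2])",
    "    RSS[s] ~ dgamma(shapeRSS[s], rateRSS)",
    "  }",
    "  rateRSS <- 1 / (2 * sv2)",
    "  for (c in 1:C) {",
    prior("mu_iso", "    mu_iso[c] ~ dnorm(0, pr_mu)"),
    prior("mu_dchi", "    mu_dchi[c] ~ dnorm(0, pr_mu)"),
    prior("sigma_iso", "    sigma_iso[c] ~ dnorm(0, pr_sigma) T(0,)"),
    prior("sigma_dchi", "    sigma_dchi[c] ~ dnorm(0, pr_sigma) T(0,)"),
    "  }",
    if (terms$ao) c(prior("beta_iso", "  beta_iso ~ dnorm(0, pr_beta)"),
                    prior("beta_dchi", "  beta_dchi ~ dnorm(0, pr_beta)")),
    if (terms$dd) c(prior("tau_iso", "  tau_iso ~ dnorm(0, pr_tau)"),
                    prior("tau_dchi", "  tau_dchi ~ dnorm(0, pr_tau)")),
    if (terms$ll) c(prior("lambda_iso", "  lambda_iso ~ dnorm(0, pr_lambda)"),
                    prior("lambda_dchi", "  lambda_dchi ~ dnorm(0, pr_lambda)")),
    prior("noise_sd", "  sv ~ dnorm(0, pr_noise) T(0,)"),
    "  sv2 <- pow(sv, 2)",
    "}")
  paste(code, collapse = "\n")
}

#' Sample the multilevel-model posterior for one ROI
#'
#' Fits the model of [model_spec()] to one ROI's voxel table by Gibbs
#' MCMC (JAGS with the `glm` block-sampling module). The Gaussian
#' voxel likelihood is collapsed exactly onto each subject's
#' regression sufficient statistics, so run time scales with subjects,
#' not voxels. Draws are returned in ppb on the covariate reference
#' scale (age 30 years, onset, lesion-free), with split-R-hat and
#' effective-sample-size diagnostics attached; a fit whose
#' population-level split-R-hat exceeds `spec$rhat_threshold` carries
#' `converged = FALSE` and raises a warning.
#'
#' @param voxels voxel table of a single ROI (`subject_id`,
#'   `theta_deg`, `chi_app_ppb`).
#' @param design output of [build_design_matrix()] for the same ROI.
#' @param spec a [model_spec()].
#' @return An object of class `msa_posterior`: `draws` (array
#'   iterations x chains x parameters, ppb scale), `diagnostics`,
#'   `converged`, `standardization`, `design`, `spec`, `roi`.
#' @export
sample_posterior <- function(voxels, design, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  roi <- if ("roi" %in% names(voxels)) unique(voxels$roi) else NA_character_
  if (length(roi) > 1L)
    stop("sample_posterior() fits one ROI at a time; got: ",
         paste(roi, collapse = ", "))
  if (!all(voxels$subject_id %in% design$subject_id))
    stop("voxel table contains subjects absent from the design")
  design <- design[design$subject_id %in% voxels$subject_id, , drop = FALSE]
  cohorts <- intersect(c("HC", "MS"), unique(design$cohort))
  if (length(cohorts) == 0L) stop("no known cohort labels in design")

  ## response scale
  std <- data.frame(roi = roi, mean = 0, sd = 1)
  chi_col <- "chi_app_ppb"
  if (spec$standardize) {
    voxels$roi <- if (is.na(roi)) "roi" else roi
    s <- standardize_ams(voxels)
    voxels <- s$voxels
    std <- s$params
    chi_col <- "chi_app_std"
  }
  stats <- collapse_subject_stats(voxels, design, chi_col)
  terms <- covariate_terms(design, spec)

  ## within-cohort covariate centering (exact reparameterization)
  centers <- center_table(design, cohorts, terms, spec)
  ci <- match(design$cohort, cohorts)
  AOc <- design$ao_scaled - centers$ao[ci]
  DDc <- design$dd_decades - centers$dd[ci]
  LLc <- design$ll_fraction - centers$ll[ci]

  fixed <- normalize_fixed(spec$fixed, cohorts, std)
  dat <- list(N = nrow(design), C = length(cohorts), coh = ci,
              bhat = stats$bhat, XtXinv = stats$XtXinv, RSS = stats$RSS,
              shapeRSS = (stats$n - 2) / 2,
              pr_mu = 1 / spec$prior_scale_mu^2,
              pr_sigma = 1 / spec$prior_scale_sigma^2,
              pr_beta = 1 / spec$prior_scale_beta^2,
              pr_tau = 1 / spec$prior_scale_tau^2,
              pr_lambda = 1 / spec$prior_scale_lambda^2,
              pr_noise = 1 / spec$prior_scale_noise^2)
  if (terms$ao) dat$AO <- AOc
  if (terms$dd) dat$DD <- DDc
  if (terms$ll) dat$LL <- LLc
  dat <- c(dat, fixed$data)

  code <- build_jags_code(terms, fixed$data)
  for (pr in grep("^pr_", names(dat), value = TRUE))
    if (!grepl(pr, code, fixed = TRUE)) dat[[pr]] <- NULL
  inits <- lapply(seq_len(spec$chains), function(k)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(spec$seed, 7000L + k)))
  monitors <- c("mu_iso", "mu_dchi", "sigma_iso", "sigma_dchi",
                if (terms$ao) c("beta_iso", "beta_dchi"),
                if (terms$dd) c("tau_iso", "tau_dchi"),
                if (terms$ll) c("lambda_iso", "lambda_dchi"),
                "sv")
  monitors <- setdiff(monitors, names(fixed$data))

  n_adapt <- max(100L, spec$warmup %/% 2L)
  jm <- rjags::jags.model(textConnection(code), data = dat, inits = inits,
                          n.chains = spec$chains, n.adapt = n_adapt,
                          quiet = TRUE)
  stats::update(jm, spec$warmup - n_adapt, progress.bar = "none")
  sm <- rjags::coda.samples(jm, monitors, n.iter = spec$draws,
                            progress.bar = "none")

  chains <- prepare_chains(sm, length(cohorts))
  if (spec$monitor_subjects)
    chains <- lapply(seq_along(chains), function(k)
      draw_subject_effects(chains[[k]], stats, design, cohorts,
                           AOc, DDc, LLc, fixed,
                           seed = derive_seed(spec$seed, 8000L + k)))
  post <- finalize_draws(chains, design, cohorts, centers, terms, std,
                         fixed, spec, roi)
  diag_pop <- post$diagnostics[!grepl("_subj\\[", post$diagnostics$parameter), ]
  post$converged <- all(is.finite(diag_pop$rhat)) &&
    max(diag_pop$rhat) < spec$rhat_threshold
  if (!post$converged)
    warning("MCMC may not have converged: max population split-R-hat = ",
            signif(max(diag_pop$rhat), 4))
  post
}

## coda output as plain matrices with stable column names (JAGS drops
## brackets on length-1 node arrays)
prepare_chains <- function(sm, C) {
  lapply(sm, function(m) {
    m <- as.matrix(m)
    for (p in c("mu_iso", "mu_dchi", "sigma_iso", "sigma_dchi"))
      colnames(m)[colnames(m) == p] <- paste0(p, "[1]")
    m
  })
}

## Subject-level components given each population draw: the exact
## bivariate-normal conditional of (chi_iso_subj, dchi_subj) given the
## subject's OLS statistics, vectorized over draws. Columns ci[s],
## dc[s] are appended on the sampler's (standardized, centered) scale.
draw_subject_effects <- function(m, stats, design, cohorts,
                                 AOc, DDc, LLc, fixed, seed) {
  nd <- nrow(m)
  gc0 <- function(p, fb) if (p %in% colnames(m)) m[, p]
         else if (!is.null(fb)) rep(fb, nd) else numeric(nd)
  fx <- fixed$data
  sv <- gc0("sv", fx$sv)
  sv2 <- sv^2
  b_i <- gc0("beta_iso", NULL); b_d <- gc0("beta_dchi", NULL)
  t_i <- gc0("tau_iso", NULL); t_d <- gc0("tau_dchi", NULL)
  l_i <- gc0("lambda_iso", NULL); l_d <- gc0("lambda_dchi", NULL)
  out <- matrix(NA_real_, nd, 2L * nrow(design))
  cn <- character(2L * nrow(design))
  with_seed(seed, {
    for (s in seq_len(nrow(design))) {
      c_idx <- match(design$cohort[s], cohorts)
      mu_i <- gc0(sprintf("mu_iso[%d]", c_idx),
                  if (!is.null(fx$mu_iso)) fx$mu_iso[c_idx])
      mu_d <- gc0(sprintf("mu_dchi[%d]", c_idx),
                  if (!is.null(fx$mu_dchi)) fx$mu_dchi[c_idx])
      s_i <- gc0(sprintf("sigma_iso[%d]", c_idx),
                 if (!is.null(fx$sigma_iso)) fx$sigma_iso[c_idx])
      s_d <- gc0(sprintf("sigma_dchi[%d]", c_idx),
                 if (!is.null(fx$sigma_dchi)) fx$sigma_dchi[c_idx])
      off1 <- b_i * AOc[s] + t_i * DDc[s] + l_i * LLc[s]
      off2 <- b_d * AOc[s] + t_d * DDc[s] + l_d * LLc[s]
      x11 <- stats$XtX[s, 1, 1]; x12 <- stats$XtX[s, 1, 2]
      x22 <- stats$XtX[s, 2, 2]
      r1v <- stats$bhat[s, 1] - off1
      r2v <- stats$bhat[s, 2] - off2
      A11 <- 1 / s_i^2 + x11 / sv2
      A12 <- x12 / sv2
      A22 <- 1 / s_d^2 + x22 / sv2
      r1 <- mu_i / s_i^2 + (x11 * r1v + x12 * r2v) / sv2
      r2 <- mu_d / s_d^2 + (x12 * r1v + x22 * r2v) / sv2
      dt <- A11 * A22 - A12^2
      m1 <- (A22 * r1 - A12 * r2) / dt
      m2 <- (A11 * r2 - A12 * r1) / dt
      ## Cholesky of the 2x2 conditional covariance, componentwise
      C11 <- A22 / dt; C12 <- -A12 / dt; C22 <- A11 / dt
      L11 <- sqrt(C11); L21 <- C12 / L11; L22 <- sqrt(C22 - L21^2)
      z1 <- rnorm(nd); z2 <- rnorm(nd)
      out[, 2L * s - 1L] <- m1 + L11 * z1
      out[, 2L * s] <- m2 + L21 * z1 + L22 * z2
      cn[2L * s - 1L] <- sprintf("ci[%d]", s)
      cn[2L * s] <- sprintf("dc[%d]", s)
    }
  })
  colnames(out) <- cn
  cbind(m, out)
}

## per-cohort covariate means used for centering (zero when disabled)
center_table <- function(design, cohorts, terms, spec) {
  z <- numeric(length(cohorts))
  if (!isTRUE(spec$center_covariates))
    return(list(ao = z, dd = z, ll = z))
  m <- function(x, on) if (on)
    vapply(cohorts, function(ch) mean(x[design$cohort == ch]), 0) else z
  list(ao = m(design$ao_scaled, terms$ao),
       dd = m(design$dd_decades, terms$dd),
       ll = m(design$ll_fraction, terms$ll))
}

## map user-facing fixed values (ppb scale) onto sampler data
## (standardized scale); cohort-valued entries become length-C vectors
normalize_fixed <- function(fixed, cohorts, std) {
  if (length(fixed) == 0L) return(list(data = list(), names = character()))
  out <- list()
  for (nm in names(fixed)) {
    v <- fixed[[nm]]
    scale_only <- nm %in% c("mu_dchi", "sigma_iso", "sigma_dchi",
                            "noise_sd", "beta_iso", "beta_dchi",
                            "tau_iso", "tau_dchi",
                            "lambda_iso", "lambda_dchi")
    v_std <- if (nm == "mu_iso") (v - std$mean) / std$sd
             else if (scale_only) v / std$sd
             else stop("cannot fix unknown parameter: ", nm)
    if (nm %in% c("mu_iso", "mu_dchi", "sigma_iso", "sigma_dchi")) {
      if (!is.null(names(v_std))) v_std <- v_std[cohorts]
      if (length(v_std) == 1L) v_std <- rep(v_std, length(cohorts))
      if (anyNA(v_std)) stop("fixed '", nm, "' must cover cohorts: ",
                             paste(cohorts, collapse = ", "))
    }
    out[[sub("noise_sd", "sv", nm)]] <- unname(v_std)
  }
  list(data = out, names = names(fixed))
}

## un-center, un-standardize and rename the raw draws
finalize_draws <- function(chains, design, cohorts, centers, terms, std,
                           fixed, spec, roi) {
  C <- length(cohorts)
  has <- function(p) p %in% colnames(chains[[1]])
  get_col <- function(m, p, fb) if (p %in% colnames(m)) m[, p] else fb
  chains <- lapply(chains, function(m) {
    zero <- numeric(nrow(m))
    b_i <- get_col(m, "beta_iso", zero); b_d <- get_col(m, "beta_dchi", zero)
    t_i <- get_col(m, "tau_iso", zero); t_d <- get_col(m, "tau_dchi", zero)
    l_i <- get_col(m, "lambda_iso", zero); l_d <- get_col(m, "lambda_dchi", zero)
    for (c in seq_len(C)) {
      sh_i <- b_i * centers$ao[c] + t_i * centers$dd[c] + l_i * centers$ll[c]
      sh_d <- b_d * centers$ao[c] + t_d * centers$dd[c] + l_d * centers$ll[c]
      mc <- sprintf("mu_iso[%d]", c)
      if (has(mc)) m[, mc] <- m[, mc] - sh_i
      mc <- sprintf("mu_dchi[%d]", c)
      if (has(mc)) m[, mc] <- m[, mc] - sh_d
      subj_c <- which(design$cohort == cohorts[c])
      for (s in subj_c) {
        cc <- sprintf("ci[%d]", s)
        if (has(cc)) m[, cc] <- m[, cc] - sh_i
        cc <- sprintf("dc[%d]", s)
        if (has(cc)) m[, cc] <- m[, cc] - sh_d
      }
    }
    ## back to ppb: locations rescale-and-shift, everything else rescales
    loc <- grepl("^(mu_iso|ci)\\[", colnames(m))
    m[, loc] <- m[, loc] * std$sd + std$mean
    m[, !loc] <- m[, !loc] * std$sd
    m
  })
  ## single-chain handling is impossible here (spec requires >= 2)
  nm <- colnames(chains[[1]])
  rename <- nm
  for (c in seq_len(C)) {
    rename[nm == sprintf("mu_iso[%d]", c)] <- sprintf("mu_iso[%s]", cohorts[c])
    rename[nm == sprintf("mu_dchi[%d]", c)] <- sprintf("mu_dchi[%s]", cohorts[c])
    rename[nm == sprintf("sigma_iso[%d]", c)] <- sprintf("sigma_iso[%s]", cohorts[c])
    rename[nm == sprintf("sigma_dchi[%d]", c)] <- sprintf("sigma_dchi[%s]", cohorts[c])
  }
  for (s in seq_len(nrow(design))) {
    rename[nm == sprintf("ci[%d]", s)] <-
      sprintf("chi_iso_subj[%s]", design$subject_id[s])
    rename[nm == sprintf("dc[%d]", s)] <-
      sprintf("dchi_subj[%s]", design$subject_id[s])
  }
  rename[nm == "sv"] <- "noise_sd"
  draws <- array(NA_real_,
                 c(nrow(chains[[1]]), length(chains), length(rename)),
                 dimnames = list(NULL, paste0("chain", seq_along(chains)),
                                 rename))
  for (k in seq_along(chains)) draws[, k, ] <- chains[[k]]
  post <- structure(list(draws = draws, roi = roi, cohorts = cohorts,
                         design = design, standardization = std,
                         spec = spec, converged = NA),
                    class = "msa_posterior")
  post$diagnostics <- convergence_diagnostics(post)
  post
}

#' @export
print.msa_posterior <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<msa_posterior> ROI %s: %d draws x %d chains, %d parameters\n",
              x$roi, d[1], d[2], d[3]))
  pop <- x$diagnostics[!grepl("_subj\\[", x$diagnostics$parameter), ]
  cat(sprintf("  max population split-R-hat %.4f, min ESS %.0f%s\n",
              max(pop$rhat), min(pop$ess),
              if (isTRUE(x$converged)) "" else " [convergence flagged]"))
  invisible(x)
}

#' Flatten posterior draws to a matrix
#'
#' @param post an `msa_posterior` (or a draws array).
#' @return Matrix with one column per parameter, chains stacked.
#' @export
as_draws_matrix <- function(post) {
  a <- if (inherits(post, "msa_posterior")) post$draws else post
  stopifnot(length(dim(a)) == 3L)
  m <- matrix(a, prod(dim(a)[1:2]), dim(a)[3])
  colnames(m) <- dimnames(a)[[3]]
  m
}

#' Fit every ROI of a cohort dataset
#'
#' Convenience wrapper: builds the per-ROI design and samples the
#' posterior ROI by ROI (each tract modelled independently).
#'
#' @param voxels voxel table spanning one or more ROIs.
#' @param subjects subject metadata table.
#' @param spec a [model_spec()].
#' @param rois ROIs to fit (default: all in `voxels`).
#' @return Named list of `msa_posterior` objects.
#' @export
fit_cohort_model <- function(voxels, subjects, spec = model_spec(),
                             rois = unique(voxels$roi)) {
  out <- lapply(rois, function(roi) {
    design <- build_design_matrix(subjects, roi, spec)
    sample_posterior(voxels[voxels$roi == roi, , drop = FALSE],
                     design, spec)
  })
  names(out) <- rois
  out
}

#' Log joint density of the multilevel model
#'
#' Sum of the voxel-level Gaussian log-likelihood around the model
#' mean, the subject-level normal log-densities, and the prior
#' log-densities, evaluated at a full set of parameter values on the
#' scale of the supplied response column. Out-of-support values
#' (non-positive SDs) give `-Inf`. The three components are attached
#' as attributes `loglik`, `logprior_subject`, `logprior_population`.
#'
#' @param params named list: `mu_iso`, `mu_dchi`, `sigma_iso`,
#'   `sigma_dchi` (named by cohort), scalar covariate effects as
#'   applicable, `noise_sd`, and named vectors `chi_iso_subj`,
#'   `dchi_subj` indexed by subject id.
#' @param voxels voxel table (single ROI).
#' @param design matching [build_design_matrix()] output.
#' @param spec a [model_spec()].
#' @param chi_col response column (default `chi_app_ppb`).
#' @return Log density (scalar), with component attributes.
#' @export
log_joint_density <- function(params, voxels, design,
                              spec = model_spec(),
                              chi_col = "chi_app_ppb") {
  cohorts <- intersect(c("HC", "MS"), unique(design$cohort))
  terms <- covariate_terms(design, spec)
  sig_i <- params$sigma_iso[cohorts]; sig_d <- params$sigma_dchi[cohorts]
  nsd <- params$noise_sd
  if (any(c(sig_i, sig_d, nsd) <= 0) || anyNA(c(sig_i, sig_d, nsd)))
    return(structure(-Inf, loglik = -Inf, logprior_subject = -Inf,
                     logprior_population = -Inf))
  gp <- function(p, d = 0) if (is.null(params[[p]])) d else params[[p]]
  b_i <- gp("beta_iso"); b_d <- gp("beta_dchi")
  t_i <- gp("tau_iso"); t_d <- gp("tau_dchi")
  l_i <- gp("lambda_iso"); l_d <- gp("lambda_dchi")
  ci <- params$chi_iso_subj[design$subject_id]
  dc <- params$dchi_subj[design$subject_id]
  a <- ci + b_i * design$ao_scaled + t_i * design$dd_decades +
    l_i * design$ll_fraction
  b <- dc + b_d * design$ao_scaled + t_d * design$dd_decades +
    l_d * design$ll_fraction
  i <- match(voxels$subject_id, design$subject_id)
  mu_vox <- a[i] + b[i] * cos(voxels$theta_deg * pi / 180)^2
  loglik <- sum(dnorm(voxels[[chi_col]], mu_vox, nsd, log = TRUE))
  ki <- match(design$cohort, cohorts)
  lp_subj <- sum(dnorm(ci, params$mu_iso[cohorts][ki], sig_i[ki],
                       log = TRUE)) +
    sum(dnorm(dc, params$mu_dchi[cohorts][ki], sig_d[ki], log = TRUE))
  ## priors; cohort-mean priors sit at the within-cohort covariate
  ## centre, matching the sampler's parameterization
  centers <- center_table(design, cohorts, terms, spec)
  mu_i_c <- params$mu_iso[cohorts] + b_i * centers$ao +
    t_i * centers$dd + l_i * centers$ll
  mu_d_c <- params$mu_dchi[cohorts] + b_d * centers$ao +
    t_d * centers$dd + l_d * centers$ll
  half_normal <- function(x, s) log(2) + dnorm(x, 0, s, log = TRUE)
  lp_pop <- sum(dnorm(mu_i_c, 0, spec$prior_scale_mu, log = TRUE)) +
    sum(dnorm(mu_d_c, 0, spec$prior_scale_mu, log = TRUE)) +
    sum(half_normal(sig_i, spec$prior_scale_sigma)) +
    sum(half_normal(sig_d, spec$prior_scale_sigma)) +
    half_normal(nsd, spec$prior_scale_noise)
  if (terms$ao) lp_pop <- lp_pop +
    dnorm(b_i, 0, spec$prior_scale_beta, log = TRUE) +
    dnorm(b_d, 0, spec$prior_scale_beta, log = TRUE)
  if (terms$dd) lp_pop <- lp_pop +
    dnorm(t_i, 0, spec$prior_scale_tau, log = TRUE) +
    dnorm(t_d, 0, spec$prior_scale_tau, log = TRUE)
  if (terms$ll) lp_pop <- lp_pop +
    dnorm(l_i, 0, spec$prior_scale_lambda, log = TRUE) +
    dnorm(l_d, 0, spec$prior_scale_lambda, log = TRUE)
  structure(loglik + lp_subj + lp_pop, loglik = loglik,
            logprior_subject = lp_subj, logprior_population = lp_pop)
}

#' Split-R-hat and effective sample size per parameter
#'
#' Split-R-hat halves each chain before comparing between- and
#' within-sequence variance (BDA3); values near 1 indicate mixing.
#' Effective sample sizes are computed chain-wise from the
#' autocorrelation spectrum (via coda) and capped at the total number
#' of draws.
#'
#' @param post an `msa_posterior` or a draws array
#'   (iterations x chains x parameters), with at least 2 chains.
#' @return Data frame: `parameter`, `rhat`, `ess`.
#' @export
convergence_diagnostics <- function(post) {
  a <- if (inherits(post, "msa_posterior")) post$draws else post
  stopifnot(length(dim(a)) == 3L)
  if (dim(a)[2] < 2L)
    stop("convergence diagnostics require at least 2 chains")
  params <- dimnames(a)[[3]]
  rhat <- vapply(seq_along(params), function(j) split_rhat(a[, , j]), 0)
  ml <- coda::as.mcmc.list(lapply(seq_len(dim(a)[2]), function(k)
    coda::mcmc(matrix(a[, k, ], dim(a)[1], dim(a)[3],
                      dimnames = list(NULL, params)))))
  ess <- pmin(coda::effectiveSize(ml), dim(a)[1] * dim(a)[2])
  data.frame(parameter = params, rhat = rhat, ess = unname(ess[params]),
             stringsAsFactors = FALSE)
}

## split-R-hat of one parameter's iterations x chains matrix
split_rhat <- function(x) {
  n <- nrow(x)
  h <- n %/% 2L
  halves <- cbind(x[seq_len(h), , drop = FALSE],
                  x[(n - h + 1L):n, , drop = FALSE])
  W <- mean(apply(halves, 2, var))
  B <- h * var(colMeans(halves))
  if (!is.finite(W) || W == 0)
    return(if (isTRUE(all(halves == halves[1]))) 1 else Inf)
  sqrt(((h - 1) / h * W + B / h) / W)
}

#' Posterior predictive voxel simulation
#'
#' For retained posterior draws, simulates apparent-susceptibility
#' voxels from the model: each subject's effective curve evaluated at
#' the supplied fibre-to-field angles plus Gaussian voxel noise. Used
#' for graphical checks against the observed binned AMS(theta) curves.
#'
#' @param post an `msa_posterior`, or any draws matrix/array carrying
#'   `chi_iso_subj[...]`/`dchi_subj[...]`, covariate-effect and
#'   `noise_sd` columns (e.g. a generating-truth point mass).
#' @param design design rows for the subjects to simulate.
#' @param theta either a numeric vector of angles used for every
#'   subject, or a named list of per-subject angle vectors (degrees).
#' @param n_draws number of posterior draws to use (sampled evenly).
#' @param seed optional seed for the noise.
#' @return Long data frame: `draw`, `subject_id`, `theta_deg`,
#'   `chi_app_ppb`.
#' @export
posterior_predictive <- function(post, design, theta, n_draws = 50,
                                 seed = NULL) {
  m <- if (is.matrix(post)) post else as_draws_matrix(post)
  idx <- unique(round(seq(1, nrow(m), length.out = min(n_draws, nrow(m)))))
  gp <- function(p) if (p %in% colnames(m)) m[, p] else 0
  th <- if (is.list(theta)) theta
        else setNames(rep(list(theta), nrow(design)), design$subject_id)
  with_seed(seed, {
    out <- vector("list", length(idx) * nrow(design))
    k <- 0L
    for (d in idx) {
      for (s in seq_len(nrow(design))) {
        id <- design$subject_id[s]
        tt <- th[[id]]
        a <- m[d, sprintf("chi_iso_subj[%s]", id)] +
          gp("beta_iso")[d] * design$ao_scaled[s] +
          gp("tau_iso")[d] * design$dd_decades[s] +
          gp("lambda_iso")[d] * design$ll_fraction[s]
        b <- m[d, sprintf("dchi_subj[%s]", id)] +
          gp("beta_dchi")[d] * design$ao_scaled[s] +
          gp("tau_dchi")[d] * design$dd_decades[s] +
          gp("lambda_dchi")[d] * design$ll_fraction[s]
        y <- a + b * cos(tt * pi / 180)^2 +
          rnorm(length(tt), 0, m[d, "noise_sd"])
        k <- k + 1L
        out[[k]] <- data.frame(draw = d, subject_id = id, theta_deg = tt,
                               chi_app_ppb = y, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}
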