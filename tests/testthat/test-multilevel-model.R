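test_that("design rows implement the covariate coding", {
  subj <- data.frame(
    subject_id = c("HC001", "MS001", "MS002"),
    cohort = c("HC", "MS", "MS"),
    age = c(30, 49, 52),
    age_at_onset = c(30, 40, 45),
    disease_duration = c(0, 9, 7),
    lesion_load.OR = c(0, 0.12, 0),
    stringsAsFactors = FALSE)
  d <- build_design_matrix(subj, "OR")
  expect_equal(d$ao_scaled, c(0, 1, 1.5))   # HC uses age at examination
  expect_equal(d$dd_decades, c(0, 0.9, 0.7))
  expect_equal(d$ll_fraction, c(0, 0.12, 0))
  expect_error(build_design_matrix(subj, "SCC"), "lesion_load.SCC")
  expect_error(build_design_matrix(subj[, -3], "OR"), "age")
})

test_that("log joint density equals a hand-computed sum of normal terms", {
  design <- data.frame(subject_id = "HC001", cohort = "HC",
                       ao_scaled = 0.5, dd_decades = 0, ll_fraction = 0,
                       stringsAsFactors = FALSE)
  vox <- data.frame(subject_id = "HC001", theta_deg = 30,
                    chi_app_ppb = -20)
  params <- list(mu_iso = c(HC = -40), mu_dchi = c(HC = 25),
                 sigma_iso = c(HC = 5), sigma_dchi = c(HC = 10),
                 beta_iso = 2, beta_dchi = -1, noise_sd = 12,
                 chi_iso_subj = c(HC001 = -38), dchi_subj = c(HC001 = 22))
  got <- log_joint_density(params, vox, design)
  ## independent hand computation
  a <- -38 + 2 * 0.5
  b <- 22 - 1 * 0.5
  loglik <- dnorm(-20, a + b * cos(30 * pi / 180)^2, 12, log = TRUE)
  lp_subj <- dnorm(-38, -40, 5, log = TRUE) + dnorm(22, 25, 10, log = TRUE)
  hn <- function(x) log(2) + dnorm(x, 0, 1, log = TRUE)
  lp_pop <- dnorm(-40 + 2 * 0.5, 0, 1, log = TRUE) +
    dnorm(25 - 1 * 0.5, 0, 1, log = TRUE) +
    hn(5) + hn(10) + hn(12) +
    dnorm(2, 0, 2.5, log = TRUE) + dnorm(-1, 0, 2.5, log = TRUE)
  expect_equal(as.numeric(got), loglik + lp_subj + lp_pop,
               tolerance = 1e-10)
  expect_equal(attr(got, "loglik"), loglik, tolerance = 1e-10)
  ## out-of-support scales give -Inf, never NaN
  bad <- params; bad$sigma_dchi <- c(HC = -1)
  expect_identical(as.numeric(log_joint_density(bad, vox, design)), -Inf)
})

test_that("log joint is concave in a subject effect around its conditional mode", {
  set.seed(61)
  design <- data.frame(subject_id = "S1", cohort = "HC",
                       ao_scaled = 0, dd_decades = 0, ll_fraction = 0)
  th <- runif(40, 10, 80)
  c2 <- cos(th * pi / 180)^2
  vox <- data.frame(subject_id = "S1", theta_deg = th,
                    chi_app_ppb = 20 * c2 - 40 + rnorm(40, 0, 8))
  base <- list(mu_iso = c(HC = -40), mu_dchi = c(HC = 20),
               sigma_iso = c(HC = 5), sigma_dchi = c(HC = 10),
               noise_sd = 8, chi_iso_subj = c(S1 = -40),
               dchi_subj = c(S1 = 20))
  spec <- model_spec(include_covariates = FALSE)
  ## conditional posterior mean of the subject anisotropy
  r <- vox$chi_app_ppb - base$chi_iso_subj[["S1"]]
  m_star <- (20 / 100 + sum(c2 * r) / 64) / (1 / 100 + sum(c2^2) / 64)
  vals <- sapply(seq(-5, 5, by = 1), function(d) {
    p <- base; p$dchi_subj <- c(S1 = m_star + d)
    as.numeric(log_joint_density(p, vox, design, spec))
  })
  expect_equal(which.max(vals), 6L)
  expect_true(all(diff(vals[1:6]) > 0))
  expect_true(all(diff(vals[6:11]) < 0))
})

test_that("likelihood doubles with a duplicated dataset and ignores row order", {
  set.seed(62)
  design <- data.frame(subject_id = c("S1", "S2"), cohort = c("HC", "MS"),
                       ao_scaled = c(0.1, -0.3), dd_decades = c(0, 0.5),
                       ll_fraction = c(0, 0.1))
  th <- runif(30, 0, 90)
  vox <- data.frame(subject_id = rep(c("S1", "S2"), 15), theta_deg = th,
                    chi_app_ppb = rnorm(30, -30, 15))
  params <- list(mu_iso = c(HC = -40, MS = -38), mu_dchi = c(HC = 27, MS = 21),
                 sigma_iso = c(HC = 5, MS = 5), sigma_dchi = c(HC = 10, MS = 10),
                 beta_iso = 3, beta_dchi = -2, tau_iso = 1, tau_dchi = -10,
                 lambda_iso = 20, lambda_dchi = -30, noise_sd = 15,
                 chi_iso_subj = c(S1 = -41, S2 = -37),
                 dchi_subj = c(S1 = 25, S2 = 18))
  one <- log_joint_density(params, vox, design)
  two <- log_joint_density(params, rbind(vox, vox), design)
  expect_equal(attr(two, "loglik"), 2 * attr(one, "loglik"),
               tolerance = 1e-12)
  shuf <- log_joint_density(params, vox[sample(30), ], design)
  expect_equal(as.numeric(shuf), as.numeric(one), tolerance = 1e-12)
})

test_that("collapsed sufficient-statistic likelihood matches the voxel-level one", {
  ## the sampler factorizes the Gaussian voxel likelihood through each
  ## subject's OLS estimate and RSS; differences of log densities
  ## between parameter settings must agree exactly
  set.seed(63)
  design <- data.frame(subject_id = "S1", cohort = "HC",
                       ao_scaled = 0, dd_decades = 0, ll_fraction = 0)
  th <- runif(50, 5, 85)
  c2 <- cos(th * pi / 180)^2
  vox <- data.frame(subject_id = "S1", theta_deg = th,
                    chi_app_ppb = 18 * c2 - 35 + rnorm(50, 0, 9))
  X <- cbind(1, c2)
  xtx <- crossprod(X)
  bh <- solve(xtx, crossprod(X, vox$chi_app_ppb))
  rss <- sum((vox$chi_app_ppb - X %*% bh)^2)
  collapsed <- function(a, b, s) {
    d <- bh - c(a, b)
    -50 * log(s) - (rss + drop(t(d) %*% xtx %*% d)) / (2 * s^2)
  }
  voxelwise <- function(a, b, s)
    sum(dnorm(vox$chi_app_ppb, a + b * c2, s, log = TRUE))
  d_col <- collapsed(-35, 18, 9) - collapsed(-30, 10, 12)
  d_vox <- voxelwise(-35, 18, 9) - voxelwise(-30, 10, 12)
  expect_equal(d_col, d_vox, tolerance = 1e-9)
})

test_that("posterior sampling is reproducible given the seed", {
  cfg <- tiny_config(n_hc = 6, n_ms = 6, voxels = 60, seed = 64)
  ds <- generate_cohort_dataset(cfg)
  spec <- model_spec(chains = 2, warmup = 200, draws = 150, seed = 99)
  des <- build_design_matrix(ds$subjects, "OR", spec)
  vox <- ds$voxels[ds$voxels$roi == "OR", ]
  p1 <- suppressWarnings(sample_posterior(vox, des, spec))
  p2 <- suppressWarnings(sample_posterior(vox, des, spec))
  expect_identical(p1$draws, p2$draws)
  p3 <- suppressWarnings(sample_posterior(vox, des,
    model_spec(chains = 2, warmup = 200, draws = 150, seed = 100)))
  expect_false(identical(p1$draws, p3$draws))
})

test_that("degenerate one-cohort model matches the analytic posterior", {
  set.seed(65)
  n_subj <- 25; nv <- 40
  sigma_iso <- 5; sigma_dchi <- 8; noise <- 10
  ids <- sprintf("S%02d", seq_len(n_subj))
  ci <- rnorm(n_subj, -40, sigma_iso)
  dc <- rnorm(n_subj, 20, sigma_dchi)
  vox <- do.call(rbind, lapply(seq_len(n_subj), function(s) {
    th <- sample_fibre_angles(angle_profile(75, 12), nv)
    data.frame(subject_id = ids[s], roi = "OR", theta_deg = th,
               chi_app_ppb = dc[s] * cos(th * pi / 180)^2 + ci[s] +
                 rnorm(nv, 0, noise))
  }))
  design <- data.frame(subject_id = ids, cohort = "HC", ao_scaled = 0,
                       dd_decades = 0, ll_fraction = 0)
  spec <- model_spec(chains = 2, warmup = 500, draws = 1500, seed = 66,
                     standardize = FALSE, include_covariates = FALSE,
                     prior_scale_mu = 1000,
                     fixed = list(sigma_iso = c(HC = sigma_iso),
                                  sigma_dchi = c(HC = sigma_dchi),
                                  noise_sd = noise))
  post <- sample_posterior(vox, design, spec)
  ## conjugate oracle: marginally bhat_s ~ MVN(mu, Sigma_s + D), flat-ish
  ## prior -> precision-weighted bivariate normal posterior for mu
  D <- diag(c(sigma_iso^2, sigma_dchi^2))
  prec <- diag(c(1e-6, 1e-6))  # Normal(0, 1000) prior precision
  mw <- c(0, 0)
  for (s in seq_len(n_subj)) {
    v <- vox[vox$subject_id == ids[s], ]
    X <- cbind(1, cos(v$theta_deg * pi / 180)^2)
    S <- noise^2 * solve(crossprod(X)) + D
    W <- solve(S)
    bh <- solve(crossprod(X), crossprod(X, v$chi_app_ppb))
    prec <- prec + W
    mw <- mw + W %*% bh
  }
  Sig <- solve(prec)
  mean_an <- drop(Sig %*% mw)
  sd_an <- sqrt(diag(Sig))
  m <- as_draws_matrix(post)
  dg <- post$diagnostics
  for (j in 1:2) {
    p <- c("mu_iso[HC]", "mu_dchi[HC]")[j]
    ess <- dg$ess[dg$parameter == p]
    expect_lt(abs(mean(m[, p]) - mean_an[j]), 3 * sd(m[, p]) / sqrt(ess))
    expect_lt(abs(sd(m[, p]) - sd_an[j]), 3 * sd_an[j] / sqrt(2 * ess))
  }
})

test_that("split-R-hat and ESS behave on constructed chains", {
  set.seed(67)
  good <- rnorm(1000)
  a <- array(c(good, good), c(1000, 2, 1),
             dimnames = list(NULL, NULL, "x"))
  d <- convergence_diagnostics(a)
  expect_lt(abs(d$rhat - 1), 1e-3)  # identical copies
  b <- array(c(rnorm(1000, 0), rnorm(1000, 10)), c(1000, 2, 1),
             dimnames = list(NULL, NULL, "x"))
  expect_gt(convergence_diagnostics(b)$rhat, 1.5)
  expect_lte(convergence_diagnostics(b)$ess, 2000)
  single <- array(good, c(1000, 1, 1), dimnames = list(NULL, NULL, "x"))
  expect_error(convergence_diagnostics(single), "2 chains")
})

test_that("posterior predictive reproduces the generating law from a truth point mass", {
  set.seed(68)
  prof <- angle_profile(75, 12)
  a_true <- -38; b_true <- 24; noise <- 12
  truth <- matrix(c(a_true, b_true, noise), 1, 3,
                  dimnames = list(NULL, c("chi_iso_subj[S1]",
                                          "dchi_subj[S1]", "noise_sd")))
  design <- data.frame(subject_id = "S1", cohort = "HC", ao_scaled = 0,
                       dd_decades = 0, ll_fraction = 0)
  th_pred <- sample_fibre_angles(prof, 1e5)
  pred <- posterior_predictive(truth, design, th_pred, n_draws = 1,
                               seed = 70)
  th_gen <- sample_fibre_angles(prof, 1e5)
  gen <- b_true * cos(th_gen * pi / 180)^2 + a_true + rnorm(1e5, 0, noise)
  ## two-sample KS distance between the predictive and generator laws
  pool <- sort(c(pred$chi_app_ppb, gen))
  f1 <- ecdf(pred$chi_app_ppb); f2 <- ecdf(gen)
  expect_lt(max(abs(f1(pool) - f2(pool))), 0.01)
  ## 95% interval calibration against held-out voxels
  qs <- quantile(pred$chi_app_ppb, c(0.025, 0.975))
  held <- b_true * cos(sample_fibre_angles(prof, 1e4) * pi / 180)^2 +
    a_true + rnorm(1e4, 0, noise)
  cover <- mean(held >= qs[1] & held <= qs[2])
  expect_lt(abs(cover - 0.95), 0.02)
  ## noise-free point mass: predictive mean at theta = 90 is the
  ## isotropic level exactly
  truth0 <- truth; truth0[, "noise_sd"] <- 0
  p90 <- posterior_predictive(truth0, design, c(90, 90), n_draws = 1)
  expect_equal(p90$chi_app_ppb, c(a_true, a_true), tolerance = 1e-12)
})
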