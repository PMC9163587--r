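test_that("default cohort sizes and covariate definitions hold", {
  subj <- sample_covariates(generator_config())
  expect_equal(sum(subj$cohort == "HC"), 64)
  expect_equal(sum(subj$cohort == "MS"), 89)
  hc <- subj[subj$cohort == "HC", ]
  ms <- subj[subj$cohort == "MS", ]
  expect_true(all(hc$disease_duration == 0))
  expect_true(all(as.matrix(hc[grep("lesion_load", names(hc))]) == 0))
  expect_equal(ms$age, ms$age_at_onset + ms$disease_duration)
  ll <- as.matrix(ms[grep("lesion_load", names(ms))])
  expect_true(all(ll >= 0 & ll <= 1))
})

test_that("disease-duration sampler hits the reported median range", {
  cfg <- generator_config(n_hc = 1, n_ms = 1e4, seed = 2)
  subj <- sample_covariates(cfg)
  dd <- subj$disease_duration[subj$cohort == "MS"]
  expect_true(all(dd >= 1 & dd <= 32))
  expect_gte(median(dd), 7)
  expect_lte(median(dd), 11)
})

test_that("noiseless voxels lie exactly on the cos^2 curve", {
  cfg <- generator_config(n_hc = 2, n_ms = 2, voxels_per_roi = 60,
                          voxel_noise_sd = 0, seed = 21)
  ds <- generate_cohort_dataset(cfg)
  fits <- fit_all_subjects(ds$voxels)
  for (i in seq_len(nrow(fits))) {
    tr <- ds$truth[ds$truth$roi == fits$roi[i] & ds$truth$level == "subject", ]
    expect_equal(fits$delta_chi[i],
                 tr$value[tr$parameter ==
                            sprintf("dchi_eff[%s]", fits$subject_id[i])],
                 tolerance = 1e-10)
    expect_equal(fits$chi_iso[i],
                 tr$value[tr$parameter ==
                            sprintf("chi_iso_eff[%s]", fits$subject_id[i])],
                 tolerance = 1e-10)
  }
})

test_that("broad-tract mean AMS approximates chi_iso + delta_chi/2", {
  ## SLF-like tract: broad theta profile with E[cos^2 theta] ~ 1/2,
  ## generating values chosen so chi_iso + delta_chi/2 = -30 ppb
  slf <- default_roi_params()$SLF
  prof <- slf$profile
  cfg <- generator_config(
    n_hc = 1, n_ms = 1, voxels_per_roi = 1e5, voxel_noise_sd = 5,
    seed = 31,
    rois = list(SLF = roi_params(prof,
      mu_iso = c(HC = -15, MS = -15), mu_dchi = c(HC = -30, MS = -30),
      sigma_iso = c(HC = 0, MS = 0), sigma_dchi = c(HC = 0, MS = 0))))
  subj <- sample_subject_effects(sample_covariates(cfg), cfg)
  vox <- generate_subject_voxels(subj[1, ], cfg, seed = 32)
  expect_lt(abs(mean(vox$chi_app_ppb) - (-30)), 1)
})

test_that("cohort datasets are deterministic and correctly sized", {
  cfg <- generator_config(n_hc = 2, n_ms = 2, voxels_per_roi = 100, seed = 8)
  ds1 <- generate_cohort_dataset(cfg)
  ds2 <- generate_cohort_dataset(cfg)
  expect_identical(ds1, ds2)
  expect_equal(nrow(ds1$voxels), 4 * 3 * 100)
  ## different seed, different data
  ds3 <- generate_cohort_dataset(generator_config(n_hc = 2, n_ms = 2,
                                                  voxels_per_roi = 100,
                                                  seed = 9))
  expect_false(identical(ds1$voxels$chi_app_ppb, ds3$voxels$chi_app_ppb))
})

test_that("degenerate hierarchy gives every MS subject identical components", {
  rois <- lapply(default_roi_params(), function(rp) {
    rp$sigma_iso[] <- 0; rp$sigma_dchi[] <- 0
    rp$beta_iso <- 0; rp$beta_dchi <- 0
    rp$tau_iso <- 0; rp$tau_dchi <- 0
    rp$lambda_iso <- 0; rp$lambda_dchi <- 0
    rp
  })
  cfg <- generator_config(n_hc = 3, n_ms = 5, voxels_per_roi = 10,
                          rois = rois, seed = 13)
  ds <- generate_cohort_dataset(cfg)
  tr <- ds$truth[ds$truth$level == "subject" & ds$truth$roi == "OR", ]
  ms_dchi <- tr$value[grepl("^dchi_eff\\[MS", tr$parameter)]
  expect_equal(length(unique(ms_dchi)), 1L)
})

test_that("subject-level draws honour the cohort distribution", {
  cfg <- generator_config(n_hc = 600, n_ms = 1, voxels_per_roi = 10,
                          seed = 17)
  subj <- sample_subject_effects(sample_covariates(cfg), cfg)
  hc <- subj[subj$cohort == "HC", ]
  rp <- cfg$rois$OR
  se_mean <- rp$sigma_dchi["HC"] / sqrt(nrow(hc))
  expect_lt(abs(mean(hc$dchi.OR) - rp$mu_dchi["HC"]), 3 * se_mean)
  se_sd <- rp$sigma_dchi["HC"] / sqrt(2 * (nrow(hc) - 1))
  expect_lt(abs(sd(hc$dchi.OR) - rp$sigma_dchi["HC"]), 3 * se_sd)
})

test_that("orientation artefact injection behaves as designed", {
  cfg <- tiny_config(n_hc = 3, n_ms = 3, voxels = 200, seed = 23)
  ds <- generate_cohort_dataset(cfg)
  expect_identical(inject_orientation_artifact(ds$voxels, 0), ds$voxels)
  ## cos^2-collinear bias shifts every fitted slope by exactly the amplitude
  f0 <- fit_all_subjects(ds$voxels)
  f1 <- fit_all_subjects(inject_orientation_artifact(ds$voxels, 10, "cos2"))
  expect_equal(f1$delta_chi, f0$delta_chi + 10, tolerance = 1e-9)
  expect_equal(f1$chi_iso, f0$chi_iso, tolerance = 1e-9)
  ## ROI-orthogonalized bias barely moves the tract fits
  f2 <- fit_all_subjects(inject_orientation_artifact(ds$voxels, 10,
                                                     "orthogonal"))
  expect_lt(max(abs(f2$delta_chi - f0$delta_chi)), 0.5)
})

test_that("datasets round-trip through TSV/YAML", {
  cfg <- tiny_config(n_hc = 2, n_ms = 2, voxels = 20, seed = 29)
  ds <- generate_cohort_dataset(cfg)
  dir <- withr::local_tempdir()
  write_cohort_dataset(ds, dir)
  vox <- read_voxel_table(file.path(dir, "voxels.tsv"))
  expect_equal(nrow(vox), nrow(ds$voxels))
  expect_equal(vox$chi_app_ppb, ds$voxels$chi_app_ppb, tolerance = 1e-9)
  cfg2 <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg2$n_ms, 2)
  expect_equal(cfg2$rois$OR$mu_dchi$HC, 27)
})
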