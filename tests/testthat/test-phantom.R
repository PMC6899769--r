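test_that("phantom specifications are validated", {
  expect_error(phantom_spec(kinetics = list(femur = list(Kpat = -1, VB = 0))),
               ">= 0")
  expect_error(phantom_spec(relaxation = list(femur = list(T1rho = 0, T2 = 20, S0 = 1))),
               "> 0")
  expect_error(phantom_spec(pet_noise = -1), ">= 0")
  expect_error(phantom_spec(weight_kg = 0), "> 0")
})

test_that("phantom regions are disjoint and cover all five tissues", {
  spec <- quiet_phantom()
  counts <- table(spec$labels[spec$labels > 0])
  expect_setequal(as.integer(names(counts)), 1:5)
  expect_true(all(counts > 50))
  # labels are a single integer volume: disjoint by construction; the sum of
  # per-label counts must equal the number of nonzero voxels
  expect_equal(sum(counts), sum(spec$labels > 0))
})

test_that("noiseless region means equal the analytic frame averages", {
  spec <- quiet_phantom()
  r <- render_dynamic_pet(spec)
  mat <- matrix(r$series$data, nrow = prod(spec$dim))
  for (nm in c("femur", "acetabulum", "cartilage_femoral", "artery")) {
    lab <- spec$label_table$label[spec$label_table$region == nm]
    got <- colMeans(mat[which(spec$labels == lab), , drop = FALSE])
    expect_equal(got, r$truth$region_tacs[[nm]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # background voxels stay zero
  expect_equal(max(abs(mat[which(spec$labels == 0), ])), 0)
})

test_that("renders are bit-identical under a fixed seed and differ across seeds", {
  spec <- phantom_spec(pet_noise = 0.17, mr_sigma = 2, seed = 7L)
  expect_identical(render_dynamic_pet(spec)$series$data,
                   render_dynamic_pet(spec)$series$data)
  expect_identical(render_relax_series(spec, "t1rho")$series$data,
                   render_relax_series(spec, "t1rho")$series$data)
  spec2 <- phantom_spec(pet_noise = 0.17, seed = 8L)
  expect_false(identical(render_dynamic_pet(spec)$series$data,
                         render_dynamic_pet(spec2)$series$data))
})

test_that("PET noise scales as sqrt(signal / frame duration)", {
  spec <- phantom_spec(pet_noise = 0.3, seed = 11L)
  clean <- render_dynamic_pet(quiet_phantom())$series$data
  noisy <- render_dynamic_pet(spec)$series$data
  resid <- noisy - clean
  s <- spec$schedule
  # pick one long and one short frame inside the acetabulum
  idx <- which(spec$labels == 2)
  for (f in c(3L, 28L)) {
    expected_sd <- spec$pet_noise * sqrt(clean[idx[1] + (f - 1) * prod(spec$dim)] /
                                         (s$duration_s[f] / 60))
    got_sd <- stats::sd(resid[idx + (f - 1) * prod(spec$dim)])
    expect_lt(abs(got_sd - expected_sd) / expected_sd, 0.15)
  }
})

test_that("relaxation-weighted snapshots follow the closed-form decay", {
  spec <- quiet_phantom()
  r <- render_relax_series(spec, "t1rho")
  lab3 <- which(spec$labels == 3)  # femoral cartilage, T1rho = 36.44 ms
  v <- vapply(seq_along(spec$tsl_ms),
              function(i) r$series$data[lab3[1] + (i - 1) * prod(spec$dim)],
              numeric(1))
  expect_equal(v, 100 * exp(-spec$tsl_ms / 36.44), tolerance = 1e-12)
  # closed-form worked example: T = 50 ms, S0 = 100 on the TSL grid
  expect_equal(100 * exp(-c(0, 15, 30, 45) / 50),
               c(100, 74.08182, 54.88116, 40.65697), tolerance = 1e-6)
  # T -> infinity limit: constant signal
  spec_inf <- phantom_spec(pet_noise = 0, mr_sigma = 0,
                           relaxation = list(femur = list(T1rho = 1e12, T2 = 1e12, S0 = 70)))
  rinf <- render_relax_series(spec_inf, "t1rho")
  labf <- which(spec_inf$labels == 1)
  sig <- matrix(rinf$series$data, nrow = prod(spec_inf$dim))[labf[1], ]
  expect_equal(sig, rep(70, 4), tolerance = 1e-9)
})

test_that("MR noise has the configured standard deviation", {
  spec <- phantom_spec(pet_noise = 0, mr_sigma = 1, seed = 5L)
  clean <- render_relax_series(quiet_phantom(), "t2")$series$data
  noisy <- render_relax_series(spec, "t2")$series$data
  resid <- as.vector(noisy - clean)
  expect_gt(length(resid), 1e4)
  expect_lt(abs(stats::sd(resid) - 1), 0.05)   # within 5% at n >> 1e4
})

test_that("simulated two-rater tables have the planted raw agreement", {
  tabs <- simulate_lesion_scores(n_subjects = 300, disagree = 0.07, seed = 2L)
  expect_s3_class(tabs$rater_a, "lesion_score_table")
  ag <- rater_agreement(tabs$rater_a, tabs$rater_b, type = "pooled")
  expect_lt(abs(ag$agreement_pct - 93), 1.5)   # E[agreement] = 93%
  expect_gt(ag$kappa, 0.8)
})

test_that("subject covariates carry the planted severity-pain correlation", {
  subj <- phantom_subjects(n = 2000, planted_r = 0.8, seed = 3L)
  expect_true(all(subj$hoos_pain >= 0 & subj$hoos_pain <= 100))
  expect_false(any(duplicated(subj$subject)))
  r <- stats::cor(subj$severity, subj$hoos_pain)
  expect_lt(abs(r - 0.8), 0.05)
})
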