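test_that("identically shaped surfaces in different poses align to coincide", {
  tpl <- femur_template()
  posed <- list(tpl,
                rigid_move(tpl, c(0.4, 0.1, -0.3), c(5, 8, -2)),
                rigid_move(tpl, c(-0.2, 0.6, 0.1), c(-9, 3, 4)))
  al <- align_surfaces(posed)
  for (i in 2:3) {
    expect_lt(sqrt(mean((al[[i]] - al[[1]])^2)), 1e-6)
  }
  # rotations proper: det(R) = +1 for every subject
  dets <- vapply(attr(al, "rotations"), det, numeric(1))
  expect_equal(dets, rep(1, 3), tolerance = 1e-10)
})

test_that("pure translations reduce alignment to centroid removal", {
  tpl <- femur_template()
  moved <- sweep(tpl, 2, c(30, -12, 5), "+")
  al <- align_surfaces(list(tpl, moved))
  expect_equal(al[[2]], sweep(moved, 2, colMeans(moved)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("alignment never introduces reflections", {
  # a strongly asymmetric perturbation that would tempt an unconstrained
  # least-squares rotation into det = -1
  tpl <- femur_template()
  set.seed(4)
  surfaces <- lapply(1:5, function(i) {
    s <- tpl + matrix(stats::rnorm(length(tpl), sd = 2), ncol = 3)
    rigid_move(s, stats::runif(3, -1, 1), stats::rnorm(3, 0, 10))
  })
  al <- align_surfaces(surfaces)
  dets <- vapply(attr(al, "rotations"), det, numeric(1))
  expect_true(all(abs(dets - 1) < 1e-8))
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  # tiny instance: 20 points x 5 subjects, oracle = eigen() of the 60x60
  # sample covariance of the flattened vectors
  set.seed(6)
  surfaces <- lapply(1:5, function(i) matrix(stats::rnorm(60), 20, 3))
  model <- fit_pca(surfaces)
  X <- t(vapply(surfaces, as.vector, numeric(60)))
  C <- stats::cov(X)
  ev <- eigen(C, symmetric = TRUE)
  expect_equal(model$eigenvalues, ev$values[1:4], tolerance = 1e-10)
  for (j in 1:4) {
    # modes match up to sign
    dot <- abs(sum(model$modes[, j] * ev$vectors[, j]))
    expect_equal(dot, 1, tolerance = 1e-10)
  }
  expect_equal(sum(model$variance_fraction), 1, tolerance = 1e-12)
})

test_that("a rank-1 family loads entirely on the first mode", {
  tpl <- femur_template()
  mode <- femur_modes(tpl)[, 2]
  surfaces <- lapply(c(-3, 3), function(s) tpl + matrix(s * mode, ncol = 3))
  model <- fit_pca(surfaces, m = 1)
  expect_equal(model$variance_fraction[1], 1, tolerance = 1e-12)
  # the recovered direction is the planted one up to sign
  expect_equal(abs(sum(model$modes[, 1] * mode)), 1, tolerance = 1e-10)
})

test_that("shape model invariants hold on a sampled cohort", {
  cohort <- sample_femur_surfaces(n_subjects = 30, seed = 12)
  model <- fit_pca(align_surfaces(cohort$surfaces))
  expect_true(all(diff(model$eigenvalues) <= 1e-12))
  expect_true(all(model$variance_fraction >= 0 & model$variance_fraction <= 1))
  expect_lte(sum(model$variance_fraction), 1 + 1e-12)
  expect_equal(colMeans(model$scores), rep(0, ncol(model$scores)),
               tolerance = 1e-10)
  G <- crossprod(model$modes)
  expect_equal(G, diag(ncol(model$modes)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: largest-|loading| entry of each mode is positive
  for (j in seq_len(ncol(model$modes))) {
    expect_gt(model$modes[which.max(abs(model$modes[, j])), j], 0)
  }
})

test_that("reconstruction is linear, symmetric and complete", {
  cohort <- sample_femur_surfaces(n_subjects = 20, seed = 13)
  al <- align_surfaces(cohort$surfaces)
  model <- fit_pca(al)
  expect_equal(reconstruct(model, numeric(0)), model$mean,
               tolerance = 1e-12, ignore_attr = TRUE)
  up <- reconstruct(model, c(0, 2))
  dn <- reconstruct(model, c(0, -2))
  expect_equal(up - model$mean, -(dn - model$mean), tolerance = 1e-10)
  # full-score reconstruction reproduces each member
  for (i in c(1, 7)) {
    rec <- reconstruct(model, model$scores[i, ], units = "raw")
    expect_lt(max(abs(rec - al[[i]])), 1e-8)
  }
  # project-then-reconstruct round trip
  sc <- project_scores(model, al[[3]])
  expect_lt(max(abs(reconstruct(model, sc, units = "raw") - al[[3]])), 1e-8)
})

test_that("planted two-mode cohorts recover fractions and subspace", {
  cohort <- sample_femur_surfaces(n_subjects = 50, mode_sd = c(2, 1), seed = 11)
  model <- fit_pca(align_surfaces(cohort$surfaces), m = 2)
  expect_lt(abs(model$variance_fraction[1] - 0.8), 0.08)  # single-cohort noise
  expect_lt(abs(model$variance_fraction[2] - 0.2), 0.08)
  expect_lt(max(principal_angles(model$modes, cohort$truth$modes)), 5)
})

test_that("subspace recovery tolerates shape-level measurement noise", {
  # noise totalling 10% of the smallest planted mode's SD in shape-vector
  # norm; per-coordinate point noise of that relative size would instead add
  # an isotropic variance floor of order sigma^2 * 3N and visibly rotate the
  # recovered subspace (see the methods discussion)
  cohort <- sample_femur_surfaces(n_subjects = 50, mode_sd = c(2, 1), seed = 21)
  p3 <- length(cohort$surfaces[[1]])
  sd_coord <- 0.1 * 1 / sqrt(p3)
  noisy <- lapply(seq_along(cohort$surfaces), function(i) {
    set.seed(100 + i)
    s <- cohort$surfaces[[i]] + matrix(stats::rnorm(p3, sd = sd_coord), ncol = 3)
    attr(s, "part") <- attr(cohort$surfaces[[i]], "part")
    s
  })
  model <- fit_pca(align_surfaces(noisy), m = 2)
  expect_lt(max(principal_angles(model$modes, cohort$truth$modes)), 5)
})

test_that("planted outcome correlations are realized in large cohorts", {
  cohort <- sample_femur_surfaces(n_subjects = 500, mode_sd = c(4, 2),
                                  planted_r = 0.8, seed = 9)
  # sampling band for r = 0.8 at n = 500 (a shade over two Fisher-z SEs)
  r_true <- stats::cor(cohort$truth$scores[, 1], cohort$truth$outcome)
  expect_gt(r_true, 0.74)
  expect_lt(r_true, 0.85)
  # the recovered score carries estimation noise on top but stays in band
  model <- fit_pca(align_surfaces(cohort$surfaces), m = 2)
  r_rec <- abs(stats::cor(model$scores[, 1], cohort$truth$outcome))
  expect_gt(r_rec, 0.74)
  expect_lt(r_rec, 0.85)
})

test_that("geometric probes identify the planted anatomical modes", {
  # cohort dominated by the head-size mode
  tpl <- femur_template()
  modes <- femur_modes(tpl)
  cohort <- sample_femur_surfaces(n_subjects = 40, mode_sd = c(0.01, 3),
                                  template = tpl, modes = modes, seed = 7)
  model <- fit_pca(align_surfaces(cohort$surfaces), m = 2)
  rep1 <- mode_feature_report(model)
  lead <- rep1[1, ]  # dominant mode = head size
  expect_gt(abs(lead$head_radius), 5 * abs(lead$shaft_thickness))
  # neck-shaft-angle mode responds monotonically over [-2, 2] SD
  cohort2 <- sample_femur_surfaces(n_subjects = 40, mode_sd = c(0.01, 0.01, 0.01, 3),
                                   template = tpl, modes = modes, seed = 8)
  model2 <- fit_pca(align_surfaces(cohort2$surfaces), m = 4)
  angles <- vapply(seq(-2, 2, by = 1), function(s) {
    sc <- rep(0, 1); sc[1] <- s
    femur_probes(reconstruct(model2, sc))[["neck_shaft_angle_deg"]]
  }, numeric(1))
  expect_true(all(diff(angles) > 0) || all(diff(angles) < 0))
  # null scores leave every probe unchanged
  base <- femur_probes(reconstruct(model, numeric(0)))
  again <- femur_probes(reconstruct(model, c(0, 0)))
  expect_equal(base, again, tolerance = 1e-12)
})

test_that("planted modes are orthonormal; non-orthogonal ones warn", {
  tpl <- femur_template()
  M <- femur_modes(tpl)
  expect_equal(crossprod(M), diag(ncol(M)), tolerance = 1e-10,
               ignore_attr = TRUE)
  oblique <- cbind(M[, 1], (M[, 1] + M[, 2]) / sqrt(2))
  expect_warning(sample_femur_surfaces(n_subjects = 3, mode_sd = c(1, 1),
                                       template = tpl, modes = oblique, seed = 1),
                 "not mutually orthogonal")
})

test_that("shape models round-trip through the CSV bundle", {
  cohort <- sample_femur_surfaces(n_subjects = 10, seed = 14)
  model <- fit_pca(align_surfaces(cohort$surfaces), m = 3)
  dir <- withr::local_tempdir()
  write_shape_model(model, dir)
  ev <- utils::read.csv(file.path(dir, "eigenvalues.csv"))
  expect_equal(ev$eigenvalue, model$eigenvalues, tolerance = 1e-10)
  modes <- as.matrix(utils::read.csv(file.path(dir, "modes.csv")))
  expect_equal(unname(modes), unname(model$modes), tolerance = 1e-10)
})

test_that("pairwise alignment matches the reference Procrustes solution", {
  tpl <- femur_template()
  moved <- rigid_move(tpl, c(0, 0, 0.4), c(5, -3, 8))
  al <- align_surfaces(list(tpl, moved))
  ref <- vegan::procrustes(al[[1]], scale(moved, scale = FALSE),
                           scale = FALSE, symmetric = FALSE)
  expect_equal(unclass(al[[2]]), unname(ref$Yrot), tolerance = 1e-10,
               ignore_attr = TRUE)
})
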