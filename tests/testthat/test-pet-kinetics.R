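test_that("SUV is the definitional dose-per-weight normalization", {
  vol <- array(250 / 70, c(4, 4, 2))
  expect_equal(compute_suv(vol, 70, 250)$data, array(1, c(4, 4, 2)))
  expect_equal(compute_suv(2 * vol, 70, 250)$data, array(2, c(4, 4, 2)))
  # direct formula oracle on an arbitrary volume
  set.seed(1)
  act <- array(stats::runif(60, 0, 30), c(5, 4, 3))
  expect_equal(compute_suv(act, 70, 250)$data, act * 70 / 250, tolerance = 1e-14)
  expect_error(compute_suv(vol, 0, 250), "weight")
  expect_error(compute_suv(vol, 70, -1), "dose")
  expect_error(compute_suv(array(-1, c(2, 2, 2)), 70, 250), ">= 0")
})

test_that("static uptake is the duration-weighted late-frame mean", {
  sched <- make_frame_schedule(list(c(2, 600), c(2, 1200)))
  dat <- array(0, c(2, 2, 1, 4))
  for (f in 1:4) dat[, , , f] <- f
  ser <- new_dynamic_pet(dat, sched)
  # frame starts are 0, 10, 20, 40 min; the window keeps frames 3 and 4
  expect_equal(static_uptake(ser, from_min = 20)[1, 1, 1],
               (3 * 1200 + 4 * 1200) / 2400)
  expect_error(static_uptake(ser, from_min = 60), "no frames")
})

test_that("mask-derived input functions equal the phantom truth exactly", {
  spec <- quiet_phantom()
  r <- render_dynamic_pet(spec)
  aif <- extract_aif(r$series, artery_mask = spec$labels == 5)
  expect_equal(aif$activity, r$truth$aif_frames, tolerance = 1e-14)
  expect_equal(aif$provenance, "mask-derived")
  expect_equal(aif$n_voxels, sum(spec$labels == 5))
})

test_that("automatic artery isolation finds true artery voxels", {
  spec <- quiet_phantom()
  r <- render_dynamic_pet(spec)
  aif <- extract_aif(r$series)
  expect_equal(aif$provenance, "auto-extracted")
  sel <- attr(aif, "voxel_index")
  expect_true(all(sel %in% which(spec$labels == 5)))
  expect_lt(max(abs(aif$activity - r$truth$aif_frames)) / max(r$truth$aif_frames),
            0.01)
})

test_that("automatic extraction fails informatively without an arterial signal", {
  sched <- make_frame_schedule(list(c(6, 60)))
  const <- new_dynamic_pet(array(5, c(4, 4, 2, 6)), sched)
  expect_error(extract_aif(const), "no arterial signal")
  short <- new_dynamic_pet(array(5, c(4, 4, 2, 3)),
                           make_frame_schedule(list(c(3, 60))))
  expect_error(extract_aif(short), "at least 4 frames")
})

test_that("the Patlak transform is the exact algebraic identity on exact TACs", {
  m <- aif_model()
  t <- table2_schedule()$mid_min
  saif <- simulate_aif(m, t)
  tac <- simulate_tissue_tac(saif, Kpat = 0.015, VB = 0.05)
  pts <- patlak_transform(tac, saif)
  expect_equal(pts$y, 0.015 * pts$x + 0.05, tolerance = 1e-12)
  # pure blood voxel: y = 1 everywhere, slope 0, intercept 1
  blood <- patlak_fit(patlak_transform(saif$activity, saif), t_star = 15)
  expect_equal(blood$Kpat, 0, tolerance = 1e-12)
  expect_equal(blood$VB, 1, tolerance = 1e-12)
})

test_that("near-zero plasma samples are dropped and reported", {
  tm <- c(0.5, 1, 2, 5, 10, 20)
  p <- c(5, 3, 1, 0.5, 0, 0)           # decayed to zero late
  aif <- new_input_function(tm, p)
  pts <- patlak_transform(rep(1, 6), aif)
  expect_equal(nrow(pts), 4L)
  expect_equal(attr(pts, "n_dropped"), 2L)
  expect_error(patlak_transform(rep(1, 6),
                                new_input_function(tm, c(1, 0, 0, 0, 0, 0))),
               "fewer than 2")
})

test_that("trapezoidal normalized time is accurate once the bolus has passed", {
  m <- aif_model()
  t <- table2_schedule()$mid_min
  saif <- simulate_aif(m, t)
  pts <- patlak_transform(saif$activity * 0, saif)  # only x matters
  x_exact <- aif_integral(m, t) / eval_aif(m, t)
  rel <- abs(pts$x - x_exact) / x_exact
  # the bolus-onset frames carry a few-percent trapezoid error by
  # construction; the error carried into the fit window is a fraction of a
  # percent and shrinks as the integral grows
  expect_lt(max(rel[t >= 2]), 0.01)
  expect_lt(max(rel[t >= 5]), 0.005)
  expect_lt(max(rel[t >= 15]), 0.003)  # the window the fit uses
})

test_that("Patlak fits recover exact parameters and handle edge cases", {
  m <- aif_model()
  t <- table2_schedule()$mid_min
  saif <- simulate_aif(m, t)
  for (kp in c(0.007, 0.015, 0.04)) {
    tac <- simulate_tissue_tac(saif, Kpat = kp, VB = 0.05)
    fit <- patlak_fit(patlak_transform(tac, saif), t_star = 15)
    expect_lt(abs(fit$Kpat - kp) / kp, 1e-8)
    expect_lt(abs(fit$VB - 0.05) / 0.05, 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  # exactness holds at any equilibration cutoff
  tac <- simulate_tissue_tac(saif, Kpat = 0.015, VB = 0.05)
  for (ts in c(0, 0.5, 5, 30)) {
    expect_lt(abs(patlak_fit(patlak_transform(tac, saif), t_star = ts)$Kpat -
                  0.015) / 0.015, 1e-8)
  }
  # two points: exact line, R^2 = 1
  two <- data.frame(t_min = c(20, 40), x = c(30, 60), y = c(1, 2))
  f2 <- patlak_fit(two, t_star = 15)
  expect_equal(f2$Kpat, 1 / 30)
  expect_equal(f2$r_squared, 1)
  expect_equal(f2$n_used, 2L)
  expect_error(patlak_fit(two, t_star = 35), "fewer than 2")
  degen <- data.frame(t_min = c(20, 40), x = c(30, 30), y = c(1, 2))
  expect_error(patlak_fit(degen, t_star = 15), "degenerate")
})

test_that("Kpat is invariant to joint rescaling of TAC and input function", {
  m <- aif_model()
  t <- table2_schedule()$mid_min
  saif <- simulate_aif(m, t)
  tac <- simulate_tissue_tac(saif, Kpat = 0.015, VB = 0.05)
  f1 <- patlak_fit(patlak_transform(tac, saif), t_star = 15)
  scaled <- new_input_function(t, saif$activity * 37)
  f2 <- patlak_fit(patlak_transform(tac * 37, scaled), t_star = 15)
  expect_equal(f2$Kpat, f1$Kpat, tolerance = 1e-12)
  expect_equal(f2$VB, f1$VB, tolerance = 1e-12)
})

test_that("compartment-mode fits approach the influx constant K1 k3 / (k2 + k3)", {
  m <- aif_model()
  t <- table2_schedule()$mid_min
  saif <- simulate_aif(m, t)
  tac <- simulate_tissue_tac(m, t, K1 = 0.1, k2 = 0.2, k3 = 0.1,
                             mode = "compartment")
  fit <- patlak_fit(patlak_transform(tac, saif), t_star = 15)
  target <- kpat_from_compartment(0.1, 0.2, 0.1)
  expect_lt(abs(fit$Kpat - target) / target, 0.02)
})

test_that("voxelwise Patlak agrees with the per-region fit", {
  spec <- quiet_phantom()
  r <- render_dynamic_pet(spec)
  aif <- extract_aif(r$series, artery_mask = spec$labels == 5)
  vox <- patlak_voxelwise(r$series, aif, mask = spec$labels == 2)
  reg <- patlak_by_region(r$series, aif, phantom_mask_set(spec))
  k_reg <- reg$Kpat[reg$region == "acetabulum"]
  expect_equal(mean(vox$Kpat[spec$labels == 2]), k_reg, tolerance = 1e-10)
  expect_true(all(is.na(vox$Kpat[spec$labels != 2])))
  # noiseless recovery of the planted acetabular Kpat from the rendered image
  expect_lt(abs(k_reg - 0.015) / 0.015, 0.02)
})

test_that("region summaries report mean, max and counts; empty regions are flagged", {
  vol <- array(0, c(4, 4, 1))
  vol[1, 1, 1] <- 1; vol[2, 1, 1] <- 1
  masks <- region_mask_set(vol, data.frame(label = c(1, 2),
                                           region = c("a", "b")))
  map <- array(5, c(4, 4, 1))
  map[1, 1, 1] <- 1; map[2, 1, 1] <- 3
  out <- region_summary(map, masks)
  expect_equal(out$mean[out$region == "a"], 2)
  expect_equal(out$max[out$region == "a"], 3)
  expect_equal(out$n_voxels[out$region == "a"], 2L)
  expect_equal(attr(out, "empty_regions"), "b")
  expect_false("b" %in% out$region)
  # uniform map: mean = max everywhere
  u <- region_summary(array(7, c(4, 4, 1)), masks)
  expect_equal(u$mean, u$max)
})
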