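test_that("mask sets validate their label dictionary", {
  vol <- array(0L, c(3, 3, 1)); vol[1, 1, 1] <- 2L
  expect_error(region_mask_set(vol, data.frame(label = 1, region = "a")),
               "missing from dictionary")
  vol2 <- array(-1L, c(2, 2, 1))
  expect_error(region_mask_set(vol2, data.frame(label = -1, region = "a")),
               "nonnegative")
})

test_that("identity resampling returns the input unchanged", {
  set.seed(2)
  vol <- array(stats::runif(4 * 5 * 3), c(4, 5, 3))
  a <- affine_from_spacing(c(1, 1, 1))
  out <- resample_to_grid(vol, a, a, dim(vol), "linear")
  expect_equal(out, vol, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(out, "n_out_of_field"), 0L)
})

test_that("orthogonal regrids permute labels exactly and conserve counts", {
  set.seed(3)
  vol <- array(sample(0:3, 6^3, replace = TRUE), c(6, 6, 6))
  src <- affine_from_spacing(c(1, 1, 1))
  # target axes: x <- y, y <- z, z <- x (a pure permutation)
  perm <- matrix(0, 4, 4); perm[1, 2] <- 1; perm[2, 3] <- 1; perm[3, 1] <- 1
  perm[4, 4] <- 1
  out <- resample_to_grid(vol, src, perm, c(6, 6, 6), "nearest")
  expect_equal(as.integer(table(out)), as.integer(table(vol)))
  # out[tx,ty,tz] samples vol at world = (ty, tz, tx)
  for (k in 1:4) {
    i <- arrayInd(which(vol == (k - 1))[1], dim(vol)) - 1   # 0-based source idx
    expect_equal(out[i[3] + 1, i[1] + 1, i[2] + 1],
                 vol[i[1] + 1, i[2] + 1, i[3] + 1])
  }
})

test_that("subvoxel shifts of a linear ramp interpolate exactly", {
  ramp <- array(rep(1:10, times = 6 * 4), c(10, 6, 4))
  src <- affine_from_spacing(c(1, 1, 1))
  tgt <- affine_from_spacing(c(1, 1, 1), origin = c(0.5, 0, 0))
  out <- resample_to_grid(ramp, src, tgt, dim(ramp), "linear")
  interior <- out[1:9, , ]
  expected <- array(rep(1:9 + 0.5, times = 6 * 4), c(9, 6, 4))
  expect_equal(interior, expected, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(resample_to_grid(ramp, matrix(0, 4, 4), tgt, dim(ramp)),
               "invertible")
})

test_that("registering an image to itself returns a near-zero field", {
  spec <- quiet_phantom()
  img <- render_dynamic_pet(spec)$series$data[, , , 28]
  fld <- register_nonrigid(img, img, maxit = 20)
  expect_lt(max(abs(fld$disp)), 0.5)
})

test_that("a known smooth warp is recovered: Dice >= 0.90 and sub-voxel field error", {
  spec <- quiet_phantom()
  img <- array(as.numeric(spec$labels > 0), spec$dim)
  warp <- synthetic_warp(spec$dim, amplitude = 3)
  moved <- apply_displacement(img, warp)
  moved_lab <- apply_displacement(spec$labels, warp, "nearest")
  # the warp is large enough that unregistered overlap fails the criterion
  expect_lt(dice_coefficient(spec$labels > 0, moved_lab > 0), 0.90)
  fld <- register_nonrigid(img, moved)
  expect_lt(fld$mse_after, fld$mse_before / 4)
  prop <- propagate_masks(fld, phantom_mask_set(spec))
  expect_gte(dice_coefficient(prop$volume > 0, moved_lab > 0), 0.90)
  resid <- sqrt(rowSums((matrix(fld$disp, ncol = 3) -
                         matrix(warp$disp, ncol = 3))^2))
  expect_lt(mean(resid[as.vector(moved > 0.1)]), 1)
})

test_that("registration quality is symmetric under input swap", {
  spec <- quiet_phantom()
  img <- array(as.numeric(spec$labels > 0), spec$dim)
  warp <- synthetic_warp(spec$dim, amplitude = 2)
  moved <- apply_displacement(img, warp)
  moved_lab <- apply_displacement(spec$labels, warp, "nearest")
  f_ab <- register_nonrigid(img, moved, maxit = 60)
  f_ba <- register_nonrigid(moved, img, maxit = 60)
  d_ab <- dice_coefficient(apply_displacement(spec$labels, f_ab, "nearest") > 0,
                           moved_lab > 0)
  d_ba <- dice_coefficient(apply_displacement(moved_lab, f_ba, "nearest") > 0,
                           spec$labels > 0)
  expect_lt(abs(d_ab - d_ba), 0.02)
  # and deterministic: same inputs, same field
  f_ab2 <- register_nonrigid(img, moved, maxit = 60)
  expect_identical(f_ab$disp, f_ab2$disp)
})

test_that("label propagation through trivial fields is exact", {
  spec <- quiet_phantom()
  masks <- phantom_mask_set(spec)
  zero <- synthetic_warp(spec$dim, amplitude = 0)
  expect_equal(propagate_masks(zero, masks)$volume, masks$volume,
               ignore_attr = TRUE)
  # integer translation: labels move exactly
  tr <- zero
  tr$disp[, , , 1] <- 2
  shifted <- propagate_masks(tr, masks)$volume
  d <- spec$dim
  expect_equal(shifted[1:(d[1] - 2), , ], masks$volume[3:d[1], , ],
               ignore_attr = TRUE)
})

test_that("active-contour refinement moves labels toward intensity edges", {
  # blurred-edge sphere whose initial mask is shifted and eroded
  d <- c(24, 24, 24)
  g <- expand.grid(x = 1:24, y = 1:24, z = 1:24)
  r <- sqrt((g$x - 12.5)^2 + (g$y - 12.5)^2 + (g$z - 12.5)^2)
  truth <- array(as.integer(r <= 7), d)
  image <- hipoa:::gauss_smooth3(array(as.numeric(truth), d), 1.5)
  init <- array(as.integer(sqrt((g$x - 14)^2 + (g$y - 13)^2 + (g$z - 12.5)^2) <= 5.5), d)
  masks <- region_mask_set(init, data.frame(label = 1, region = "bone"))
  zero <- synthetic_warp(d, amplitude = 0)
  plain <- propagate_masks(zero, masks)
  refined <- propagate_masks(zero, masks, refine = TRUE, image = image,
                             iterations = 15, lambda_smooth = 0.05)
  d0 <- dice_coefficient(plain$volume, truth, 1)
  d1 <- dice_coefficient(refined$volume, truth, 1)
  expect_gt(d1, d0)
  expect_gt(d1, 0.9)
  expect_error(propagate_masks(zero, masks, refine = TRUE), "intensity image")
})

test_that("Dice behaves as a set-overlap measure", {
  a <- array(0L, c(3, 3, 1)); b <- a
  a[1:2, 1, 1] <- 1L; b[2:3, 1, 1] <- 1L
  expect_equal(dice_coefficient(a, b, 1), 2 * 1 / 4)
  expect_equal(dice_coefficient(a, a, 1), 1)
  expect_true(is.na(dice_coefficient(a * 0L, b * 0L, 1)))
})
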