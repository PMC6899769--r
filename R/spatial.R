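#' Labelled region mask set
#'
#' An integer label volume plus a dictionary mapping labels to region names
#' (femur, acetabulum, cartilage subregions, artery, ...).
#'
#' @param volume integer 3D array, 0 = background.
#' @param table data frame with columns `label`, `region` covering every
#'   nonzero label in `volume`.
#' @param affine optional 4x4 voxel-to-world matrix (RAS+, mm).
#' @export
region_mask_set <- function(volume, table, affine = NULL) {
  labs <- sort(unique(as.vector(volume)))
  labs <- labs[labs != 0]
  if (any(labs < 0) || any(labs != round(labs))) {
    stop("labels must be nonnegative integers", call. = FALSE)
  }
  missing <- setdiff(labs, table$label)
  if (length(missing)) stop("labels missing from dictionary: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  structure(list(volume = volume, table = table, affine = affine),
            class = "region_mask_set")
}

#' Mask set of a phantom specification
#' @param spec a `phantom_spec`.
#' @export
phantom_mask_set <- function(spec) {
  region_mask_set(spec$labels, spec$label_table,
                  affine = diag(c(spec$voxel_mm, 1)))
}

#' Resample a volume onto a target grid
#'
#' Maps every target voxel centre through the target affine to world (mm) and
#' back through the inverse source affine, then interpolates: trilinear for
#' intensity volumes, nearest-neighbour for label volumes. Voxel indices are
#' 0-based in the affine convention (RAS+); out-of-field voxels are set to 0
#' and counted in the `n_out_of_field` attribute.
#'
#' @param volume 3D source array.
#' @param src_affine,tgt_affine 4x4 voxel-to-world matrices.
#' @param tgt_dim target grid size (3 ints).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return resampled 3D array of size `tgt_dim`.
#' @export
resample_to_grid <- function(volume, src_affine, tgt_affine, tgt_dim,
                             interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (abs(det(src_affine)) < 1e-12 || abs(det(tgt_affine)) < 1e-12) {
    stop("affines must be invertible", call. = FALSE)
  }
  g <- as.matrix(expand.grid(x = seq_len(tgt_dim[1]) - 1,
                             y = seq_len(tgt_dim[2]) - 1,
                             z = seq_len(tgt_dim[3]) - 1))
  world <- cbind(g, 1) %*% t(tgt_affine)
  srcv <- world %*% t(solve(src_affine))
  pts <- srcv[, 1:3, drop = FALSE] + 1      # to 1-based array coordinates
  vals <- if (interpolation == "linear") {
    interp3_linear(volume, pts, fill = 0)
  } else {
    interp3_nearest(volume, pts, fill = 0)
  }
  d <- dim(volume)
  oof <- pts[, 1] < 1 - 1e-9 | pts[, 1] > d[1] + 1e-9 |
    pts[, 2] < 1 - 1e-9 | pts[, 2] > d[2] + 1e-9 |
    pts[, 3] < 1 - 1e-9 | pts[, 3] > d[3] + 1e-9
  out <- array(vals, tgt_dim)
  attr(out, "n_out_of_field") <- sum(oof)
  out
}

#' Simple voxel-to-world affine from spacing and origin
#' @param spacing voxel size (mm, 3 values).
#' @param origin world position of voxel (0,0,0) (mm).
#' @export
affine_from_spacing <- function(spacing, origin = c(0, 0, 0)) {
  a <- diag(c(spacing, 1))
  a[1:3, 4] <- origin
  a
}

# --- free-form deformation registration ------------------------------------

# separable Gaussian smoothing of a 3D array (reflected boundaries)
gauss_smooth3 <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  smooth_axis <- function(v, axis) {
    d <- dim(v)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    vp <- aperm(v, perm)
    dp <- dim(vp)
    m <- matrix(vp, dp[1], dp[2] * dp[3])
    n <- dp[1]
    pad <- rbind(m[pmin(r:1, n), , drop = FALSE], m,
                 m[pmax(n - 0:(r - 1), 1), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + n - 1), , drop = FALSE]
    aperm(array(out, dp), order(perm))
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}

# mean-pool downsampling by 2 along each axis
downsample2 <- function(vol) {
  d <- dim(vol)
  nd <- floor(d / 2)
  v <- vol[seq_len(2 * nd[1]), seq_len(2 * nd[2]), seq_len(2 * nd[3]), drop = FALSE]
  (v[seq(1, 2 * nd[1], 2), seq(1, 2 * nd[2], 2), seq(1, 2 * nd[3], 2), drop = FALSE] +
   v[seq(2, 2 * nd[1], 2), seq(1, 2 * nd[2], 2), seq(1, 2 * nd[3], 2), drop = FALSE] +
   v[seq(1, 2 * nd[1], 2), seq(2, 2 * nd[2], 2), seq(1, 2 * nd[3], 2), drop = FALSE] +
   v[seq(2, 2 * nd[1], 2), seq(2, 2 * nd[2], 2), seq(1, 2 * nd[3], 2), drop = FALSE] +
   v[seq(1, 2 * nd[1], 2), seq(1, 2 * nd[2], 2), seq(2, 2 * nd[3], 2), drop = FALSE] +
   v[seq(2, 2 * nd[1], 2), seq(1, 2 * nd[2], 2), seq(2, 2 * nd[3], 2), drop = FALSE] +
   v[seq(1, 2 * nd[1], 2), seq(2, 2 * nd[2], 2), seq(2, 2 * nd[3], 2), drop = FALSE] +
   v[seq(2, 2 * nd[1], 2), seq(2, 2 * nd[2], 2), seq(2, 2 * nd[3], 2), drop = FALSE]) / 8
}

# Gradient descent with Barzilai-Borwein steps and Armijo backtracking.
# The trilinear-interpolation objective is only piecewise smooth (derivative
# kinks at integer sample positions), which defeats strong-Wolfe line
# searches; plain descent with a sufficient-decrease backtrack is robust to
# the kinks and fully deterministic.
bb_descent <- function(par, fn, gr, maxit = 60, step0 = 0.3, tol = 1e-8) {
  f <- fn(par); g <- gr(par)
  p_prev <- NULL; g_prev <- NULL
  converged <- FALSE
  for (it in seq_len(maxit)) {
    gmax <- max(abs(g))
    if (gmax < 1e-14) { converged <- TRUE; break }
    if (is.null(p_prev)) {
      a <- step0 / gmax
    } else {
      s <- par - p_prev; yv <- g - g_prev
      sy <- sum(s * yv)
      a <- if (sy > 1e-30) sum(s * s) / sy else step0 / gmax
      a <- min(a, 1 / gmax)          # cap: at most 1 voxel change per step
    }
    gsq <- sum(g^2)
    accepted <- FALSE
    for (bt in 1:30) {
      pn <- par - a * g
      fnv <- fn(pn)
      if (is.finite(fnv) && fnv <= f - 1e-4 * a * gsq) { accepted <- TRUE; break }
      a <- a / 2
    }
    if (!accepted) { converged <- TRUE; break }   # no descent direction left
    p_prev <- par; g_prev <- g
    rel <- (f - fnv) / max(abs(f), 1e-30)
    par <- pn; f <- fnv; g <- gr(par)
    if (rel < tol) { converged <- TRUE; break }
  }
  list(par = par, value = f, converged = converged || maxit == 0)
}

# Control-grid geometry for a given image size and spacing: control points at
# 1 + spacing * (0 .. nc-1), covering the full grid.
ctrl_geometry <- function(d, spacing) {
  nc <- pmax(ceiling((d - 1) / spacing) + 1, 2)
  list(nc = nc, spacing = spacing)
}

# Per-voxel interpolation stencil into the control grid: 8 corner linear
# indices and weights for trilinear interpolation.
ctrl_stencil <- function(d, geom) {
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  s <- geom$spacing; nc <- geom$nc
  fx <- (g$x - 1) / s; fy <- (g$y - 1) / s; fz <- (g$z - 1) / s
  i0 <- pmin(floor(fx), nc[1] - 2); j0 <- pmin(floor(fy), nc[2] - 2)
  k0 <- pmin(floor(fz), nc[3] - 2)
  ax <- fx - i0; ay <- fy - j0; az <- fz - k0
  corners <- list()
  wts <- list()
  n <- 1L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    corners[[n]] <- (i0 + dx) + nc[1] * ((j0 + dy) + nc[2] * (k0 + dz)) + 1L
    wts[[n]] <- (if (dx) ax else 1 - ax) *
                (if (dy) ay else 1 - ay) *
                (if (dz) az else 1 - az)
    n <- n + 1L
  }
  list(corners = corners, wts = wts, n_ctrl = prod(nc))
}

ctrl_upsample <- function(P, stencil) {
  # P: n_ctrl vector -> dense voxel vector
  out <- 0
  for (n in 1:8) out <- out + stencil$wts[[n]] * P[stencil$corners[[n]]]
  out
}

ctrl_restrict <- function(v, stencil) {
  # transpose of ctrl_upsample: dense voxel vector -> n_ctrl vector
  out <- numeric(stencil$n_ctrl)
  for (n in 1:8) {
    acc <- rowsum(v * stencil$wts[[n]], stencil$corners[[n]])
    out[as.integer(rownames(acc))] <- out[as.integer(rownames(acc))] + acc[, 1]
  }
  out
}

# squared forward differences of the control lattice and their gradient
ctrl_roughness <- function(P3, nc) {
  pen <- 0
  grad <- array(0, dim(P3))
  arr <- array(P3, c(nc, 3))
  g <- array(0, c(nc, 3))
  for (ax in 1:3) {
    if (nc[ax] < 2) next
    idx_hi <- slice.index(arr, ax) > 1
    dif <- apply_diff(arr, ax)
    pen <- pen + sum(dif^2)
    g <- g + diff_transpose(dif, ax, nc)
  }
  list(pen = pen, grad = array(2 * g, dim(P3)))
}

apply_diff <- function(arr, ax) {
  nc <- dim(arr)[1:3]
  if (ax == 1) arr[-1, , , , drop = FALSE] - arr[-nc[1], , , , drop = FALSE]
  else if (ax == 2) arr[, -1, , , drop = FALSE] - arr[, -nc[2], , , drop = FALSE]
  else arr[, , -1, , drop = FALSE] - arr[, , -nc[3], , drop = FALSE]
}

diff_transpose <- function(dif, ax, nc) {
  g <- array(0, c(nc, 3))
  if (ax == 1) {
    g[-1, , , ] <- g[-1, , , , drop = FALSE] + dif
    g[-nc[1], , , ] <- g[-nc[1], , , , drop = FALSE] - dif
  } else if (ax == 2) {
    g[, -1, , ] <- g[, -1, , , drop = FALSE] + dif
    g[, -nc[2], , ] <- g[, -nc[2], , , drop = FALSE] - dif
  } else {
    g[, , -1, ] <- g[, , -1, , drop = FALSE] + dif
    g[, , -nc[3], ] <- g[, , -nc[3], , drop = FALSE] - dif
  }
  g
}

#' Nonrigid registration by multi-resolution free-form deformation
#'
#' Estimates a smooth displacement field u such that
#' `moving(x + u(x)) ~ fixed(x)` in the mean-squared-error sense. The field is
#' parameterized by displacements on a coarse control lattice interpolated
#' trilinearly to the voxel grid; a first-difference roughness penalty with
#' weight `lambda` regularizes the lattice. Optimization is quasi-Newton
#' (L-BFGS-B) with analytic gradients, run coarse-to-fine over `levels`
#' image pyramids. The procedure has no random initialization and is
#' deterministic given its inputs and configuration.
#'
#' @param moving,fixed 3D arrays on the same grid.
#' @param spacing control-point spacing in voxels at the finest level.
#' @param levels number of pyramid levels (downsampling by 2 per level);
#'   capped automatically so the coarsest level keeps at least 4 voxels per axis.
#' @param lambda roughness-penalty weight.
#' @param maxit L-BFGS-B iteration cap per level.
#' @param presmooth Gaussian sigma (voxels) applied to both images before
#'   matching at the finest level.
#' @return a `displacement_field`: list with `disp` (4D array, last dim = 3,
#'   voxel units; maps fixed-grid coordinates to moving-space sample points),
#'   `voxel_mm`, `converged`, `mse_before`, `mse_after`.
#' @export
register_nonrigid <- function(moving, fixed, spacing = 3, levels = 3,
                              lambda = 0.01, maxit = 80, presmooth = 1,
                              voxel_mm = c(1, 1, 1)) {
  if (!identical(dim(moving), dim(fixed))) {
    stop("moving and fixed must share a grid", call. = FALSE)
  }
  d <- dim(moving)
  if (min(d) < 2^(levels - 1) * 4) levels <- max(1, floor(log2(min(d) / 4)) + 1)
  pyr_m <- list(gauss_smooth3(moving, presmooth))
  pyr_f <- list(gauss_smooth3(fixed, presmooth))
  if (levels > 1) {
    for (l in 2:levels) {
      pyr_m[[l]] <- downsample2(pyr_m[[l - 1]])
      pyr_f[[l]] <- downsample2(pyr_f[[l - 1]])
    }
  }
  field <- NULL   # dense field at the previous (coarser) level
  conv <- TRUE
  for (l in levels:1) {
    M <- pyr_m[[l]]; FX <- pyr_f[[l]]
    dl <- dim(M)
    geom <- ctrl_geometry(dl, spacing)
    st <- ctrl_stencil(dl, geom)
    base <- as.matrix(expand.grid(x = seq_len(dl[1]), y = seq_len(dl[2]),
                                  z = seq_len(dl[3])))
    nvox <- nrow(base)
    # initialize control displacements from the coarser level's dense field
    P <- matrix(0, st$n_ctrl, 3)
    if (!is.null(field)) {
      cg <- expand.grid(x = 1 + geom$spacing * (0:(geom$nc[1] - 1)),
                        y = 1 + geom$spacing * (0:(geom$nc[2] - 1)),
                        z = 1 + geom$spacing * (0:(geom$nc[3] - 1)))
      coarse_pts <- (as.matrix(cg) + 0.5) / 2 + 0.25   # fine -> coarse coords
      for (c in 1:3) {
        P[, c] <- 2 * interp3_linear(field[, , , c], coarse_pts, fill = 0)
      }
    }
    scale_mse <- stats::var(as.vector(FX)); if (scale_mse <= 0) scale_mse <- 1
    objective <- function(par) {
      P3 <- matrix(par, ncol = 3)
      pos <- base
      for (c in 1:3) pos[, c] <- base[, c] + ctrl_upsample(P3[, c], st)
      r <- interp3_linear(M, pos, edge = "clamp") - as.vector(FX)
      rough <- ctrl_roughness(P3, geom$nc)
      sum(r^2) / (nvox * scale_mse) + lambda * rough$pen / st$n_ctrl
    }
    gradient <- function(par) {
      P3 <- matrix(par, ncol = 3)
      pos <- base
      for (c in 1:3) pos[, c] <- base[, c] + ctrl_upsample(P3[, c], st)
      r <- interp3_linear(M, pos, edge = "clamp") - as.vector(FX)
      g <- matrix(0, st$n_ctrl, 3)
      for (c in 1:3) {
        e <- matrix(0, 1, 3); e[c] <- 0.5
        dM <- (interp3_linear(M, sweep(pos, 2, e[1, ], "+"), edge = "clamp") -
               interp3_linear(M, sweep(pos, 2, -e[1, ], "+"), edge = "clamp"))
        g[, c] <- ctrl_restrict(2 * r * dM / (nvox * scale_mse), st)
      }
      rough <- ctrl_roughness(P3, geom$nc)
      as.vector(g + lambda * rough$grad / st$n_ctrl)
    }
    opt <- bb_descent(as.vector(P), objective, gradient, maxit = maxit)
    if (!opt$converged) conv <- FALSE
    P <- matrix(opt$par, ncol = 3)
    field <- array(0, c(dl, 3))
    for (c in 1:3) field[, , , c] <- array(ctrl_upsample(P[, c], st), dl)
  }
  pos <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3])))
  warp_pos <- pos
  for (c in 1:3) warp_pos[, c] <- pos[, c] + as.vector(field[, , , c])
  mse_before <- mean((moving - fixed)^2)
  mse_after <- mean((interp3_linear(moving, warp_pos, edge = "clamp") - as.vector(fixed))^2)
  structure(list(disp = field, voxel_mm = voxel_mm,
                 converged = conv && mse_after <= mse_before,
                 mse_before = mse_before, mse_after = mse_after),
            class = "displacement_field")
}

#' Warp a volume with a displacement field
#'
#' Samples `volume` at `x + u(x)` for every voxel of the field's grid.
#' @param volume 3D array in the moving space.
#' @param field a `displacement_field` (or 4D displacement array).
#' @param interpolation `"linear"` or `"nearest"`.
#' @export
apply_displacement <- function(volume, field,
                               interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  disp <- if (inherits(field, "displacement_field")) field$disp else field
  d <- dim(disp)[1:3]
  pos <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3])))
  for (c in 1:3) pos[, c] <- pos[, c] + as.vector(disp[, , , c])
  vals <- if (interpolation == "linear") interp3_linear(volume, pos)
          else interp3_nearest(volume, pos)
  array(vals, d)
}

#' Propagate atlas labels through a displacement field
#'
#' Nearest-neighbour warp of an integer label volume, optionally followed by
#' an active-contour-style refinement that evolves each bone label toward
#' intensity edges: boundary voxels are exchanged with the background when
#' that lowers a piecewise-constant (Chan-Vese-like) energy with a curvature
#' penalty of weight `lambda_smooth`, and any fragment disconnected from the
#' region's main component is reverted, so the label's topology is preserved.
#'
#' @param field a `displacement_field` mapping reference to subject space.
#' @param masks a `region_mask_set` in the moving (atlas) space.
#' @param refine if `TRUE`, run the refinement against `image`.
#' @param image intensity volume in the fixed space (required when refining).
#' @param labels_to_refine label IDs to evolve (default: all).
#' @param iterations maximum refinement sweeps.
#' @param lambda_smooth curvature-penalty weight.
#' @return a `region_mask_set` on the field's grid.
#' @export
propagate_masks <- function(field, masks, refine = FALSE, image = NULL,
                            labels_to_refine = NULL, iterations = 10,
                            lambda_smooth = 0.5) {
  warped <- apply_displacement(masks$volume, field, interpolation = "nearest")
  warped <- array(as.integer(round(warped)), dim(warped))
  if (refine) {
    if (is.null(image)) stop("refinement requires an intensity image", call. = FALSE)
    if (is.null(labels_to_refine)) labels_to_refine <- masks$table$label
    for (lab in labels_to_refine) {
      warped <- refine_label_active_contour(warped, lab, image,
                                            iterations, lambda_smooth)
    }
  }
  region_mask_set(warped, masks$table, affine = masks$affine)
}

# count of 6-neighbours belonging to a mask, per voxel
neighbor_count6 <- function(mask) {
  d <- dim(mask)
  m <- mask * 1
  out <- array(0, d)
  out[-d[1], , ] <- out[-d[1], , ] + m[-1, , ]
  out[-1, , ] <- out[-1, , ] + m[-d[1], , ]
  out[, -d[2], ] <- out[, -d[2], ] + m[, -1, ]
  out[, -1, ] <- out[, -1, ] + m[, -d[2], ]
  out[, , -d[3]] <- out[, , -d[3]] + m[, , -1]
  out[, , -1] <- out[, , -1] + m[, , -d[3]]
  out
}

refine_label_active_contour <- function(labels, lab, image, iterations,
                                        lambda_smooth) {
  for (it in seq_len(iterations)) {
    inside <- labels == lab
    if (!any(inside)) break
    free <- labels == 0L
    mu_in <- mean(image[inside])
    mu_out <- if (any(free)) mean(image[free]) else mu_in  # piecewise-constant
    nb <- neighbor_count6(inside)
    band_out <- free & nb > 0            # background voxels touching the label
    band_in <- inside & nb < 6           # label voxels on the boundary
    changed <- FALSE
    # energy difference for assigning a voxel to the region vs background,
    # with a curvature term favouring locally filled neighbourhoods
    if (any(band_out)) {
      sc <- (image[band_out] - mu_in)^2 - (image[band_out] - mu_out)^2 +
        lambda_smooth * (1 - 2 * nb[band_out] / 6)
      add <- which(band_out)[sc < 0]
      if (length(add)) { labels[add] <- lab; changed <- TRUE }
    }
    inside <- labels == lab
    nb <- neighbor_count6(inside)
    band_in <- inside & nb < 6
    if (any(band_in)) {
      sc <- (image[band_in] - mu_out)^2 - (image[band_in] - mu_in)^2 +
        lambda_smooth * (1 - 2 * (6 - nb[band_in]) / 6)
      rm_ <- which(band_in)[sc < 0]
      if (length(rm_)) { labels[rm_] <- 0L; changed <- TRUE }
    }
    # topology guard: keep only the largest connected component's changes
    comp <- connected_components_3d(labels == lab)
    frag <- labels == lab & comp != 1L
    if (any(frag)) labels[frag] <- 0L
    if (!changed) break
  }
  labels
}

#' Dice overlap coefficient of a label between two volumes
#'
#' @param a,b label volumes on the same grid.
#' @param label the label value to compare (default: any nonzero).
#' @export
dice_coefficient <- function(a, b, label = NULL) {
  ma <- if (is.null(label)) a != 0 else a == label
  mb <- if (is.null(label)) b != 0 else b == label
  denom <- sum(ma) + sum(mb)
  if (denom == 0) return(NA_real_)
  2 * sum(ma & mb) / denom
}
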