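#' Generalized Procrustes alignment of corresponded surfaces
#'
#' Iteratively removes translation and rotation (Kabsch solution with the
#' determinant constrained to +1, so reflections are never introduced) against
#' the running mean shape until the mean changes by less than `tol` RMS.
#' Scale is deliberately retained: size-bearing features (head size, shaft
#' thickness) are genuine shape modes here and scaling-out would erase them.
#'
#' @param surfaces list of N x 3 matrices with identical correspondence.
#' @param tol convergence tolerance on the RMS change of the mean shape (mm).
#' @param max_iter iteration cap.
#' @return list of aligned surfaces (attributes preserved); attribute
#'   `rotations` holds the per-subject rotation matrices.
#' @export
align_surfaces <- function(surfaces, tol = 1e-8, max_iter = 100) {
  stopifnot(length(surfaces) >= 2)
  N <- nrow(surfaces[[1]])
  if (!all(vapply(surfaces, nrow, integer(1)) == N)) {
    stop("all surfaces must share the same point count", call. = FALSE)
  }
  centered <- lapply(surfaces, function(s) {
    out <- sweep(s, 2, colMeans(s))
    attributes(out)$part <- attr(s, "part")
    out
  })
  rots <- rep(list(diag(3)), length(surfaces))
  ref <- centered[[1]]
  for (it in seq_len(max_iter)) {
    aligned <- vector("list", length(centered))
    for (i in seq_along(centered)) {
      R <- kabsch_rotation(centered[[i]], ref)
      rots[[i]] <- R
      aligned[[i]] <- centered[[i]] %*% R
    }
    new_ref <- Reduce(`+`, aligned) / length(aligned)
    delta <- sqrt(mean((new_ref - ref)^2))
    ref <- new_ref
    if (delta < tol) break
  }
  out <- vector("list", length(centered))
  for (i in seq_along(centered)) {
    a <- centered[[i]] %*% rots[[i]]
    attr(a, "part") <- attr(surfaces[[i]], "part")
    out[[i]] <- a
  }
  attr(out, "rotations") <- rots
  out
}

# optimal rotation mapping a onto b (both centered), det = +1 enforced
kabsch_rotation <- function(a, b) {
  s <- svd(crossprod(a, b))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Fit a PCA statistical shape model
#'
#' Eigendecomposition of the sample covariance of the flattened (3N) point
#' vectors. Variance fractions are eigenvalues over their total; per-subject
#' scores are the centered data projected on the modes (zero mean by
#' construction); each mode's sign is fixed so its largest-magnitude loading
#' is positive.
#'
#' @param surfaces list of aligned N x 3 matrices (>= 2 subjects).
#' @param m number of modes to retain (default: subjects - 1).
#' @return a `shape_model`: list with `mean` (N x 3), `modes` (3N x m,
#'   orthonormal columns), `eigenvalues` (mm^2, nonincreasing),
#'   `variance_fraction`, `scores` (subjects x m), `n_points`, `part`.
#' @export
fit_pca <- function(surfaces, m = NULL) {
  n <- length(surfaces)
  stopifnot(n >= 2)
  X <- t(vapply(surfaces, as.vector, numeric(length(surfaces[[1]]))))
  if (is.null(m)) m <- n - 1
  if (m > n - 1) stop("m must be <= subjects - 1", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  ev_all <- sv$d^2 / (n - 1)
  keep <- seq_len(min(m, sum(sv$d > 1e-12 * max(sv$d, 1))))
  modes <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-|loading| entry positive
  for (j in seq_along(keep)) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) modes[, j] <- -modes[, j]
  }
  scores <- Xc %*% modes
  ev <- ev_all[keep]
  structure(list(mean = matrix(mu, ncol = 3),
                 modes = modes,
                 eigenvalues = ev,
                 variance_fraction = ev / sum(ev_all),
                 scores = scores,
                 n_points = nrow(surfaces[[1]]),
                 part = attr(surfaces[[1]], "part")),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> %d points, %d modes; leading variance fractions: %s\n",
              x$n_points, ncol(x$modes),
              paste(sprintf("%.1f%%", 100 * utils::head(x$variance_fraction, 5)),
                    collapse = ", ")))
  invisible(x)
}

#' Reconstruct a surface from shape-model scores
#'
#' `mean + sum_j score_j * sqrt(lambda_j) * mode_j` when scores are given in
#' standard-deviation units (the convention for mean +/- 2 SD mode
#' visualizations), or `mean + sum_j score_j * mode_j` for raw-unit scores
#' (e.g. a row of `model$scores`).
#'
#' @param model a `shape_model`.
#' @param scores numeric vector, length <= number of modes.
#' @param units `"sd"` or `"raw"`.
#' @return N x 3 surface (with the model's part labels attached).
#' @export
reconstruct <- function(model, scores, units = c("sd", "raw")) {
  units <- match.arg(units)
  k <- length(scores)
  stopifnot(k <= ncol(model$modes))
  coef <- if (units == "sd") scores * sqrt(model$eigenvalues[seq_len(k)]) else scores
  v <- as.vector(model$mean) + as.vector(model$modes[, seq_len(k), drop = FALSE] %*% coef)
  out <- matrix(v, ncol = 3)
  attr(out, "part") <- model$part
  out
}

#' Project a surface onto a shape model
#'
#' @param model a `shape_model`.
#' @param surface N x 3 matrix on the model's correspondence.
#' @return raw-unit score vector.
#' @export
project_scores <- function(model, surface) {
  as.vector(crossprod(model$modes, as.vector(surface) - as.vector(model$mean)))
}

#' Geometric response of each mode: feature change per +1 SD
#'
#' Evaluates probe functions on `mean + 1 SD * mode_j` minus their value on
#' the mean shape, giving the table used to label modes anatomically on
#' phantom data (e.g. a planted head-size mode moves the head-radius probe and
#' leaves the shaft probe near zero).
#'
#' @param model a `shape_model` whose surfaces carry part labels.
#' @param probes function(surface) -> named numeric vector; defaults to
#'   [femur_probes()].
#' @param sd_step SD multiple at which to evaluate the response.
#' @return data frame: one row per mode, one column per probe (delta per
#'   `sd_step` SD).
#' @export
mode_feature_report <- function(model, probes = femur_probes, sd_step = 1) {
  base <- probes(reconstruct(model, numeric(0)))
  rows <- lapply(seq_len(ncol(model$modes)), function(j) {
    s <- rep(0, j); s[j] <- sd_step
    probes(reconstruct(model, s)) - base
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(mode = seq_len(ncol(model$modes)),
               variance_fraction = model$variance_fraction, out)
  rownames(out) <- NULL
  out
}

#' Principal angles between two mode subspaces (degrees)
#'
#' @param A,B matrices whose columns span the two subspaces.
#' @export
principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

#' Write/read a shape model as a CSV bundle
#'
#' Four plain CSV files (`mean.csv`, `modes.csv`, `eigenvalues.csv`,
#' `scores.csv`) under a directory.
#' @param model a `shape_model`.
#' @param dir output directory (created if needed).
#' @rdname shape_model_io
#' @export
write_shape_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(model$mean, file.path(dir, "mean.csv"), row.names = FALSE)
  utils::write.csv(model$modes, file.path(dir, "modes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(eigenvalue = model$eigenvalues,
                              variance_fraction = model$variance_fraction),
                   file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  utils::write.csv(model$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a corresponded surface as an ASCII PLY point cloud
#' @param surface N x 3 matrix.
#' @param path output file.
#' @export
write_surface_ply <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(surface)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(surface, trim = TRUE), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
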