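#' Voxelwise mono-exponential relaxometry
#'
#' Fits \eqn{S(\tau) = S_0 e^{-\tau/T}} independently to every masked voxel of
#' a TSL (T1rho) or TE (T2) series by damped Gauss-Newton (Levenberg-
#' Marquardt) least squares, initialized from the log-linear regression of the
#' positive samples. The two-parameter solver is vectorized across voxels:
#' each iteration solves the 2x2 normal equations with a per-voxel damping
#' factor, so whole-slice fits cost elementwise arithmetic rather than one
#' optimizer call per voxel. (On single curves it agrees with
#' `minpack.lm::nlsLM` to solver tolerance; the vectorization across voxels is
#' the reason it is implemented here.)
#'
#' Voxels are flagged invalid when they have fewer than two positive samples,
#' hit the physiologic bounds `T_bounds` (default 1-300 ms, the plausible
#' cartilage/bone range), or fit with R-squared below `r2_min`.
#'
#' @param series a `relax_series` (4D stack + preparation times).
#' @param mask optional logical volume restricting the fit.
#' @param T_bounds lower/upper bounds on the relaxation time (ms).
#' @param r2_min minimum R-squared for a voxel to count as valid.
#' @param refine if `FALSE`, return the log-linear initialization without
#'   Levenberg-Marquardt refinement.
#' @param max_iter maximum LM iterations.
#' @return a `relax_map`: list of 3D arrays `T_ms`, `S0`, `r_squared`,
#'   `valid` (logical), plus `kind` and `tau_ms`. Invalid voxels keep their
#'   last estimate but are flagged, never silently zeroed.
#' @export
fit_monoexp <- function(series, mask = NULL, T_bounds = c(1, 300),
                        r2_min = 0.5, refine = TRUE, max_iter = 50) {
  stopifnot(inherits(series, "relax_series"))
  tau <- series$tau_ms
  if (length(unique(tau)) < 2) stop("need >= 2 distinct preparation times",
                                    call. = FALSE)
  d3 <- dim(series$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d3)
  if (!identical(dim(mask), d3)) stop("mask misaligned with series", call. = FALSE)
  idx <- which(as.logical(mask))
  V <- matrix(series$data, nrow = prod(d3))[idx, , drop = FALSE]
  stop_if_not_finite(V, "signal")
  nt <- length(tau)

  # log-linear initialization over positive samples
  pos <- V > 0
  npos <- rowSums(pos)
  y <- log(pmax(V, .Machine$double.eps))
  w <- pos * 1
  sw <- pmax(rowSums(w), 1)
  tw <- as.vector(w %*% tau) / sw
  yw <- rowSums(w * y) / sw
  tc <- w * (matrix(tau, nrow(V), nt, byrow = TRUE) - tw)
  sxx <- rowSums(tc * (matrix(tau, nrow(V), nt, byrow = TRUE) - tw))
  sxy <- rowSums(tc * (y - yw))
  slope <- ifelse(sxx > 0, sxy / sxx, 0)
  T0 <- ifelse(slope < 0, -1 / slope, T_bounds[2])
  T0 <- pmin(pmax(T0, T_bounds[1]), T_bounds[2])
  S0 <- exp(yw + slope * tw)
  degenerate <- npos < 2

  model <- function(s, Tm) s * exp(-outer(Tm, tau, function(a, b) b / a))
  sse <- function(s, Tm) rowSums((V - model(s, Tm))^2)

  s <- S0; Tm <- T0
  if (refine) {
    lam <- rep(1e-3, length(idx))
    cur <- sse(s, Tm)
    for (it in seq_len(max_iter)) {
      E <- exp(-outer(Tm, tau, function(a, b) b / a))
      R <- V - s * E
      J2 <- s * E * outer(1 / Tm^2, tau)        # d model / d T
      A11 <- rowSums(E * E)
      A12 <- rowSums(E * J2)
      A22 <- rowSums(J2 * J2)
      g1 <- rowSums(E * R)
      g2 <- rowSums(J2 * R)
      B11 <- A11 * (1 + lam); B22 <- A22 * (1 + lam)
      det <- B11 * B22 - A12^2
      det[abs(det) < 1e-300] <- 1e-300
      ds <- (B22 * g1 - A12 * g2) / det
      dT <- (B11 * g2 - A12 * g1) / det
      s_new <- pmax(s + ds, .Machine$double.eps)
      T_new <- pmin(pmax(Tm + dT, T_bounds[1]), T_bounds[2])
      new <- sse(s_new, T_new)
      better <- new < cur & is.finite(new)
      s[better] <- s_new[better]
      Tm[better] <- T_new[better]
      cur[better] <- new[better]
      lam <- ifelse(better, pmax(lam / 3, 1e-12), pmin(lam * 5, 1e8))
      if (max(abs(c(ds[better], dT[better])), 0) < 1e-10) break
    }
  }
  fitted <- model(s, Tm)
  ss_res <- rowSums((V - fitted)^2)
  vmean <- rowMeans(V)
  ss_tot <- rowSums((V - vmean)^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 0)
  tolb <- 1e-9 * diff(T_bounds)
  at_bound <- Tm <= T_bounds[1] + tolb | Tm >= T_bounds[2] - tolb
  valid <- !degenerate & !at_bound & r2 >= r2_min & s > 0

  mk <- function(v, fill = NA_real_) { m <- array(fill, d3); m[idx] <- v; m }
  structure(list(T_ms = mk(Tm), S0 = mk(s), r_squared = mk(r2),
                 valid = mk(valid, FALSE) & array(as.logical(mask), d3),
                 kind = series$kind, tau_ms = tau),
            class = "relax_map")
}

#' @export
print.relax_map <- function(x, ...) {
  v <- x$T_ms[x$valid]
  cat(sprintf("<relax_map> %s: %d valid voxels, T = %.2f +/- %.2f ms\n",
              x$kind, length(v), mean(v), stats::sd(v)))
  invisible(x)
}

#' Per-region relaxation-time summary
#'
#' Mean relaxation time over valid voxels of each labelled region, with the
#' valid fraction reported so silent fit failures are visible.
#'
#' @param map a `relax_map`.
#' @param masks a `region_mask_set`.
#' @return data frame: region, mean_T_ms, sd_T_ms, n_voxels, valid_fraction.
#' @export
roi_relaxation <- function(map, masks) {
  stopifnot(inherits(map, "relax_map"),
            identical(dim(map$T_ms), dim(masks$volume)))
  rows <- lapply(seq_len(nrow(masks$table)), function(i) {
    lab <- masks$table$label[i]
    in_reg <- masks$volume == lab
    n <- sum(in_reg)
    if (n == 0) return(NULL)
    ok <- in_reg & map$valid
    v <- map$T_ms[ok]
    data.frame(region = masks$table$region[i],
               mean_T_ms = if (length(v)) mean(v) else NA_real_,
               sd_T_ms = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_voxels = n, valid_fraction = sum(ok) / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
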