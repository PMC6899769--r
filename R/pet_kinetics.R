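#' Convert an activity volume to standardized uptake values
#'
#' SUV = activity concentration (kBq/mL) x body weight (kg) / injected dose
#' (MBq), under the 1 g/mL tissue-density convention, so a voxel holding the
#' injected dose diluted uniformly over the body volume reads SUV 1.
#'
#' @param activity 3D array of activity concentration (kBq/mL), >= 0.
#' @param weight_kg body weight (kg), > 0.
#' @param dose_mbq injected dose (MBq), > 0.
#' @param source free-text provenance note.
#' @return An `suv_map`: list with `data` (unitless 3D array), `weight_kg`,
#'   `dose_mbq`, `source`.
#' @export
compute_suv <- function(activity, weight_kg, dose_mbq, source = "") {
  if (weight_kg <= 0) stop("weight must be > 0", call. = FALSE)
  if (dose_mbq <= 0) stop("injected dose must be > 0", call. = FALSE)
  stop_if_not_finite(activity, "activity")
  if (any(activity < 0)) stop("activity must be >= 0", call. = FALSE)
  structure(list(data = activity * weight_kg / dose_mbq,
                 weight_kg = weight_kg, dose_mbq = dose_mbq, source = source),
            class = "suv_map")
}

#' Static uptake volume from a dynamic series
#'
#' Duration-weighted mean activity over the frames of the final uptake phase
#' (default: all frames starting at or after `from_min`), the conventional
#' "static" image a late acquisition would produce.
#'
#' @param series a `dynamic_pet`.
#' @param from_min start of the averaging window (min).
#' @return 3D activity array (kBq/mL).
#' @export
static_uptake <- function(series, from_min = 30) {
  stopifnot(inherits(series, "dynamic_pet"))
  keep <- series$schedule$start_s / 60 >= from_min
  if (!any(keep)) stop("no frames at or after ", from_min, " min", call. = FALSE)
  w <- series$schedule$duration_s[keep]
  d <- series$data[, , , keep, drop = FALSE]
  out <- array(0, dim(d)[1:3])
  np <- prod(dim(d)[1:3])
  for (i in seq_along(w)) out <- out + array(d[(i - 1) * np + seq_len(np)], dim(out)) * w[i]
  out / sum(w)
}

#' Extract the arterial input function from a dynamic PET series
#'
#' With an artery mask, P(t) is the mean activity over the mask voxels in each
#' frame. Without one, arterial voxels are found automatically: candidates
#' must peak within the first `early_window_min` minutes and decline by at
#' least `decline_frac` of their peak by scan end; the top `k` candidates by
#' early-window peak value are reduced to their largest 6-connected component
#' and averaged.
#'
#' @param series a `dynamic_pet` with at least 4 frames.
#' @param artery_mask optional logical/0-1 volume marking the femoral artery.
#' @param k number of top candidate voxels in automatic mode.
#' @param early_window_min early window within which an arterial TAC must peak.
#' @param decline_frac required fractional decline from peak by the last frame.
#' @return an `input_function` with provenance `"mask-derived"` or
#'   `"auto-extracted"` and the source voxel count.
#' @export
extract_aif <- function(series, artery_mask = NULL, k = 20,
                        early_window_min = 2, decline_frac = 0.5) {
  stopifnot(inherits(series, "dynamic_pet"))
  sched <- series$schedule
  if (nrow(sched) < 4) stop("need at least 4 frames", call. = FALSE)
  nvox <- prod(dim(series$data)[1:3])
  mat <- matrix(series$data, nrow = nvox)          # voxels x frames
  if (!is.null(artery_mask)) {
    idx <- which(as.logical(artery_mask))
    if (!length(idx)) stop("artery mask is empty", call. = FALSE)
    p <- colMeans(mat[idx, , drop = FALSE])
    return(new_input_function(sched$mid_min, pmax(p, 0),
                              provenance = "mask-derived",
                              n_voxels = length(idx)))
  }
  early <- sched$mid_min <= early_window_min
  if (!any(early)) stop("no frames within the early window", call. = FALSE)
  peak_frame <- max.col(mat, ties.method = "first")
  peak_val <- mat[cbind(seq_len(nvox), peak_frame)]
  last_val <- mat[, ncol(mat)]
  cand <- early[peak_frame] & peak_val > 0 &
    (last_val <= (1 - decline_frac) * peak_val)
  if (!any(cand)) stop("no arterial signal found", call. = FALSE)
  early_peak <- apply(mat[, early, drop = FALSE], 1, max)
  ord <- order(early_peak * cand, decreasing = TRUE)
  sel <- ord[seq_len(min(k, sum(cand)))]
  selvol <- array(FALSE, dim(series$data)[1:3])
  selvol[sel] <- TRUE
  comp <- connected_components_3d(selvol)
  keep <- which(comp == 1L)
  p <- colMeans(mat[keep, , drop = FALSE])
  out <- new_input_function(sched$mid_min, pmax(p, 0),
                            provenance = "auto-extracted",
                            n_voxels = length(keep))
  attr(out, "voxel_index") <- keep
  out
}

#' Patlak transformation of a tissue TAC against an input function
#'
#' Maps the data to normalized-time coordinates
#' \eqn{x(t) = \int_0^t P\,d\tau / P(t)} (min) and \eqn{y(t) = ROI(t)/P(t)}.
#' For an irreversibly trapped tracer the points fall on a straight line
#' after equilibration, with slope Kpat and intercept VB. The running
#' integral is trapezoidal over the sample times with P taken as 0 at t = 0;
#' points where P(t) is below `eps` times its maximum are dropped and
#' reported.
#'
#' @param tac tissue activity at the input function's sample times.
#' @param aif an `input_function` on the same time grid.
#' @param eps relative plasma-activity threshold below which points are
#'   excluded (guards the division near t = 0).
#' @return data frame with columns `t_min`, `x`, `y` for the retained points;
#'   attribute `n_dropped` counts excluded points.
#' @export
patlak_transform <- function(tac, aif, eps = 1e-6) {
  stopifnot(inherits(aif, "input_function"))
  t <- aif$times_min
  p <- aif$activity
  if (length(tac) != length(t)) {
    stop("TAC and input function must share the same time grid", call. = FALSE)
  }
  # trapezoid from t = 0 with P(0) = 0
  tt <- c(0, t); pp <- c(0, p)
  cumint <- pracma::cumtrapz(tt, pp)[-1]
  ok <- p > eps * max(p)
  if (sum(ok) < 2) stop("fewer than 2 valid Patlak points", call. = FALSE)
  out <- data.frame(t_min = t[ok], x = cumint[ok] / p[ok], y = tac[ok] / p[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Fit the Patlak line after equilibration
#'
#' Ordinary least squares through the transformed points with mid-time at or
#' beyond the equilibration cutoff `t_star` (default 15 min): the slope is
#' the influx constant Kpat (1/min) and the intercept the effective blood
#' distribution volume VB.
#'
#' @param points output of [patlak_transform()].
#' @param t_star equilibration time (min); only points with `t_min >= t_star`
#'   enter the fit.
#' @param weights optional per-point weights (e.g. frame durations).
#' @return a `patlak_fit`: list with `Kpat`, `VB`, `r_squared`, `n_used`,
#'   `t_star`.
#' @export
patlak_fit <- function(points, t_star = 15, weights = NULL) {
  late <- points$t_min >= t_star
  if (sum(late) < 2) stop("fewer than 2 points at or beyond t* = ", t_star,
                          " min", call. = FALSE)
  d <- points[late, ]
  w <- if (is.null(weights)) rep(1, nrow(d)) else weights[late]
  if (stats::var(d$x) <= 0) stop("degenerate Patlak abscissa (zero variance)",
                                 call. = FALSE)
  fit <- stats::lm(y ~ x, data = d, weights = w)
  ss_res <- sum(w * stats::residuals(fit)^2)
  ss_tot <- sum(w * (d$y - stats::weighted.mean(d$y, w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(Kpat = unname(stats::coef(fit)[2]),
                 VB = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_used = nrow(d), t_star = t_star),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("<patlak_fit> Kpat = %.5g 1/min, VB = %.4g, R^2 = %.4f (%d frames, t* = %g min)\n",
              x$Kpat, x$VB, x$r_squared, x$n_used, x$t_star))
  invisible(x)
}

#' Region-mean Patlak analysis of a dynamic series
#'
#' Averages the TAC over each region of a mask set and fits the Patlak line.
#'
#' @param series a `dynamic_pet`.
#' @param aif an `input_function` on the series' mid-time grid.
#' @param masks a `region_mask_set` (see [region_mask_set()]).
#' @param t_star equilibration cutoff (min).
#' @return data frame: region, Kpat, VB, r_squared, n_voxels.
#' @export
patlak_by_region <- function(series, aif, masks, t_star = 15) {
  stopifnot(inherits(series, "dynamic_pet"))
  nvox <- prod(dim(series$data)[1:3])
  mat <- matrix(series$data, nrow = nvox)
  rows <- lapply(seq_len(nrow(masks$table)), function(i) {
    lab <- masks$table$label[i]
    idx <- which(masks$volume == lab)
    if (!length(idx)) return(NULL)
    tac <- colMeans(mat[idx, , drop = FALSE])
    fit <- patlak_fit(patlak_transform(tac, aif), t_star = t_star)
    data.frame(region = masks$table$region[i], Kpat = fit$Kpat, VB = fit$VB,
               r_squared = fit$r_squared, n_voxels = length(idx),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Voxelwise Patlak slope and intercept within a mask
#'
#' Closed-form OLS applied independently to every masked voxel's transformed
#' points (shared abscissa since the input function is common), restricted to
#' bone masks by default for cost.
#'
#' @inheritParams patlak_by_region
#' @param mask logical volume of voxels to fit.
#' @return list of 3D maps `Kpat`, `VB`, `r_squared` (NA outside the mask).
#' @export
patlak_voxelwise <- function(series, aif, mask, t_star = 15, eps = 1e-6) {
  stopifnot(inherits(series, "dynamic_pet"))
  t <- aif$times_min; p <- aif$activity
  tt <- c(0, t); pp <- c(0, p)
  cumint <- pracma::cumtrapz(tt, pp)[-1]
  ok <- p > eps * max(p) & t >= t_star
  if (sum(ok) < 2) stop("fewer than 2 valid late points", call. = FALSE)
  x <- (cumint / p)[ok]
  idx <- which(as.logical(mask))
  nvox <- prod(dim(series$data)[1:3])
  mat <- matrix(series$data, nrow = nvox)[idx, ok, drop = FALSE]
  y <- sweep(mat, 2, p[ok], "/")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.vector(y %*% xc) / sxx
  inter <- rowMeans(y) - slope * mean(x)
  fitted_ss <- slope^2 * sxx
  tot_ss <- rowSums((y - rowMeans(y))^2)
  r2 <- ifelse(tot_ss > 0, fitted_ss / tot_ss, 1)
  mk <- function(v) { m <- array(NA_real_, dim(series$data)[1:3]); m[idx] <- v; m }
  list(Kpat = mk(slope), VB = mk(inter), r_squared = mk(pmin(pmax(r2, 0), 1)))
}

#' Per-region summary of a scalar map
#'
#' Mean, maximum and voxel count of a 3D map (SUV, Kpat, ...) over each
#' labelled region; empty regions are flagged and excluded from the rows.
#'
#' @param map 3D array or `suv_map`.
#' @param masks a `region_mask_set`.
#' @return data frame: region, mean, max, n_voxels; attribute
#'   `empty_regions` lists labels with no voxels.
#' @export
region_summary <- function(map, masks) {
  if (inherits(map, "suv_map")) map <- map$data
  stopifnot(identical(dim(map), dim(masks$volume)))
  empty <- character(0)
  rows <- lapply(seq_len(nrow(masks$table)), function(i) {
    lab <- masks$table$label[i]
    v <- map[masks$volume == lab]
    v <- v[!is.na(v)]
    if (!length(v)) { empty <<- c(empty, masks$table$region[i]); return(NULL) }
    data.frame(region = masks$table$region[i], mean = mean(v), max = max(v),
               n_voxels = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "empty_regions") <- empty
  out
}
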