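#' Simulate a tissue time-activity curve (TAC)
#'
#' Two generating modes are provided. `patlak_exact` constructs
#' \deqn{ROI(t) = K_{pat}\int_0^t P\,d\tau + V_B\,P(t)}
#' identically, so the Patlak plot of the output against the same input
#' function is an exact straight line with slope Kpat and intercept VB at all
#' times — the reference signal for testing the graphical analysis.
#' `compartment` integrates the irreversible two-tissue compartment system
#' \deqn{\dot C_1 = K_1 P - (k_2 + k_3) C_1,\qquad \dot C_2 = k_3 C_1,}
#' with measured signal \eqn{C_1 + C_2 + v_B P}; its Patlak slope converges to
#' \eqn{K_{pat} = K_1 k_3 / (k_2 + k_3)} after equilibration.
#'
#' When `aif` is a closed-form `aif_model`, integrals are analytic and the
#' curve is the physical ground truth. When `aif` is a sampled
#' `input_function`, `patlak_exact` uses the same trapezoidal cumulative
#' integral as [patlak_transform()] (with P = 0 at t = 0), making recovery of
#' (Kpat, VB) by [patlak_fit()] an algebraic identity on any positive input
#' and any equilibration cutoff.
#'
#' @param aif an `aif_model` or a sampled `input_function`.
#' @param times_min evaluation times (min), sorted, nonnegative; defaults to
#'   the sample times when `aif` is an `input_function`.
#' @param Kpat,VB Patlak parameters for `patlak_exact` mode (1/min, unitless).
#' @param K1,k2,k3,vB compartment parameters for `compartment` mode
#'   (mL/min/mL, 1/min, 1/min, unitless).
#' @param mode `"patlak_exact"` or `"compartment"`.
#' @return numeric activity (kBq/mL) at `times_min`.
#' @export
simulate_tissue_tac <- function(aif, times_min = NULL,
                                Kpat = NULL, VB = NULL,
                                K1 = NULL, k2 = NULL, k3 = NULL, vB = 0,
                                mode = c("patlak_exact", "compartment")) {
  mode <- match.arg(mode)
  if (inherits(aif, "input_function")) {
    if (is.null(times_min)) times_min <- aif$times_min
    if (!isTRUE(all.equal(times_min, aif$times_min))) {
      stop("times must match the sampled input function's grid", call. = FALSE)
    }
    if (mode == "patlak_exact") {
      stopifnot(!is.null(Kpat), !is.null(VB))
      if (Kpat < 0 || VB < 0) stop("kinetic parameters must be >= 0", call. = FALSE)
      p <- aif$activity
      cumint <- pracma::cumtrapz(c(0, times_min), c(0, p))[-1]
      return(Kpat * cumint + VB * p)
    }
    # compartment mode on a sampled input: linear interpolation of P(t)
    aif <- sampled_aif_interp(aif)
  }
  stopifnot(inherits(aif, c("aif_model", "aif_interp")))
  if (is.null(times_min)) stop("times_min is required", call. = FALSE)
  if (any(times_min < 0)) stop("times must be nonnegative", call. = FALSE)
  if (mode == "patlak_exact") {
    stopifnot(!is.null(Kpat), !is.null(VB))
    if (Kpat < 0 || VB < 0) stop("kinetic parameters must be >= 0", call. = FALSE)
    Kpat * aif_integral(aif, times_min) + VB * eval_aif(aif, times_min)
  } else {
    stopifnot(!is.null(K1), !is.null(k2), !is.null(k3))
    if (any(c(K1, k2, k3, vB) < 0)) {
      stop("kinetic parameters must be >= 0", call. = FALSE)
    }
    if (k2 + k3 == 0 && K1 > 0) {
      stop("k2 + k3 = 0 with K1 > 0: influx constant undefined", call. = FALSE)
    }
    sol <- integrate_2tcm(aif, sort(unique(c(0, times_min))), K1, k2, k3)
    c1 <- stats::approx(sol$time, sol$C1, xout = times_min)$y
    c2 <- stats::approx(sol$time, sol$C2, xout = times_min)$y
    c1 + c2 + vB * eval_aif(aif, times_min)
  }
}

# Integrate the irreversible two-tissue system with deSolve; an extra state
# accumulates the integral of the tissue signal so frame averages come out of
# the antiderivative exactly rather than by quadrature.
integrate_2tcm <- function(aif, times_min, K1, k2, k3, vB = 0) {
  rhs <- function(t, y, parms) {
    p <- eval_aif(aif, t)
    dC1 <- K1 * p - (k2 + k3) * y[1]
    dC2 <- k3 * y[1]
    droi <- y[1] + y[2] + vB * p
    list(c(dC1, dC2, droi))
  }
  out <- deSolve::lsoda(c(C1 = 0, C2 = 0, cumROI = 0), times_min, rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  as.data.frame(out)
}

#' Frame-averaged tissue activity for a phantom TAC
#'
#' Scanners report the mean activity over each frame interval, not a midpoint
#' sample. For `patlak_exact` TACs the average is evaluated from the
#' closed-form antiderivative
#' \eqn{\int ROI = K_{pat}\iint P + V_B \int P}; for `compartment` TACs the
#' ODE system carries the cumulative signal as an extra state.
#'
#' @inheritParams simulate_tissue_tac
#' @param schedule a `frame_schedule`.
#' @param midpoint if `TRUE`, sample the TAC at frame mid-times instead of
#'   averaging over the interval.
#' @return numeric vector, one value per frame (kBq/mL).
#' @export
tac_frame_average <- function(aif, schedule,
                              Kpat = NULL, VB = NULL,
                              K1 = NULL, k2 = NULL, k3 = NULL, vB = 0,
                              mode = c("patlak_exact", "compartment"),
                              midpoint = FALSE) {
  mode <- match.arg(mode)
  validate_frame_schedule(schedule)
  if (midpoint) {
    return(simulate_tissue_tac(aif, schedule$mid_min, Kpat = Kpat, VB = VB,
                               K1 = K1, k2 = k2, k3 = k3, vB = vB, mode = mode))
  }
  t0 <- schedule$start_s / 60
  t1 <- (schedule$start_s + schedule$duration_s) / 60
  dur <- schedule$duration_s / 60
  if (mode == "patlak_exact") {
    stopifnot(!is.null(Kpat), !is.null(VB))
    G <- function(t) Kpat * aif_double_integral(aif, t) + VB * aif_integral(aif, t)
    (G(t1) - G(t0)) / dur
  } else {
    stopifnot(!is.null(K1), !is.null(k2), !is.null(k3))
    if (k2 + k3 == 0 && K1 > 0) {
      stop("k2 + k3 = 0 with K1 > 0: influx constant undefined", call. = FALSE)
    }
    bounds <- sort(unique(c(0, t0, t1)))
    sol <- integrate_2tcm(aif, bounds, K1, k2, k3, vB = vB)
    cum <- stats::approx(sol$time, sol$cumROI, xout = c(t0[1], t1))$y
    diff(c(cum)) / dur
  }
}

#' Frame-averaged plasma activity
#'
#' Closed-form interval average of the bolus model over each frame; this is
#' what artery voxels carry in the rendered dynamic series.
#' @inheritParams tac_frame_average
#' @export
aif_frame_average <- function(aif, schedule, midpoint = FALSE) {
  validate_frame_schedule(schedule)
  if (midpoint) return(eval_aif(aif, schedule$mid_min))
  t0 <- schedule$start_s / 60
  t1 <- (schedule$start_s + schedule$duration_s) / 60
  (aif_integral(aif, t1) - aif_integral(aif, t0)) / (schedule$duration_s / 60)
}

#' Influx constant implied by compartment parameters
#'
#' \eqn{K_{pat} = K_1 k_3 / (k_2 + k_3)}, the late-time Patlak slope of the
#' irreversible two-tissue model.
#' @inheritParams simulate_tissue_tac
#' @export
kpat_from_compartment <- function(K1, k2, k3) {
  if (k2 + k3 == 0) {
    if (K1 > 0) stop("k2 + k3 = 0 with K1 > 0: influx constant undefined",
                     call. = FALSE)
    return(0)
  }
  K1 * k3 / (k2 + k3)
}
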