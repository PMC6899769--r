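#' Tri-exponential bolus model for the arterial input function
#'
#' The plasma activity is modelled as a sum of three exponentials with
#' coefficients summing to zero,
#' \deqn{P(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} - (A_1 + A_2) e^{-\lambda_0 t},}
#' with the rise rate \eqn{\lambda_0} larger than both decay rates so that
#' P(0) = 0, the curve rises to a single early peak and then decays
#' monotonically. The form is smooth and integrable in closed form, which the
#' Patlak stages exploit for exact oracles. Times are in minutes, activity in
#' kBq/mL.
#'
#' @param A amplitudes of the two decaying terms (kBq/mL), both >= 0.
#' @param lambda decay rates of the two decaying terms (1/min), both > 0.
#' @param rise rise rate \eqn{\lambda_0} (1/min), must exceed `max(lambda)`.
#' @return An object of class `aif_model` with fields `coef` (three signed
#'   amplitudes) and `mu` (three rates).
#' @export
aif_model <- function(A = c(40, 6), lambda = c(0.8, 0.03), rise = 4) {
  stopifnot(length(A) == 2, length(lambda) == 2, length(rise) == 1)
  if (any(A < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (any(lambda <= 0) || rise <= 0) stop("rates must be > 0", call. = FALSE)
  if (sum(A) > 0 && rise <= max(lambda)) {
    stop("rise rate must exceed both decay rates (otherwise P(t) < 0)",
         call. = FALSE)
  }
  structure(list(coef = c(A, -sum(A)), mu = c(lambda, rise)),
            class = "aif_model")
}

#' Evaluate an AIF model, its running integral, and its double integral
#'
#' `eval_aif` gives P(t); `aif_integral` gives \eqn{\int_0^t P\,d\tau};
#' `aif_double_integral` gives \eqn{\int_0^t \int_0^s P\,d\tau\,ds}. All are
#' closed-form, so frame-averaged activities and Patlak abscissae can be
#' checked to machine precision.
#'
#' @param model an `aif_model`.
#' @param t_min times in minutes (>= 0).
#' @rdname eval_aif
#' @export
eval_aif <- function(model, t_min) {
  if (inherits(model, "aif_interp")) return(model$fun(t_min))
  drop(exp(-outer(t_min, model$mu)) %*% model$coef)
}

# linear-interpolation view of a sampled input function (P = 0 at t = 0,
# constant extrapolation beyond the last sample)
sampled_aif_interp <- function(aif) {
  t <- aif$times_min; p <- aif$activity
  if (t[1] > 0) { t <- c(0, t); p <- c(0, p) }
  structure(list(fun = stats::approxfun(t, p, rule = 2)), class = "aif_interp")
}

#' @rdname eval_aif
#' @export
aif_integral <- function(model, t_min) {
  drop((1 - exp(-outer(t_min, model$mu))) %*% (model$coef / model$mu))
}

#' @rdname eval_aif
#' @export
aif_double_integral <- function(model, t_min) {
  m <- model$mu; a <- model$coef
  sapply(t_min, function(t) sum(a / m * (t - (1 - exp(-m * t)) / m)))
}

#' Simulate a sampled plasma input function
#'
#' Evaluates the bolus model on the given time grid and wraps the result as an
#' `input_function`, the sampled-P(t) container used by the Patlak stages.
#'
#' @param model an `aif_model`.
#' @param times_min sorted nonnegative sample times (min), typically frame
#'   mid-times.
#' @return An `input_function`: list with `times_min`, `activity` (kBq/mL),
#'   `provenance`, `n_voxels`.
#' @export
simulate_aif <- function(model, times_min) {
  if (is.unsorted(times_min, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(times_min < 0)) stop("times must be nonnegative", call. = FALSE)
  p <- eval_aif(model, times_min)
  if (any(p < -1e-12 * max(abs(p), 1))) {
    stop("model parameters yield negative plasma activity", call. = FALSE)
  }
  new_input_function(times_min, pmax(p, 0), provenance = "simulated")
}

new_input_function <- function(times_min, activity, provenance = "supplied",
                               n_voxels = NA_integer_) {
  stopifnot(length(times_min) == length(activity))
  if (is.unsorted(times_min, strictly = TRUE)) {
    stop("input-function times must be strictly increasing", call. = FALSE)
  }
  if (any(activity < 0)) stop("plasma activity must be >= 0", call. = FALSE)
  structure(list(times_min = as.numeric(times_min),
                 activity = as.numeric(activity),
                 provenance = provenance,
                 n_voxels = n_voxels),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("<input_function> %d samples over [%.2f, %.2f] min, peak %.3g kBq/mL (%s)\n",
              length(x$times_min), min(x$times_min), max(x$times_min),
              max(x$activity), x$provenance))
  invisible(x)
}
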