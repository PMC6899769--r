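#' Specification of the digital hip phantom
#'
#' The phantom is a voxelized hip with disjoint labelled regions (femur,
#' acetabulum, femoral and acetabular cartilage, femoral artery) on a regular
#' grid. Each region carries known tracer kinetics (either Patlak parameters
#' directly, or irreversible two-tissue compartment parameters) and known
#' relaxation times, so every downstream estimate can be compared against
#' ground truth.
#'
#' Defaults reflect a 45-min dynamic [18F]-NaF acquisition (12 x 10 s,
#' 6 x 30 s, 10 x 4 min frames) with influx constants of realistic magnitude
#' (acetabulum 0.015 1/min, femur 0.007 1/min), combined T1rho/T2 MAPSS-style
#' preparation times (TSL 0/15/30/45 ms, TE 0/10.4/20.8/41.6 ms) and cartilage
#' relaxation times around 36 ms (T1rho) and 34 ms (T2). PET noise is
#' pseudo-Poisson: zero-mean Gaussian with standard deviation
#' `pet_noise * sqrt(signal / duration_min)`; MR noise is additive Gaussian
#' with standard deviation `mr_sigma` on a tissue amplitude of 100.
#'
#' @param dim integer grid size (3 axes).
#' @param voxel_mm voxel edge lengths (mm).
#' @param schedule a `frame_schedule` for the dynamic PET acquisition.
#' @param aif an `aif_model` used as the arterial input.
#' @param kinetics named list (one entry per tissue region) of either
#'   `list(Kpat=, VB=)` or `list(K1=, k2=, k3=, vB=)`.
#' @param relaxation named list per region: `list(T1rho=, T2=, S0=)` (ms, a.u.).
#' @param tsl_ms,te_ms spin-lock and echo-time schedules (ms).
#' @param pet_noise pseudo-Poisson PET noise scale (0 = noiseless).
#' @param mr_sigma additive Gaussian MR noise sd (0 = noiseless).
#' @param weight_kg,dose_mbq,age_yr,pain subject covariates attached to the
#'   phantom (body weight, injected dose, age, HOOS-type pain score).
#' @param seed RNG seed used by the renderers.
#' @return A `phantom_spec` list, including the label volume and label table.
#' @export
phantom_spec <- function(dim = c(32L, 32L, 20L),
                         voxel_mm = c(2, 2, 2),
                         schedule = make_frame_schedule(),
                         aif = aif_model(),
                         kinetics = list(
                           femur = list(Kpat = 0.007, VB = 0.05),
                           acetabulum = list(Kpat = 0.015, VB = 0.05),
                           cartilage_femoral = list(Kpat = 0.003, VB = 0.08),
                           cartilage_acetabular = list(Kpat = 0.004, VB = 0.08)
                         ),
                         relaxation = list(
                           femur = list(T1rho = 25, T2 = 20, S0 = 100),
                           acetabulum = list(T1rho = 25, T2 = 20, S0 = 100),
                           cartilage_femoral = list(T1rho = 36.44, T2 = 33.57, S0 = 100),
                           cartilage_acetabular = list(T1rho = 36.44, T2 = 33.57, S0 = 100),
                           artery = list(T1rho = 150, T2 = 150, S0 = 60)
                         ),
                         tsl_ms = c(0, 15, 30, 45),
                         te_ms = c(0, 10.4, 20.8, 41.6),
                         pet_noise = 0.17,
                         mr_sigma = 2,
                         weight_kg = 70, dose_mbq = 250,
                         age_yr = 55, pain = 75,
                         seed = 1L) {
  validate_frame_schedule(schedule)
  stopifnot(inherits(aif, "aif_model"), length(dim) == 3, length(voxel_mm) == 3)
  for (nm in names(kinetics)) {
    k <- kinetics[[nm]]
    vals <- unlist(k)
    if (any(vals < 0)) stop("kinetic parameters must be >= 0 in region ", nm,
                            call. = FALSE)
  }
  for (nm in names(relaxation)) {
    r <- relaxation[[nm]]
    if (any(c(r$T1rho, r$T2) <= 0)) {
      stop("relaxation times must be > 0 in region ", nm, call. = FALSE)
    }
  }
  if (pet_noise < 0 || mr_sigma < 0) stop("noise levels must be >= 0", call. = FALSE)
  if (weight_kg <= 0 || dose_mbq <= 0) stop("weight and dose must be > 0",
                                            call. = FALSE)
  lab <- phantom_labels(dim)
  structure(list(dim = as.integer(dim), voxel_mm = voxel_mm,
                 schedule = schedule, aif = aif,
                 kinetics = kinetics, relaxation = relaxation,
                 tsl_ms = tsl_ms, te_ms = te_ms,
                 pet_noise = pet_noise, mr_sigma = mr_sigma,
                 weight_kg = weight_kg, dose_mbq = dose_mbq,
                 age_yr = age_yr, pain = pain,
                 seed = as.integer(seed),
                 labels = lab$volume, label_table = lab$table),
            class = "phantom_spec")
}

#' Geometric label layout of the hip phantom
#'
#' Femoral head (sphere) capped by a femoral-cartilage shell, an
#' acetabular-cartilage shell and the acetabular bone shell above it, plus a
#' femoral-artery column. Regions are disjoint by construction.
#'
#' @param dim 3-vector of grid sizes.
#' @return list with `volume` (integer array) and `table` (label dictionary).
#' @export
phantom_labels <- function(dim = c(32L, 32L, 20L)) {
  d <- as.integer(dim)
  ctr <- c(d[1] / 2, d[2] * 0.38, d[3] / 2)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  r <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2)
  sup <- g$y > ctr[2]                      # superior hemisphere: joint space
  scale <- min(d) / 20
  lab <- integer(nrow(g))
  lab[r <= 6.5 * scale] <- 1L                                  # femur
  lab[r > 6.5 * scale & r <= 8 * scale & sup] <- 3L            # femoral cartilage
  lab[r > 8 * scale & r <= 9.5 * scale & sup] <- 4L            # acetabular cartilage
  lab[r > 9.5 * scale & r <= 12.5 * scale & sup] <- 2L         # acetabulum
  art <- (g$x - round(d[1] * 0.85))^2 + (g$y - round(d[2] * 0.2))^2 <= (1.6 * scale)^2
  lab[art] <- 5L                                               # femoral artery
  vol <- array(lab, d)
  tbl <- data.frame(
    label = 1:5,
    region = c("femur", "acetabulum", "cartilage_femoral",
               "cartilage_acetabular", "artery"),
    stringsAsFactors = FALSE
  )
  list(volume = vol, table = tbl)
}

region_mask <- function(spec, region) {
  lab <- spec$label_table$label[spec$label_table$region == region]
  if (length(lab) != 1) stop("unknown region: ", region, call. = FALSE)
  spec$labels == lab
}

#' Render the dynamic PET series of the phantom
#'
#' Each tissue voxel receives the interval average of its region's TAC over
#' every frame; artery voxels carry the interval-averaged input function.
#' With `pet_noise > 0`, independent Gaussian noise with standard deviation
#' `pet_noise * sqrt(signal / duration_min)` is added per voxel and frame
#' (shorter frames are noisier, as in count-limited reconstructions).
#'
#' @param spec a `phantom_spec`.
#' @param midpoint sample TACs at frame mid-times instead of interval averages.
#' @return list with `series` (a `dynamic_pet`), and `truth`: the region TAC
#'   table, per-region Kpat/VB, the AIF model and its frame averages, and the
#'   label volume.
#' @export
render_dynamic_pet <- function(spec, midpoint = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  sched <- spec$schedule
  nf <- nrow(sched)
  tacs <- list()
  truth_kin <- list()
  for (nm in names(spec$kinetics)) {
    k <- spec$kinetics[[nm]]
    if (!is.null(k$Kpat)) {
      tacs[[nm]] <- tac_frame_average(spec$aif, sched, Kpat = k$Kpat, VB = k$VB,
                                      mode = "patlak_exact", midpoint = midpoint)
      truth_kin[[nm]] <- list(Kpat = k$Kpat, VB = k$VB, mode = "patlak_exact")
    } else {
      tacs[[nm]] <- tac_frame_average(spec$aif, sched, K1 = k$K1, k2 = k$k2,
                                      k3 = k$k3, vB = k$vB %||% 0,
                                      mode = "compartment", midpoint = midpoint)
      truth_kin[[nm]] <- list(Kpat = kpat_from_compartment(k$K1, k$k2, k$k3),
                              VB = NA_real_, mode = "compartment")
    }
  }
  tacs[["artery"]] <- aif_frame_average(spec$aif, sched, midpoint = midpoint)
  data <- array(0, c(spec$dim, nf))
  for (nm in names(tacs)) {
    m <- region_mask(spec, nm)
    idx <- which(m)
    for (f in seq_len(nf)) {
      data[idx + (f - 1L) * prod(spec$dim)] <- tacs[[nm]][f]
    }
  }
  if (spec$pet_noise > 0) {
    data <- with_seed(spec$seed, {
      dur_min <- rep(sched$duration_s / 60, each = prod(spec$dim))
      sd <- spec$pet_noise * sqrt(pmax(data, 0) / dur_min)
      data + array(stats::rnorm(length(data), sd = sd), dim(data))
    })
  }
  series <- new_dynamic_pet(data, sched, spec$voxel_mm)
  truth <- list(region_tacs = tacs, kinetics = truth_kin, aif = spec$aif,
                aif_frames = tacs[["artery"]], labels = spec$labels,
                label_table = spec$label_table)
  list(series = series, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Container for a 4D dynamic PET series
#'
#' @param data 4D array (x, y, z, frame) of activity in kBq/mL.
#' @param schedule a `frame_schedule` with one row per frame.
#' @param voxel_mm voxel edge lengths (mm).
#' @param affine optional 4x4 voxel-to-world (RAS+, mm) matrix.
#' @export
new_dynamic_pet <- function(data, schedule, voxel_mm = c(2, 2, 2),
                            affine = NULL) {
  stopifnot(length(dim(data)) == 4)
  validate_frame_schedule(schedule)
  if (dim(data)[4] != nrow(schedule)) {
    stop("frame count does not match 4th dimension", call. = FALSE)
  }
  stop_if_not_finite(data, "activity")
  if (is.unsorted(schedule$mid_s, strictly = TRUE)) {
    stop("frame mid-times must be strictly increasing", call. = FALSE)
  }
  if (is.null(affine)) affine <- diag(c(voxel_mm, 1))
  structure(list(data = data, schedule = schedule, voxel_mm = voxel_mm,
                 affine = affine),
            class = "dynamic_pet")
}

#' Render relaxation-weighted MR snapshot stacks of the phantom
#'
#' Produces the mono-exponential series \eqn{S(\tau) = S_0 e^{-\tau/T}} per
#' voxel at each preparation time (TSL for T1rho contrast, TE for T2), plus
#' the voxelwise ground-truth maps. Additive Gaussian noise of sd `mr_sigma`
#' is applied when nonzero.
#'
#' @param spec a `phantom_spec`.
#' @param kind `"t1rho"` (TSL schedule) or `"t2"` (TE schedule).
#' @return list: `series` (a `relax_series`), `truth_T` and `truth_S0`
#'   voxelwise maps.
#' @export
render_relax_series <- function(spec, kind = c("t1rho", "t2")) {
  kind <- match.arg(kind)
  tau <- if (kind == "t1rho") spec$tsl_ms else spec$te_ms
  if (any(tau < 0)) stop("preparation times must be >= 0", call. = FALSE)
  Tmap <- array(NA_real_, spec$dim)
  S0map <- array(0, spec$dim)
  for (nm in names(spec$relaxation)) {
    r <- spec$relaxation[[nm]]
    m <- region_mask(spec, nm)
    Tmap[m] <- if (kind == "t1rho") r$T1rho else r$T2
    S0map[m] <- r$S0
  }
  stack <- array(0, c(spec$dim, length(tau)))
  for (i in seq_along(tau)) {
    s <- ifelse(is.na(Tmap), 0, S0map * exp(-tau[i] / Tmap))
    stack[, , , i] <- s
  }
  if (spec$mr_sigma > 0) {
    stack <- with_seed(spec$seed + 1L, {
      stack + array(stats::rnorm(length(stack), sd = spec$mr_sigma), dim(stack))
    })
  }
  list(series = new_relax_series(stack, tau, kind),
       truth_T = Tmap, truth_S0 = S0map)
}

#' Container for a relaxation-weighted image stack
#'
#' @param data 4D array (x, y, z, tau).
#' @param tau_ms preparation times in ms (TSL or TE), strictly increasing.
#' @param kind contrast kind, `"t1rho"` or `"t2"`.
#' @export
new_relax_series <- function(data, tau_ms, kind = c("t1rho", "t2")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(data)) == 4)
  if (dim(data)[4] != length(tau_ms)) {
    stop("tau count does not match 4th dimension", call. = FALSE)
  }
  if (any(tau_ms < 0) || is.unsorted(tau_ms, strictly = TRUE)) {
    stop("preparation times must be >= 0 and strictly increasing", call. = FALSE)
  }
  structure(list(data = data, tau_ms = as.numeric(tau_ms), kind = kind),
            class = "relax_series")
}

#' Simulate two-rater semi-quantitative lesion score tables
#'
#' Rater A draws cartilage grades (0-2) and bone-marrow-edema grades (0-3)
#' independently per subject and subregion from fixed marginals; rater B
#' repeats A's grade with probability `1 - disagree`, otherwise re-draws a
#' different in-range grade uniformly. The expected raw agreement is therefore
#' `1 - disagree` by construction, giving a known anchor for the
#' agreement statistics.
#'
#' @param n_subjects number of subjects.
#' @param disagree probability rater B departs from rater A on a cell.
#' @param p_cart,p_bme marginal grade probabilities for rater A.
#' @param seed RNG seed.
#' @return list of two `lesion_score_table` data frames, `rater_a`, `rater_b`.
#' @export
simulate_lesion_scores <- function(n_subjects = 10,
                                   disagree = 0.07,
                                   p_cart = c(0.6, 0.3, 0.1),
                                   p_bme = c(0.55, 0.25, 0.15, 0.05),
                                   seed = 1L) {
  stopifnot(disagree >= 0, disagree <= 1)
  with_seed(seed, {
    cells <- expand.grid(subject = seq_len(n_subjects),
                         subregion = hip_subregions(),
                         stringsAsFactors = FALSE)
    n <- nrow(cells)
    ca <- sample(0:2, n, replace = TRUE, prob = p_cart)
    ba <- sample(0:3, n, replace = TRUE, prob = p_bme)
    flip <- function(g, lo, hi) {
      f <- stats::runif(length(g)) < disagree
      g2 <- g
      if (any(f)) {
        g2[f] <- vapply(g[f], function(v) sample(setdiff(lo:hi, v), 1L),
                        numeric(1))
      }
      g2
    }
    a <- data.frame(cells, rater = "A", cartilage_grade = ca, bme_grade = ba,
                    stringsAsFactors = FALSE)
    b <- data.frame(cells, rater = "B",
                    cartilage_grade = flip(ca, 0, 2),
                    bme_grade = flip(ba, 0, 3),
                    stringsAsFactors = FALSE)
    list(rater_a = lesion_score_table(a), rater_b = lesion_score_table(b))
  })
}

#' Simulate a subject covariate table with planted associations
#'
#' Generates a cohort with age, sex, BMI, weight, injected dose and a
#' HOOS-type pain subscale (0-100, 0 = worst). A latent severity variable
#' drives pain and any requested outcome so that chosen pairs have a known
#' population correlation.
#'
#' @param n subjects.
#' @param planted_r population correlation between `severity` and pain.
#' @param seed RNG seed.
#' @return data frame with one row per subject; the latent `severity` column
#'   is included as ground truth.
#' @export
phantom_subjects <- function(n = 10, planted_r = 0.8, seed = 1L) {
  stopifnot(abs(planted_r) <= 1)
  with_seed(seed, {
    z <- stats::rnorm(n)
    pain_lat <- planted_r * z + sqrt(1 - planted_r^2) * stats::rnorm(n)
    data.frame(
      subject = seq_len(n),
      age = round(stats::rnorm(n, 55, 10)),
      sex = sample(c("M", "F"), n, replace = TRUE),
      bmi = round(stats::rnorm(n, 27, 4), 1),
      weight_kg = round(stats::rnorm(n, 75, 12), 1),
      dose_mbq = round(stats::rnorm(n, 250, 20), 1),
      hoos_pain = pmin(100, pmax(0, round(50 + 15 * pain_lat))),
      severity = z,
      stringsAsFactors = FALSE
    )
  })
}
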