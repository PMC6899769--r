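#' Parametric proximal-femur template surface
#'
#' An analytic corresponded point set standing in for a real femur mesh: a
#' cylindrical shaft, a cylindrical neck at a neck-shaft angle of about 130
#' degrees, a spherical head, and a greater-trochanter bump on the lateral
#' shaft. Every point carries a part label (`shaft`, `neck`, `head`,
#' `trochanter`) so geometric probes (head radius, shaft thickness, neck-shaft
#' angle, trochanter prominence) can be evaluated on any deformed copy.
#' Coordinates are mm; the shaft axis is +z (superior), the neck points
#' medially in +x.
#'
#' @param n_theta angular samples around each cylinder/sphere.
#' @param n_axial axial samples along the shaft and neck.
#' @return N x 3 matrix with attributes `part` (factor) and `anatomy`
#'   (list of construction parameters).
#' @export
femur_template <- function(n_theta = 16, n_axial = 10) {
  r_shaft <- 14; shaft_z <- seq(-80, -10, length.out = n_axial)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  shaft <- cbind(rep(r_shaft * cos(theta), n_axial),
                 rep(r_shaft * sin(theta), n_axial),
                 rep(shaft_z, each = n_theta))
  neck_angle <- 130 * pi / 180                      # neck-shaft angle
  ndir <- c(sin(pi - neck_angle), 0, cos(pi - neck_angle))  # ~(0.766, 0, 0.643)
  r_neck <- 9; neck_len <- seq(5, 32, length.out = max(4, n_axial %/% 2))
  # orthonormal frame around the neck axis
  u <- c(-ndir[3], 0, ndir[1]); v <- c(0, 1, 0)
  neck <- do.call(rbind, lapply(neck_len, function(l) {
    ctr <- l * ndir
    t(ctr + r_neck * (outer(u, cos(theta)) + outer(v, sin(theta))))
  }))
  head_ctr <- 40 * ndir
  r_head <- 22
  phi <- seq(0.15 * pi, 0.85 * pi, length.out = n_axial)
  head <- do.call(rbind, lapply(phi, function(p) {
    cbind(head_ctr[1] + r_head * sin(p) * cos(theta),
          head_ctr[2] + r_head * sin(p) * sin(theta),
          head_ctr[3] + r_head * cos(p))
  }))
  # greater trochanter: lateral bump at the shaft top
  troch_ctr <- c(-r_shaft - 6, 0, -8)
  troch <- do.call(rbind, lapply(seq(0.2 * pi, 0.8 * pi, length.out = 4), function(p) {
    cbind(troch_ctr[1] - 10 * sin(p) * cos(theta / 2),
          troch_ctr[2] + 10 * sin(p) * sin(theta / 2),
          troch_ctr[3] + 10 * cos(p))
  }))
  pts <- rbind(shaft, neck, head, troch)
  part <- factor(c(rep("shaft", nrow(shaft)), rep("neck", nrow(neck)),
                   rep("head", nrow(head)), rep("trochanter", nrow(troch))),
                 levels = c("shaft", "neck", "head", "trochanter"))
  attr(pts, "part") <- part
  attr(pts, "anatomy") <- list(r_shaft = r_shaft, r_neck = r_neck,
                               r_head = r_head, head_ctr = head_ctr,
                               neck_dir = ndir, troch_ctr = troch_ctr)
  pts
}

#' Planted displacement modes of the femur template
#'
#' Six anatomically interpretable displacement fields evaluated at the
#' template points: greater-trochanter prominence, femoral-head size, shaft
#' thickness, neck-shaft angle (linearized rotation of the head/neck about
#' the neck base), a cam-type head-neck bump, and a superomedial osteophyte
#' bump. The raw fields are orthonormalized (Gram-Schmidt on the flattened
#' 3N vectors) so planted variances translate directly into PCA eigenvalues.
#'
#' @param template output of [femur_template()].
#' @param orthonormalize if `FALSE`, return the raw anatomical fields.
#' @return 3N x m matrix of unit-norm, mutually orthogonal mode vectors, with
#'   attribute `mode_names`.
#' @export
femur_modes <- function(template, orthonormalize = TRUE) {
  part <- attr(template, "part")
  an <- attr(template, "anatomy")
  N <- nrow(template)
  gaussw <- function(ctr, scale) exp(-rowSums(sweep(template, 2, ctr)^2) / scale^2)

  disp <- list()
  # 1: trochanter prominence — outward displacement of trochanter points
  w <- gaussw(an$troch_ctr, 12) * (part == "trochanter")
  dir <- sweep(template, 2, an$troch_ctr)
  dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-9)
  disp$trochanter <- dir * w

  # 2: head size — radial expansion of the head about its centre
  w <- (part == "head") * 1
  dir <- sweep(template, 2, an$head_ctr)
  dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-9)
  disp$head_size <- dir * w

  # 3: shaft thickness — radial expansion about the shaft axis (z)
  w <- (part %in% c("shaft", "trochanter")) * 1
  dir <- cbind(template[, 1], template[, 2], 0)
  dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-9)
  disp$shaft_thickness <- dir * w

  # 4: neck-shaft angle — linearized rotation of neck+head about the y axis
  w <- (part %in% c("neck", "head")) * 1
  rel <- template                       # rotation about the neck base (origin)
  disp$neck_shaft_angle <- cbind(rel[, 3], 0, -rel[, 1]) * w * 0.05

  # 5: cam bump — anterolateral bump at the head-neck junction
  junction <- an$head_ctr - an$r_head * an$neck_dir
  w <- gaussw(junction + c(0, 8, 0), 10)
  nrm <- sweep(template, 2, an$head_ctr)
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-9)
  disp$cam <- nrm * w * (part %in% c("head", "neck"))

  # 6: osteophyte — superomedial head bump
  osteo_ctr <- an$head_ctr + an$r_head * c(0.5, 0, 0.85)
  w <- gaussw(osteo_ctr, 9) * (part == "head")
  disp$osteophyte <- nrm * w

  M <- vapply(disp, function(m) as.vector(m), numeric(3 * N))
  if (orthonormalize) {
    # project out the similarity-group generators (global translations and
    # infinitesimal rotations about the centroid): alignment would otherwise
    # absorb part of each planted mode, and the recovered PCA subspace would
    # no longer match the planted one
    ctr <- colMeans(template)
    rel <- sweep(template, 2, ctr)
    gen <- cbind(
      as.vector(matrix(rep(c(1, 0, 0), each = N), ncol = 3)),
      as.vector(matrix(rep(c(0, 1, 0), each = N), ncol = 3)),
      as.vector(matrix(rep(c(0, 0, 1), each = N), ncol = 3)),
      as.vector(cbind(0, -rel[, 3], rel[, 2])),
      as.vector(cbind(rel[, 3], 0, -rel[, 1])),
      as.vector(cbind(-rel[, 2], rel[, 1], 0))
    )
    Qg <- qr.Q(qr(gen))
    M <- M - Qg %*% crossprod(Qg, M)
    Q <- qr.Q(qr(M))
    # keep the sign of each column aligned with the raw field
    sgn <- sign(colSums(Q * M)); sgn[sgn == 0] <- 1
    M <- sweep(Q, 2, sgn, "*")
  } else {
    M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  }
  colnames(M) <- names(disp)
  attr(M, "mode_names") <- names(disp)
  M
}

#' Sample a cohort of corresponded femur surfaces with known shape modes
#'
#' Subject i is `template + sum_j score_ij * mode_j`, with mode scores drawn
#' independently from zero-mean normals with the given standard deviations
#' (mm). A continuous outcome ("pain") is generated with a planted population
#' correlation `planted_r` against the score of `outcome_mode`, so the
#' association layer can be validated against known truth.
#'
#' @param n_subjects cohort size (>= 2).
#' @param mode_sd standard deviations of the mode scores (mm); length defines
#'   how many template modes are active.
#' @param planted_r population correlation between the outcome and the
#'   `outcome_mode` score, in [-1, 1].
#' @param outcome_mode index of the mode driving the outcome.
#' @param template,modes optionally supply a template and mode matrix;
#'   defaults to [femur_template()] and [femur_modes()]. Non-orthogonal mode
#'   matrices are accepted with a warning.
#' @param seed RNG seed.
#' @return list: `surfaces` (list of N x 3 matrices), `truth` (template,
#'   modes, scores, outcome, planted_r, mode_sd).
#' @export
sample_femur_surfaces <- function(n_subjects = 50,
                                  mode_sd = c(4, 2, 1.5, 1, 0.7, 0.5),
                                  planted_r = 0.8, outcome_mode = 1,
                                  template = femur_template(),
                                  modes = NULL, seed = 1L) {
  stopifnot(n_subjects >= 2, abs(planted_r) <= 1, all(mode_sd >= 0))
  if (is.null(modes)) modes <- femur_modes(template)
  m <- length(mode_sd)
  stopifnot(m <= ncol(modes))
  modes <- modes[, seq_len(m), drop = FALSE]
  G <- crossprod(modes)
  if (max(abs(G - diag(diag(G)))) > 1e-6) {
    warning("planted modes are not mutually orthogonal", call. = FALSE)
  }
  with_seed(seed, {
    scores <- matrix(stats::rnorm(n_subjects * m), n_subjects, m)
    scores <- sweep(scores, 2, mode_sd, "*")
    surfaces <- lapply(seq_len(n_subjects), function(i) {
      s <- template + matrix(modes %*% scores[i, ], ncol = 3)
      attr(s, "part") <- attr(template, "part")
      s
    })
    z <- scores[, outcome_mode] / max(mode_sd[outcome_mode], 1e-12)
    outcome <- planted_r * z + sqrt(1 - planted_r^2) * stats::rnorm(n_subjects)
    list(surfaces = surfaces,
         truth = list(template = template, modes = modes, scores = scores,
                      mode_sd = mode_sd, outcome = outcome,
                      planted_r = planted_r, outcome_mode = outcome_mode))
  })
}

# --- geometric probes on (deformed) template copies -------------------------

#' Geometric probes for labelling shape modes
#'
#' Estimators evaluated on any surface that carries the template's part
#' labels: femoral-head radius (mean distance of head points to their
#' centroid), shaft thickness (mean in-plane distance of shaft points to the
#' fitted shaft axis), neck-shaft angle (degrees, between the principal axes
#' of the shaft and neck point sets), and trochanter prominence (mean distance
#' of trochanter points from the shaft axis).
#'
#' @param surface N x 3 matrix with a `part` attribute.
#' @return named numeric vector.
#' @export
femur_probes <- function(surface) {
  part <- attr(surface, "part")
  stopifnot(!is.null(part), length(part) == nrow(surface))
  head_pts <- surface[part == "head", , drop = FALSE]
  shaft_pts <- surface[part == "shaft", , drop = FALSE]
  neck_pts <- surface[part == "neck", , drop = FALSE]
  troch_pts <- surface[part == "trochanter", , drop = FALSE]
  head_radius <- mean(sqrt(rowSums(sweep(head_pts, 2, colMeans(head_pts))^2)))
  axis_of <- function(p) {
    v <- svd(scale(p, scale = FALSE))$v[, 1]
    if (v[3] < 0) v <- -v
    v
  }
  shaft_axis <- axis_of(shaft_pts)
  ctr <- colMeans(shaft_pts)
  radial <- function(p) {
    rel <- sweep(p, 2, ctr)
    along <- rel %*% shaft_axis
    perp <- rel - along %*% t(shaft_axis)
    sqrt(rowSums(perp^2))
  }
  shaft_thickness <- mean(radial(shaft_pts))
  neck_axis <- axis_of(neck_pts)
  ang <- acos(pmin(pmax(abs(sum(shaft_axis * neck_axis)), -1), 1))
  neck_shaft_deg <- 180 - ang * 180 / pi
  troch_prominence <- mean(radial(troch_pts))
  c(head_radius = head_radius, shaft_thickness = shaft_thickness,
    neck_shaft_angle_deg = neck_shaft_deg,
    trochanter_prominence = troch_prominence)
}
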