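#' The ten hip subregions used for morphologic grading
#'
#' Acetabular/femoral anterior and posterior (sagittal plane) and the
#' superolateral, superomedial, lateral and inferior subregions (coronal
#' plane): AA, FA, AP, FP, ASL, ASM, FL, FSL, FSM, FI.
#' @export
hip_subregions <- function() {
  c("AA", "FA", "AP", "FP", "ASL", "ASM", "FL", "FSL", "FSM", "FI")
}

# Bone-marrow-edema size thresholds of the grading scheme (documentation
# constants; grading from images is a human task): grade 1 <= 0.5 cm,
# grade 2 in (0.5, 1.5] cm, grade 3 > 1.5 cm.
BME_SIZE_THRESHOLDS_CM <- c(grade1_max = 0.5, grade2_max = 1.5)

#' Validate a semi-quantitative lesion score table
#'
#' Cartilage lesions are graded 0 (no loss), 1 (partial-thickness loss),
#' 2 (full-thickness loss); bone-marrow-edema-like lesions 0-3 by size; both
#' in the ten standard subregions per subject and rater.
#'
#' @param df data frame with columns `subject`, `rater`, `subregion`,
#'   `cartilage_grade`, `bme_grade`.
#' @return the validated table with class `lesion_score_table`.
#' @export
lesion_score_table <- function(df) {
  need <- c("subject", "rater", "subregion", "cartilage_grade", "bme_grade")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  bad_sr <- setdiff(unique(df$subregion), hip_subregions())
  if (length(bad_sr)) stop("unknown subregions: ", paste(bad_sr, collapse = ", "),
                           call. = FALSE)
  check_grade <- function(g, lo, hi, what) {
    bad <- which(!(g %in% lo:hi))
    if (length(bad)) {
      stop(sprintf("%s out of range [%d,%d] at subject %s, subregion %s",
                   what, lo, hi, df$subject[bad[1]], df$subregion[bad[1]]),
           call. = FALSE)
    }
  }
  check_grade(df$cartilage_grade, 0, 2, "cartilage grade")
  check_grade(df$bme_grade, 0, 3, "BME grade")
  per <- table(df$subject, df$rater)
  if (any(per != length(hip_subregions()))) {
    stop("each subject x rater must have exactly the 10 subregions",
         call. = FALSE)
  }
  class(df) <- unique(c("lesion_score_table", class(df)))
  df
}

#' Per-subject total lesion scores
#'
#' Sums the grades over the ten subregions. With maximal grades everywhere the
#' cartilage total is 20 and the bone-marrow total is 30.
#'
#' @param table a `lesion_score_table` (single rater, or pass `rater` to
#'   select one).
#' @param rater optional rater ID to subset.
#' @return data frame: `subject`, `cartilage_total` (0-20), `bme_total` (0-30).
#' @export
total_scores <- function(table, rater = NULL) {
  table <- lesion_score_table(as.data.frame(table))
  if (!is.null(rater)) table <- table[table$rater == rater, ]
  if (length(unique(table$rater)) > 1) {
    stop("table contains multiple raters; pass `rater` to select one",
         call. = FALSE)
  }
  agg <- stats::aggregate(cbind(cartilage_total = cartilage_grade,
                                bme_total = bme_grade) ~ subject,
                          data = table, FUN = sum)
  agg[order(agg$subject), ]
}

#' Inter-rater agreement: Cohen's kappa and percent agreement
#'
#' Pools the per-cell grades of the two raters and computes
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement \eqn{p_o}
#' and chance agreement \eqn{p_e} from the marginal grade frequencies.
#' Unweighted by default; linear weights are available for the ordinal scales.
#' By default each score type is assessed separately; `type = "pooled"`
#' concatenates cartilage and BME gradings into one rating set.
#'
#' @param table_a,table_b `lesion_score_table`s for the two raters, covering
#'   the same subjects and subregions.
#' @param type `"cartilage"`, `"bme"` or `"pooled"`.
#' @param weights `"unweighted"` or `"linear"`.
#' @return list: `kappa`, `agreement_pct`, `p_o`, `p_e`, `n_cells`. When both
#'   raters are constant and identical, `p_e = 1` and kappa is undefined
#'   (`NA`) with 100% agreement.
#' @export
rater_agreement <- function(table_a, table_b,
                            type = c("cartilage", "bme", "pooled"),
                            weights = c("unweighted", "linear")) {
  type <- match.arg(type)
  weights <- match.arg(weights)
  a <- lesion_score_table(as.data.frame(table_a))
  b <- lesion_score_table(as.data.frame(table_b))
  key <- function(d) paste(d$subject, d$subregion)
  a <- a[order(a$subject, a$subregion), ]
  b <- b[order(b$subject, b$subregion), ]
  if (!identical(key(a), key(b))) {
    stop("raters must cover identical subject x subregion cells", call. = FALSE)
  }
  ga <- switch(type,
               cartilage = a$cartilage_grade,
               bme = a$bme_grade,
               pooled = c(a$cartilage_grade, b_offset(a)))
  gb <- switch(type,
               cartilage = b$cartilage_grade,
               bme = b$bme_grade,
               pooled = c(b$cartilage_grade, b_offset(b)))
  cohen_kappa(ga, gb, weights = weights)
}

# Offset BME grades so pooled cartilage/BME categories stay distinct.
b_offset <- function(d) d$bme_grade + 10L

#' Cohen's kappa for two paired categorical ratings
#'
#' @param x,y equal-length integer/character rating vectors.
#' @param weights `"unweighted"` or `"linear"` (linear requires numeric-coded
#'   ordinal categories).
#' @return list: `kappa`, `agreement_pct`, `p_o`, `p_e`, `n_cells`.
#' @export
cohen_kappa <- function(x, y, weights = c("unweighted", "linear")) {
  weights <- match.arg(weights)
  stopifnot(length(x) == length(y))
  lev <- sort(unique(c(x, y)))
  tab <- table(factor(x, lev), factor(y, lev)) / length(x)
  if (weights == "unweighted") {
    w <- diag(length(lev))
  } else {
    v <- as.numeric(lev)
    if (any(is.na(v))) stop("linear weights need numeric categories", call. = FALSE)
    w <- 1 - abs(outer(v, v, "-")) / max(diff(range(v)), 1)
  }
  p_o <- sum(w * tab)
  marg_x <- rowSums(tab); marg_y <- colSums(tab)
  p_e <- sum(w * outer(marg_x, marg_y))
  raw_agree <- sum(diag(tab))
  kappa <- if (abs(1 - p_e) < 1e-12) NA_real_ else (p_o - p_e) / (1 - p_e)
  list(kappa = kappa, agreement_pct = 100 * raw_agree,
       p_o = p_o, p_e = p_e, n_cells = length(x))
}
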