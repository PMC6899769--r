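#' Default end-to-end pipeline configuration
#'
#' A complete configuration for the phantom-driven run: phantom geometry and
#' noise, the dynamic frame phases, Patlak equilibration time, relaxometry
#' contrasts, shape-cohort settings, two-rater scoring simulation, a
#' registration self-consistency stage, and the association screen. All
#' stochastic stages derive their seeds from the single `seed` field.
#'
#' @param out_dir output directory for stage files and the manifest.
#' @param seed master RNG seed.
#' @return nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = tempfile("hipoa_run_"),
                                    seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    phantom = list(dim = c(32L, 32L, 20L), voxel_mm = c(2, 2, 2),
                   pet_noise = 0, mr_sigma = 0,
                   weight_kg = 70, dose_mbq = 250),
    frames = list(c(12, 10), c(6, 30), c(10, 240)),
    t_star = 15,
    aif = list(use_mask = TRUE, k = 20),
    relaxometry = list(kinds = c("t1rho", "t2")),
    shape = list(n_subjects = 50, mode_sd = c(4, 2, 1.5, 1, 0.7, 0.5),
                 planted_r = 0.8, n_modes = 6),
    scoring = list(n_subjects = 10, disagree = 0.07),
    registration = list(enabled = TRUE, amplitude_vox = 1.5,
                        spacing = 4, levels = 3, lambda = 0.01, maxit = 40),
    stats = list(n_subjects = 50, planted_r = 0.8)
  )
}

required_config_fields <- function() {
  c("out_dir", "seed", "phantom", "frames", "t_star", "aif",
    "relaxometry", "shape", "scoring", "registration", "stats")
}

#' Run the full phantom-to-associations pipeline
#'
#' Executes every stage in dependency order: phantom rendering, input-function
#' extraction, region Patlak fits, SUV mapping and region summaries,
#' T1rho/T2 relaxometry, PET-to-MR-grid resampling, a registration
#' self-consistency check (a known smooth warp of the phantom is recovered and
#' scored by label Dice), the femur shape model, two-rater lesion scoring with
#' agreement, and the association screen. Every output file is plain
#' NIfTI/CSV/JSON; a manifest records the configuration hash, the seed, the
#' per-stage timings and the MD5 of every file, so a rerun with identical
#' config is bit-identical and verifiably so.
#'
#' @param config a config list as from [default_pipeline_config()], or a path
#'   to a YAML file holding one.
#' @param quiet suppress stage messages.
#' @return invisibly, a list with `manifest` (also written to
#'   `manifest.json`), and the in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  missing <- setdiff(required_config_fields(), names(config))
  if (length(missing)) {
    stop("config field missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  files <- character(0)
  timings <- list()
  results <- list()
  stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s",
                                      name, conditionMessage(e))), log_path)
      partial <- list(config_hash = config_hash(config), seed = config$seed,
                      completed_stages = names(timings), failed_stage = name)
      jsonlite::write_json(partial, file.path(out_dir, "manifest_partial.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    say("stage %-14s done in %6.2f s", name, timings[[name]])
    res
  }

  results$phantom <- stage("phantom", function() {
    ph <- config$phantom
    spec <- phantom_spec(dim = ph$dim, voxel_mm = ph$voxel_mm,
                         schedule = make_frame_schedule(config$frames),
                         pet_noise = ph$pet_noise, mr_sigma = ph$mr_sigma,
                         weight_kg = ph$weight_kg, dose_mbq = ph$dose_mbq,
                         seed = config$seed)
    pet <- render_dynamic_pet(spec)
    f1 <- file.path(out_dir, "dynamic_pet.nii")
    write_volume_nifti(pet$series$data, f1, spec$voxel_mm)
    f2 <- file.path(out_dir, "frame_schedule.csv")
    write_frame_schedule(spec$schedule, f2)
    f3 <- file.path(out_dir, "labels.nii")
    write_volume_nifti(spec$labels, f3, spec$voxel_mm)
    files <<- c(files, f1, f2, f3)
    list(spec = spec, pet = pet, masks = phantom_mask_set(spec))
  })
  spec <- results$phantom$spec
  pet <- results$phantom$pet
  masks <- results$phantom$masks

  results$kinetics <- stage("pet_kinetics", function() {
    aif <- if (isTRUE(config$aif$use_mask)) {
      extract_aif(pet$series, artery_mask = region_mask(spec, "artery"))
    } else {
      extract_aif(pet$series, k = config$aif$k)
    }
    patlak <- patlak_by_region(pet$series, aif, masks, t_star = config$t_star)
    suv <- compute_suv(static_uptake(pet$series), spec$weight_kg, spec$dose_mbq,
                       source = "phantom static window")
    suv_tab <- region_summary(suv, masks)
    f1 <- file.path(out_dir, "patlak_regions.csv")
    utils::write.csv(patlak, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "suv_regions.csv")
    utils::write.csv(suv_tab, f2, row.names = FALSE)
    f3 <- file.path(out_dir, "suv.nii")
    write_volume_nifti(suv$data, f3, spec$voxel_mm)
    files <<- c(files, f1, f2, f3)
    list(aif = aif, patlak = patlak, suv = suv, suv_regions = suv_tab)
  })

  results$relaxometry <- stage("relaxometry", function() {
    cart <- region_mask(spec, "cartilage_femoral") |
      region_mask(spec, "cartilage_acetabular")
    out <- list()
    for (kind in config$relaxometry$kinds) {
      rend <- render_relax_series(spec, kind = kind)
      fit <- fit_monoexp(rend$series, mask = cart)
      tab <- roi_relaxation(fit, masks)
      fmap <- file.path(out_dir, paste0(kind, "_map.nii"))
      write_volume_nifti(ifelse(is.na(fit$T_ms), 0, fit$T_ms), fmap,
                         spec$voxel_mm)
      ftab <- file.path(out_dir, paste0(kind, "_regions.csv"))
      utils::write.csv(tab, ftab, row.names = FALSE)
      files <<- c(files, fmap, ftab)
      out[[kind]] <- list(fit = fit, regions = tab, truth_T = rend$truth_T)
    }
    out
  })

  results$spatial <- stage("spatial", function() {
    # PET (coarse axial grid) -> MR-like (finer sagittal-oriented grid)
    suv <- results$kinetics$suv$data
    src_aff <- affine_from_spacing(spec$voxel_mm)
    mr_dim <- spec$dim * 2L
    tgt_aff <- affine_from_spacing(spec$voxel_mm / 2)
    on_mr <- resample_to_grid(suv, src_aff, tgt_aff, mr_dim, "linear")
    f1 <- file.path(out_dir, "suv_on_mr_grid.nii")
    write_volume_nifti(on_mr, f1, spec$voxel_mm / 2)
    files <<- c(files, f1)
    reg <- NULL
    if (isTRUE(config$registration$enabled)) {
      rc <- config$registration
      img <- gauss_smooth3(array(as.numeric(spec$labels > 0), spec$dim), 1)
      warp <- synthetic_warp(spec$dim, amplitude = rc$amplitude_vox)
      moved <- apply_displacement(img, warp)
      moved_lab <- apply_displacement(spec$labels, warp, "nearest")
      fld <- register_nonrigid(img, moved, spacing = rc$spacing,
                               levels = rc$levels, lambda = rc$lambda,
                               maxit = rc$maxit)
      prop <- propagate_masks(fld, masks)
      dice <- dice_coefficient(prop$volume > 0, moved_lab > 0)
      f2 <- file.path(out_dir, "registration_check.csv")
      utils::write.csv(data.frame(metric = c("dice_bone", "mse_before", "mse_after"),
                                  value = c(dice, fld$mse_before, fld$mse_after)),
                       f2, row.names = FALSE)
      files <<- c(files, f2)
      reg <- list(field = fld, dice = dice)
    }
    list(suv_on_mr = on_mr, registration = reg)
  })

  results$shape <- stage("shape_model", function() {
    sh <- config$shape
    cohort <- sample_femur_surfaces(n_subjects = sh$n_subjects,
                                    mode_sd = sh$mode_sd,
                                    planted_r = sh$planted_r,
                                    seed = config$seed + 10L)
    aligned <- align_surfaces(cohort$surfaces)
    model <- fit_pca(aligned, m = sh$n_modes)
    dir_model <- file.path(out_dir, "shape_model")
    write_shape_model(model, dir_model)
    report <- mode_feature_report(model)
    f1 <- file.path(dir_model, "mode_features.csv")
    utils::write.csv(report, f1, row.names = FALSE)
    files <<- c(files, file.path(dir_model, c("mean.csv", "modes.csv",
                                              "eigenvalues.csv", "scores.csv")),
                f1)
    list(cohort = cohort, model = model, report = report)
  })

  results$scoring <- stage("scoring", function() {
    sc <- config$scoring
    tabs <- simulate_lesion_scores(n_subjects = sc$n_subjects,
                                   disagree = sc$disagree,
                                   seed = config$seed + 20L)
    totals <- total_scores(tabs$rater_a)
    agree <- rater_agreement(tabs$rater_a, tabs$rater_b, type = "pooled")
    f1 <- file.path(out_dir, "lesion_totals.csv")
    utils::write.csv(totals, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "rater_agreement.json")
    jsonlite::write_json(agree, f2, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    files <<- c(files, f1, f2)
    list(tables = tabs, totals = totals, agreement = agree)
  })

  results$stats <- stage("stats", function() {
    st <- config$stats
    subj <- phantom_subjects(n = st$n_subjects, planted_r = st$planted_r,
                             seed = config$seed + 30L)
    shape_scores <- results$shape$model$scores
    n_common <- min(nrow(subj), nrow(shape_scores))
    rec <- cbind(subj[seq_len(n_common), ],
                 shape1 = shape_scores[seq_len(n_common), 1],
                 shape_outcome = results$shape$cohort$truth$outcome[seq_len(n_common)])
    pairs <- data.frame(x = c("severity", "shape1", "age"),
                        y = c("hoos_pain", "shape_outcome", "hoos_pain"),
                        stringsAsFactors = FALSE)
    screen <- association_screen(rec, pairs,
                                 covariate_map = list("age|hoos_pain" = "bmi"))
    f1 <- file.path(out_dir, "subjects.csv")
    utils::write.csv(subj, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "associations.csv")
    utils::write.csv(screen, f2, row.names = FALSE)
    files <<- c(files, f1, f2)
    list(records = rec, screen = screen)
  })

  manifest <- list(
    package = "hipoa",
    config_hash = config_hash(config),
    seed = config$seed,
    stages = names(timings),
    timings_s = timings,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = sub(paste0("^", out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  say("pipeline complete: %d files, manifest written", length(files))
  invisible(list(manifest = manifest, results = results, out_dir = out_dir))
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical JSON serialization; identical configs hash equally
#' regardless of list construction order. The output directory is excluded:
#' the hash identifies the computation, not where its files land.
#' @param config config list.
#' @export
config_hash <- function(config) {
  config$out_dir <- NULL
  canon <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                            digits = NA)
  f <- tempfile()
  writeLines(canon, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

#' Smooth synthetic displacement field for self-consistency tests
#'
#' A separable sinusoidal field with the given peak amplitude (voxels),
#' tapered to zero at the volume faces so warped content never leaves the
#' field of view.
#'
#' @param dim grid size.
#' @param amplitude peak displacement (voxels).
#' @param periods sinusoid periods across the volume.
#' @return a `displacement_field`.
#' @export
synthetic_warp <- function(dim, amplitude = 1.5, periods = 1) {
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                   z = seq_len(dim[3]))
  nx <- (g$x - 1) / (dim[1] - 1); ny <- (g$y - 1) / (dim[2] - 1)
  nz <- (g$z - 1) / (dim[3] - 1)
  taper <- sin(pi * nx) * sin(pi * ny) * sin(pi * nz)
  u <- array(0, c(dim, 3))
  u[, , , 1] <- array(amplitude * sin(2 * pi * periods * ny) * taper, dim)
  u[, , , 2] <- array(amplitude * sin(2 * pi * periods * nz) * taper, dim)
  u[, , , 3] <- array(amplitude * 0.5 * sin(2 * pi * periods * nx) * taper, dim)
  structure(list(disp = u, voxel_mm = c(1, 1, 1), converged = TRUE,
                 mse_before = NA_real_, mse_after = NA_real_),
            class = "displacement_field")
}
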