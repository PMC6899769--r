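#!/usr/bin/env Rscript
# Geometric glue: resample the coarse axial PET grid into the finer MR grid,
# then validate the nonrigid registration by recovering a known smooth warp of
# the phantom and scoring propagated labels by Dice, with and without
# active-contour refinement against the intensity image.

suppressPackageStartupMessages(library(hipoa))
out <- "results/04_spatial"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- phantom_spec(pet_noise = 0, mr_sigma = 0)
masks <- phantom_mask_set(spec)

# PET (2 mm axial) -> MR-like grid (1 mm)
pet <- render_dynamic_pet(spec)
suv <- compute_suv(static_uptake(pet$series), spec$weight_kg, spec$dose_mbq)
on_mr <- resample_to_grid(suv$data, affine_from_spacing(spec$voxel_mm),
                          affine_from_spacing(spec$voxel_mm / 2),
                          spec$dim * 2L, "linear")
write_volume_nifti(on_mr, file.path(out, "suv_on_mr_grid.nii"), spec$voxel_mm / 2)
cat(sprintf("Resampled SUV to %s grid (%d voxels out of field)\n",
            paste(spec$dim * 2L, collapse = "x"), attr(on_mr, "n_out_of_field")))

# registration self-consistency on a known smooth warp
img <- array(as.numeric(spec$labels > 0), spec$dim)
warp <- synthetic_warp(spec$dim, amplitude = 3)
moved <- apply_displacement(img, warp)
moved_lab <- apply_displacement(spec$labels, warp, "nearest")
d0 <- dice_coefficient(spec$labels > 0, moved_lab > 0)
fld <- register_nonrigid(img, moved)
prop <- propagate_masks(fld, masks)
d1 <- dice_coefficient(prop$volume > 0, moved_lab > 0)
resid <- sqrt(rowSums((matrix(fld$disp, ncol = 3) - matrix(warp$disp, ncol = 3))^2))
mres <- mean(resid[as.vector(moved > 0.1)])

# refinement against the warped intensity image
prop_ref <- propagate_masks(fld, masks, refine = TRUE,
                            image = apply_displacement(img, warp),
                            labels_to_refine = c(1L, 2L),
                            iterations = 10, lambda_smooth = 0.05)
d2 <- dice_coefficient(prop_ref$volume > 0, moved_lab > 0)

summary <- data.frame(
  metric = c("dice_unregistered", "dice_registered", "dice_refined",
             "mean_field_residual_vox", "mse_before", "mse_after"),
  value = c(d0, d1, d2, mres, fld$mse_before, fld$mse_after))
write.csv(summary, file.path(out, "registration_summary.csv"), row.names = FALSE)
cat("Registration self-consistency:\n"); print(summary)
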