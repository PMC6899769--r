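#!/usr/bin/env Rscript
# Voxelwise T1rho and T2 mapping of the phantom cartilage: mono-exponential
# Levenberg-Marquardt fits over the TSL/TE schedules, ROI summaries against
# ground truth, and the noise-bias curve at the default MR noise level.

suppressPackageStartupMessages(library(hipoa))
out <- "results/03_relaxometry"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

spec <- phantom_spec(pet_noise = 0, mr_sigma = 2, seed = seed)
masks <- phantom_mask_set(spec)
cart <- array(spec$labels %in% c(3, 4), spec$dim)

for (kind in c("t1rho", "t2")) {
  rend <- render_relax_series(spec, kind)
  fit <- fit_monoexp(rend$series, mask = cart)
  tab <- roi_relaxation(fit, masks)
  write_volume_nifti(ifelse(is.na(fit$T_ms), 0, fit$T_ms),
                     file.path(out, paste0(kind, "_map.nii")), spec$voxel_mm)
  write.csv(tab, file.path(out, paste0(kind, "_regions.csv")), row.names = FALSE)
  truth <- if (kind == "t1rho") spec$relaxation$cartilage_femoral$T1rho
           else spec$relaxation$cartilage_femoral$T2
  got <- tab$mean_T_ms[tab$region == "cartilage_femoral"]
  cat(sprintf("%s: femoral cartilage mean %.2f ms (truth %.2f, bias %.2f%%), valid %.0f%%\n",
              kind, got, truth, 100 * (got - truth) / truth,
              100 * tab$valid_fraction[tab$region == "cartilage_femoral"]))
}

# bias vs noise level at the cartilage T1rho of 36.44 ms
tau <- spec$tsl_ms
rows <- lapply(c(0.5, 1, 2, 4, 8), function(sg) {
  sig <- array(rep(100 * exp(-tau / 36.44), each = 10000), c(100, 100, 1, 4))
  set.seed(seed)
  sig <- sig + array(rnorm(length(sig), sd = sg), dim(sig))
  f <- fit_monoexp(new_relax_series(sig, tau, "t1rho"))
  data.frame(sigma = sg, mean_T = mean(f$T_ms[f$valid]),
             bias_pct = 100 * (mean(f$T_ms[f$valid]) - 36.44) / 36.44,
             valid_fraction = mean(f$valid))
})
bias <- do.call(rbind, rows)
write.csv(bias, file.path(out, "noise_bias.csv"), row.names = FALSE)
cat("Noise-bias curve (10^4 voxels, S0 = 100):\n"); print(bias)
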