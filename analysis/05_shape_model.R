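#!/usr/bin/env Rscript
# Statistical shape model of the femur: sample a cohort from the planted
# low-rank shape space, align (translation + rotation, scale retained), fit
# PCA, report variance fractions and the anatomical response of each mode, and
# write mean +/- 2 SD reconstructions of the leading modes as PLY point clouds.

suppressPackageStartupMessages(library(hipoa))
out <- "results/05_shape_model"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

cohort <- sample_femur_surfaces(n_subjects = 50,
                                mode_sd = c(4, 2, 1.5, 1, 0.7, 0.5),
                                planted_r = 0.8, seed = seed)
aligned <- align_surfaces(cohort$surfaces)
model <- fit_pca(aligned, m = 6)
write_shape_model(model, file.path(out, "model"))

planted_fracs <- cohort$truth$mode_sd^2 / sum(cohort$truth$mode_sd^2)
cat("Variance fractions (recovered vs planted):\n")
print(data.frame(mode = 1:6,
                 recovered = round(model$variance_fraction, 4),
                 planted = round(planted_fracs, 4)))
angle <- max(principal_angles(model$modes, cohort$truth$modes))
cat(sprintf("Max principal angle to the planted 6-mode subspace: %.3f deg\n", angle))

report <- mode_feature_report(model)
write.csv(report, file.path(out, "mode_features.csv"), row.names = FALSE)
cat("Geometric probe response per +1 SD:\n"); print(round(report, 3))

for (j in 1:3) {
  for (s in c(-2, 2)) {
    sc <- rep(0, j); sc[j] <- s
    write_surface_ply(reconstruct(model, sc),
                      file.path(out, sprintf("mode%d_%+dsd.ply", j, s)))
  }
}
write_surface_ply(model$mean, file.path(out, "mean_shape.ply"))

r <- pearson(model$scores[, 1], cohort$truth$outcome)
cat(sprintf("Mode-1 score vs planted outcome: r = %.3f (planted 0.8), p = %.2g\n",
            r$r, r$p))
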