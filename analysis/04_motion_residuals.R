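#!/usr/bin/env Rscript
# Motion-correction and pre-processing audit: (a) residual rigid transforms
# between two runs of per-timepoint motion correction, at the scale actually
# observed between OS installations (translations ~1e-5 mm, rotations just
# under 0.1 degrees); (b) stage-wise attribution of the image difference
# across the pre-processing chain.

suppressPackageStartupMessages(library(reprotrace))
dir.create("results", showWarnings = FALSE)
set.seed(1)

# (a) residual transforms over a 30-timepoint series, written and re-read
# through FLIRT-style ASCII .mat files as a real audit would consume them
dir_a <- tempfile("runA_"); dir_b <- tempfile("runB_")
dir.create(dir_a); dir.create(dir_b)
for (t in seq_len(30)) {
  rp <- gen_rigid_pair(axis = rnorm(3), angle_deg = runif(1, 0, 0.096),
                       translation_mm = runif(1, 0, 1e-5), seed = t)
  write_flirt_matrix(rp$t1, file.path(dir_a, sprintf("MAT_%04d", t - 1)))
  write_flirt_matrix(rp$t2, file.path(dir_b, sprintf("MAT_%04d", t - 1)))
}
res <- series_residuals(load_flirt_series(dir_a), load_flirt_series(dir_b))
print(res)
write.table(as.data.frame(res), "results/04_residuals.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# (b) stage-wise MAD profile: small difference after motion correction,
# reduced by smoothing, amplified by intensity normalization
mads <- c(motion_correction = 0.18, thresholding = 0.16, smoothing = 0.08,
          intensity_normalization = 0.9, temporal_filtering = 1.0)
ss <- gen_stage_series(shape = c(24, 24, 16), n_timepoints = 20,
                       stage_mads = mads, seed = 1)
prof <- stage_mad_profile(ss$stages)
print(prof)
write.table(as.data.frame(prof), "results/04_stage_mad.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("\nFinding: all 30 residuals stay below %.3g mm translation and\n",
            attr(res, "max_translation_mm") * 1.0001))
cat(sprintf("%.4g degrees rotation - numerically real but physically\n",
            attr(res, "max_rotation_deg") * 1.0001))
cat("negligible motion disagreement. The normalized MAD profile shows the\n")
cat("motion-correction stage contributing less than 20% of the final\n")
cat("difference, with intensity normalization the main amplifier.\n")
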