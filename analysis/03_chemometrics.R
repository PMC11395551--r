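#!/usr/bin/env Rscript
# Stage 3 — multivariate structure of the key-compound block.
#
# PCA for unsupervised structure, OPLS-DA contrasting the wild-type sample
# (S1) against the mutant-fermented samples (S2-S4), VIP marker selection,
# 200-permutation validation and CV-ANOVA. Also clusters samples and
# compounds on the full quantified matrix (the heatmap structure).
# Outputs land in results/chemometrics/.

suppressPackageStartupMessages(library(aromakey))
cfg <- aroma_config(n_permutations = 200, random_seed = 1)
set.seed(cfg$random_seed)
bundle <- read_bundle("results/bundle_fixture")
out <- "results/chemometrics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

run <- run_pipeline(bundle, cfg, out_dir = out)

cat(sprintf("PCA: PC1+PC2 explain %.1f%% of the key-compound variance\n",
            100 * sum(run$pca$explained_per_component[1:2])))
cat(sprintf("OPLS-DA (S1 vs S2-S4): R2X=%.3f R2Y=%.3f Q2=%.3f, %d orthogonal component(s)\n",
            run$opls$R2X, run$opls$R2Y, run$opls$Q2, run$opls$n_orth))
cat(sprintf("permutation validation (n=%d): p=%.4g, intercepts R2Y=%.3f Q2=%.3f\n",
            run$permutation$n, run$permutation$p_value,
            run$permutation$r2y_intercept, run$permutation$q2_intercept))
cat(sprintf("CV-ANOVA: F=%.2f (df %d,%d), p=%.4g\n",
            run$cv_anova$F, run$cv_anova$df1, run$cv_anova$df2,
            run$cv_anova$p_value))
vips <- sort(run$vip[run$vip > 1], decreasing = TRUE)
cat(sprintf("VIP > 1 markers (%d): %s\n", length(vips),
            paste(sprintf("%s (%.2f)", names(vips), vips), collapse = ", ")))
cl <- run$hca_samples$clusters
cat("HCA sample partition at k=2:",
    paste(names(cl), cl, collapse = " "), "\n")
cat("tables written to", out, "\n")
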