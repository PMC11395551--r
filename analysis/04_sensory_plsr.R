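#!/usr/bin/env Rscript
# Stage 4 — linking key compounds to sensory attributes.
#
# Two-factor PLSR of the six QDA attributes on the key-compound
# concentrations, correlation loadings for the biplot, and jack-knife
# significance of the regression coefficients per attribute.
# Outputs land in results/sensory/.

suppressPackageStartupMessages(library(aromakey))
cfg <- aroma_config()
bundle <- read_bundle("results/bundle_fixture")
out <- "results/sensory"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

peaks <- assign_peaks(bundle$peaks, bundle$library, bundle$ladder)
quant <- quantify_table(peaks, bundle$is_spec)
roav_tbl <- roav_table(quant, bundle$library)
screen <- screen_roav(roav_tbl, cfg$roav_threshold)
gco <- gco_consensus(bundle$gco, cfg$gco_min_panelists,
                     library = bundle$library, ladder = bundle$ladder)
key <- intersect_key_compounds(screen, gco)

X <- key_compound_matrix(quant, key$members)
Y <- sensory_attribute_matrix(bundle$sensory, rownames(X))
fit <- plsr_sensory(X, Y)
jk <- jackknife_significance(fit, alpha = cfg$alpha)

write.csv(fit$correlation_loadings, file.path(out, "correlation_loadings.csv"),
          row.names = FALSE)
write.csv(jk, file.path(out, "jackknife.csv"), row.names = FALSE)

cat(sprintf("PLSR: 2 factors explain %.0f%% of X (key compounds) and %.0f%% of Y (attributes)\n",
            100 * fit$explained_x, 100 * fit$explained_y))
sig_soy <- jk[jk$attribute == "soy_sauce_like" & jk$significant &
                jk$coefficient > 0, ]
cat(sprintf("compounds positively and significantly tied to the overall aroma (%d):\n",
            nrow(sig_soy)))
cat(paste(sprintf("  %s (b=%.3f)", sig_soy$variable, sig_soy$coefficient),
          collapse = "\n"), "\n")
cl <- fit$correlation_loadings
for (a in c("roasted", "smoky")) {
  row <- cl[cl$variable == a & cl$block == "attribute", ]
  cat(sprintf("attribute '%s' correlation loadings: (%.2f, %.2f)\n",
              a, row$r1, row$r2))
}
cat("tables written to", out, "\n")
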