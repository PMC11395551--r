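#!/usr/bin/env Rscript
# Stage 2 — identification, quantitation and the key-compound screen.
#
# Reads results/bundle_fixture/, assigns peaks by retention index, applies
# the internal-standard formula Cx = Ax*Cs*Vs/(As*mx), computes rOAV and the
# chemical-class totals, then intersects the rOAV screen with the GC-O
# consensus into the key-compound set. Tables land in results/screen/.

suppressPackageStartupMessages(library(aromakey))
cfg <- aroma_config()
bundle <- read_bundle("results/bundle_fixture")
out <- "results/screen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

peaks <- assign_peaks(bundle$peaks, bundle$library, bundle$ladder,
                      cfg$ri_match_tolerance)
quant <- quantify_table(peaks, bundle$is_spec)
roav_tbl <- roav_table(quant, bundle$library)
classes <- aggregate_classes(quant, bundle$library, "S1")

screen <- screen_roav(roav_tbl, cfg$roav_threshold)
gco <- gco_consensus(bundle$gco, cfg$gco_min_panelists,
                     library = bundle$library, ladder = bundle$ladder)
key <- intersect_key_compounds(screen, gco)
groups <- assign_odor_groups(
  key$members,
  setNames(bundle$library$odor_descriptor, bundle$library$name)[key$members]
)

write.csv(quant, file.path(out, "quantified.csv"), row.names = FALSE)
write.csv(roav_tbl, file.path(out, "roav.csv"), row.names = FALSE)
write.csv(classes, file.path(out, "class_totals.csv"), row.names = FALSE)
write.csv(gco, file.path(out, "gco_consensus.csv"), row.names = FALSE)
write.csv(groups, file.path(out, "odor_groups.csv"), row.names = FALSE)

cat(sprintf("rOAV >= %g pass counts: %s\n", cfg$roav_threshold,
            paste(sprintf("%s=%d", names(screen$counts), screen$counts),
                  collapse = ", ")))
cat(sprintf("cross-sample rOAV intersection: %d compounds\n",
            length(key$roav_intersection)))
cat(sprintf("GC-O consensus set: %d compounds\n", length(key$gco_set)))
cat(sprintf("key compounds (rOAV n GC-O): %d\n", length(key$members)))
cat(paste(" ", key$members, collapse = "\n"), "\n")
tot <- classes[classes$chem_class == "total", ]
cat("grand totals (ug/kg):",
    paste(sprintf("%s=%.0f", tot$sample_id, tot$total_ug_kg), collapse = ", "), "\n")
cat("tables written to", out, "\n")
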