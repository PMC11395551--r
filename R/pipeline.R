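# End-to-end orchestration: quantify -> rOAV -> screen -> HCA -> PCA ->
# OPLS-DA (VIP, permutation, CV-ANOVA) -> PLSR (correlation loadings,
# jack-knife) -> ANOVA-LSD per key compound.

#' Run the full key-aroma analysis pipeline
#'
#' Executes every stage on a dataset bundle and optionally writes each
#' stage's tables as CSV plus a plain-text summary and a run manifest.
#' All randomness (permutation test) is governed by `config$random_seed`;
#' identical (bundle, config) runs are identical.
#'
#' @param bundle a `dataset_bundle` (see [dataset_bundle()], [read_bundle()]).
#' @param config an [aroma_config()].
#' @param out_dir output directory for CSVs, or `NULL` to skip writing.
#' @param reference_sample baseline sample for class percent changes and the
#'   discriminant contrast (default: first sample id in sort order).
#' @return list of class `"aroma_run"` with elements `quant, roav, classes,
#'   screen, gco, key_set, odor_groups, hca_samples, hca_compounds, pca,
#'   opls, vip, permutation, cv_anova, plsr, jackknife, anova_lsd, manifest`.
#' @export
run_pipeline <- function(bundle, config = aroma_config(), out_dir = NULL,
                         reference_sample = NULL) {
  stopifnot(inherits(bundle, "dataset_bundle"), inherits(config, "aroma_config"))
  set.seed(config$random_seed)
  ak_log("INFO", "pipeline start (seed %d, scaling %s)",
         config$random_seed, config$scaling)

  report <- validate_bundle(bundle)
  if (any(report$level == "error")) {
    stop("bundle validation failed: ",
         paste(report$message[report$level == "error"], collapse = "; "),
         call. = FALSE)
  }

  samples <- sort(unique(bundle$peaks$sample_id))
  if (is.null(reference_sample)) reference_sample <- samples[1]

  # -- quantitation -----------------------------------------------------------
  peaks <- assign_peaks(bundle$peaks, bundle$library, bundle$ladder,
                        tolerance = config$ri_match_tolerance)
  quant <- quantify_table(peaks, bundle$is_spec)
  roav_tbl <- roav_table(quant, bundle$library)
  classes <- aggregate_classes(quant, bundle$library, reference_sample)

  # -- screening --------------------------------------------------------------
  screen <- screen_roav(roav_tbl, config$roav_threshold, config$roav_strict)
  gco <- gco_consensus(bundle$gco, config$gco_min_panelists,
                       library = bundle$library, ladder = bundle$ladder,
                       tolerance = config$ri_match_tolerance)
  key_set <- intersect_key_compounds(screen, gco)
  desc_map <- setNames(bundle$library$odor_descriptor, bundle$library$name)
  odor_groups <- assign_odor_groups(key_set$members,
                                    unname(desc_map[key_set$members]))

  # -- class/compound structure -----------------------------------------------
  # heatmap preprocessing: per-compound (row) unit-variance scaling; both
  # dendrograms are computed on the same scaled matrix
  mat <- compound_sample_matrix(quant)
  rs <- apply(mat, 1, sd); rs[rs == 0] <- 1
  mat_scaled <- sweep(sweep(mat, 1, rowMeans(mat)), 1, rs, "/")
  hca_samples <- hca_cluster(t(mat_scaled), k = 2, scale_rows = FALSE)
  hca_compounds <- if (nrow(mat) >= 2) {
    hca_cluster(mat_scaled, k = 2, scale_rows = FALSE)
  } else NULL

  # -- multivariate on the key compounds --------------------------------------
  X <- key_compound_matrix(quant, key_set$members)
  cls <- factor(ifelse(sub("\\..*$", "", rownames(X)) == reference_sample,
                       "reference", "mutant"),
                levels = c("reference", "mutant"))
  Xs <- autoscale(X, config$scaling)
  pca <- pca_fit(Xs, k = min(2, ncol(X)))
  opls <- opls_da_fit(Xs, cls, n_orth = config$n_orth_components,
                      cv_folds = config$cv_folds)
  rownames(opls$W) <- colnames(X)
  vip_scores <- vip(opls)
  perm <- permutation_test(Xs, cls, n = config$n_permutations,
                           n_orth = opls$n_orth, cv_folds = config$cv_folds)
  cva <- cv_anova_opls(opls, Xs)

  # -- PLSR against sensory attributes ----------------------------------------
  Y <- sensory_attribute_matrix(bundle$sensory, rownames(X))
  plsr <- plsr_sensory(X, Y, n_components = 2, scaling = config$scaling)
  jack <- jackknife_significance(plsr, alpha = config$alpha)

  # -- univariate comparison per key compound ---------------------------------
  lsd <- lapply(setNames(key_set$members, key_set$members), function(cmp) {
    rows <- quant[quant$compound_name == cmp, , drop = FALSE]
    anova_lsd(rows$concentration, rows$sample_id, alpha = config$alpha)
  })

  manifest <- list(
    config = unclass(config),
    reference_sample = reference_sample,
    samples = samples,
    n_compounds = length(unique(quant$compound_name)),
    version = as.character(utils::packageVersion("aromakey"))
  )
  src <- attr(bundle, "source_dir")
  if (!is.null(src)) {
    files <- list.files(src, full.names = TRUE)
    manifest$input_md5 <- as.list(tools::md5sum(files))
  }

  run <- structure(
    list(validation = report, quant = quant, roav = roav_tbl, classes = classes,
         screen = screen, gco = gco, key_set = key_set,
         odor_groups = odor_groups,
         hca_samples = hca_samples, hca_compounds = hca_compounds,
         pca = pca, opls = opls, vip = vip_scores, permutation = perm,
         cv_anova = cva, plsr = plsr, jackknife = jack, anova_lsd = lsd,
         manifest = manifest),
    class = "aroma_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir, bundle)
  run
}

#' Replicate-mean compound x sample concentration matrix
#' @param quant quantified table.
#' @return matrix (compounds x samples), ug/g.
#' @export
compound_sample_matrix <- function(quant) {
  agg <- dplyr::summarise(
    dplyr::group_by(quant, .data$compound_name, .data$sample_id),
    Ci = mean(.data$concentration), .groups = "drop"
  )
  samples <- sort(unique(agg$sample_id))
  comps <- sort(unique(agg$compound_name))
  mat <- matrix(0, length(comps), length(samples),
                dimnames = list(comps, samples))
  mat[cbind(match(agg$compound_name, comps), match(agg$sample_id, samples))] <- agg$Ci
  mat
}

#' Observation (sample x replicate) matrix of key-compound concentrations
#' @param quant quantified table.
#' @param compounds compound names for the columns.
#' @return matrix with rownames `sample.replicate`.
#' @export
key_compound_matrix <- function(quant, compounds) {
  rows <- quant[quant$compound_name %in% compounds, , drop = FALSE]
  obs <- sort(unique(paste(rows$sample_id, rows$replicate, sep = ".")))
  mat <- matrix(0, length(obs), length(compounds),
                dimnames = list(obs, sort(compounds)))
  key <- paste(rows$sample_id, rows$replicate, sep = ".")
  mat[cbind(match(key, obs), match(rows$compound_name, colnames(mat)))] <-
    rows$concentration
  mat
}

#' Per-sample mean sensory attribute matrix aligned to observation rows
#' @param sensory sensory score tibble.
#' @param obs_rownames rownames of the observation matrix
#'   (`sample.replicate`).
#' @return matrix (observations x attributes).
#' @export
sensory_attribute_matrix <- function(sensory, obs_rownames) {
  agg <- dplyr::summarise(
    dplyr::group_by(sensory, .data$sample_id, .data$attribute),
    score = mean(.data$score), .groups = "drop"
  )
  samples <- sub("\\..*$", "", obs_rownames)
  attrs <- SENSORY_ATTRIBUTES[SENSORY_ATTRIBUTES %in% unique(agg$attribute)]
  mat <- matrix(NA_real_, length(obs_rownames), length(attrs),
                dimnames = list(obs_rownames, attrs))
  for (a in attrs) {
    sc <- setNames(agg$score[agg$attribute == a], agg$sample_id[agg$attribute == a])
    mat[, a] <- unname(sc[samples])
  }
  if (anyNA(mat)) stop("sensory sheet does not cover every sample", call. = FALSE)
  mat
}

# write every stage's tables + summary + manifest
write_run <- function(run, out_dir, bundle) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  w(run$quant, "quantified.csv")
  w(run$roav, "roav.csv")
  w(run$classes, "class_totals.csv")
  w(run$gco, "gco_consensus.csv")
  venn <- tibble(
    region = c("key", "roav_only", "gco_only"),
    count = unname(run$key_set$venn_counts),
    members = c(paste(run$key_set$members, collapse = ";"),
                paste(run$key_set$roav_only, collapse = ";"),
                paste(run$key_set$gco_only, collapse = ";"))
  )
  w(venn, "venn_regions.csv")
  w(run$odor_groups, "odor_groups.csv")
  w(tibble(compound = names(run$vip), vip = unname(run$vip)), "vip.csv")
  w(run$permutation$permuted, "permutation_scatter.csv")
  w(run$plsr$correlation_loadings, "correlation_loadings.csv")
  w(run$jackknife, "jackknife.csv")
  letters_tbl <- dplyr::bind_rows(lapply(names(run$anova_lsd), function(cmp) {
    lt <- run$anova_lsd[[cmp]]$letters
    tibble(compound = cmp, sample = names(lt), letter = unname(lt),
           mean = as.numeric(run$anova_lsd[[cmp]]$means[names(lt)]))
  }))
  w(letters_tbl, "lsd_letters.csv")
  writeLines(run$hca_samples$newick, file.path(out_dir, "hca_samples.nwk"))
  if (!is.null(run$hca_compounds)) {
    writeLines(run$hca_compounds$newick, file.path(out_dir, "hca_compounds.nwk"))
  }

  summary_lines <- c(
    "aromakey pipeline summary",
    sprintf("samples: %s", paste(run$manifest$samples, collapse = ", ")),
    sprintf("compounds quantified: %d  [quantified.csv]", run$manifest$n_compounds),
    sprintf("rOAV pass counts: %s  [roav.csv]",
            paste(sprintf("%s=%d", names(run$screen$counts), run$screen$counts),
                  collapse = ", ")),
    sprintf("rOAV cross-sample intersection: %d  [venn_regions.csv]",
            length(run$key_set$roav_intersection)),
    sprintf("GC-O consensus set: %d  [gco_consensus.csv]",
            length(run$key_set$gco_set)),
    sprintf("key compounds: %d (%s)  [venn_regions.csv]",
            length(run$key_set$members),
            paste(run$key_set$members, collapse = ", ")),
    sprintf("OPLS-DA: R2X=%.3f R2Y=%.3f Q2=%.3f (orth=%d)  [vip.csv]",
            run$opls$R2X, run$opls$R2Y, run$opls$Q2, run$opls$n_orth),
    sprintf("permutation test: p=%.4g (n=%d)  [permutation_scatter.csv]",
            run$permutation$p_value, run$permutation$n),
    sprintf("CV-ANOVA: F=%.3f (df %d,%d) p=%.4g",
            run$cv_anova$F, run$cv_anova$df1, run$cv_anova$df2,
            run$cv_anova$p_value),
    sprintf("PLSR: R2X=%.3f R2Y=%.3f  [correlation_loadings.csv]",
            run$plsr$explained_x, run$plsr$explained_y)
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  yaml::write_yaml(run$manifest, file.path(out_dir, "manifest.yml"))
  invisible(out_dir)
}

#' @export
print.aroma_run <- function(x, ...) {
  cat("<aroma_run>\n")
  cat(sprintf("  key compounds: %d of %d rOAV-intersection / %d GC-O\n",
              length(x$key_set$members), length(x$key_set$roav_intersection),
              length(x$key_set$gco_set)))
  cat(sprintf("  OPLS-DA R2Y=%.3f Q2=%.3f, permutation p=%.4g, CV-ANOVA F=%.2f\n",
              x$opls$R2Y, x$opls$Q2, x$permutation$p_value, x$cv_anova$F))
  invisible(x)
}
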