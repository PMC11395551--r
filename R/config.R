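#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline in one validated object.
#' All stage functions take the relevant scalar directly; the config exists so
#' a whole run is reproducible from a single record (see [run_pipeline()]).
#'
#' @param roav_threshold rOAV cut-off for the aroma-activity screen; a compound
#'   with rOAV at or above this value in a sample counts as a significant
#'   contributor there. Dimensionless, default 1.
#' @param roav_strict logical; if `TRUE` the screen uses a strict `>` instead
#'   of the default inclusive `>=` comparison.
#' @param gco_min_panelists minimum number of distinct panelists that must
#'   report a compound (in any replicate sniffing session) for GC-O consensus.
#' @param gco_panel_size size of the sniffing panel.
#' @param ri_match_tolerance maximum |observed RI - reference RI| for a library
#'   match, in retention-index units.
#' @param cv_folds folds for venetian-blind cross-validation of latent models.
#' @param n_permutations label permutations for supervised-model validation.
#' @param n_orth_components orthogonal components for OPLS-DA: a non-negative
#'   integer, or `"auto"` to add components while cross-validated Q2 improves
#'   (capped at 3).
#' @param scaling column scaling for latent models: `"unit_variance"`,
#'   `"pareto"` or `"center_only"`.
#' @param alpha two-sided significance level for univariate tests and the
#'   jack-knife coefficient test.
#' @param random_seed integer seed governing every stochastic step of a run.
#'
#' @return A list of class `"aroma_config"`.
#' @export
aroma_config <- function(roav_threshold = 1.0,
                         roav_strict = FALSE,
                         gco_min_panelists = 2L,
                         gco_panel_size = 3L,
                         ri_match_tolerance = 15,
                         cv_folds = 7L,
                         n_permutations = 200L,
                         n_orth_components = "auto",
                         scaling = c("unit_variance", "pareto", "center_only"),
                         alpha = 0.05,
                         random_seed = 1L) {
  scaling <- match.arg(scaling)
  stopifnot(
    roav_threshold > 0, ri_match_tolerance > 0,
    gco_min_panelists >= 1, gco_min_panelists <= gco_panel_size,
    cv_folds >= 2, n_permutations >= 1,
    alpha > 0, alpha < 1
  )
  if (!identical(n_orth_components, "auto")) {
    stopifnot(is.numeric(n_orth_components), n_orth_components >= 0)
    n_orth_components <- as.integer(n_orth_components)
  }
  structure(
    list(
      roav_threshold = roav_threshold,
      roav_strict = roav_strict,
      gco_min_panelists = as.integer(gco_min_panelists),
      gco_panel_size = as.integer(gco_panel_size),
      ri_match_tolerance = ri_match_tolerance,
      cv_folds = as.integer(cv_folds),
      n_permutations = as.integer(n_permutations),
      n_orth_components = n_orth_components,
      scaling = scaling,
      alpha = alpha,
      random_seed = as.integer(random_seed)
    ),
    class = "aroma_config"
  )
}

#' Read a configuration file
#'
#' The file is a flat YAML mapping whose keys mirror the arguments of
#' [aroma_config()]; unknown keys are an error so typos cannot silently
#' fall back to defaults.
#'
#' @param path path to a YAML file.
#' @return An `aroma_config` object.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(aroma_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(aroma_config, raw)
}

#' Write a configuration file
#'
#' @param config an `aroma_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "aroma_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.aroma_config <- function(x, ...) {
  cat("<aroma_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Structured logging to stderr.  Levels: DEBUG < INFO < WARN.
ak_log <- function(level = c("INFO", "WARN", "DEBUG"), fmt, ...) {
  level <- match.arg(level)
  opt <- getOption("aromakey.log_level", "INFO")
  rank <- c(DEBUG = 1L, INFO = 2L, WARN = 3L)
  if (rank[[level]] < rank[[opt]]) return(invisible(NULL))
  message(sprintf("[aromakey %s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}
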