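#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd var cor setNames
NULL

# Closed vocabularies ---------------------------------------------------------

#' Chemical classes recognised by the compound library
#' @export
CHEM_CLASSES <- c(
  "pyrazine", "ketone", "acid", "alcohol", "aldehyde", "phenol",
  "ester", "furan", "oxazole", "sulfide", "other"
)

#' Sensory attributes of the QDA sheet
#' @export
SENSORY_ATTRIBUTES <- c(
  "soy_sauce_like", "roasted", "smoky", "sweet", "buttery", "grain"
)

#' Normalize a compound name
#'
#' Compound names are matched case-insensitively after trimming and collapsing
#' internal whitespace, so "Guaiacol " and "guaiacol" are the same compound.
#'
#' @param x character vector of names.
#' @return normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# CSV plumbing ----------------------------------------------------------------

read_csv_checked <- function(path, required, label) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", label, path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "%s file %s is missing required column(s): %s",
      label, path, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  df
}

# data line number in the file = data row index + header line
line_of <- function(i) i + 1L

# Peak tables -----------------------------------------------------------------

#' Read a per-sample peak table
#'
#' Expects a UTF-8 CSV with header columns `sample_id, replicate, peak_id,
#' retention_time, area` and optionally `assigned_compound`. Every row is
#' validated; failures carry the file line number.
#'
#' @param path CSV path.
#' @return A tibble of peak records.
#' @export
read_peak_table <- function(path) {
  df <- read_csv_checked(
    path,
    c("sample_id", "replicate", "peak_id", "retention_time", "area"),
    "peak table"
  )
  if (!"assigned_compound" %in% names(df)) {
    df$assigned_compound <- rep(NA_character_, nrow(df))
  }
  out <- tibble(
    sample_id = as.character(df$sample_id),
    replicate = suppressWarnings(as.integer(df$replicate)),
    peak_id = as.character(df$peak_id),
    retention_time = suppressWarnings(as.numeric(df$retention_time)),
    area = suppressWarnings(as.numeric(df$area)),
    assigned_compound = ifelse(
      is.na(df$assigned_compound) | df$assigned_compound == "",
      NA_character_, normalize_name(df$assigned_compound)
    )
  )
  validate_peaks(out, path = path)
  out
}

validate_peaks <- function(peaks, path = "<in-memory>") {
  bad <- which(is.na(peaks$replicate) | peaks$replicate < 1)
  if (length(bad) > 0) {
    stop(sprintf("peak table %s: invalid replicate on line %d",
                 path, line_of(bad[1])), call. = FALSE)
  }
  bad <- which(is.na(peaks$retention_time) | peaks$retention_time < 0)
  if (length(bad) > 0) {
    stop(sprintf("peak table %s: invalid retention_time on line %d",
                 path, line_of(bad[1])), call. = FALSE)
  }
  bad <- which(is.na(peaks$area) | peaks$area < 0)
  if (length(bad) > 0) {
    stop(sprintf("peak table %s: negative or non-numeric area on line %d",
                 path, line_of(bad[1])), call. = FALSE)
  }
  key <- paste(peaks$sample_id, peaks$replicate, peaks$peak_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf(
      "peak table %s: duplicate (sample_id, replicate, peak_id) on line %d",
      path, line_of(dup[1])
    ), call. = FALSE)
  }
  invisible(peaks)
}

# Compound library ------------------------------------------------------------

#' Read a compound library
#'
#' Columns: `name, chem_class, ref_ri, odor_threshold, odor_descriptor`,
#' optionally `alias` (semicolon-separated synonyms resolved onto `name`).
#' `odor_threshold` is the odor threshold in water, ug/kg; empty when unknown.
#'
#' @param path CSV path.
#' @return A tibble with one row per compound plus an `aliases` list-column.
#' @export
read_library <- function(path) {
  df <- read_csv_checked(
    path, c("name", "chem_class", "ref_ri", "odor_threshold", "odor_descriptor"),
    "compound library"
  )
  if (!"alias" %in% names(df)) df$alias <- rep("", nrow(df))
  df$alias <- as.character(df$alias)
  df$alias[is.na(df$alias)] <- ""
  out <- tibble(
    name = normalize_name(df$name),
    chem_class = tolower(trimws(df$chem_class)),
    ref_ri = suppressWarnings(as.numeric(df$ref_ri)),
    odor_threshold = suppressWarnings(as.numeric(df$odor_threshold)),
    odor_descriptor = as.character(df$odor_descriptor),
    aliases = lapply(df$alias, function(a) {
      a <- strsplit(as.character(a), ";", fixed = TRUE)[[1]]
      normalize_name(a[nzchar(trimws(a))])
    })
  )
  validate_library(out, path = path)
  out
}

validate_library <- function(lib, path = "<in-memory>") {
  dup <- which(duplicated(lib$name))
  if (length(dup) > 0) {
    stop(sprintf("compound library %s: duplicate name '%s' on line %d",
                 path, lib$name[dup[1]], line_of(dup[1])), call. = FALSE)
  }
  bad <- which(!lib$chem_class %in% CHEM_CLASSES)
  if (length(bad) > 0) {
    stop(sprintf("compound library %s: unknown chem_class '%s' on line %d",
                 path, lib$chem_class[bad[1]], line_of(bad[1])), call. = FALSE)
  }
  bad <- which(!is.na(lib$odor_threshold) & lib$odor_threshold <= 0)
  if (length(bad) > 0) {
    stop(sprintf("compound library %s: non-positive odor_threshold on line %d",
                 path, line_of(bad[1])), call. = FALSE)
  }
  invisible(lib)
}

#' Resolve a compound name or alias against a library
#'
#' @param x character vector of (possibly alias) names.
#' @param library a compound library tibble.
#' @return canonical names; `NA` where unresolvable.
#' @export
resolve_name <- function(x, library) {
  x <- normalize_name(x)
  amap <- list()
  if ("aliases" %in% names(library)) {
    for (i in seq_len(nrow(library))) {
      for (a in library$aliases[[i]]) amap[[a]] <- library$name[i]
    }
  }
  vapply(x, function(nm) {
    if (nm %in% library$name) return(nm)
    if (!is.null(amap[[nm]])) return(amap[[nm]])
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Alkane ladder ---------------------------------------------------------------

#' Read an n-alkane ladder
#'
#' Columns `carbon_number, retention_time`; both must be strictly increasing
#' and at least two alkanes are required to define a retention-index scale.
#'
#' @param path CSV path.
#' @return A tibble of class `"alkane_ladder"`.
#' @export
read_ladder <- function(path) {
  df <- read_csv_checked(path, c("carbon_number", "retention_time"), "alkane ladder")
  out <- tibble(
    carbon_number = suppressWarnings(as.integer(df$carbon_number)),
    retention_time = suppressWarnings(as.numeric(df$retention_time))
  )
  validate_ladder(out, path = path)
  out
}

#' Construct/validate an alkane ladder from vectors
#' @param carbon_number integer carbon numbers.
#' @param retention_time retention times, minutes.
#' @return ladder tibble.
#' @export
alkane_ladder <- function(carbon_number, retention_time) {
  out <- tibble(
    carbon_number = as.integer(carbon_number),
    retention_time = as.numeric(retention_time)
  )
  validate_ladder(out)
  out
}

validate_ladder <- function(ladder, path = "<in-memory>") {
  if (nrow(ladder) < 2) {
    stop(sprintf("alkane ladder %s: need at least 2 alkanes", path), call. = FALSE)
  }
  if (any(is.na(ladder$carbon_number)) || any(is.na(ladder$retention_time))) {
    stop(sprintf("alkane ladder %s: non-numeric entries", path), call. = FALSE)
  }
  if (any(diff(ladder$carbon_number) <= 0)) {
    stop(sprintf("alkane ladder %s: carbon numbers must be strictly increasing", path),
         call. = FALSE)
  }
  if (any(diff(ladder$retention_time) <= 0)) {
    stop(sprintf("alkane ladder %s: retention times must be strictly increasing", path),
         call. = FALSE)
  }
  invisible(ladder)
}

# Internal standard -----------------------------------------------------------

#' Internal-standard specification
#'
#' Describes the quantitation spike: `Cs` the spike concentration (ug/mL),
#' `Vs` the spiked volume (mL) and `mx` the sample mass (g). The defaults are
#' the conventional 5 uL of 180 ug/mL sec-octanol added to a 3 g sample.
#'
#' @param compound_name name of the internal standard compound.
#' @param Cs spike concentration, ug/mL.
#' @param Vs spike volume, mL.
#' @param mx sample mass, g.
#' @return list of class `"internal_standard"`.
#' @export
internal_standard <- function(compound_name = "sec-octanol",
                              Cs = 180, Vs = 0.005, mx = 3) {
  stopifnot(Cs > 0, Vs > 0, mx > 0)
  structure(
    list(compound_name = normalize_name(compound_name), Cs = Cs, Vs = Vs, mx = mx),
    class = "internal_standard"
  )
}

# GC-O events -----------------------------------------------------------------

#' Read a GC-O event log
#'
#' Columns: `sample_id, replicate, panelist, compound, retention_time,
#' intensity, descriptor`. Each event names the odor either by library
#' compound (preferred) or by retention time; intensity is an integer 1..5.
#'
#' @param path CSV path.
#' @return tibble of GC-O events.
#' @export
read_gco <- function(path) {
  df <- read_csv_checked(
    path, c("sample_id", "replicate", "panelist", "intensity"), "GC-O log"
  )
  if (!"compound" %in% names(df)) df$compound <- rep(NA_character_, nrow(df))
  if (!"retention_time" %in% names(df)) df$retention_time <- rep(NA_real_, nrow(df))
  if (!"descriptor" %in% names(df)) df$descriptor <- rep("", nrow(df))
  df$descriptor <- as.character(df$descriptor)
  df$descriptor[is.na(df$descriptor)] <- ""
  out <- tibble(
    sample_id = as.character(df$sample_id),
    replicate = suppressWarnings(as.integer(df$replicate)),
    panelist = as.character(df$panelist),
    compound = ifelse(is.na(df$compound) | df$compound == "",
                      NA_character_, normalize_name(df$compound)),
    retention_time = suppressWarnings(as.numeric(df$retention_time)),
    intensity = suppressWarnings(as.integer(df$intensity)),
    descriptor = as.character(df$descriptor)
  )
  validate_gco(out, path = path)
  out
}

validate_gco <- function(gco, path = "<in-memory>") {
  bad <- which(is.na(gco$intensity) | !gco$intensity %in% 1:5)
  if (length(bad) > 0) {
    stop(sprintf("GC-O log %s: intensity outside 1..5 on line %d",
                 path, line_of(bad[1])), call. = FALSE)
  }
  bad <- which(is.na(gco$compound) & is.na(gco$retention_time))
  if (length(bad) > 0) {
    stop(sprintf("GC-O log %s: event with neither compound nor retention_time on line %d",
                 path, line_of(bad[1])), call. = FALSE)
  }
  invisible(gco)
}

# Sensory scores --------------------------------------------------------------

#' Read a QDA sensory score sheet
#'
#' Columns: `sample_id, panelist, session, attribute, score`; attributes from
#' the six-attribute vocabulary, scores integer 1..5.
#'
#' @param path CSV path.
#' @return tibble of sensory scores.
#' @export
read_sensory <- function(path) {
  df <- read_csv_checked(
    path, c("sample_id", "panelist", "session", "attribute", "score"),
    "sensory sheet"
  )
  out <- tibble(
    sample_id = as.character(df$sample_id),
    panelist = as.character(df$panelist),
    session = suppressWarnings(as.integer(df$session)),
    attribute = tolower(trimws(df$attribute)),
    score = suppressWarnings(as.integer(df$score))
  )
  validate_sensory(out, path = path)
  out
}

validate_sensory <- function(sensory, path = "<in-memory>") {
  bad <- which(!sensory$attribute %in% SENSORY_ATTRIBUTES)
  if (length(bad) > 0) {
    stop(sprintf("sensory sheet %s: unknown attribute '%s' on line %d",
                 path, sensory$attribute[bad[1]], line_of(bad[1])), call. = FALSE)
  }
  bad <- which(is.na(sensory$score) | !sensory$score %in% 1:5)
  if (length(bad) > 0) {
    stop(sprintf("sensory sheet %s: score outside 1..5 on line %d",
                 path, line_of(bad[1])), call. = FALSE)
  }
  invisible(sensory)
}

# Bundle ----------------------------------------------------------------------

#' Assemble a dataset bundle
#'
#' A bundle is the complete input of one study: peak tables, alkane ladder,
#' compound library, internal-standard spec, GC-O events and sensory scores.
#'
#' @param peaks,library,ladder,is_spec,gco,sensory the component tables.
#' @return list of class `"dataset_bundle"`.
#' @export
dataset_bundle <- function(peaks, library, ladder, is_spec, gco, sensory) {
  validate_peaks(peaks)
  validate_library(library)
  validate_ladder(ladder)
  stopifnot(inherits(is_spec, "internal_standard"))
  validate_gco(gco)
  validate_sensory(sensory)
  structure(
    list(peaks = peaks, library = library, ladder = ladder,
         is_spec = is_spec, gco = gco, sensory = sensory),
    class = "dataset_bundle"
  )
}

#' Cross-reference validation of a dataset bundle
#'
#' Pure report-only check: returns a tibble of issues (empty when the bundle
#' is fully cross-consistent). `error`-level issues are assignments to
#' compounds absent from the library; `warning`-level issues are coverage
#' gaps (samples missing from the sensory or GC-O sheets).
#'
#' @param peaks,library,ladder,is_spec,gco,sensory bundle components (or pass
#'   a `dataset_bundle` as the single first argument).
#' @return tibble with columns `level, table, message`.
#' @export
validate_bundle <- function(peaks, library = NULL, ladder = NULL,
                            is_spec = NULL, gco = NULL, sensory = NULL) {
  if (inherits(peaks, "dataset_bundle")) {
    b <- peaks
    peaks <- b$peaks; library <- b$library; ladder <- b$ladder
    is_spec <- b$is_spec; gco <- b$gco; sensory <- b$sensory
  }
  issues <- list()
  add <- function(level, table, message) {
    issues[[length(issues) + 1L]] <<- tibble(
      level = level, table = table, message = message
    )
  }

  assigned <- unique(peaks$assigned_compound)
  assigned <- assigned[!is.na(assigned)]
  known <- c(library$name, is_spec$compound_name)
  for (nm in setdiff(assigned, known)) {
    if (is.na(resolve_name(nm, library))) {
      add("error", "peaks", sprintf("assigned compound '%s' absent from library", nm))
    }
  }

  gco_named <- unique(gco$compound[!is.na(gco$compound)])
  for (nm in setdiff(gco_named, library$name)) {
    if (is.na(resolve_name(nm, library))) {
      add("error", "gco", sprintf("GC-O compound '%s' absent from library", nm))
    }
  }

  samples <- unique(peaks$sample_id)
  for (s in setdiff(samples, unique(sensory$sample_id))) {
    add("warning", "sensory", sprintf("sample '%s' has no sensory scores", s))
  }
  for (s in setdiff(samples, unique(gco$sample_id))) {
    add("warning", "gco", sprintf("sample '%s' has no GC-O events", s))
  }
  for (s in setdiff(unique(sensory$sample_id), samples)) {
    add("warning", "sensory", sprintf("sensory sample '%s' has no peak data", s))
  }

  if (length(issues) == 0) {
    return(tibble(level = character(), table = character(), message = character()))
  }
  dplyr::bind_rows(issues)
}

#' Write a dataset bundle as a directory of CSV files
#'
#' Writes `peaks.csv, library.csv, ladder.csv, gco.csv, sensory.csv` and
#' `internal_standard.yml` under `dir`. [read_bundle()] round-trips it.
#'
#' @param bundle a `dataset_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- bundle$library
  lib$alias <- vapply(lib$aliases, paste, character(1), collapse = ";")
  lib$aliases <- NULL
  utils::write.csv(bundle$peaks, file.path(dir, "peaks.csv"), row.names = FALSE)
  utils::write.csv(lib, file.path(dir, "library.csv"), row.names = FALSE)
  utils::write.csv(bundle$ladder, file.path(dir, "ladder.csv"), row.names = FALSE)
  utils::write.csv(bundle$gco, file.path(dir, "gco.csv"), row.names = FALSE)
  utils::write.csv(bundle$sensory, file.path(dir, "sensory.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(bundle$is_spec), file.path(dir, "internal_standard.yml"))
  invisible(dir)
}

#' Read a dataset bundle directory written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return a `dataset_bundle`.
#' @export
read_bundle <- function(dir) {
  is_raw <- yaml::read_yaml(file.path(dir, "internal_standard.yml"))
  b <- dataset_bundle(
    peaks = read_peak_table(file.path(dir, "peaks.csv")),
    library = read_library(file.path(dir, "library.csv")),
    ladder = read_ladder(file.path(dir, "ladder.csv")),
    is_spec = internal_standard(is_raw$compound_name, is_raw$Cs, is_raw$Vs, is_raw$mx),
    gco = read_gco(file.path(dir, "gco.csv")),
    sensory = read_sensory(file.path(dir, "sensory.csv"))
  )
  attr(b, "source_dir") <- dir
  b
}
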