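# Retention-index identification and internal-standard semi-quantitation.

#' Retention index on an n-alkane ladder
#'
#' Temperature-programmed (van den Dool-Kratz) linear retention index:
#' RI = 100 * (n + (rt - rt_n) / (rt_{n+1} - rt_n)) between the bracketing
#' alkanes with carbon numbers n and n+1. Retention times outside the ladder
#' span are extrapolated on the nearest segment's slope and flagged.
#'
#' @param rt retention time(s), minutes.
#' @param ladder alkane ladder tibble (see [alkane_ladder()]).
#' @param quiet suppress the extrapolation warning log.
#' @return tibble with columns `rt, ri, extrapolated`.
#' @export
compute_retention_index <- function(rt, ladder, quiet = FALSE) {
  validate_ladder(ladder)
  cn <- ladder$carbon_number
  lrt <- ladder$retention_time
  n_seg <- length(cn) - 1L
  seg <- findInterval(rt, lrt, rightmost.closed = FALSE, all.inside = TRUE)
  seg <- pmin(pmax(seg, 1L), n_seg)
  # carbon numbers need not be consecutive; interpolate on the actual span
  ri <- 100 * (cn[seg] +
    (cn[seg + 1L] - cn[seg]) * (rt - lrt[seg]) / (lrt[seg + 1L] - lrt[seg]))
  extrap <- rt < lrt[1L] | rt > lrt[length(lrt)]
  if (any(extrap) && !quiet) {
    ak_log("WARN", "%d retention time(s) outside the alkane ladder span; RI extrapolated",
           sum(extrap))
  }
  tibble(rt = rt, ri = ri, extrapolated = extrap)
}

#' Match a retention index against a compound library
#'
#' Returns the library entries whose reference RI lies within `tolerance`
#' of the observed RI, ranked by |delta RI| with lexicographic name order as
#' the deterministic tie-break.
#'
#' @param ri observed retention index (scalar).
#' @param library compound library tibble.
#' @param tolerance maximum |ref_ri - ri|, RI units.
#' @return tibble of candidates with a `delta_ri` column (possibly 0 rows).
#' @export
match_library <- function(ri, library, tolerance = 15) {
  stopifnot(tolerance > 0, length(ri) == 1)
  cand <- library[!is.na(library$ref_ri), , drop = FALSE]
  delta <- abs(cand$ref_ri - ri)
  keep <- delta <= tolerance
  cand <- cand[keep, , drop = FALSE]
  cand$delta_ri <- delta[keep]
  cand[order(cand$delta_ri, cand$name), , drop = FALSE]
}

#' Assign peaks to library compounds by retention index
#'
#' Peaks already carrying an `assigned_compound` keep it (after alias
#' resolution); the rest are assigned to the best RI match within tolerance,
#' or left unassigned with a log entry.
#'
#' @param peaks peak tibble.
#' @param library compound library.
#' @param ladder alkane ladder.
#' @param tolerance RI match tolerance.
#' @return `peaks` with `assigned_compound` filled and an `ri` column added.
#' @export
assign_peaks <- function(peaks, library, ladder, tolerance = 15) {
  ri <- compute_retention_index(peaks$retention_time, ladder, quiet = TRUE)
  out <- peaks
  out$ri <- ri$ri
  # pre-assigned names resolve onto canonical library names where possible;
  # names outside the library (e.g. the internal standard) are kept verbatim
  pre <- !is.na(out$assigned_compound)
  resolved <- resolve_name(out$assigned_compound[pre], library)
  out$assigned_compound[pre] <- ifelse(
    is.na(resolved), normalize_name(out$assigned_compound[pre]), resolved
  )
  todo <- which(!pre)
  for (i in todo) {
    cand <- match_library(out$ri[i], library, tolerance)
    out$assigned_compound[i] <- if (nrow(cand) > 0) cand$name[1] else NA_character_
  }
  n_un <- sum(is.na(out$assigned_compound))
  if (n_un > 0) {
    ak_log("WARN", "%d peak(s) could not be assigned to a library compound", n_un)
  }
  out
}

#' Internal-standard quantitation of one peak
#'
#' Semi-quantitation against a co-injected internal standard:
#' Cx = Ax * Cs * Vs / (As * mx), giving ug of analyte per g of sample, where
#' Ax and As are the analyte and internal-standard peak areas, Cs (ug/mL) and
#' Vs (mL) describe the spike and mx (g) is the sample mass.
#'
#' @param peak a 1-row peak tibble (or list with `area`).
#' @param is_area internal-standard peak area in the same run (> 0).
#' @param is_spec an [internal_standard()] spec.
#' @return concentration in ug/g.
#' @export
quantify_peak <- function(peak, is_area, is_spec) {
  if (is.na(is_area) || is_area <= 0) {
    stop(sprintf("internal standard area must be > 0 (got %s) for sample %s replicate %s",
                 format(is_area), peak$sample_id, peak$replicate), call. = FALSE)
  }
  peak$area * is_spec$Cs * is_spec$Vs / (is_area * is_spec$mx)
}

#' Quantify a full peak table
#'
#' Looks up the internal-standard peak within each (sample, replicate) run,
#' applies [quantify_peak()] to every other assigned peak, and drops the
#' internal standard itself from the compound table.
#'
#' @param peaks assigned peak tibble (see [assign_peaks()]).
#' @param is_spec internal-standard spec.
#' @return tibble `sample_id, replicate, compound_name, Ax, As, concentration`
#'   (ug/g).
#' @export
quantify_table <- function(peaks, is_spec) {
  is_name <- is_spec$compound_name
  runs <- unique(peaks[, c("sample_id", "replicate")])
  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    run <- peaks[peaks$sample_id == runs$sample_id[i] &
                   peaks$replicate == runs$replicate[i], , drop = FALSE]
    is_rows <- which(!is.na(run$assigned_compound) & run$assigned_compound == is_name)
    if (length(is_rows) == 0) {
      stop(sprintf("no internal-standard peak ('%s') in sample %s replicate %d",
                   is_name, runs$sample_id[i], runs$replicate[i]), call. = FALSE)
    }
    As <- sum(run$area[is_rows])
    analyte <- run[setdiff(seq_len(nrow(run)), is_rows), , drop = FALSE]
    analyte <- analyte[!is.na(analyte$assigned_compound), , drop = FALSE]
    out[[i]] <- tibble(
      sample_id = analyte$sample_id,
      replicate = analyte$replicate,
      compound_name = analyte$assigned_compound,
      Ax = analyte$area,
      As = As,
      concentration = analyte$area * is_spec$Cs * is_spec$Vs / (As * is_spec$mx)
    )
  }
  dplyr::bind_rows(out)
}

#' Relative odor activity value
#'
#' rOAV = Ci / OTi with Ci the compound's concentration and OTi its odor
#' threshold in water. Ci arrives in ug/g and thresholds in ug/kg, so Ci is
#' converted (x 1000) before the ratio. A missing threshold yields `NA`
#' (undefined), never zero: such compounds are excluded from the rOAV screen
#' but can still be rescued by GC-O.
#'
#' @param Ci concentration(s), ug/g.
#' @param OTi odor threshold(s), ug/kg in water; `NA` when unknown.
#' @return dimensionless rOAV, `NA` where the threshold is missing.
#' @export
roav <- function(Ci, OTi) {
  stopifnot(all(Ci >= 0, na.rm = TRUE))
  if (any(!is.na(OTi) & OTi <= 0)) {
    stop("odor thresholds must be strictly positive", call. = FALSE)
  }
  ifelse(is.na(OTi), NA_real_, (Ci * 1000) / OTi)
}

#' Per-sample rOAV table
#'
#' Ci is the replicate mean concentration within each sample group (one rOAV
#' per compound per sample, as screening convention dictates).
#'
#' @param quant quantified table from [quantify_table()].
#' @param library compound library (supplies odor thresholds).
#' @return tibble `sample_id, compound_name, Ci, OTi, roav`.
#' @export
roav_table <- function(quant, library) {
  agg <- dplyr::summarise(
    dplyr::group_by(quant, .data$sample_id, .data$compound_name),
    Ci = mean(.data$concentration), .groups = "drop"
  )
  ot <- setNames(library$odor_threshold, library$name)
  agg$OTi <- unname(ot[agg$compound_name])
  n_missing <- sum(is.na(agg$OTi))
  if (n_missing > 0) {
    ak_log("INFO", "%d compound-sample rows lack an odor threshold; rOAV undefined there",
           n_missing)
  }
  agg$roav <- roav(agg$Ci, agg$OTi)
  agg
}

#' Chemical-class totals and percent change versus a reference sample
#'
#' Replicate-averaged concentrations are summed within each chemical class
#' per sample and reported in ug/kg, alongside the signed percent change
#' against the reference sample. A `total` pseudo-class carries the grand
#' total per sample.
#'
#' @param quant quantified table (ug/g).
#' @param library compound library (supplies classes).
#' @param reference_sample sample id used as the change baseline.
#' @return tibble `sample_id, chem_class, total_ug_kg, pct_change_vs_reference`.
#' @export
aggregate_classes <- function(quant, library, reference_sample) {
  if (!reference_sample %in% quant$sample_id) {
    stop(sprintf("reference sample '%s' absent from the quantified table",
                 reference_sample), call. = FALSE)
  }
  cls <- setNames(library$chem_class, library$name)
  unknown <- setdiff(unique(quant$compound_name), names(cls))
  if (length(unknown) > 0) {
    stop("quantified compounds missing from the library: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  per_comp <- dplyr::summarise(
    dplyr::group_by(quant, .data$sample_id, .data$compound_name),
    Ci = mean(.data$concentration), .groups = "drop"
  )
  per_comp$chem_class <- unname(cls[per_comp$compound_name])

  per_class <- dplyr::summarise(
    dplyr::group_by(per_comp, .data$sample_id, .data$chem_class),
    total_ug_kg = sum(.data$Ci) * 1000, .groups = "drop"
  )
  grand <- dplyr::summarise(
    dplyr::group_by(per_comp, .data$sample_id),
    total_ug_kg = sum(.data$Ci) * 1000, .groups = "drop"
  )
  grand$chem_class <- "total"
  out <- dplyr::bind_rows(per_class, grand[, names(per_class)])

  # complete missing (sample, class) cells with zero totals
  full <- expand.grid(
    sample_id = unique(out$sample_id),
    chem_class = unique(out$chem_class),
    stringsAsFactors = FALSE
  )
  out <- dplyr::left_join(as_tibble(full), out, by = c("sample_id", "chem_class"))
  out$total_ug_kg[is.na(out$total_ug_kg)] <- 0

  ref <- out[out$sample_id == reference_sample, c("chem_class", "total_ug_kg")]
  ref_map <- setNames(ref$total_ug_kg, ref$chem_class)
  ref_tot <- unname(ref_map[out$chem_class])
  out$pct_change_vs_reference <- ifelse(
    ref_tot > 0, 100 * (out$total_ug_kg - ref_tot) / ref_tot,
    ifelse(out$total_ug_kg == 0, 0, Inf)
  )
  out[order(out$sample_id, out$chem_class), , drop = FALSE]
}
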