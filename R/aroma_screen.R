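# rOAV / GC-O key-compound screening.

#' GC-O consensus detection
#'
#' A compound counts as consensus-detected in a sample when at least
#' `min_panelists` distinct panelists report it in any replicate sniffing
#' session. `mean_intensity` averages every report made by the detecting
#' panelists across replicates. Events logged by retention time only are
#' resolved to compounds with [match_library()] before pooling.
#'
#' @param events GC-O event tibble (see [read_gco()]).
#' @param min_panelists consensus rule; conventional panels use >= 2 of 3.
#' @param library optional compound library, needed when any event is logged
#'   by retention time.
#' @param ladder optional alkane ladder for retention-time resolution.
#' @param tolerance RI tolerance for retention-time resolution.
#' @return tibble `sample_id, compound_name, n_panelists_detecting,
#'   mean_intensity, consensus, descriptor`.
#' @export
gco_consensus <- function(events, min_panelists = 2L,
                          library = NULL, ladder = NULL, tolerance = 15) {
  ev <- events
  by_rt <- is.na(ev$compound)
  if (any(by_rt)) {
    if (is.null(library) || is.null(ladder)) {
      stop("GC-O events logged by retention time need a library and ladder",
           call. = FALSE)
    }
    ri <- compute_retention_index(ev$retention_time[by_rt], ladder, quiet = TRUE)$ri
    resolved <- vapply(ri, function(r) {
      cand <- match_library(r, library, tolerance)
      if (nrow(cand) > 0) cand$name[1] else NA_character_
    }, character(1))
    ev$compound[by_rt] <- resolved
    if (anyNA(resolved)) {
      ak_log("WARN", "%d GC-O event(s) could not be resolved to a compound",
             sum(is.na(resolved)))
    }
    ev <- ev[!is.na(ev$compound), , drop = FALSE]
  }
  if (nrow(ev) == 0) {
    return(tibble(
      sample_id = character(), compound_name = character(),
      n_panelists_detecting = integer(), mean_intensity = numeric(),
      consensus = logical(), descriptor = character()
    ))
  }
  out <- dplyr::summarise(
    dplyr::group_by(ev, .data$sample_id, compound_name = .data$compound),
    n_panelists_detecting = dplyr::n_distinct(.data$panelist),
    mean_intensity = mean(.data$intensity),
    descriptor = paste(sort(unique(.data$descriptor[nzchar(.data$descriptor)])),
                       collapse = "; "),
    .groups = "drop"
  )
  out$consensus <- out$n_panelists_detecting >= min_panelists
  out <- out[order(out$sample_id, out$compound_name), , drop = FALSE]
  out[, c("sample_id", "compound_name", "n_panelists_detecting",
          "mean_intensity", "consensus", "descriptor")]
}

#' rOAV screening
#'
#' Per sample, the set of compounds whose rOAV is defined and at or above the
#' threshold (inclusive by default), plus the cross-sample intersection.
#'
#' @param roav_tbl rOAV table from [roav_table()].
#' @param threshold rOAV cut-off (> 0), default 1.
#' @param strict use strict `>` instead of the inclusive `>=`.
#' @return list with `per_sample` (named list of character sets),
#'   `intersection` (character), and `counts` (named integer).
#' @export
screen_roav <- function(roav_tbl, threshold = 1, strict = FALSE) {
  stopifnot(threshold > 0)
  samples <- sort(unique(roav_tbl$sample_id))
  per_sample <- lapply(samples, function(s) {
    rows <- roav_tbl[roav_tbl$sample_id == s & !is.na(roav_tbl$roav), , drop = FALSE]
    pass <- if (strict) rows$roav > threshold else rows$roav >= threshold
    sort(rows$compound_name[pass])
  })
  names(per_sample) <- samples
  intersection <- if (length(per_sample) > 0) {
    sort(Reduce(intersect, per_sample))
  } else character()
  list(
    per_sample = per_sample,
    intersection = intersection,
    counts = vapply(per_sample, length, integer(1))
  )
}

#' Intersect the rOAV and GC-O screens into the key-compound set
#'
#' Key compounds are those passing the rOAV screen in every sample *and*
#' reaching GC-O consensus in at least one sample (Venn intersection).
#' `roav_only` and `gco_only` are the exclusive Venn regions relative to the
#' rOAV cross-sample intersection and the pooled GC-O consensus set.
#'
#' @param roav_screen result of [screen_roav()].
#' @param gco_records consensus tibble from [gco_consensus()].
#' @return list of class `"key_compound_set"` with `members, roav_intersection,
#'   gco_set, roav_only, gco_only, per_sample_roav_pass, venn_counts`.
#' @export
intersect_key_compounds <- function(roav_screen, gco_records) {
  gco_set <- sort(unique(gco_records$compound_name[gco_records$consensus]))
  ri <- roav_screen$intersection
  members <- intersect(ri, gco_set)
  out <- list(
    members = sort(members),
    roav_intersection = ri,
    gco_set = gco_set,
    roav_only = sort(setdiff(ri, gco_set)),
    gco_only = sort(setdiff(gco_set, ri)),
    per_sample_roav_pass = roav_screen$per_sample,
    venn_counts = c(
      members = length(members),
      roav_only = length(setdiff(ri, gco_set)),
      gco_only = length(setdiff(gco_set, ri))
    )
  )
  structure(out, class = "key_compound_set")
}

#' @export
print.key_compound_set <- function(x, ...) {
  cat("<key_compound_set>\n")
  cat(sprintf("  rOAV cross-sample intersection: %d\n", length(x$roav_intersection)))
  cat(sprintf("  GC-O consensus set:             %d\n", length(x$gco_set)))
  cat(sprintf("  key compounds (intersection):   %d\n", length(x$members)))
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

# descriptor keyword -> odor group; scanned in order, first hit wins
.odor_group_rules <- list(
  list(group = 1L, words = c("roast", "nutty", "nut", "cocoa", "chocolate",
                             "coffee", "potato", "baked")),
  list(group = 2L, words = c("butter", "cream", "yoghurt", "yogurt", "caramel",
                             "burnt sugar", "popcorn", "sweet")),
  list(group = 3L, words = c("smok", "woody", "wood", "earth", "grass",
                             "cucumber", "herb", "medical")),
  list(group = 4L, words = c("pungent", "mushroom", "sweat", "cheese",
                             "stinky", "pea", "sour"))
)

#' Assign key compounds to odor groups from their descriptors
#'
#' Deterministic keyword rules map pooled odor descriptors to four odor
#' groups: 1 roasted/nutty, 2 buttery/caramel, 3 smoky/earthy,
#' 4 pungent/mushroom. Descriptors matching no rule are left `"unassigned"`
#' with a warning log.
#'
#' @param compounds character vector of compound names.
#' @param descriptors character vector of descriptors, parallel to `compounds`.
#' @return tibble `compound_name, group, rationale`.
#' @export
assign_odor_groups <- function(compounds, descriptors) {
  stopifnot(length(compounds) == length(descriptors))
  desc <- tolower(ifelse(is.na(descriptors), "", descriptors))
  group <- character(length(compounds))
  rationale <- character(length(compounds))
  for (i in seq_along(compounds)) {
    hit <- NA_integer_
    word <- ""
    for (rule in .odor_group_rules) {
      m <- rule$words[vapply(rule$words, grepl, logical(1), x = desc[i], fixed = TRUE)]
      if (length(m) > 0) { hit <- rule$group; word <- m[1]; break }
    }
    if (is.na(hit)) {
      group[i] <- "unassigned"
      rationale[i] <- "no descriptor keyword matched"
      ak_log("WARN", "compound '%s': descriptor '%s' maps to no odor group",
             compounds[i], descriptors[i])
    } else {
      group[i] <- as.character(hit)
      rationale[i] <- sprintf("keyword '%s'", word)
    }
  }
  tibble(compound_name = compounds, group = group, rationale = rationale)
}
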