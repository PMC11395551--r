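# One-way ANOVA with Fisher-LSD letters, qPCR fold change, and
# hierarchical clustering for class/compound heatmap structure.

#' One-way ANOVA with Fisher-LSD compact letter display
#'
#' Pools the within-group mean square from a one-way ANOVA, tests every pair
#' of groups with a two-sided t-test on the pooled error, and summarizes the
#' pairwise significance pattern as compact letters by the insert-and-absorb
#' algorithm: groups sharing a letter are not significantly different at
#' `alpha`. With `protected = TRUE` the pairwise tests are only performed
#' when the omnibus F test is itself significant (all groups then share "a"
#' otherwise).
#'
#' @param values numeric vector of observations.
#' @param groups grouping vector, parallel to `values`.
#' @param alpha significance level.
#' @param protected require a significant omnibus F before pairwise testing.
#' @return list of class `"anova_lsd"`: `means, mse, df_error, f_value,
#'   f_p_value, pairwise` (tibble `group1, group2, p_value`), `letters`
#'   (named character), `alpha`.
#' @export
anova_lsd <- function(values, groups, alpha = 0.05, protected = FALSE) {
  g <- as.factor(groups)
  stopifnot(length(values) == length(g), nlevels(g) >= 2)
  ns <- table(g)
  if (any(ns < 2)) stop("every group needs at least 2 replicates", call. = FALSE)

  fit <- stats::lm(values ~ g)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  if (max(abs(stats::residuals(fit))) <= 1e-12 * max(abs(values), 1)) {
    stop("zero within-group variance everywhere: pooled MSE degenerate",
         call. = FALSE)
  }
  f_value <- an[1, "F value"]
  f_p <- an[1, "Pr(>F)"]

  lev <- levels(g)
  means <- tapply(values, g, mean)
  pairs <- utils::combn(lev, 2)
  p_pair <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    tstat <- (means[[pr[1]]] - means[[pr[2]]]) / se
    2 * stats::pt(-abs(tstat), df = df_err)
  })
  pairwise <- tibble(group1 = pairs[1, ], group2 = pairs[2, ], p_value = p_pair)

  if (protected && f_p > alpha) {
    letters <- setNames(rep("a", length(lev)), lev)
  } else {
    sig <- matrix(FALSE, length(lev), length(lev), dimnames = list(lev, lev))
    for (j in seq_len(ncol(pairs))) {
      s <- p_pair[j] <= alpha
      sig[pairs[1, j], pairs[2, j]] <- s
      sig[pairs[2, j], pairs[1, j]] <- s
    }
    # order groups by descending mean, as conventionally displayed
    ord <- lev[order(-means)]
    letters <- compact_letters(sig, ord)
  }
  structure(
    list(means = means, mse = mse, df_error = df_err,
         f_value = f_value, f_p_value = f_p,
         pairwise = pairwise, letters = letters, alpha = alpha),
    class = "anova_lsd"
  )
}

# Insert-and-absorb compact letter display.
# sig[i, j] TRUE when groups i and j differ significantly.
# Returns letters such that two groups share a letter iff not significantly
# different (exactly encodes the pairwise matrix).
compact_letters <- function(sig, order_groups = rownames(sig)) {
  groups <- order_groups
  # each "letter set" is a character vector of mutually non-different groups
  sets <- list(groups[1])
  for (gi in groups[-1]) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (!any(sig[gi, sets[[k]]])) {
        sets[[k]] <- c(sets[[k]], gi)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- gi
    # insert step: every significant pair must be separated; every
    # non-significant pair must share a set — add sets for uncovered pairs
    for (gj in groups[seq_len(match(gi, groups) - 1)]) {
      if (!sig[gi, gj] &&
          !any(vapply(sets, function(s) all(c(gi, gj) %in% s), logical(1)))) {
        sets[[length(sets) + 1]] <- c(gj, gi)
      }
    }
  }
  # grow each set maximally (absorb), then drop sets contained in another
  for (k in seq_along(sets)) {
    for (gi in groups) {
      if (!gi %in% sets[[k]] && !any(sig[gi, sets[[k]]])) {
        sets[[k]] <- c(sets[[k]], gi)
      }
    }
  }
  keep <- rep(TRUE, length(sets))
  for (k in seq_along(sets)) {
    for (m in seq_along(sets)) {
      if (k != m && keep[m] &&
          all(sets[[k]] %in% sets[[m]]) &&
          (length(sets[[k]]) < length(sets[[m]]) || k > m)) {
        keep[k] <- FALSE
        break
      }
    }
  }
  sets <- sets[keep]
  out <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets)) {
    for (gi in sets[[k]]) out[gi] <- paste0(out[gi], letters[k])
  }
  # present letters per group in alphabetical order
  vapply(out, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""),
         character(1))
}

#' Relative expression fold change by the 2^-ddCt method
#'
#' ddCt = (Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl);
#' fold = 2^-ddCt. Replicate Ct values are averaged before differencing.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl Ct values
#'   (scalars or replicate vectors) for target/reference gene in the
#'   case/control condition.
#' @return list `delta_delta_ct, fold`.
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(
    all(ct_target_case > 0), all(ct_ref_case > 0),
    all(ct_target_ctrl > 0), all(ct_ref_ctrl > 0)
  )
  ddct <- (mean(ct_target_case) - mean(ct_ref_case)) -
    (mean(ct_target_ctrl) - mean(ct_ref_ctrl))
  list(delta_delta_ct = ddct, fold = 2^(-ddct))
}

#' Hierarchical clustering of a heatmap matrix
#'
#' Rows are autoscaled (unit variance) before agglomerative clustering with
#' Euclidean distance and average linkage (defaults), mirroring standard
#' heatmap practice. Returns the merge tree plus a flat cut; the same call
#' applied to `t(mat)` clusters the other dimension.
#'
#' @param mat numeric matrix (items in rows).
#' @param k number of flat clusters to cut.
#' @param distance distance measure for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @param scale_rows autoscale rows before clustering.
#' @return list of class `"hca_result"`: `hclust`, `clusters` (named integer),
#'   `heights`, `newick` (text dendrogram).
#' @export
hca_cluster <- function(mat, k = 2, distance = "euclidean",
                        linkage = "average", scale_rows = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 items to cluster", call. = FALSE)
  if (k > nrow(mat)) stop("k exceeds the number of items", call. = FALSE)
  m <- mat
  if (scale_rows) {
    s <- apply(m, 1, sd)
    s[s == 0] <- 1
    m <- sweep(sweep(m, 1, rowMeans(m)), 1, s, "/")
  }
  hc <- stats::hclust(stats::dist(m, method = distance), method = linkage)
  cl <- stats::cutree(hc, k = k)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  structure(
    list(hclust = hc, clusters = cl, heights = hc$height, newick = nwk),
    class = "hca_result"
  )
}
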