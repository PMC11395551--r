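# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the package's own code paths.

# silence INFO logs during tests; warnings stay visible in the log stream
options(aromakey.log_level = "WARN")

# ---- brute-force agglomerative clustering (euclidean / average linkage) -----
# Returns merge heights in order, plus the final two-cluster partition.
oracle_agglomerate <- function(mat, k = 2) {
  clusters <- as.list(seq_len(nrow(mat)))
  d2 <- function(i, j) sqrt(sum((mat[i, ] - mat[j, ])^2))
  heights <- numeric(0)
  while (length(clusters) > k - 1 && length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        # average linkage: mean pairwise distance between members
        dd <- mean(outer(clusters[[a]], clusters[[b]], Vectorize(d2)))
        if (dd < best_d) { best_d <- dd; best <- c(a, b) }
      }
    }
    if (length(clusters) == k) break
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  partition <- integer(nrow(mat))
  for (ci in seq_along(clusters)) partition[clusters[[ci]]] <- ci
  list(heights = heights, partition = partition)
}

# full merge-height sequence down to one cluster
oracle_merge_heights <- function(mat) {
  clusters <- as.list(seq_len(nrow(mat)))
  d2 <- function(i, j) sqrt(sum((mat[i, ] - mat[j, ])^2))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(outer(clusters[[a]], clusters[[b]], Vectorize(d2)))
      if (dd < best_d) { best_d <- dd; best <- c(a, b) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# ---- closed-form 1-component PLS1 (independent of pls_fit) ------------------
# X (n x p) and y (n) assumed pre-scaled/centered.
oracle_pls1_coef <- function(X, y) {
  w <- crossprod(X, y)[, 1]
  w <- w / sqrt(sum(w^2))
  t <- (X %*% w)[, 1]
  cc <- sum(t * y) / sum(t^2)
  w * cc
}

# ---- compact-letter audit ---------------------------------------------------
# TRUE when the letter display exactly encodes the pairwise significance
# matrix: groups share >= 1 letter iff NOT significantly different.
audit_letters <- function(letters_map, pairwise, alpha) {
  for (i in seq_len(nrow(pairwise))) {
    g1 <- pairwise$group1[i]; g2 <- pairwise$group2[i]
    shared <- length(intersect(strsplit(letters_map[[g1]], "")[[1]],
                               strsplit(letters_map[[g2]], "")[[1]])) > 0
    sig <- pairwise$p_value[i] <= alpha
    if (shared == sig) return(FALSE)
  }
  TRUE
}

# ---- tiny in-memory bundle for IO tests ------------------------------------
tiny_bundle <- function() {
  lib <- tibble::tibble(
    name = c("guaiacol", "2,3-butanedione", "nonanal"),
    chem_class = c("phenol", "ketone", "aldehyde"),
    ref_ri = c(1860, 980, 1390),
    odor_threshold = c(3, 1, NA),
    odor_descriptor = c("smoky, woody", "buttery", "fatty"),
    aliases = list(character(), character(), character())
  )
  peaks <- tibble::tibble(
    sample_id = rep(c("S1", "S2"), each = 4),
    replicate = 1L,
    peak_id = rep(c("P1", "P2", "P3", "IS"), 2),
    retention_time = rep(c(30.1, 5.4, 21.5, 25.0), 2),
    area = c(2e5, 1e5, 5e4, 1e6, 4e5, 1.1e5, 6e4, 1e6),
    assigned_compound = rep(c("guaiacol", "2,3-butanedione", "nonanal",
                              "sec-octanol"), 2)
  )
  ladder <- aromakey::alkane_ladder(7:30, seq(4, 50, length.out = 24))
  gco <- tibble::tibble(
    sample_id = rep(c("S1", "S2"), each = 3),
    replicate = 1L,
    panelist = rep(c("A", "B", "C"), 2),
    compound = "guaiacol",
    retention_time = NA_real_,
    intensity = c(4L, 5L, 3L, 4L, 4L, 5L),
    descriptor = "smoky"
  )
  sensory <- tibble::tibble(
    sample_id = rep(c("S1", "S2"), each = 6),
    panelist = "QP1",
    session = 1L,
    attribute = rep(aromakey::SENSORY_ATTRIBUTES, 2),
    score = rep(3L, 12)
  )
  aromakey::dataset_bundle(peaks, lib, ladder,
                           aromakey::internal_standard(), gco, sensory)
}
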