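# GC-O consensus, rOAV screening, Venn intersection, odor groups.

mk_gco <- function(...) {
  rows <- list(...)
  tibble::tibble(
    sample_id = vapply(rows, `[[`, "", 1),
    replicate = as.integer(vapply(rows, `[[`, "", 2)),
    panelist = vapply(rows, `[[`, "", 3),
    compound = vapply(rows, `[[`, "", 4),
    retention_time = NA_real_,
    intensity = as.integer(vapply(rows, `[[`, "", 5)),
    descriptor = ""
  )
}

test_that("GC-O consensus counts distinct panelists across replicates", {
  ev <- mk_gco(
    c("S1", "1", "A", "x", "3"),
    c("S1", "2", "A", "x", "3"),
    c("S1", "1", "B", "x", "5")
  )
  out <- gco_consensus(ev, min_panelists = 2)
  expect_true(out$consensus)
  expect_equal(out$n_panelists_detecting, 2)
  expect_equal(out$mean_intensity, (3 + 3 + 5) / 3)

  one <- gco_consensus(mk_gco(c("S1", "1", "A", "x", "4")), min_panelists = 2)
  expect_false(one$consensus)

  all3 <- gco_consensus(mk_gco(
    c("S1", "1", "A", "x", "4"), c("S1", "1", "B", "x", "4"),
    c("S1", "1", "C", "x", "4")
  ), min_panelists = 2)
  expect_equal(all3$n_panelists_detecting, 3)
  expect_true(all3$consensus)
})

test_that("GC-O events logged by retention time resolve through the library", {
  lib <- tibble::tibble(
    name = "guaiacol", chem_class = "phenol", ref_ri = 1860,
    odor_threshold = 3, odor_descriptor = "smoky",
    aliases = list(character())
  )
  lad <- alkane_ladder(c(18, 19), c(30, 32))
  ev <- tibble::tibble(
    sample_id = "S1", replicate = 1L, panelist = c("A", "B"),
    compound = NA_character_,
    retention_time = 31.2,  # RI 1860
    intensity = 4L, descriptor = "smoky"
  )
  out <- gco_consensus(ev, 2, library = lib, ladder = lad, tolerance = 15)
  expect_equal(out$compound_name, "guaiacol")
  expect_true(out$consensus)
})

test_that("rOAV screen is inclusive at the threshold and skips undefined values", {
  tbl <- tibble::tibble(
    sample_id = rep(c("S1", "S2"), each = 3),
    compound_name = rep(c("at", "below", "undef"), 2),
    Ci = 1, OTi = 1,
    roav = rep(c(1.0, 0.99, NA), 2)
  )
  sc <- screen_roav(tbl, threshold = 1)
  expect_equal(sc$per_sample$S1, "at")
  expect_equal(sc$intersection, "at")
  strict <- screen_roav(tbl, threshold = 1, strict = TRUE)
  expect_equal(length(strict$per_sample$S1), 0)
})

test_that("per-sample pass counts and intersection follow set algebra", {
  # planted structure: 15 core compounds pass everywhere; one extra passes in
  # S3+S4 and two more in S4 only -> counts 15,15,16,18, intersection 15
  core <- sprintf("core%02d", 1:15)
  extra3 <- "only34"; extra4 <- c("only4a", "only4b")
  rows <- list()
  for (s in c("S1", "S2", "S3", "S4")) {
    pass <- core
    if (s %in% c("S3", "S4")) pass <- c(pass, extra3)
    if (s == "S4") pass <- c(pass, extra4)
    fail <- setdiff(c(core, extra3, extra4), pass)
    rows[[s]] <- tibble::tibble(
      sample_id = s,
      compound_name = c(pass, fail),
      Ci = 1, OTi = 1,
      roav = c(rep(2, length(pass)), rep(0.5, length(fail)))
    )
  }
  sc <- screen_roav(dplyr::bind_rows(rows), 1)
  expect_equal(unname(sc$counts), c(15, 15, 16, 18))
  # oracle: plain set algebra over the constructed pass sets
  expect_equal(sc$intersection, sort(core))
})

test_that("key-compound intersection partitions the Venn regions exactly", {
  sc <- list(per_sample = list(S1 = c("a", "b", "c")),
             intersection = c("a", "b", "c"))
  gco_none <- tibble::tibble(compound_name = character(), consensus = logical())
  ks <- intersect_key_compounds(sc, gco_none)
  expect_equal(ks$members, character(0))
  expect_equal(ks$roav_only, c("a", "b", "c"))

  gco_same <- tibble::tibble(compound_name = c("a", "b", "c"), consensus = TRUE)
  ks2 <- intersect_key_compounds(sc, gco_same)
  expect_equal(ks2$members, c("a", "b", "c"))
  expect_equal(ks2$roav_only, character(0))
  expect_equal(ks2$gco_only, character(0))

  gco_mix <- tibble::tibble(compound_name = c("b", "c", "d", "e"),
                            consensus = c(TRUE, TRUE, TRUE, FALSE))
  ks3 <- intersect_key_compounds(sc, gco_mix)
  # set-algebra oracle
  g <- c("b", "c", "d"); r <- c("a", "b", "c")
  expect_equal(ks3$members, sort(intersect(r, g)))
  expect_equal(ks3$roav_only, sort(setdiff(r, g)))
  expect_equal(ks3$gco_only, sort(setdiff(g, r)))
  all_regions <- c(ks3$members, ks3$roav_only, ks3$gco_only)
  expect_equal(anyDuplicated(all_regions), 0)
  expect_setequal(all_regions, union(r, g))
})

test_that("raising thresholds never grows a screen (monotonicity), and results ignore row order", {
  set.seed(9)
  tbl <- tibble::tibble(
    sample_id = rep(c("S1", "S2"), each = 30),
    compound_name = rep(sprintf("c%02d", 1:30), 2),
    Ci = 1, OTi = 1,
    roav = runif(60, 0, 3)
  )
  for (th in c(0.5, 1, 1.5, 2)) {
    lo <- screen_roav(tbl, th)
    hi <- screen_roav(tbl, th + 0.5)
    for (s in names(lo$per_sample)) {
      expect_true(all(hi$per_sample[[s]] %in% lo$per_sample[[s]]))
    }
  }
  shuf <- tbl[sample(nrow(tbl)), ]
  expect_equal(screen_roav(shuf, 1), screen_roav(tbl, 1))

  ev <- mk_gco(
    c("S1", "1", "A", "x", "3"), c("S1", "1", "B", "x", "4"),
    c("S1", "1", "A", "y", "2")
  )
  c2 <- gco_consensus(ev, 2)
  c3 <- gco_consensus(ev, 3)
  expect_true(sum(c3$consensus) <= sum(c2$consensus))
  expect_equal(gco_consensus(ev[sample(nrow(ev)), ], 2), c2)
})

test_that("descriptor keywords map deterministically to the four odor groups", {
  og <- assign_odor_groups(
    c("2,3,5-trimethylpyrazine", "guaiacol", "3-hydroxy-2-butanone",
      "1-octen-3-ol", "mystery"),
    c("roasted peanut, cocoa", "smoky, woody", "buttery, creamy",
      "mushroom", "")
  )
  expect_equal(og$group, c("1", "3", "2", "4", "unassigned"))
})
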