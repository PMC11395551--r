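# Retention indices, library matching, quantitation, rOAV, class totals.

test_that("retention index hits 100 x carbon number at alkanes and is linear between", {
  lad <- alkane_ladder(c(7, 8, 10, 11), c(5.0, 8.0, 14.0, 17.5))
  # alkane identity
  ri <- compute_retention_index(lad$retention_time, lad, quiet = TRUE)
  expect_equal(ri$ri, 100 * lad$carbon_number)
  expect_false(any(ri$extrapolated))
  # midpoint between C10 and C11
  expect_equal(compute_retention_index(mean(c(14.0, 17.5)), lad, quiet = TRUE)$ri, 1050)
  # hand evaluation on the C7-C8 segment: 5 + 1.5 of 3 min span
  expect_equal(compute_retention_index(6.5, lad, quiet = TRUE)$ri, 750)
  # non-consecutive carbons (C8 -> C10) interpolate across 200 RI units
  expect_equal(compute_retention_index(11.0, lad, quiet = TRUE)$ri, 900)
})

test_that("retention index is strictly monotone and flags extrapolation", {
  lad <- alkane_ladder(7:30, 2 + 1.55 * (7:30) + 0.005 * (7:30)^2)
  set.seed(11)
  rts <- sort(runif(500, 5, 55))
  ri <- compute_retention_index(rts, lad, quiet = TRUE)
  expect_true(all(diff(ri$ri) > 0))
  expect_true(compute_retention_index(1.0, lad, quiet = TRUE)$extrapolated)
  expect_true(compute_retention_index(60.0, lad, quiet = TRUE)$extrapolated)
  expect_false(compute_retention_index(20.0, lad, quiet = TRUE)$extrapolated)
})

test_that("library matching ranks by |delta RI| with lexicographic tie-break", {
  lib <- tibble::tibble(
    name = c("b-compound", "a-compound", "far"),
    chem_class = "other",
    ref_ri = c(990, 1010, 1200),
    odor_threshold = NA_real_, odor_descriptor = "",
    aliases = list(character(), character(), character())
  )
  hit <- match_library(1010, lib, tolerance = 15)
  expect_equal(hit$name[1], "a-compound")

  expect_equal(nrow(match_library(1500, lib, tolerance = 15)), 0)

  tie <- match_library(1000, lib, tolerance = 15)
  expect_equal(tie$name, c("a-compound", "b-compound"))  # equal |dRI| = 10
  expect_equal(tie$delta_ri, c(10, 10))
})

test_that("internal-standard quantitation reproduces the spike arithmetic", {
  spec <- internal_standard("sec-octanol", Cs = 180, Vs = 0.005, mx = 3)
  pk <- function(a) tibble::tibble(sample_id = "S1", replicate = 1L, area = a)
  # Ax = As with the conventional spike -> 0.3 ug/g
  expect_equal(quantify_peak(pk(1e6), 1e6, spec), 0.3)
  expect_equal(quantify_peak(pk(0), 1e6, spec), 0)
  expect_equal(quantify_peak(pk(2.5e6), 1e6, spec), 0.75)
  expect_error(quantify_peak(pk(100), 0, spec), "internal standard area")
})

test_that("quantitation is linear in Ax and inverse in sample mass", {
  set.seed(4)
  for (i in 1:20) {
    Ax <- runif(1, 1e3, 1e7); As <- runif(1, 1e5, 1e7)
    Cs <- runif(1, 50, 500); Vs <- runif(1, 1e-3, 1e-2); mx <- runif(1, 1, 10)
    pk <- tibble::tibble(sample_id = "S", replicate = 1L, area = Ax)
    pk2 <- tibble::tibble(sample_id = "S", replicate = 1L, area = 2 * Ax)
    c1 <- quantify_peak(pk, As, internal_standard("is", Cs, Vs, mx))
    c2 <- quantify_peak(pk2, As, internal_standard("is", Cs, Vs, mx))
    c3 <- quantify_peak(pk, As, internal_standard("is", Cs, Vs, 2 * mx))
    expect_equal(c2, 2 * c1, tolerance = 1e-12)
    expect_equal(c3, c1 / 2, tolerance = 1e-12)
  }
})

test_that("rOAV is the unit-reconciled concentration/threshold ratio", {
  # Ci in ug/g is converted to ug/kg before dividing by the ug/kg threshold
  expect_equal(roav(0.0015, 1.5), 1.0)   # threshold identity
  expect_equal(roav(0, 10), 0)
  expect_equal(roav(0.003, 1.5), 2.0)
  expect_true(is.na(roav(1, NA)))        # undefined, not zero
  expect_error(roav(1, -2), "positive")
  # scale invariance
  set.seed(5)
  ci <- runif(10); ot <- runif(10, 0.1, 10); k <- runif(10, 0.5, 20)
  expect_equal(roav(ci * k, ot * k), roav(ci, ot), tolerance = 1e-12)
})

test_that("class aggregation sums members, converts units and tracks percent change", {
  lib <- tibble::tibble(
    name = c("acid1", "acid2", "ketone1"),
    chem_class = c("acid", "acid", "ketone"),
    ref_ri = NA_real_, odor_threshold = NA_real_, odor_descriptor = "",
    aliases = list(character(), character(), character())
  )
  quant <- tibble::tibble(
    sample_id = rep(c("S1", "S4"), each = 3),
    replicate = 1L,
    compound_name = rep(c("acid1", "acid2", "ketone1"), 2),
    Ax = 1, As = 1,
    concentration = c(1.0, 1.4, 2.0, 1.0, 2.0, 2.0)
  )
  agg <- aggregate_classes(quant, lib, "S1")
  s4_acid <- agg[agg$sample_id == "S4" & agg$chem_class == "acid", ]
  expect_equal(s4_acid$total_ug_kg, 3000)      # 3.0 ug/g
  expect_equal(s4_acid$pct_change_vs_reference, 25)
  s4_ket <- agg[agg$sample_id == "S4" & agg$chem_class == "ketone", ]
  expect_equal(s4_ket$pct_change_vs_reference, 0)

  # empty class in one sample -> total 0, -100% vs nonzero reference
  quant_gap <- quant[!(quant$sample_id == "S4" & quant$compound_name == "ketone1"), ]
  agg_gap <- aggregate_classes(quant_gap, lib, "S1")
  gap <- agg_gap[agg_gap$sample_id == "S4" & agg_gap$chem_class == "ketone", ]
  expect_equal(gap$total_ug_kg, 0)
  expect_equal(gap$pct_change_vs_reference, -100)

  expect_error(aggregate_classes(quant, lib, "S9"), "reference sample")
})

test_that("class totals are conserved against the per-sample grand total", {
  res <- generate_dataset(simulation_design(seed = 8))
  pk <- assign_peaks(res$bundle$peaks, res$bundle$library, res$bundle$ladder)
  quant <- quantify_table(pk, res$bundle$is_spec)
  agg <- aggregate_classes(quant, res$bundle$library, "S1")
  for (s in unique(agg$sample_id)) {
    cls_sum <- sum(agg$total_ug_kg[agg$sample_id == s & agg$chem_class != "total"])
    grand <- agg$total_ug_kg[agg$sample_id == s & agg$chem_class == "total"]
    expect_equal(cls_sum, grand, tolerance = 1e-9)
  }
})
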