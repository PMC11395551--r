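# Generator determinism, inversion consistency, planted-truth bookkeeping.

test_that("zero-noise generation inverts exactly through quantitation", {
  res <- generate_dataset(simulation_design(replicate_cv = 0,
                                            plant_effects = FALSE, seed = 3))
  pk <- assign_peaks(res$bundle$peaks, res$bundle$library, res$bundle$ladder)
  quant <- quantify_table(pk, res$bundle$is_spec)
  m <- compound_sample_matrix(quant)
  truth <- res$truth$true_means[rownames(m), colnames(m)]
  expect_equal(unname(m), unname(truth), tolerance = 1e-9)
  # no planted effects: every group identical
  expect_equal(max(abs(m - m[, 1])), 0)
})

test_that("bundles are identical for equal seeds and differ across seeds", {
  a <- generate_dataset(simulation_design(seed = 5))
  b <- generate_dataset(simulation_design(seed = 5))
  c <- generate_dataset(simulation_design(seed = 6))
  expect_identical(a$bundle, b$bundle)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$bundle$peaks$area, c$bundle$peaks$area))
})

test_that("generated bundles pass cross-reference validation with an empty report", {
  res <- generate_dataset(simulation_design(seed = 7))
  expect_equal(nrow(validate_bundle(res$bundle)), 0)
  fx <- study_fixture()
  expect_equal(nrow(validate_bundle(fx$bundle)), 0)
})

test_that("the planted key set spans the four odor groups and the expected roles", {
  res <- generate_dataset(simulation_design(seed = 1))
  expect_length(res$truth$key_set, 12)
  expect_length(res$truth$vip_markers, 5)
  expect_true(all(res$truth$vip_markers %in% res$truth$key_set))
  lib <- res$bundle$library
  desc <- setNames(lib$odor_descriptor, lib$name)
  og <- assign_odor_groups(res$truth$key_set, unname(desc[res$truth$key_set]))
  expect_setequal(unique(og$group), c("1", "2", "3", "4"))
})

test_that("recovery metrics count exactly", {
  truth <- list(
    key_set = sprintf("k%02d", 1:12),
    vip_markers = sprintf("k%02d", 1:5),
    cluster_partition = c(S1 = 1, S2 = 1, S3 = 1, S4 = 2),
    correlation_signs = tibble::tibble(attribute = character(),
                                       compound = character(), sign = numeric())
  )
  perfect <- truth_report(truth, truth$key_set, truth$vip_markers,
                          truth$cluster_partition)
  get <- function(r, m) r$value[r$metric == m]
  expect_equal(get(perfect, "key_precision"), 1)
  expect_equal(get(perfect, "key_recall"), 1)
  expect_equal(get(perfect, "cluster_rand_index"), 1)

  empty <- truth_report(truth, character(0))
  expect_equal(get(empty, "key_recall"), 0)

  fp <- truth_report(truth, c(truth$key_set, "impostor"))
  expect_equal(get(fp, "key_precision"), 12 / 13)
  expect_equal(get(fp, "key_recall"), 1)
  expect_equal(get(fp, "key_exact"), 0)
})

test_that("raising a compound's group-4 multiplier raises its recovered group-4 mean", {
  lvls <- c(1, 2, 4)
  means <- sapply(lvls, function(mlt) {
    vals <- sapply(1:6, function(s) {
      res <- generate_dataset(simulation_design(
        seed = s,
        extra_multipliers = list("guaiacol" = c(1, 1, 1, mlt))
      ))
      pk <- assign_peaks(res$bundle$peaks, res$bundle$library, res$bundle$ladder)
      quant <- quantify_table(pk, res$bundle$is_spec)
      m <- compound_sample_matrix(quant)
      m["guaiacol", "S4"]
    })
    mean(vals)
  })
  expect_true(all(diff(means) > 0))
})

test_that("rand index distinguishes identical, refined and unrelated partitions", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_lt(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1)
  expect_equal(rand_index(c(1, 2, 3), c(1, 2, 3)), 1)
})
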