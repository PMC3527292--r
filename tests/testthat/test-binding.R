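phase_sets <- function(...) {
  # build one protein's phase -> interval list from 1-based closed pairs
  sets <- list(...)
  lapply(sets, function(m) {
    if (is.null(m)) IRanges::IRanges() else
      IRanges::IRanges(start = m[, 1], end = m[, 2])
  })
}

test_that("the five-way binding recode follows the phase patterns", {
  iv <- rbind(c(1, 100))
  mk <- function(mid = NULL, late = NULL, trans = NULL, stat = NULL)
    manual_profiles(list("H-NS" = phase_sets(
      mid_exponential = mid, late_exponential = late,
      transition = trans, stationary = stat)))
  expect_equal(classify_site_binding(50, mk(iv, iv, iv, iv), "H-NS"),
               "always")
  expect_equal(classify_site_binding(50, mk(mid = iv), "H-NS"), "early")
  expect_equal(classify_site_binding(50, mk(mid = iv, late = iv), "H-NS"),
               "early")
  expect_equal(classify_site_binding(50, mk(stat = iv), "H-NS"), "late")
  expect_equal(classify_site_binding(50, mk(trans = iv, stat = iv), "H-NS"),
               "late")
  expect_equal(classify_site_binding(50, mk(), "H-NS"), "never")
  # patterns outside the four named ones go to "other"
  expect_equal(classify_site_binding(50, mk(late = iv, trans = iv), "H-NS"),
               "other")
  expect_equal(classify_site_binding(50, mk(mid = iv, stat = iv), "H-NS"),
               "other")
  expect_equal(classify_site_binding(50, mk(late = iv), "H-NS"), "other")
})

test_that("every site gets exactly one category and counts partition the genome", {
  cfg <- tiny_config(seed = 17)
  bp <- simulate_binding_profiles(cfg$genome_length, cfg)
  cats <- classify_binding_categories(seq_len(cfg$genome_length), bp)
  for (protein in names(bp$profiles)) {
    col <- cats[[paste0("cat_", protein_key(protein))]]
    expect_false(anyNA(col))
    expect_equal(sum(table(col)), cfg$genome_length)
  }
})

test_that("Fis can never be always- or late-bound with exponential-only profiles", {
  cfg <- tiny_config(seed = 18)
  bp <- simulate_binding_profiles(cfg$genome_length, cfg)
  fis <- classify_binding_categories(seq_len(cfg$genome_length),
                                     bp)$cat_fis
  expect_equal(sum(fis %in% c("always", "late")), 0L)
})

test_that("exclusive timing flags follow the era rule", {
  iv <- rbind(c(1, 100))
  mk <- function(mid = NULL, late = NULL, trans = NULL, stat = NULL)
    manual_profiles(list("IhfA" = phase_sets(
      mid_exponential = mid, late_exponential = late,
      transition = trans, stationary = stat)))
  expect_equal(flag_exclusive_timing(50, mk(mid = iv, late = iv), "IhfA"),
               "exclusively_early")
  expect_equal(flag_exclusive_timing(50, mk(stat = iv), "IhfA"),
               "exclusively_late")
  expect_equal(flag_exclusive_timing(50, mk(late = iv, stat = iv), "IhfA"),
               "neither")
  expect_equal(flag_exclusive_timing(50, mk(), "IhfA"), "unbound")
})
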