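test_that("full interphase overlap reproduces identical phase sets", {
  cfg <- tiny_config(interphase_overlap = 1, seed = 2)
  bp <- simulate_binding_profiles(cfg$genome_length, cfg)
  for (protein in names(bp$profiles)) {
    sets <- bp$profiles[[protein]]
    for (ph in names(sets)[-1])
      expect_identical(as.data.frame(sets[[ph]]),
                       as.data.frame(sets[[1]]))
  }
})

test_that("zero overlap yields disjoint phase sets per protein", {
  cfg <- tiny_config(interphase_overlap = 0, seed = 3)
  bp <- simulate_binding_profiles(cfg$genome_length, cfg)
  shared <- IRanges::intersect(bp$profiles[["H-NS"]][["stationary"]],
                               bp$profiles[["H-NS"]][["mid_exponential"]])
  expect_equal(sum(IRanges::width(shared)), 0L)
})

test_that("realized overlap tracks the configured value on a 200 kb genome", {
  cfg <- sim_config(genome_length = 200000, interphase_overlap = 0.5,
                    seed = 3)
  bp <- simulate_binding_profiles(cfg$genome_length, cfg)
  ov <- measure_interphase_overlap(bp, "H-NS", "transition", "stationary")
  expect_gte(ov, 0.45)
  expect_lte(ov, 0.55)
  # sharing decays with temporal distance
  ov2 <- measure_interphase_overlap(bp, "H-NS", "mid_exponential",
                                    "stationary")
  expect_lt(ov2, ov)
})

test_that("Fis is restricted to the exponential phases", {
  cfg <- tiny_config(seed = 5)
  bp <- simulate_binding_profiles(cfg$genome_length, cfg)
  expect_setequal(names(bp$profiles$Fis),
                  c("mid_exponential", "late_exponential"))
})

test_that("coverage hits its target and infeasible coverage errors", {
  cfg <- tiny_config(binding_fraction = 0.04, seed = 6)
  bp <- simulate_binding_profiles(cfg$genome_length, cfg)
  cov <- binding_coverage_summary(bp)
  expect_true(all(abs(cov$fraction - 0.04) < 1e-3))
  expect_error(
    simulate_binding_profiles(5000, tiny_config(genome_length = 5000,
                                                binding_fraction = 0.3)),
    "coverage")
})

test_that("BED round trip preserves interval sets and merges records", {
  cfg <- tiny_config(seed = 7)
  bp <- simulate_binding_profiles(cfg$genome_length, cfg)
  dir <- withr::local_tempdir()
  write_binding_beds(bp, dir)
  re <- load_binding_profiles(dir, genome_length = cfg$genome_length)
  for (protein in names(bp$profiles))
    for (ph in names(bp$profiles[[protein]]))
      expect_identical(as.data.frame(re$profiles[[protein]][[ph]]),
                       as.data.frame(bp$profiles[[protein]][[ph]]))
})

test_that("BED loading merges overlap/abutting records and flags bad input", {
  dir <- withr::local_tempdir()
  writeLines(c("chr\t10\t50", "chr\t40\t80"),
             file.path(dir, "Fis_mid_exponential.bed"))
  writeLines(c("chr\t10\t20", "chr\t20\t30"),
             file.path(dir, "IhfA_stationary.bed"))
  file.create(file.path(dir, "IhfB_transition.bed"))
  p <- load_binding_profiles(dir, genome_length = 100)
  m <- p$profiles$Fis$mid_exponential
  expect_equal(c(IRanges::start(m), IRanges::end(m)), c(11L, 80L))
  a <- p$profiles$IhfA$stationary
  expect_equal(c(IRanges::start(a), IRanges::end(a)), c(11L, 30L))
  expect_length(p$profiles$IhfB$transition, 0L)
  writeLines("chr\t5", file.path(dir, "Fis_stationary.bed"))
  expect_error(load_binding_profiles(dir), "parse error.*line 1")
  file.remove(file.path(dir, "Fis_stationary.bed"))
  writeLines("chr\t1\t2", file.path(dir, "Dps_stationary.bed"))
  expect_error(load_binding_profiles(dir), "naming error")
})
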