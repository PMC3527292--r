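test_that("an exact tandem duplication is fully masked", {
  base <- random_dna(3000, seed = 41)
  dup_block <- substr(base, 1001, 1400)  # 400 bp duplicated
  seq_s <- paste0(substr(base, 1, 2000), dup_block, substr(base, 2001, 3000))
  m <- compute_uniqueness_mask(seq_s, window = 300, step = 10,
                               max_mismatch = 2)
  # every window fully inside either copy must be covered by the mask
  for (s in seq(1001, 1101, by = 10))
    expect_true(IRanges::overlapsAny(IRanges::IRanges(s, s + 299), m,
                                     type = "within"))
  for (s in seq(2001, 2101, by = 10))
    expect_true(IRanges::overlapsAny(IRanges::IRanges(s, s + 299), m,
                                     type = "within"))
})

test_that("a random sequence with no repeats has an empty mask", {
  seq_s <- random_dna(10000, seed = 42)
  m <- compute_uniqueness_mask(seq_s)
  expect_length(m, 0L)
  expect_length(naive_uniqueness_mask(seq_s), 0L)
})

test_that("a duplicate diverged beyond the mismatch budget is not masked", {
  base <- random_dna(2600, seed = 43)
  dup <- strsplit(substr(base, 1001, 1600), "")[[1]]
  # plant a mismatch every 80 bp: every 300 bp window spans >= 3 of them
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  at <- seq(10, 600, by = 80)
  dup[at] <- flip[dup[at]]
  seq_s <- paste0(base, paste(dup, collapse = ""))
  expect_length(compute_uniqueness_mask(seq_s), 0L)
  expect_length(naive_uniqueness_mask(seq_s), 0L)
})

test_that("fast and naive masks agree on mixed fixtures", {
  base <- random_dna(4000, seed = 44)
  seq_s <- paste0(base, substr(base, 501, 900),
                  random_dna(800, seed = 45))
  f <- compute_uniqueness_mask(seq_s)
  n <- naive_uniqueness_mask(seq_s)
  expect_identical(as.data.frame(f), as.data.frame(n))
  # reverse-strand duplications are caught too
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(base, 101, 500))))
  seq_rc <- paste0(base, rc, random_dna(600, seed = 46))
  f2 <- compute_uniqueness_mask(seq_rc)
  n2 <- naive_uniqueness_mask(seq_rc)
  expect_identical(as.data.frame(f2), as.data.frame(n2))
  expect_gt(length(f2), 0L)
})

test_that("windows longer than the sequence are rejected", {
  expect_error(compute_uniqueness_mask(random_dna(200, 4), window = 300),
               "window")
})
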