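test_that("zero rates leave all leaves identical to the root", {
  cfg <- tiny_config(base_rates = setNames(rep(0, 12), mutation_types()),
                     seed = 2)
  g <- simulate_genome(cfg)
  tr <- make_strain_tree(cfg$n_strains, seed = 2)
  ev <- evolve_alignment(g, tr, NULL, cfg)
  expect_equal(nrow(ev$truth$changes), 0L)
  expect_true(all(vapply(ev$alignment$seqs, identical, logical(1),
                         g$sequence)))
})

test_that("realized change fraction matches the configured rate", {
  rate <- 0.02
  cfg <- sim_config(genome_length = 50000, n_genes = 0,
                    base_rates = setNames(rep(rate / 3, 12),
                                          mutation_types()),
                    n_strains = 4, seed = 5)
  g <- simulate_genome(cfg)
  tr <- make_strain_tree(4, seed = 5)
  ev <- evolve_alignment(g, tr, NULL, cfg)
  # every base has total outflow `rate`; expected events = rate * treelen * L
  treelen <- sum(tr$edge.length)
  expected <- rate * treelen * cfg$genome_length
  se <- sqrt(expected)
  expect_lt(abs(nrow(ev$truth$changes) - expected), 3 * se)
})

test_that("the CCWGG multiplier scales focal C>T rates by the set factor", {
  # fixture genome enriched in CCAGG motifs so focal events are plentiful
  set.seed(31)
  block <- function() paste(c("CCAGG", sample(c("A", "C", "G", "T"), 45,
                                              TRUE)), collapse = "")
  seq_s <- paste(vapply(seq_len(2000), function(i) block(), character(1)),
                 collapse = "")
  g <- structure(list(sequence = seq_s, length = nchar(seq_s),
                      genes = data.frame(gene_id = character(0),
                                         start = integer(0),
                                         end = integer(0),
                                         strand = character(0),
                                         frame = integer(0)),
                      sites = NULL), class = "nap_genome")
  rates <- setNames(rep(0.001, 12), mutation_types())
  rates["C>T"] <- 0.02
  rates["G>A"] <- 0.02
  cfg <- sim_config(genome_length = g$length, n_strains = 3,
                    base_rates = rates, ccwgg_multiplier = 10,
                    branch_mean = 0.1, seed = 8)
  tr <- make_strain_tree(3, seed = 8, branch_mean = 0.1)
  ev <- evolve_alignment(g, tr, NULL, cfg)
  ctx <- scan_methylation_contexts(seq_s)
  foc <- ctx[ctx$motif == "CCWGG", ]
  fkey <- paste(foc$position, ifelse(foc$strand == "+", "C>T", "G>A"))
  ch <- ev$truth$changes
  ckey <- paste(ch$site, paste0(ch$from, ">", ch$to))
  n_focal_events <- sum(ckey %in% fkey)
  seq_v <- strsplit(seq_s, "")[[1]]
  is_c <- seq_v == "C"; is_g <- seq_v == "G"
  n_focal <- nrow(foc)
  bg_c <- setdiff(which(is_c), foc$position[foc$strand == "+"])
  bg_g <- setdiff(which(is_g), foc$position[foc$strand == "-"])
  n_bg_events <- sum(ch$site %in% bg_c & ch$from == "C" & ch$to == "T") +
    sum(ch$site %in% bg_g & ch$from == "G" & ch$to == "A")
  ratio <- (n_focal_events / n_focal) /
    (n_bg_events / (length(bg_c) + length(bg_g)))
  expect_gte(ratio, 7)
  expect_lte(ratio, 13)
})

test_that("excessive per-branch probability is rejected", {
  cfg <- tiny_config(base_rates = setNames(rep(10, 12), mutation_types()))
  g <- simulate_genome(cfg)
  tr <- make_strain_tree(cfg$n_strains, seed = 1)
  expect_error(evolve_alignment(g, tr, NULL, cfg), "0.5")
})

test_that("evolution is deterministic and truth matches leaf differences", {
  cfg <- tiny_config(seed = 13, n_genes = 0,
                     base_rates = setNames(rep(0.002, 12),
                                           mutation_types()))
  g <- simulate_genome(cfg)
  tr <- make_strain_tree(cfg$n_strains, seed = 13)
  ev1 <- evolve_alignment(g, tr, NULL, cfg)
  ev2 <- evolve_alignment(g, tr, NULL, cfg)
  expect_identical(ev1$alignment$seqs, ev2$alignment$seqs)
  expect_identical(ev1$truth$changes, ev2$truth$changes)
  # low-rate regime: sites with exactly one event on a leaf's root path
  # must show exactly that difference at the leaf
  ch <- ev1$truth$changes
  once <- names(which(table(ch$site) == 1))
  leaf_ch <- ch[ch$site %in% once & ch$branch %in% tr$tip.label, ]
  for (k in seq_len(min(nrow(leaf_ch), 50))) {
    leafseq <- ev1$alignment$seqs[[leaf_ch$branch[k]]]
    expect_identical(substr(leafseq, leaf_ch$site[k], leaf_ch$site[k]),
                     leaf_ch$to[k])
  }
})

test_that("the implied odds ratio is the configured modifier ratio", {
  be <- c(early = 2, never = 1, late = 0.5)
  cfg <- tiny_config(binding_effect = be)
  expect_equal(implied_odds_ratio(cfg, "C>T", "early", "never"), 2,
               tolerance = 1e-12)
  expect_equal(implied_odds_ratio(cfg, "C>T", "late", "early"), 0.25,
               tolerance = 1e-12)
})
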