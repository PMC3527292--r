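quartet_recon <- function(states_vec, tr) {
  states <- matrix(states_vec, 5, 1,
                   dimnames = list(c("A", "B", "C", "D", "outgroup"), NULL))
  marginal_ancestral_reconstruction(states, tr, model = model_jc())
}

test_that("a clean quartet site yields exactly one polarized change", {
  tr <- quartet_tree()
  rec <- quartet_recon(c("T", "T", "C", "C", "C"), tr)
  ch <- call_high_confidence_changes(rec, tr, positions = 101L)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$from, "C")
  expect_equal(ch$to, "T")
  expect_equal(ch$position, 101L)
  # branch is the stem of the (A,B) cherry
  ab_node <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(ch$branch, paste0("node", ab_node))
  expect_equal(ch$fitch_count, 1L)
})

test_that("a poorly supported implicated node suppresses the call", {
  tr <- quartet_tree(ab_support = 90)
  rec <- quartet_recon(c("T", "T", "C", "C", "C"), tr)
  ch <- call_high_confidence_changes(rec, tr)
  expect_equal(nrow(ch), 0L)
  # but a relaxed support threshold admits it again
  ch2 <- call_high_confidence_changes(rec, tr, support_threshold = 80)
  expect_equal(nrow(ch2), 1L)
})

test_that("monomorphic and homoplasic sites are never called", {
  tr <- quartet_tree()
  expect_equal(nrow(call_high_confidence_changes(
    quartet_recon(c("C", "C", "C", "C", "C"), tr), tr)), 0L)
  # T on two non-sister leaves: two events required
  expect_equal(nrow(call_high_confidence_changes(
    quartet_recon(c("T", "C", "T", "C", "C"), tr), tr)), 0L)
  expect_equal(fitch_count(tr, c(A = "T", B = "C", C = "T", D = "C",
                                 outgroup = "C")), 2L)
  expect_equal(fitch_count(tr, c(A = "T", B = "T", C = "C", D = "C",
                                 outgroup = "C")), 1L)
})

test_that("a high posterior threshold suppresses uncertain ancestries", {
  tr <- quartet_tree()
  rec <- quartet_recon(c("T", "T", "C", "C", "C"), tr)
  ch <- call_high_confidence_changes(rec, tr, posterior_threshold = 0.999999)
  expect_equal(nrow(ch), 0L)
})

test_that("raising either threshold never increases the number of calls", {
  cfg <- tiny_config(seed = 21, n_strains = 6,
                     low_support_fraction = 0.3)
  g <- simulate_genome(cfg)
  tr <- make_strain_tree(6, seed = 21, low_support_fraction = 0.3)
  ev <- evolve_alignment(g, tr, NULL, cfg)
  s <- extract_analyzable_sites(ev$alignment)
  rec <- marginal_ancestral_reconstruction(
    ev$alignment, tr, sites = match(s$polymorphic, seq_len(cfg$genome_length)))
  n_calls <- function(post, supp)
    nrow(call_high_confidence_changes(rec, tr, support_threshold = supp,
                                      posterior_threshold = post,
                                      positions = s$polymorphic))
  for (supp in c(50, 98, 100))
    expect_true(all(diff(sapply(c(0.5, 0.9, 0.99), n_calls, supp = supp))
                    <= 0))
  for (post in c(0.7, 0.9))
    expect_true(all(diff(sapply(c(50, 98, 100),
                                function(s2) n_calls(post, s2))) <= 0))
})
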