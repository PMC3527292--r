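test_that("transition matrices are proper stochastic matrices", {
  for (seed in 1:4) {
    m <- random_model(seed)
    expect_equal(rowSums(m$Q), rep(0, 4), tolerance = 1e-10,
                 ignore_attr = TRUE)
    for (t in c(0.01, 0.3, 2)) {
      P <- transition_matrix(m, t)
      expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_true(all(P >= 0))
    }
    # stationarity: pi is a left eigenvector of P(t)
    expect_equal(as.numeric(m$pi %*% transition_matrix(m, 0.7)),
                 as.numeric(m$pi), tolerance = 1e-10)
  }
  expect_error(model_hky(kappa = -1), "kappa")
  expect_error(model_hky(freqs = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("a monomorphic column reconstructs its state everywhere", {
  tr <- random_fixture_tree(5, seed = 2)
  states <- matrix("C", 5, 3, dimnames = list(tr$tip.label, NULL))
  rec <- marginal_ancestral_reconstruction(states, tr, model = model_jc())
  for (v in seq_along(rec$posterior)) {
    if (is.null(rec$posterior[[v]])) next
    expect_true(all(apply(rec$posterior[[v]], 2, which.max) == 2))
  }
})

test_that("posteriors match exhaustive enumeration on small trees", {
  for (seed in 1:12) {
    n <- sample(3:6, 1)
    tr <- random_fixture_tree(n, seed = 100 + seed)
    set.seed(200 + seed)
    states <- matrix(sample(c("A", "C", "G", "T"), n * 10, TRUE), n,
                     dimnames = list(tr$tip.label, NULL))
    mod <- random_model(300 + seed)
    rec <- marginal_ancestral_reconstruction(states, tr, model = mod)
    oracle <- enumerate_ancestral_posteriors(states, tr, mod)
    ntip <- ape::Ntip(tr)
    for (v in (ntip + 1):(ntip + tr$Nnode))
      expect_lt(max(abs(rec$posterior[[v]] - oracle[[v]])), 1e-10)
  }
})

test_that("posteriors are proper distributions and converge in the short-branch limit", {
  tr <- ape::read.tree(text = "(a:1e-9,b:1e-9);")
  states <- matrix(c("G", "G"), 2, 1, dimnames = list(c("a", "b"), NULL))
  rec <- marginal_ancestral_reconstruction(states, tr, model = model_jc())
  expect_gt(rec$posterior[[3]]["G", 1], 1 - 1e-6)
  tr5 <- random_fixture_tree(5, seed = 4)
  set.seed(5)
  st <- matrix(sample(c("A", "C", "G", "T"), 5 * 20, TRUE), 5,
               dimnames = list(tr5$tip.label, NULL))
  rec5 <- marginal_ancestral_reconstruction(st, tr5, model = model_hky(3))
  for (v in 6:9)
    expect_equal(colSums(rec5$posterior[[v]]), rep(1, 20),
                 tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("leaf/strain mismatch raises a data error", {
  tr <- random_fixture_tree(4, seed = 1)
  states <- matrix("A", 3, 2, dimnames = list(tr$tip.label[1:3], NULL))
  expect_error(marginal_ancestral_reconstruction(states, tr,
                                                 model = model_jc()),
               "data error")
})
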