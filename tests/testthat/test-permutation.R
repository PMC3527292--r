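test_that("conformity follows the strict directional rules", {
  cc <- make_combo_fixture(mut_e = c(1, 2, 1, 1, 2, 2),
                           mut_l = c(3, 1, 1, 0, 3, 0),
                           ctx_e = rep(100, 6), ctx_l = rep(100, 6))
  ob <- observed_conformity_pattern(cc)
  expect_true(ob[["hns/CCWGG"]])     # late 0.03 > early 0.01
  expect_true(ob[["hns/control"]])   # late 0.01 < early 0.02
  expect_false(ob[["ihfa/CCWGG"]])   # exact tie does not conform
  expect_true(ob[["ihfa/control"]])
  expect_true(all(ob[c("ihfb/CCWGG", "ihfb/control")]))
  zero <- make_combo_fixture(rep(0, 6), rep(0, 6), rep(100, 6),
                             c(0, rep(100, 5)))
  expect_true(is.na(observed_conformity_pattern(zero)[1]))
})

test_that("the exact oracle reproduces hand-enumerated allocations", {
  one <- data.frame(protein = "hns", motif = "CCWGG", n_mut_early = 0,
                    n_mut_late = 1, n_ctx_early = 50, n_ctx_late = 50)
  expect_equal(exact_pvalue_oracle(one), 0.5)  # one mutation, fair split
  two <- one
  two$n_mut_late <- 2
  # both mutations must land late: (1/2)^2
  expect_equal(exact_pvalue_oracle(two), 0.25)
  ctl <- data.frame(protein = "hns", motif = "control", n_mut_early = 1,
                    n_mut_late = 0, n_ctx_early = 50, n_ctx_late = 50)
  expect_equal(exact_pvalue_oracle(ctl), 0.5)
  # independent combos multiply
  both <- rbind(two, ctl)
  expect_equal(exact_pvalue_oracle(both), 0.25 * 0.5)
  # unequal context counts shift the allocation probability
  sk <- one
  sk$n_ctx_late <- 150  # p_late = 0.75; conform iff the mutation lands late
  expect_equal(exact_pvalue_oracle(sk), 0.75)
  big <- make_combo_fixture(rep(20, 6), rep(20, 6), rep(100, 6),
                            rep(100, 6))
  expect_error(exact_pvalue_oracle(transform(big, n_mut_late = 200,
                                             n_ctx_late = 1000)),
               "too large")
})

test_that("the Monte-Carlo sampler agrees with the oracle within 3 MC SE", {
  fixtures <- list(
    make_combo_fixture(c(1, 2, 0, 1, 2, 1), c(2, 0, 1, 1, 1, 0),
                       c(50, 60, 40, 30, 70, 80),
                       c(55, 50, 45, 35, 60, 70)),
    make_combo_fixture(c(0, 1, 1, 0, 2, 1), c(1, 1, 2, 1, 0, 1),
                       rep(120, 6), rep(80, 6)))
  for (fx in fixtures) {
    ex <- exact_pvalue_oracle(fx)
    mc <- permutation_pvalue(fx, n_reps = 100000, seed = 3)
    se <- sqrt(ex * (1 - ex) / mc$n_reps)
    expect_lt(abs(mc$p_value - ex), 3 * se + 2 / mc$n_reps)
    expect_equal(mc$p_value, (mc$n_all_conform + 1) / (mc$n_reps + 1))
  }
})

test_that("the permutation P is deterministic and validates inputs", {
  fx <- make_combo_fixture(c(1, 2, 0, 1, 2, 1), c(2, 0, 1, 1, 1, 0),
                           rep(60, 6), rep(60, 6))
  expect_identical(permutation_pvalue(fx, 5000, seed = 8)$p_value,
                   permutation_pvalue(fx, 5000, seed = 8)$p_value)
  expect_error(permutation_pvalue(fx, 0, seed = 1), "n_reps")
  bad <- fx
  bad$n_mut_early[1] <- 1000
  expect_error(permutation_pvalue(bad, 10, 1), "exceed")
})

test_that("the null depends on counts only through totals and contexts", {
  a <- make_combo_fixture(c(4, 1, 2, 0, 3, 2), c(0, 3, 1, 3, 0, 1),
                          rep(90, 6), rep(110, 6))
  b <- a
  b$n_mut_early <- c(2, 2, 0, 1, 1, 3)
  b$n_mut_late <- (a$n_mut_early + a$n_mut_late) - b$n_mut_early
  expect_equal(exact_pvalue_oracle(a), exact_pvalue_oracle(b))
  expect_identical(permutation_pvalue(a, 20000, seed = 2)$p_value,
                   permutation_pvalue(b, 20000, seed = 2)$p_value)
})

test_that("null-generated data all-conform at the oracle's exact frequency", {
  ctx_e <- rep(400, 6); ctx_l <- rep(600, 6)
  totals <- c(7, 9, 6, 9, 8, 7)  # keeps the oracle's state space enumerable
  base <- make_combo_fixture(totals, rep(0, 6), ctx_e, ctx_l)
  ex <- exact_pvalue_oracle(base)  # depends only on totals and contexts
  set.seed(99)
  n_rep <- 2000
  conform <- vapply(seq_len(n_rep), function(i) {
    late <- rbinom(6, totals, ctx_l / (ctx_e + ctx_l))
    fx <- make_combo_fixture(totals - late, late, ctx_e, ctx_l)
    all(observed_conformity_pattern(fx))
  }, logical(1))
  se <- sqrt(ex * (1 - ex) / n_rep)
  expect_lt(abs(mean(conform) - ex), 3 * se)
})
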