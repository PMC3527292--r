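make_table <- function(n_changed, n_unchanged, seed = 1) {
  set.seed(seed)
  n <- n_changed + n_unchanged
  data.frame(position = seq_len(n),
             changed = rep(c(TRUE, FALSE), c(n_changed, n_unchanged)),
             binding = factor(sample(c("never", "early", "late"), n, TRUE)),
             x = rnorm(n))
}

test_that("subsampling keeps the changed class intact at a 5:1 ratio", {
  ds <- assemble_dataset(make_table(100, 10000), seed = 2)
  expect_equal(nrow(ds$data), 600L)
  expect_equal(sum(ds$data$outcome == "changed"), 100L)
  expect_equal(sum(ds$data$outcome == "unchanged"), 500L)
  expect_warning(short <- assemble_dataset(make_table(100, 300), seed = 2),
                 "using all")
  expect_equal(nrow(short$data), 400L)
  expect_error(assemble_dataset(make_table(0, 50)), "zero changed")
  a <- assemble_dataset(make_table(50, 5000), seed = 9)
  b <- assemble_dataset(make_table(50, 5000), seed = 9)
  expect_identical(a$data, b$data)
  expect_true("binding" %in% a$binding_cols)
})

test_that("a perfectly separating feature reaches AUC 1", {
  tab <- make_table(150, 1500)
  tab$x <- ifelse(tab$changed, 1, 0) + rnorm(nrow(tab), 0, 0.01)
  ds <- assemble_dataset(tab, seed = 1)
  auc <- fit_and_score(ds, classifier_params(n_trees = 100, seed = 1))
  expect_equal(auc, 1)
})

test_that("permuted labels give chance-level out-of-bag AUC", {
  aucs <- vapply(1:12, function(r) {
    tab <- make_table(120, 1200, seed = r)
    set.seed(1000 + r)
    tab$changed <- sample(tab$changed)
    ds <- assemble_dataset(tab, seed = r)
    fit_and_score(ds, classifier_params(n_trees = 150, seed = r))
  }, numeric(1))
  # mean of null AUCs should sit at 0.5 within 3 standard errors
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(length(aucs)))
})

test_that("out-of-bag AUC approaches the binormal closed form", {
  delta <- 0.8
  n <- 5000
  set.seed(77)
  changed <- rep(c(TRUE, FALSE), c(n / 2, n / 2))
  tab <- data.frame(position = seq_len(n), changed = changed,
                    x = rnorm(n, ifelse(changed, delta, -delta), 1))
  ds <- structure(list(data = data.frame(
    outcome = factor(ifelse(changed, "changed", "unchanged"),
                     levels = c("unchanged", "changed")), x = tab$x),
    binding_cols = character(0), mutation_type = NULL, ratio = 1),
    class = "classifier_dataset")
  auc <- fit_and_score(ds, classifier_params(n_trees = 300, k = 1,
                                             seed = 3))
  expect_lt(abs(auc - pnorm(delta * sqrt(2))), 0.03)
})

test_that("the K aggregation rule normalizes, averages and breaks ties low", {
  # engineered profiles with mean normalized AUC peaking at K = 3
  auc <- rbind(c(0.60, 0.62, 0.70, 0.65),
               c(0.55, 0.60, 0.64, 0.63),
               c(0.70, 0.74, 0.75, 0.70))
  expect_equal(select_k(auc, 1:4)$k_star, 3L)
  # one dataset: K* is its raw argmax
  expect_equal(select_k(rbind(c(0.5, 0.9, 0.7)), 1:3)$k_star, 2L)
  # opposite monotone trends of equal magnitude tie -> smallest K
  tie <- rbind(c(0.6, 0.65, 0.7), c(0.7, 0.65, 0.6))
  expect_equal(select_k(tie, 1:3)$k_star, 1L)
  expect_warning(deg <- select_k(rbind(c(0.6, 0.6), c(0.7, 0.7)), 1:2),
                 "constant")
  expect_equal(deg$k_star, 1L)
})

test_that("optimize_split_features evaluates the grid on real forests", {
  tab <- make_table(80, 800, seed = 5)
  tab$x2 <- rnorm(nrow(tab))
  ds <- assemble_dataset(tab, seed = 5)
  opt <- optimize_split_features(list(ds, ds),
                                 classifier_params(n_trees = 60, seed = 2),
                                 k_grid = 1:3)
  expect_true(opt$k_star %in% 1:3)
  expect_equal(dim(opt$auc), c(2L, 3L))
  expect_true(all(opt$normalized >= 0 & opt$normalized <= 1))
})

test_that("binding randomization preserves margins, reproduces, and flags df", {
  st <- simulate_site_table(site_sim_config(n_sites = 4000,
                                            binding_coef = log(3),
                                            seed = 12))
  ds <- assemble_dataset(st$sites, seed = 3)
  p <- classifier_params(n_trees = 120, seed = 4)
  r1 <- binding_randomization_test(ds, p, n_rand = 6, seed = 5)
  r2 <- binding_randomization_test(ds, p, n_rand = 6, seed = 5)
  expect_identical(r1$auc_randomized, r2$auc_randomized)
  expect_identical(r1$z, r2$z)
  expect_equal(r1$p_one_tailed, pnorm(r1$z, lower.tail = FALSE))
  # a strong binding signal should stand far above the randomized AUCs
  expect_gt(r1$z, 2)
  # single randomization: spread undefined, flagged
  r0 <- binding_randomization_test(ds, p, n_rand = 1, seed = 5)
  expect_true(r0$sd_zero)
  expect_true(is.na(r0$p_one_tailed))
})

test_that("six one-tailed P values with four below 0.1 give a 15% FDR", {
  p_values <- c(0.01, 0.03, 0.06, 0.09, 0.4, 0.8)
  k <- sum(p_values < 0.1)
  expect_equal(estimate_fdr(0.1, length(p_values), k)$fdr, 0.15)
})
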