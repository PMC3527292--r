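# hand-built census: 1200 genic sites on the plus strand, half bound
hand_sites <- function() {
  n <- 1200
  data.frame(position = seq_len(n),
             base = rep(c("C", "G", "A", "T"), n / 4),
             sense_base = rep(c("C", "G", "A", "T"), n / 4),
             sense_strand = "+",
             site_class = "fourfold",
             stratum = rep(c("bound", "unbound"), each = n / 2),
             stringsAsFactors = FALSE)
}

test_that("rates are hand-count ratios and empty change sets give zero", {
  sites <- hand_sites()
  empty <- data.frame(position = integer(0), from = character(0),
                      to = character(0))
  tab0 <- tabulate_mutability(empty, sites, stratum = "stratum")
  expect_true(all(tab0$rate == 0))
  # 3 C>T changes among the 150 bound at-risk C sites -> rate 0.02
  ch <- data.frame(position = c(1, 5, 9),
                   from = "C", to = "T", stringsAsFactors = FALSE)
  tab <- tabulate_mutability(ch, sites, stratum = "stratum")
  row <- tab[tab$type == "C>T" & tab$stratum == "bound", ]
  expect_equal(row$n_changes, 3)
  expect_equal(row$n_at_risk, 150)
  expect_equal(row$rate, 3 / 150)
})

test_that("stratum counts conserve totals and couples sum their strands", {
  set.seed(7)
  sites <- hand_sites()
  idx <- sample(nrow(sites), 120)
  flip <- c(A = "G", G = "A", C = "T", T = "C")
  ch <- data.frame(position = sites$position[idx],
                   from = sites$base[idx],
                   to = unname(flip[sites$base[idx]]),
                   stringsAsFactors = FALSE)
  tab <- tabulate_mutability(ch, sites, stratum = "stratum")
  for (tp in unique(paste0(ch$from, ">", ch$to))) {
    expect_equal(sum(tab$n_changes[tab$type == tp]),
                 sum(paste0(ch$from, ">", ch$to) == tp))
  }
  cpl <- tabulate_mutability(ch, sites, stratum = "stratum",
                             collapse_couples = TRUE)
  for (cp in names(mutation_couples())) {
    members <- mutation_couples()[[cp]]
    expect_equal(sum(cpl$n_changes[cpl$type == cp]),
                 sum(tab$n_changes[tab$type %in% members]))
  }
  # couple denominators count each duplex site once: 150 C + 150 G per
  # stratum for the C:G couples, likewise for A:T
  expect_equal(unique(cpl$n_at_risk), 300)
})

test_that("minus-strand changes are re-expressed on the sense strand", {
  sites <- data.frame(position = 1:2, base = c("G", "G"),
                      sense_base = c("C", "G"),
                      sense_strand = c("-", "+"),
                      site_class = "fourfold", stratum = "all",
                      stringsAsFactors = FALSE)
  ch <- data.frame(position = 1:2, from = "G", to = "A",
                   stringsAsFactors = FALSE)
  tab <- suppressWarnings(
    tabulate_mutability(ch, sites, stratum = "stratum"))
  expect_equal(tab$n_changes[tab$type == "C>T"], 1)  # minus-strand gene
  expect_equal(tab$n_changes[tab$type == "G>A"], 1)  # plus-strand gene
})

test_that("odds ratios and Woolf intervals match closed forms", {
  same <- odds_ratio_ci(10, 1000, 10, 1000)
  expect_equal(same$or, 1)
  o <- odds_ratio_ci(10, 1000, 20, 1000)
  expect_equal(o$or, (20 / 980) / (10 / 990), tolerance = 1e-12)
  se <- sqrt(1 / 20 + 1 / 980 + 1 / 10 + 1 / 990)
  expect_equal(o$ci_low, exp(log(o$or) - qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(o$ci_high, exp(log(o$or) + qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_false(o$undefined)
  # Haldane-Anscombe on zero cells
  h <- odds_ratio_ci(0, 100, 5, 100)
  expect_equal(h$or, (5.5 / 95.5) / (0.5 / 100.5), tolerance = 1e-12)
  expect_true(odds_ratio_ci(0, 50, 0, 50)$undefined)
  expect_error(odds_ratio_ci(5, 3, 1, 10))
})

test_that("the expected-false-positive FDR matches its arithmetic", {
  expect_equal(estimate_fdr(0.1, 6, 4)$fdr, 0.15)
  expect_equal(estimate_fdr(0.05, 10, 10)$fdr, 0.05)
  expect_equal(estimate_fdr(0.1, 10, 1)$fdr, 1)
  z <- estimate_fdr(0.1, 5, 0)
  expect_true(z$undefined)
  expect_true(is.na(z$fdr))
  expect_error(estimate_fdr(1.5, 5, 2))
})

test_that("context mutability counts only strand-resolved focal changes", {
  cen <- scan_methylation_contexts(
    paste0("AAAACCAGGAAAA", "AAAACCTAAAAAA"))
  timing <- data.frame(position = 1:26,
                       timing_hns = rep("exclusively_late", 26))
  foc <- cen$position[cen$motif == "CCWGG" & cen$strand == "+"]
  ch_on <- data.frame(position = foc, from = "C", to = "T",
                      stringsAsFactors = FALSE)
  tab <- context_mutability(cen, ch_on, timing)
  row <- tab[tab$motif == "CCWGG" & tab$stratum == "exclusively_late", ]
  expect_equal(row$n_changes, 1L)
  expect_equal(row$rate, row$n_changes / row$n_contexts)
  # moving the change one base off the focal position drops it
  ch_off <- data.frame(position = foc + 1L, from = "C", to = "T",
                       stringsAsFactors = FALSE)
  tab_off <- context_mutability(cen, ch_off, timing)
  expect_equal(sum(tab_off$n_changes), 0L)
  # a G>A at the minus-strand focal counts for CCWGG
  foc_m <- cen$position[cen$motif == "CCWGG" & cen$strand == "-"]
  ch_m <- data.frame(position = foc_m, from = "G", to = "A",
                     stringsAsFactors = FALSE)
  expect_equal(sum(context_mutability(cen, ch_m, timing)$n_changes), 1L)
})
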