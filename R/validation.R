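# Parameter-recovery harnesses: run the package's estimators on data
# simulated with known ground truth and report how well the truth is
# recovered. Used by the test suite and by scripts/acceptance.R.

#' Reconstruction accuracy against the enumeration oracle
#'
#' Generates random small fixtures (rooted trees with 3-6 leaves, random
#' branch lengths, random reversible models, random leaf states), computes
#' marginal posteriors by the pruning algorithm and by exhaustive
#' enumeration, and reports the largest absolute posterior difference seen.
#'
#' @param n_fixtures Number of random fixtures.
#' @param sites_per_fixture Alignment columns per fixture.
#' @param seed Integer seed.
#' @return List: `max_abs_diff`, `n_fixtures`.
#' @export
validate_reconstruction_oracle <- function(n_fixtures = 200,
                                           sites_per_fixture = 10,
                                           seed = 1L) {
  worst <- 0
  with_seed(stage_seed(seed, "recon_oracle"), {
    for (i in seq_len(n_fixtures)) {
      n <- sample(3:6, 1)
      tr <- ape::rtree(n, rooted = TRUE,
                       br = function(k) runif(k, 0.02, 0.4))
      tr$tip.label <- paste0("s", seq_len(n))
      states <- matrix(sample(c("A", "C", "G", "T"),
                              n * sites_per_fixture, TRUE), n,
                       dimnames = list(tr$tip.label, NULL))
      pick <- sample(4, 1)
      mod <- if (pick == 1) model_jc()
      else if (pick == 2) model_k80(kappa = runif(1, 1, 6))
      else {
        f <- runif(4, 0.5, 2); f <- f / sum(f)
        if (pick == 3) model_hky(kappa = runif(1, 1, 6), freqs = f)
        else model_gtr(rates = runif(6, 0.3, 3), freqs = f)
      }
      rec <- marginal_ancestral_reconstruction(states, tr, model = mod)
      oracle <- enumerate_ancestral_posteriors(states, tr, mod)
      for (v in (n + 1L):(n + tr$Nnode))
        worst <- max(worst, max(abs(rec$posterior[[v]] - oracle[[v]])))
    }
  })
  list(max_abs_diff = worst, n_fixtures = n_fixtures)
}

#' Change-calling recovery on a synthetic low-rate run
#'
#' Evolves an alignment in the low-rate regime with fully supported nodes,
#' runs site filtering, reconstruction and high-confidence change calling
#' at default thresholds, and scores recall and precision of the ground
#' truth (matching site, branch and direction).
#'
#' @param seed Integer seed.
#' @param genome_length,n_genes,n_strains Generator conditions.
#' @return List: `recall`, `precision`, `n_true`, `n_called`.
#' @export
change_recovery_run <- function(seed = 1L, genome_length = 50000,
                                n_genes = 40, n_strains = 8) {
  cfg <- sim_config(genome_length = genome_length, n_genes = n_genes,
                    n_strains = n_strains, low_support_fraction = 0,
                    seed = stage_seed(seed, "recovery_cfg"))
  g <- simulate_genome(cfg)
  tr <- make_strain_tree(n_strains, seed = stage_seed(seed, "recovery_tree"),
                         branch_mean = cfg$branch_mean,
                         outgroup_scale = cfg$outgroup_scale,
                         low_support_fraction = 0)
  ev <- evolve_alignment(g, tr, NULL, cfg)
  s <- extract_analyzable_sites(ev$alignment)
  rec <- marginal_ancestral_reconstruction(
    ev$alignment, tr, sites = match(s$polymorphic, seq_len(genome_length)))
  ch <- call_high_confidence_changes(rec, tr, positions = s$polymorphic)
  tk <- with(ev$truth$changes, paste(site, branch, from, to))
  ck <- with(ch, paste(position, branch, from, to))
  list(recall = mean(tk %in% ck), precision = mean(ck %in% tk),
       n_true = length(tk), n_called = length(ck))
}

#' Odds-ratio recovery for a configured binding effect
#'
#' Simulates site tables in which the early-bound category carries a
#' log(2) change in odds (true OR exactly 2), forms the early-versus-never
#' 2x2 table per replicate, and reports Woolf CI coverage of the true OR
#' and the mean log-OR bias.
#'
#' @param seed Integer seed.
#' @param n_reps Replicates.
#' @param n_sites Sites per replicate (roughly 45% early, 45% never).
#' @param effect True odds ratio attached to the early category.
#' @return List: `coverage`, `mean_log_bias`, `mean_or`, `n_per_stratum`.
#' @export
or_recovery_run <- function(seed = 1L, n_reps = 200, n_sites = 120000,
                            effect = 2) {
  zero_conf <- list(log_expr = 0, lagging = 0, origin_dist = 0, gc = 0,
                    twofold = 0)
  cover <- logical(n_reps)
  logor <- numeric(n_reps)
  n_min <- Inf
  for (r in seq_len(n_reps)) {
    st <- simulate_site_table(site_sim_config(
      n_sites = n_sites, intercept = qlogis(0.05),
      binding_coef = c(early = log(effect)),
      binding_probs = c(never = 0.45, early = 0.45, late = 0.04,
                        always = 0.03, other = 0.03),
      confounder_coefs = zero_conf,
      seed = stage_seed(seed, paste0("or_rep_", r))))$sites
    nev <- st$binding == "never"
    ear <- st$binding == "early"
    n_min <- min(n_min, sum(nev), sum(ear))
    o <- odds_ratio_ci(sum(st$changed[nev]), sum(nev),
                       sum(st$changed[ear]), sum(ear),
                       orientation = "early vs never")
    cover[r] <- o$ci_low <= effect && effect <= o$ci_high
    logor[r] <- log(o$or)
  }
  list(coverage = mean(cover),
       mean_log_bias = mean(logor) - log(effect),
       mean_or = exp(mean(logor)), n_per_stratum = n_min)
}

#' Size and power of the binding-randomization test
#'
#' `classifier_null_size` runs the full randomization test on site tables
#' whose binding coefficient is zero (confounders retain their default
#' effects) and reports the rejection rate at `alpha`.
#' `classifier_power_run` does the same with a log(2) binding coefficient
#' at the published scale (30,000 sites, 500 trees) and reports the
#' fraction of runs significant at 0.05.
#'
#' @param n_runs Independent seeded runs.
#' @param n_sites Sites per run.
#' @param n_trees Forest size.
#' @param n_rand Randomizations per run.
#' @param alpha Rejection threshold.
#' @param seed Integer seed.
#' @return List with the rejection/power rate, the per-run P values and
#'   the conditions used.
#' @export
classifier_null_size <- function(n_runs = 40, n_sites = 4000,
                                 n_trees = 150, n_rand = 25, alpha = 0.1,
                                 seed = 1L) {
  p <- vapply(seq_len(n_runs), function(r)
    randomization_p_once(n_sites, 0, n_trees, n_rand,
                         stage_seed(seed, paste0("size_", r))),
    numeric(1))
  list(rejection_rate = mean(p < alpha), p_values = p, alpha = alpha,
       n_runs = n_runs)
}

#' @rdname classifier_null_size
#' @export
classifier_power_run <- function(n_runs = 20, n_sites = 30000,
                                 n_trees = 500, n_rand = 10, seed = 1L) {
  p <- vapply(seq_len(n_runs), function(r)
    randomization_p_once(n_sites, log(2), n_trees, n_rand,
                         stage_seed(seed, paste0("power_", r))),
    numeric(1))
  list(power = mean(p < 0.05), p_values = p, n_runs = n_runs)
}

randomization_p_once <- function(n_sites, coef, n_trees, n_rand, seed) {
  st <- simulate_site_table(site_sim_config(n_sites = n_sites,
                                            binding_coef = coef,
                                            seed = seed))
  ds <- assemble_dataset(st$sites, seed = stage_seed(seed, "ds"))
  params <- classifier_params(n_trees = n_trees,
                              seed = stage_seed(seed, "rf"))
  binding_randomization_test(ds, params, n_rand = n_rand,
                             seed = stage_seed(seed, "bt"))$p_one_tailed
}

#' Mutation-spectrum recovery at 4-fold synonymous sites
#'
#' Evolves a gene-dense genome under the default transition-biased rates,
#' reconstructs and calls changes, tabulates the six strand-collapsed
#' couples at 4-fold sites, and compares the estimated spectrum with the
#' configured one (rank of the C:G>T:A couple and Spearman correlation).
#'
#' @param seed Integer seed.
#' @param genome_length,n_genes Generator conditions.
#' @return List: `top_couple`, `spearman_rho`, `table` (couple, configured
#'   rate, estimated rate).
#' @export
spectrum_recovery_run <- function(seed = 1L, genome_length = 200000,
                                  n_genes = 160) {
  cfg <- sim_config(genome_length = genome_length, n_genes = n_genes,
                    n_strains = 8, low_support_fraction = 0,
                    seed = stage_seed(seed, "spec_cfg"))
  g <- simulate_genome(cfg)
  tr <- make_strain_tree(8, seed = stage_seed(seed, "spec_tree"),
                         branch_mean = cfg$branch_mean,
                         outgroup_scale = cfg$outgroup_scale)
  ev <- evolve_alignment(g, tr, NULL, cfg)
  s <- extract_analyzable_sites(ev$alignment)
  rec <- marginal_ancestral_reconstruction(
    ev$alignment, tr, sites = match(s$polymorphic, seq_len(genome_length)))
  ch <- call_high_confidence_changes(rec, tr, positions = s$polymorphic)
  st <- build_site_table(g, s$census)
  st$stratum <- "all"
  tab <- tabulate_mutability(ch, st, stratum = "stratum",
                             collapse_couples = TRUE)
  configured <- vapply(mutation_couples(),
                       function(m) unname(cfg$base_rates[m[1]]),
                       numeric(1))
  est <- setNames(tab$rate, tab$type)[names(configured)]
  list(top_couple = tab$type[which.max(tab$rate)],
       spearman_rho = cor(configured, est, method = "spearman"),
       table = data.frame(couple = names(configured),
                          configured = unname(configured),
                          estimated = unname(est)))
}

#' Uniqueness-mask validation on planted-repeat fixtures
#'
#' Builds a 10 kb fixture with one exact duplication, checks that every
#' window fully inside either copy is masked, and compares the fast mask
#' with the brute-force all-shifts oracle on this fixture and on a
#' repeat-free one.
#'
#' @param seed Integer seed.
#' @return List: `dup_fully_masked`, `oracle_agreement` (both fixtures),
#'   `masked_bases`.
#' @export
mask_validation_run <- function(seed = 1L) {
  with_seed(stage_seed(seed, "mask_fix"), {
    base <- paste(sample(c("A", "C", "G", "T"), 9500, TRUE), collapse = "")
    dup <- substr(base, 3001, 3500)
    seq_dup <- paste0(substr(base, 1, 6000), dup,
                      substr(base, 6001, 9500))
    seq_free <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE),
                      collapse = "")
    f1 <- compute_uniqueness_mask(seq_dup)
    n1 <- naive_uniqueness_mask(seq_dup)
    f2 <- compute_uniqueness_mask(seq_free)
    n2 <- naive_uniqueness_mask(seq_free)
    win_inside <- function(lo, hi) {
      starts <- seq.int(lo, hi - 300 + 1, by = 10)
      starts <- starts[(starts - 1) %% 10 == 0]
      all(IRanges::overlapsAny(IRanges::IRanges(starts, width = 300), f1,
                               type = "within"))
    }
    dup_ok <- win_inside(3001, 3500) && win_inside(6001, 6500)
    list(dup_fully_masked = dup_ok,
         oracle_agreement = identical(as.data.frame(f1),
                                      as.data.frame(n1)) &&
           identical(as.data.frame(f2), as.data.frame(n2)) &&
           length(f2) == 0,
         masked_bases = sum(IRanges::width(f1)))
  })
}
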