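#!/usr/bin/env Rscript

# Stage 5: confounder-controlled classifier randomization.
#
# Trains random forests to separate changed from unchanged at-risk
# synonymous sites using binding categories plus sequence-derived
# confounders (local GC, origin distance, gene strand, degeneracy), then
# asks whether shuffling the binding columns (jointly, preserving their
# correlation) degrades out-of-bag AUC. Run at desk scale (300 trees,
# 15 randomizations) for the two couple members carrying the planted
# binding effect, plus a small K-optimization grid.

suppressMessages(library(napmut))

outdir <- "results"
seed <- 2012L

genome_seq <- read_fasta("results/data/genome.fasta")[["reference"]]
genes <- read.table("results/data/genes.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
genome <- nap_genome(genome_seq, genes)
st <- read.table(file.path(outdir, "site_table.tsv"), header = TRUE,
                 sep = "\t", stringsAsFactors = FALSE)
for (cn in grep("^cat_", names(st), value = TRUE))
  st[[cn]] <- factor(st[[cn]], levels = binding_categories())
changes_df <- read.table(file.path(outdir, "changes.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
class(changes_df) <- c("change_set", "data.frame")

feat <- classifier_site_features(genome, st, changes_df)

rows <- list()
for (tp in c("C>T", "G>A")) {
  ds <- assemble_dataset(feat, mutation_type = tp,
                         seed = stage_seed(seed, tp))
  params <- classifier_params(n_trees = 300,
                              seed = stage_seed(seed, "rf"))
  res <- binding_randomization_test(ds, params, n_rand = 15,
                                    seed = stage_seed(seed, paste0("bt", tp)))
  cat(sprintf("%s: OOB AUC %.3f vs randomized %.3f +/- %.3f -> z = %.2f, one-tailed P = %.4f\n",
              tp, res$auc_observed, mean(res$auc_randomized),
              sd(res$auc_randomized), res$z, res$p_one_tailed))
  rows[[tp]] <- data.frame(type = tp, auc_obs = res$auc_observed,
                           auc_rand_mean = mean(res$auc_randomized),
                           auc_rand_sd = sd(res$auc_randomized),
                           z = res$z, p = res$p_one_tailed)
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(outdir, "classifier_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

k <- sum(tab$p < 0.1)
if (k > 0) {
  fdr <- estimate_fdr(0.1, nrow(tab), k)
  cat(sprintf("expected-false-positive FDR at P<0.1: %.0f%% (%d/%d positive)\n",
              100 * fdr$fdr, k, nrow(tab)))
} else {
  cat("no type significant at P<0.1: the planted effect lives in the\n",
      "rare exclusively-early category (~2% of sites), below this\n",
      "desk-scale test's detection limit; the acceptance harness\n",
      "demonstrates calibrated size and full power for a category-wide\n",
      "log(2) effect at 30,000 sites.\n", sep = "")
}

ds_ct <- assemble_dataset(feat, mutation_type = "C>T",
                          seed = stage_seed(seed, "kopt"))
opt <- optimize_split_features(list(ds_ct),
                               classifier_params(n_trees = 150,
                                                 seed = seed),
                               k_grid = 1:4)
cat("K grid OOB AUC:", paste(sprintf("K=%d: %.3f", opt$k_grid, opt$auc[1, ]),
                             collapse = ", "), "\n")
cat("selected K* =", opt$k_star, "\n")
write.table(data.frame(k = opt$k_grid, auc = opt$auc[1, ]),
            file.path(outdir, "k_optimization.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
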