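#!/usr/bin/env Rscript

# Stage 3: stratified mutability and odds ratios.
#
# Joins the change calls to the at-risk census, assigns every site its
# binding category per NAP (always/early/late/never/other), the any-NAP
# bound flag and exclusive-timing flags, then tabulates changes per
# nucleotide at risk at 4-fold synonymous sites: bound-vs-unbound couples
# with odds ratios (values > 1 = higher mutability unbound), and
# exclusively-early vs exclusively-late odds ratios per protein (values
# > 1 = higher mutability early-bound). The simulation planted a 2x C>T
# effect in early-bound and 0.5x in late-bound sequence, so C:G>T:A is
# the couple to watch.

suppressMessages(library(napmut))

data_dir <- "results/data"
outdir <- "results"

genome_seq <- read_fasta(file.path(data_dir, "genome.fasta"))[["reference"]]
genes <- read.table(file.path(data_dir, "genes.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
genome <- nap_genome(genome_seq, genes)
profiles <- load_binding_profiles(file.path(data_dir, "beds"),
                                  genome_length = genome$length)
census <- read.table(file.path(outdir, "census.tsv"), header = TRUE,
                     sep = "\t")$position
changes <- read.table(file.path(outdir, "changes.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
ctx <- scan_methylation_contexts(genome_seq)

st <- build_site_table(genome, census, profiles, ctx)
write.table(st, file.path(outdir, "site_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tab_any <- tabulate_mutability(changes, st, stratum = "bound_any",
                               collapse_couples = TRUE)
write.table(tab_any, file.path(outdir, "mutability_bound_vs_unbound.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("couple-level mutability at 4-fold sites (changes per site at risk):\n")
print(tab_any, row.names = FALSE)

or_rows <- list()
for (cp in names(mutation_couples())) {
  b <- tab_any[tab_any$type == cp & tab_any$stratum == "bound", ]
  u <- tab_any[tab_any$type == cp & tab_any$stratum == "unbound", ]
  if (nrow(b) == 0 || nrow(u) == 0) next
  o <- odds_ratio_ci(b$n_changes, b$n_at_risk, u$n_changes, u$n_at_risk,
                     orientation = "unbound vs bound")
  o$type <- cp
  or_rows[[cp]] <- o
}
or_any <- do.call(rbind, or_rows)
write.table(or_any, file.path(outdir, "or_bound_vs_unbound.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

timing_rows <- list()
for (key in protein_key(names(profiles$profiles))) {
  tc <- paste0("timing_", key)
  tab_t <- suppressWarnings(
    tabulate_mutability(changes, st, stratum = tc, collapse_couples = TRUE))
  e <- tab_t[tab_t$type == "C:G>T:A" & tab_t$stratum == "exclusively_early", ]
  l <- tab_t[tab_t$type == "C:G>T:A" & tab_t$stratum == "exclusively_late", ]
  if (nrow(e) == 0 || nrow(l) == 0) next
  o <- odds_ratio_ci(l$n_changes, l$n_at_risk, e$n_changes, e$n_at_risk,
                     orientation = "exclusively_early vs exclusively_late")
  o$protein <- key
  timing_rows[[key]] <- o
}
or_timing <- do.call(rbind, timing_rows)
write.table(or_timing, file.path(outdir, "or_timing.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nC:G>T:A odds ratios, exclusively early vs late bound:\n")
print(or_timing, row.names = FALSE)
cat("\n(planted effect: early 2x, late 0.5x -> true early/late OR = 4",
    "for the focal protein hns; other proteins dilute toward 1)\n")
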