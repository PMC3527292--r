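#!/usr/bin/env Rscript

# Stage 4: 5-methylcytosine context analysis.
#
# The second cytosine of CCWGG is Dcm-methylated; its deamination drives
# C>T hotspots that the VSP repair pathway corrects mainly during
# stationary phase. The simulation planted a 6x hotspot multiplier at
# CCWGG focal cytosines. This stage censuses CCWGG and CCWHH control
# focal sites on both strands, computes context-resolved mutability per
# protein and exclusive-timing stratum, and runs the preserved-totals
# permutation test for the joint pattern (CCWGG: late > early; control:
# late < early across the three NAPs with late-phase binding).

suppressMessages(library(napmut))

outdir <- "results"
st <- read.table(file.path(outdir, "site_table.tsv"), header = TRUE,
                 sep = "\t", stringsAsFactors = FALSE)
changes <- read.table(file.path(outdir, "changes.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
genome_seq <- read_fasta("results/data/genome.fasta")[["reference"]]

ctx <- scan_methylation_contexts(genome_seq)
cat(sprintf("contexts: %d CCWGG focal sites, %d CCWHH controls\n",
            sum(ctx$motif == "CCWGG"), sum(ctx$motif == "control")))

timing_cols <- c("position", grep("^timing_", names(st), value = TRUE))
ctx_tab <- context_mutability(ctx, changes, st[timing_cols])
write.table(ctx_tab, file.path(outdir, "context_mutability.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cc <- combo_counts(ctx_tab)
write.table(cc, file.path(outdir, "combo_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(cc, row.names = FALSE)

ob <- observed_conformity_pattern(cc)
if (anyNA(ob)) {
  cat("\nsome NAP+context combos have zero exclusively-bound contexts;\n",
      "the joint permutation test is unevaluable on this simulation\n")
} else {
  cat("\nobserved conformity:", paste(names(ob), ob, collapse = "; "), "\n")
  cat(sprintf("%d/6 combos conform to the late-hotspot pattern.\n",
              sum(ob)))
  cat("The simulation plants the CCWGG multiplier uniformly across\n",
      "timing strata (no context-by-timing interaction), so conformity\n",
      "at chance level is the expected outcome here.\n", sep = "")
  perm <- permutation_pvalue(cc, n_reps = 100000, seed = 2012)
  cat(sprintf(paste0("Under the preserved-totals null, P(all six conform)",
                     " = %.4f (%d/%d reps)\n"),
              perm$p_value, perm$n_all_conform, perm$n_reps))
  cat("-- the bar a genuine joint pattern must clear.\n")
  jsonlite::write_json(list(p_all_conform = perm$p_value,
                            n_reps = perm$n_reps,
                            n_observed_conforming = sum(ob),
                            observed_conformity = as.list(ob)),
                       file.path(outdir, "permutation.json"),
                       auto_unbox = TRUE)
}
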