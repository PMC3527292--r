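#!/usr/bin/env Rscript

# Stage 2: reconstruct the history of nucleotide changes.
#
# Loads the simulated inputs from results/data/, masks non-unique genome
# regions (300 nt windows, 10 nt offset, <= 2 mismatches), filters
# alignment columns (no gaps, ingroup-polymorphic, unmasked), reconstructs
# marginal ancestral states under an HKY model estimated from the data,
# and calls high-confidence changes with the three filters (single event,
# posterior >= 0.9, no dependence on nodes below 98% support). Because the
# truth is known, the script also reports recall and precision.

suppressMessages(library(napmut))

data_dir <- "results/data"
outdir <- "results"

aln <- read_alignment(file.path(data_dir, "alignment.fasta"),
                      file.path(data_dir, "blocks.tsv"))
tree <- ape::read.tree(file.path(data_dir, "tree.nwk"))
genome_seq <- read_fasta(file.path(data_dir, "genome.fasta"))[["reference"]]

mask <- compute_uniqueness_mask(genome_seq)
cat(sprintf("uniqueness mask: %d bases (%.2f%% of genome)\n",
            sum(IRanges::width(mask)),
            100 * sum(IRanges::width(mask)) / nchar(genome_seq)))

sites <- extract_analyzable_sites(aln, mask)
cat(sprintf("analyzable census: %d sites, %d ingroup-polymorphic\n",
            length(sites$census), length(sites$polymorphic)))

recon <- marginal_ancestral_reconstruction(
  aln, tree, sites = match(sites$polymorphic, alignment_ref_positions(aln)))
changes <- call_high_confidence_changes(recon, tree,
                                        positions = sites$polymorphic)
write.table(changes, file.path(outdir, "changes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(position = sites$census, ref_base = sites$ref_base),
            file.path(outdir, "census.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.table(file.path(data_dir, "truth.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
tk <- with(truth, paste(site, branch, from, to))
ck <- with(changes, paste(position, branch, from, to))
cat(sprintf("called %d changes; recall %.3f, precision %.3f\n",
            nrow(changes), mean(tk %in% ck), mean(ck %in% tk)))
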