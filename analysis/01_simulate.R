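#!/usr/bin/env Rscript

# Stage 1: simulate the study system.
#
# Generates a strain phylogeny, an annotated genome, growth-phase-resolved
# binding profiles for the four NAPs, and an alignment evolved with
# growth-phase-dependent binding effects: early-bound sequence (focal
# protein H-NS) carries doubled C>T/G>A rates, late-bound sequence halved
# rates, and CCWGG focal cytosines a 6-fold C>T hotspot multiplier.
# All inputs plus the ground-truth change list land in results/data/.

suppressMessages(library(napmut))

outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 2012L

be <- matrix(1, 5, 12, dimnames = list(binding_categories(),
                                       mutation_types()))
be["early", c("C>T", "G>A")] <- 2
be["late", c("C>T", "G>A")] <- 0.5

cfg <- sim_config(genome_length = 120000, n_genes = 100, n_strains = 8,
                  binding_fraction = 0.08, interphase_overlap = 0.5,
                  binding_effect = be, focal_protein = "H-NS",
                  ccwgg_multiplier = 6, seed = seed)

tree <- make_strain_tree(cfg$n_strains, seed = stage_seed(seed, "tree"),
                         branch_mean = cfg$branch_mean,
                         outgroup_scale = cfg$outgroup_scale)
genome <- simulate_genome(cfg)
profiles <- simulate_binding_profiles(genome, cfg)
ev <- evolve_alignment(genome, tree, profiles, cfg)

write_fasta(setNames(genome$sequence, "reference"),
            file.path(outdir, "genome.fasta"))
write_alignment(ev$alignment, file.path(outdir, "alignment.fasta"),
                file.path(outdir, "blocks.tsv"))
ape::write.tree(tree, file.path(outdir, "tree.nwk"))
write_binding_beds(profiles, file.path(outdir, "beds"))
write_gene_table(genome, file.path(outdir, "genes.tsv"))
write.table(ev$truth$changes, file.path(outdir, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cov <- binding_coverage_summary(profiles)
cat(sprintf("genome: %d bp, %d genes, %d fourfold sites\n",
            genome$length, nrow(genome$genes),
            sum(genome$sites$site_class == "fourfold")))
cat(sprintf("binding coverage per (protein, phase): %.1f%% (target 8%%)\n",
            100 * mean(cov$fraction)))
cat(sprintf("true changes placed on the tree: %d\n",
            nrow(ev$truth$changes)))
cat(sprintf("interphase sharing H-NS stationary->transition: %.2f\n",
            measure_interphase_overlap(profiles, "H-NS", "transition",
                                       "stationary")))
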