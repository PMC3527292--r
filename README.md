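# napmut

Growth phase-resolved effects of nucleoid-associated protein (NAP)
binding on sequence mutability in bacteria.

## The problem

Four abundant *E. coli* NAPs — Fis, H-NS, IhfA and IhfB — occupy large,
growth-phase-dependent portions of the chromosome. Bound protein can
shield DNA from mutagens, but it can also block repair enzymes; which
effect dominates should depend on *when* the protein is bound relative to
when damage and repair happen across the growth cycle (mid-exponential,
late exponential, transition to stationary, stationary). `napmut` is for
researchers in molecular evolution who want to measure this from
comparative data: it reconstructs single-nucleotide changes across a
strain phylogeny, labels every at-risk nucleotide with growth-phase
binding categories, and contrasts mutability across those categories with
confounder controls.

Mutability of a stratum is

```
m(type, stratum) = n_changes(type, stratum) / n_at_risk(type, stratum)
```

changes per nucleotide at risk, where an at-risk nucleotide for, say,
C>T is every C in the same site class (4-fold synonymous by default) and
stratum. Strata are contrasted by odds ratios with Woolf 95% CIs
(Haldane–Anscombe corrected), binding-category information is tested by
a random-forest binding-randomization Z-test (out-of-bag AUC, one-tailed
P), and 5-methylcytosine deamination hotspots (the second C of Dcm's
CCWGG motif, against CCWHH controls) get a dedicated preserved-totals
permutation test with an exact enumeration oracle.

Every stage is paired with a synthetic-data generator (tree, genome,
binding profiles, evolved alignment, direct logistic site tables) with
recorded ground truth, so the whole pipeline runs and is tested without
any external data.

## Worked example

Simulate a small system, call changes, and estimate a planted binding
effect (early-bound C>T/G>A rates doubled for H-NS):

```r
library(napmut)

be <- matrix(1, 5, 12, dimnames = list(binding_categories(),
                                       mutation_types()))
be["early", c("C>T", "G>A")] <- 2
cfg <- sim_config(genome_length = 50000, n_genes = 40, n_strains = 8,
                  binding_fraction = 0.12, interphase_overlap = 0.25,
                  binding_effect = be, focal_protein = "H-NS", seed = 7)
tree     <- make_strain_tree(8, seed = 7)
genome   <- simulate_genome(cfg)
profiles <- simulate_binding_profiles(genome, cfg)
ev       <- evolve_alignment(genome, tree, profiles, cfg)

sites <- extract_analyzable_sites(ev$alignment)
recon <- marginal_ancestral_reconstruction(
  ev$alignment, tree, sites = sites$polymorphic)
chg   <- call_high_confidence_changes(recon, tree,
                                      positions = sites$polymorphic)

st  <- build_site_table(genome, sites$census, profiles)
tab <- tabulate_mutability(chg, st, stratum = "cat_hns",
                           site_classes = c("fourfold", "twofold",
                                            "coding_other", "intergenic"))
tab[tab$type == "C>T" & tab$stratum %in% c("early", "never"), ]
```

```
 type stratum n_changes n_at_risk       rate
  C>T   never       109      3807 0.02863147
  C>T   early        42       593 0.07082631
```

Early-bound cytosines changed to T at roughly 2.5 times the rate of
never-bound ones in this replicate (the planted effect is 2x); the odds
ratio quantifies it with its uncertainty:

```r
e <- tab[tab$type == "C>T" & tab$stratum == "early", ]
n <- tab[tab$type == "C>T" & tab$stratum == "never", ]
odds_ratio_ci(n$n_changes, n$n_at_risk, e$n_changes, e$n_at_risk,
              orientation = "early vs never")
```

```
       or   ci_low ci_high    orientation undefined
 2.586057 1.791578 3.73285 early vs never     FALSE
```

The point estimate sits above the planted odds ratio of 2 in this single
replicate, but the 95% interval covers it; the acceptance harness checks
that coverage holds at the nominal rate over 200 replicates.

The full narrative workflow lives in `analysis/01_simulate.R` through
`analysis/05_classifier.R`: simulation with growth-phase- and
context-dependent effects, uniqueness masking and change calling with
recall/precision against the recorded truth, bound-vs-unbound and
early-vs-late odds ratios, the CCWGG/CCWHH permutation test, and the
classifier randomization with the 15% expected-false-positive FDR
worked example. Each script reads its inputs from `results/` and writes
its tables back there.

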