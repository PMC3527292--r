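---
title: "Methods: growth phase-resolved NAP binding and sequence mutability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth phase-resolved NAP binding and sequence mutability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Abundant bacterial nucleoid-associated proteins (NAPs) — Fis, H-NS, IhfA
and IhfB in *E. coli* — coat substantial fractions of the chromosome, and
their binding landscapes change radically across the growth cycle
(mid-exponential, late exponential, transition to stationary, stationary).
Protein occupancy can shield DNA from mutagens but can also obstruct
repair enzymes, and which force wins should depend on *when* the protein
sits on the DNA relative to when damage and repair occur. `napmut`
implements an analysis that asks this question with comparative data:
changes are reconstructed across a phylogeny of closely related strains,
every at-risk nucleotide is labelled with growth-phase-resolved binding
categories, and mutability — changes per nucleotide at risk — is
contrasted across binding strata, with a classifier-based control for
confounders and a dedicated test for 5-methylcytosine deamination
hotspots (CCWGG).

Because the original inputs (54 genomes, ChIP-Seq binding calls) are
large external datasets, the package pairs every analysis stage with a
synthetic-data generator that produces all inputs with known ground
truth. All validation claims below are therefore statements about
recovery of simulated truth or agreement with exact oracles, not about
real *E. coli* data.

## Pipeline stages and their models

### Uniqueness mask

Binding calls from short reads require unique mappability, so genomic
regions whose 300 nt windows (offset 10 nt) match a second locale on
either strand with at most 2 mismatches are excluded. The implementation
uses the pigeonhole principle: a window within 2 mismatches of another
locale must share one of its three 100-mer chunks exactly; exact chunk
hits (Aho–Corasick via `Biostrings::matchPDict`) are then verified by
full-window Hamming distance. A quadratic all-shifts scan
(`naive_uniqueness_mask`) serves as the brute-force oracle in tests.

### Site filters

Analyzable columns contain no gap or ambiguity in any strain (outgroup
included) and do not overlap the mask; they form the at-risk census used
for denominators. Polymorphic sites additionally vary within the ingroup
— a column where only the outgroup differs counts in the census but is
not polymorphic, which polarizes changes and avoids counting events on
the outgroup lineage.

### Ancestral reconstruction

Marginal posteriors for every internal node are computed exactly under a
reversible substitution model: a Felsenstein pruning pass for inside
partial likelihoods and a pre-order outside pass, combined per node and
normalized. JC, K80, HKY and GTR are available; the default is HKY with
empirical base frequencies and a transition/transversion ratio set by
method of moments from pairwise mismatch counts. The model is
deliberately lightweight — at the low divergences this analysis targets,
posterior ancestral states are extremely insensitive to the model, and
the test suite verifies posteriors against exhaustive enumeration over
all joint ancestral assignments (max abs difference < 1e-10 on random
trees with up to 6 leaves). Which substitution model the original
likelihood reconstruction used is not documented; HKY-by-moments is this
package's choice.

### Change calling (three filters)

A high-confidence change requires:

1. **Single event**: the site's minimal parsimony count is exactly 1,
   computed with Hartigan's generalization of Fitch counting (exact on
   polytomies, which the support filter creates). Ancestral ties break
   toward the outgroup state, mirroring outgroup rooting.
2. **Posterior**: the ancestral node of the implicated branch supports
   the ancestral base with marginal posterior >= 0.9.
3. **Support**: all internal nodes with bootstrap support below 98 are
   collapsed into polytomies; the change is retained only if the event
   count is still 1 and the implicated branch (same child node, same
   descendant leaf set) is unchanged. "Not dependent on poorly supported
   topology" admits several readings; collapse-and-recompute is the
   conservative one adopted here.

Events whose single change would sit ambiguously on either side of the
root are discarded: their direction would be an artifact of rooting.
Raising either threshold can only shrink the change set (tested as a
property).

### Stratified mutability and odds ratios

Mutability is `n_changes / n_at_risk` per (mutation type x stratum),
where at-risk sites share the focal base, site class and stratum.
Strand-specific types are expressed on the sense (non-transcribed) strand
of the containing gene; intergenic sites have no defined sense strand and
enter only the strand-collapsed couple summaries, in which each duplex
site is counted once under its pyrimidine label. 4-fold synonymous sites
are the default site class (2-fold sites can be added for transitions).
Odds ratios use Woolf's log-scale 95% interval with the Haldane–Anscombe
+0.5 correction when a cell is empty; the original analysis does not name
its CI method, so this choice is the package's own. Coverage of the
interval is verified by simulation: with a planted odds ratio of 2 and
2 x 10^5-site replicates, 95% CI coverage must land in [93%, 97%] over
200 replicates.

### CCWGG context analysis and permutation test

Dcm methylates the second cytosine of CCWGG (W = A/T); deamination of
5-meC yields T:G mismatches repaired by the VSP pathway, which is active
mainly in stationary phase. Both strands are scanned (the motif class is
its own reverse complement, so focal cytosines come in strand pairs);
CCWHH (H = A/C/T) occurrences are the neighbourhood-matched controls and
never double-count as CCWGG. The joint pattern of interest is: CCWGG
mutability higher in exclusively-late-bound than exclusively-early-bound
sequence, and the reverse for controls, across H-NS, IhfA and IhfB. The
significance test preserves each combo's total mutation count and
reallocates every mutation independently to late/early with probability
proportional to the contexts at risk (binomial allocation — the
description of the original procedure implies no without-replacement
constraint). P is the add-one-corrected fraction of 100,000 replicates
in which all six combos conform; conformity uses strict inequalities, so
ties count against the pattern (the conservative reading; tie handling
is not documented in the source analysis). An exact enumeration oracle
(`exact_pvalue_oracle`, product of per-combo binomial tail sums) verifies
the sampler on every enumerable fixture.

One property one might expect — that adding late-CCWGG mutations can
only decrease P — is actually false for this null: the reallocation
distribution depends on the observed data only through per-combo totals,
and the all-conform probability is non-monotone in a total (with equal
contexts and strict conformity the single-combo values are 0.5, 0.25,
0.5 for totals 1, 2, 3 — a parity effect). The tested invariant is the
true one: P depends on the counts only through totals and contexts.

### Classifier randomization

To ask whether binding carries information about mutability that
confounders cannot reproduce, a random forest discriminates changed from
unchanged at-risk sites using binding categories plus confounders. The
published settings are kept as defaults: unchanged class subsampled to
exactly 5:1 (changed class intact), 10,000 trees, depth cap 10, K = 2
features per split, 5:1 minority class weight, out-of-bag AUC as the
score. K is optimized by min–max normalizing each dataset's AUC-vs-K
profile to [0, 1], averaging across datasets and taking the argmax (ties
to the smallest K). Significance comes from refitting with the binding
columns shuffled; all binding columns are shuffled as one block with a
single row permutation, because shuffling them independently would
destroy inter-protein correlation and overstate binding information
(whether the original shuffle was joint or per-column is not documented;
the joint version is default and the choice is localized in
`binding_randomization_test`). The Z-score of the observed AUC against
the randomized AUCs yields a one-tailed P (upper tail: only a drop upon
randomization is meaningful). The worked false-discovery example — six
tests, four below P < 0.1 — gives FDR = 0.6/4 = 15% via
`estimate_fdr()`.

## The synthetic-data generator

The generator defines the study conditions under which all recovery
claims are made:

* **Tree**: rooted binary, exponential ingroup branch lengths (mean
  0.02 substitutions/site), one outgroup attached at the root on short
  edges (0.2x the mean). Events on the two root-incident edges produce
  no ingroup polymorphism and are invisible to any method; a close
  outgroup keeps the simulated truth observable while preserving
  polarization. Bootstrap supports are a two-component mixture (98–100
  high, 50–97 low) so the support filter has both classes to act on.
* **Genome**: random sequence at configurable GC, non-overlapping genes
  of 300–900 bp on random strands, degeneracy classified from the
  standard genetic code. Coordinates are 0-based half-open in emitted
  BED, 1-based closed internally.
* **Binding**: per (protein, phase) interval sets with geometric lengths
  (mean 200 bp — the real interval length distribution is not published;
  this default is an explicit free parameter). Each earlier phase reuses
  a configured fraction of the adjacent later phase's bound bases, so
  sharing decays with temporal distance as observed in the real
  profiles; Fis exists only in the two exponential phases. Fresh
  intervals avoid all other phases of the same protein, making the
  realized sharing equal the configured value to within a base or two.
* **Evolution**: at most one Bernoulli event per site per branch, with
  probability `base_rate(type) x branch_length x binding_modifier x
  CCWGG multiplier`; the error raised above per-branch probability 0.5
  marks the exit from the single-event regime the downstream filters
  assume. Default rates are transition-biased with C:G>T:A dominant and
  distinct values per couple. Contexts are defined on the ancestral
  genome (context drift is negligible at these rates). Because
  modifiers multiply the rate, the implied true odds ratio between
  binding strata is exactly the modifier ratio.
* **Site-table shortcut**: classifier and odds-ratio studies draw
  outcomes directly from a logistic model over independent features
  (binding category, per-phase log-normal expression, replication
  strand, origin distance, local GC, degeneracy), so the true odds
  ratio of a category is exactly the exponentiated coefficient.
  Independence of features is a deliberate simplification: real
  confounders correlate with binding, which is precisely why the
  classifier control exists; the generator's role here is calibration,
  not realism.

What passing these tests shows — and does not show: recovery works under
the generator's assumptions (no recombination, no indels, no rate
heterogeneity beyond the configured modifiers, single reference
coordinate system). Real data violate several of these; the original
filters exist exactly to blunt such violations, and their behaviour
under recombination or alignment error is not certified by this suite.

## Problem sizes used in validation

Chosen as the package's validation conditions: 200 random fixtures
(<= 6 leaves) for the reconstruction oracle; one 50 kb, 8-strain run for
change-calling recovery (recall >= 0.9, precision >= 0.95); 200
replicates of 1.2 x 10^5 sites for CI coverage; 100,000 replicates for
the permutation sampler checks; 40 null runs (4,000 sites, 150 trees,
25 randomizations) for the size of the randomization test and 20 runs
(30,000 sites, 500 trees, log 2 binding coefficient) for its power. The
power harness uses 10 randomizations per run (6 in the standalone
acceptance script): under a real signal the observed AUC sits many
standard deviations above the randomized distribution, so the spread
estimate needs little precision;
one 200 kb run for spectrum rank recovery (Spearman rho > 0.9 over the
six couples). The full-scale defaults (10,000 trees, 50 randomizations,
100,000 permutation replicates) remain the exported defaults.

## Known limitations

* Marginal (not joint) reconstruction; no among-site rate heterogeneity.
* The collapse reading of the support filter is one interpretation of an
  ambiguous rule; it is not claimed to reproduce the original
  bookkeeping exactly.
* The recode of mixed binding patterns to `other` discards complex but
  potentially genuine binding behaviour; `other` is retained as a
  first-class category in classifier features and excluded only from the
  four-category univariate contrasts.
* Intergenic strand-specific summaries are undefined by construction;
  intergenic sites appear only at couple level.
* The synthetic permutation-test P on generator output is not comparable
  to any published value, which depends on the real change set.
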