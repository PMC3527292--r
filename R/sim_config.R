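#' Default per-type substitution rates
#'
#' Rates are probabilities of change per site per unit of branch length,
#' before binding and context modifiers. The default spectrum is
#' transition-biased with C:G>T:A clearly dominant, mirroring the rank
#' order seen in mutation-accumulation assays, and with distinct values
#' per couple so rank recovery is well defined.
#'
#' @return Named numeric vector over [mutation_types()].
#' @export
default_base_rates <- function() {
  r <- c(
    "C>T" = 0.100, "G>A" = 0.100,
    "A>G" = 0.050, "T>C" = 0.050,
    "C>A" = 0.030, "G>T" = 0.030,
    "A>T" = 0.018, "T>A" = 0.018,
    "C>G" = 0.010, "G>C" = 0.010,
    "A>C" = 0.004, "T>G" = 0.004
  )
  r[mutation_types()]
}

#' Binding categories used for rate modification and classification
#' @return Character vector of the five per-protein binding categories.
#' @export
binding_categories <- function() c("always", "early", "late", "never", "other")

#' Build a simulation configuration
#'
#' Collects and validates every tunable of the synthetic-data generator:
#' genome and gene structure, strain number, binding interval structure per
#' protein and growth phase, per-type base substitution rates, multiplicative
#' binding-category and CCWGG-context rate modifiers, and the seed.
#'
#' @param genome_length Genome size in bp (circular), >= 1000.
#' @param n_genes Number of non-overlapping protein-coding genes.
#' @param n_strains Number of ingroup strains (>= 3); one outgroup is added.
#' @param phase_names The four growth-phase labels, in temporal order.
#' @param proteins NAP names. Fis receives profiles only for the two
#'   exponential phases.
#' @param binding_fraction Target bound fraction of the genome per
#'   (protein, phase).
#' @param interphase_overlap Fraction of a phase's bound bases reused from
#'   the temporally adjacent later phase; sharing between distant phases
#'   decays as the product along the chain.
#' @param interval_mean_length Mean binding-interval length in bp
#'   (geometric lengths).
#' @param base_rates Named numeric vector over [mutation_types()];
#'   probability of change per site per unit branch length.
#' @param binding_effect Multiplicative rate modifier per binding category of
#'   `focal_protein`. Either a named vector over [binding_categories()]
#'   (applied to all types) or a categories x types matrix.
#' @param focal_protein Protein whose binding category modulates rates in
#'   [evolve_alignment()].
#' @param ccwgg_multiplier Rate multiplier for C>T at CCWGG focal cytosines
#'   (strand-resolved; G>A on the reference strand for minus-strand focals).
#' @param gene_length_range Min/max gene length in bp (rounded to codons).
#' @param gc Genome GC content of the ancestral sequence.
#' @param branch_mean Mean ingroup branch length (substitution-model units).
#' @param outgroup_scale Length of the outgroup and ingroup stem edges
#'   relative to `branch_mean`.
#' @param low_support_fraction Fraction of internal nodes drawn from the
#'   low-support component (50-97) rather than the high one (98-100).
#' @param seed Integer seed.
#' @return An object of class `sim_config` (validated list).
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 20000, n_genes = 15, n_strains = 6)
sim_config <- function(genome_length = 50000,
                       n_genes = 40,
                       n_strains = 8,
                       phase_names = growth_phases(),
                       proteins = nap_proteins(),
                       binding_fraction = 0.05,
                       interphase_overlap = 0.5,
                       interval_mean_length = 200,
                       base_rates = default_base_rates(),
                       binding_effect = NULL,
                       focal_protein = "H-NS",
                       ccwgg_multiplier = 1,
                       gene_length_range = c(300, 900),
                       gc = 0.5,
                       branch_mean = 0.02,
                       outgroup_scale = 0.2,
                       low_support_fraction = 0,
                       seed = 1L) {
  if (length(phase_names) != 4L)
    stop("phase_names must have exactly 4 entries")
  if (!setequal(names(base_rates), mutation_types()) ||
      length(base_rates) != 12L)
    stop("base_rates must be named over the 12 mutation types")
  if (any(base_rates < 0)) stop("base_rates must be >= 0")
  props <- c(binding_fraction, interphase_overlap, gc, low_support_fraction)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]")
  if (genome_length < 1000) stop("genome_length must be >= 1000")
  if (n_strains < 3) stop("n_strains must be >= 3")
  if (ccwgg_multiplier < 0) stop("ccwgg_multiplier must be >= 0")
  be <- normalize_binding_effect(binding_effect)
  if (any(be < 0)) stop("binding_effect modifiers must be >= 0")
  if (!focal_protein %in% proteins) stop("focal_protein must be one of proteins")
  cfg <- list(
    genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
    n_strains = as.integer(n_strains), phase_names = phase_names,
    proteins = proteins, binding_fraction = binding_fraction,
    interphase_overlap = interphase_overlap,
    interval_mean_length = interval_mean_length,
    base_rates = base_rates[mutation_types()], binding_effect = be,
    focal_protein = focal_protein, ccwgg_multiplier = ccwgg_multiplier,
    gene_length_range = gene_length_range, gc = gc,
    branch_mean = branch_mean, outgroup_scale = outgroup_scale,
    low_support_fraction = low_support_fraction, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Accepts NULL (all 1), a named vector over categories, or a full
# categories x types matrix; returns the 5 x 12 matrix form.
normalize_binding_effect <- function(binding_effect) {
  cats <- binding_categories()
  types <- mutation_types()
  if (is.null(binding_effect)) {
    m <- matrix(1, length(cats), length(types), dimnames = list(cats, types))
    return(m)
  }
  if (is.matrix(binding_effect)) {
    if (!setequal(rownames(binding_effect), cats) ||
        !setequal(colnames(binding_effect), types))
      stop("binding_effect matrix must be categories x mutation types")
    return(binding_effect[cats, types])
  }
  if (is.null(names(binding_effect)) ||
      !all(names(binding_effect) %in% cats))
    stop("binding_effect vector must be named by binding categories")
  v <- setNames(rep(1, length(cats)), cats)
  v[names(binding_effect)] <- binding_effect
  matrix(v, length(cats), length(types), dimnames = list(cats, types))
}

#' Implied true odds ratio between two binding strata
#'
#' Closed form on the configured per-branch change probabilities: the
#' modifiers act multiplicatively on the rate, so the implied odds ratio of
#' one stratum against another is the ratio of their configured modifiers.
#'
#' @param config A [sim_config()].
#' @param type Mutation type, e.g. `"C>T"`.
#' @param numerator,denominator Binding categories contrasted.
#' @return Numeric odds ratio.
#' @export
implied_odds_ratio <- function(config, type, numerator, denominator) {
  stopifnot(inherits(config, "sim_config"))
  config$binding_effect[numerator, type] / config$binding_effect[denominator, type]
}
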