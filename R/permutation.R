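#' Build combo counts for the context permutation test
#'
#' One row per (NAP, motif class) combination with the mutation and
#' context-at-risk counts in the exclusively-early and exclusively-late
#' strata, as needed by [permutation_pvalue()].
#'
#' @param context_tab Output of [context_mutability()].
#' @param proteins Protein keys to include (default the three NAPs with
#'   late-phase binding).
#' @return data.frame of class `combo_counts`: protein, motif,
#'   n_mut_early, n_mut_late, n_ctx_early, n_ctx_late.
#' @export
combo_counts <- function(context_tab,
                         proteins = protein_key(c("H-NS", "IhfA", "IhfB"))) {
  rows <- list()
  for (pr in proteins) {
    for (motif in c("CCWGG", "control")) {
      sel <- context_tab$protein == pr & context_tab$motif == motif
      pick <- function(stratum, col) {
        v <- context_tab[sel & context_tab$stratum == stratum, col]
        if (length(v) == 0) 0L else as.integer(v)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein = pr, motif = motif,
        n_mut_early = pick("exclusively_early", "n_changes"),
        n_mut_late = pick("exclusively_late", "n_changes"),
        n_ctx_early = pick("exclusively_early", "n_contexts"),
        n_ctx_late = pick("exclusively_late", "n_contexts"))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("combo_counts", "data.frame")
  out
}

validate_combo_counts <- function(counts) {
  need <- c("protein", "motif", "n_mut_early", "n_mut_late",
            "n_ctx_early", "n_ctx_late")
  if (!all(need %in% names(counts))) stop("combo counts missing columns")
  if (any(counts$n_mut_early > counts$n_ctx_early) ||
      any(counts$n_mut_late > counts$n_ctx_late))
    stop("mutation counts exceed contexts at risk")
  if (any(counts[c("n_mut_early", "n_mut_late",
                   "n_ctx_early", "n_ctx_late")] < 0))
    stop("negative counts")
  counts
}

#' Conformity of each combo to the methylation-timing pattern
#'
#' A CCWGG combo conforms when its late-bound mutation rate strictly
#' exceeds its early-bound rate (deamination hotspots more mutable when
#' bound during stationary phase); a control combo conforms when the
#' late-bound rate is strictly lower. Ties never conform. Combos with zero
#' contexts in a stratum are unevaluable (NA).
#'
#' @param counts A `combo_counts` data.frame.
#' @return Logical vector, one element per combo row (NA = unevaluable).
#' @export
observed_conformity_pattern <- function(counts) {
  counts <- validate_combo_counts(counts)
  rate_e <- counts$n_mut_early / counts$n_ctx_early
  rate_l <- counts$n_mut_late / counts$n_ctx_late
  out <- ifelse(counts$motif == "CCWGG", rate_l > rate_e, rate_l < rate_e)
  out[counts$n_ctx_early == 0 | counts$n_ctx_late == 0] <- NA
  setNames(out, paste(counts$protein, counts$motif, sep = "/"))
}

# conformity of hypothetical late-mutation counts (vectorized over reps)
conform_vec <- function(m_late, m_tot, ctx_e, ctx_l, is_ccwgg) {
  rate_l <- m_late / ctx_l
  rate_e <- (m_tot - m_late) / ctx_e
  if (is_ccwgg) rate_l > rate_e else rate_l < rate_e
}

#' Monte-Carlo permutation P for the joint methylation-timing pattern
#'
#' Preserves each combo's total mutation count and reallocates every
#' mutation independently to the late-bound category with probability
#' `n_ctx_late / (n_ctx_early + n_ctx_late)` (binomial allocation by
#' context availability). The P value is the add-one-corrected fraction of
#' replicates in which all combos conform to the expected pattern:
#' `p = (n_all_conform + 1) / (n_reps + 1)`.
#'
#' @param counts A `combo_counts` data.frame.
#' @param n_reps Number of permutation replicates.
#' @param seed Integer seed.
#' @return List of class `permutation_result`: `observed_conformity`,
#'   `n_reps`, `n_all_conform`, `p_value`.
#' @export
permutation_pvalue <- function(counts, n_reps = 100000, seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  counts <- validate_combo_counts(counts)
  obs <- observed_conformity_pattern(counts)
  if (anyNA(obs)) stop("combo with zero contexts in a stratum: unevaluable")
  all_ok <- rep(TRUE, n_reps)
  with_seed(stage_seed(seed, "ccwgg_perm"), {
    for (i in seq_len(nrow(counts))) {
      m_tot <- counts$n_mut_early[i] + counts$n_mut_late[i]
      p_late <- counts$n_ctx_late[i] /
        (counts$n_ctx_early[i] + counts$n_ctx_late[i])
      m_late <- rbinom(n_reps, m_tot, p_late)
      all_ok <- all_ok & conform_vec(m_late, m_tot, counts$n_ctx_early[i],
                                     counts$n_ctx_late[i],
                                     counts$motif[i] == "CCWGG")
    }
  })
  k <- sum(all_ok)
  structure(list(observed_conformity = obs, n_reps = n_reps,
                 n_all_conform = k, p_value = (k + 1) / (n_reps + 1)),
            class = "permutation_result")
}

#' Exact probability that all combos conform (enumeration oracle)
#'
#' Sums binomial allocation probabilities over every joint outcome of the
#' per-combo late-mutation counts; combos are independent, so the joint
#' probability is the product of per-combo conform probabilities. Refuses
#' state spaces larger than 10^6 outcomes.
#'
#' @param counts A `combo_counts` data.frame.
#' @return Exact probability that every combo conforms.
#' @export
exact_pvalue_oracle <- function(counts) {
  counts <- validate_combo_counts(counts)
  m_tots <- counts$n_mut_early + counts$n_mut_late
  if (prod(m_tots + 1) > 1e6)
    stop("state space too large: ", prod(m_tots + 1), " outcomes")
  p_all <- 1
  for (i in seq_len(nrow(counts))) {
    m_tot <- m_tots[i]
    p_late <- counts$n_ctx_late[i] /
      (counts$n_ctx_early[i] + counts$n_ctx_late[i])
    m_late <- 0:m_tot
    ok <- conform_vec(m_late, m_tot, counts$n_ctx_early[i],
                      counts$n_ctx_late[i], counts$motif[i] == "CCWGG")
    p_all <- p_all * sum(dbinom(m_late[ok], m_tot, p_late))
  }
  p_all
}
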