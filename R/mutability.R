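#' Stratified mutability: changes per nucleotide at risk
#'
#' For every mutation type and stratum level, counts the observed changes
#' and the at-risk denominators (all sites of the type's ancestral base in
#' the same stratum and site class) and forms the rate. Strand-specific
#' types are expressed on the sense (non-transcribed) strand for genic
#' sites; intergenic sites have no defined sense strand and are excluded
#' from strand-specific summaries but enter couple-level ones. With
#' `collapse_couples = TRUE` the six complementary couples are tabulated on
#' the reference strand, each duplex site counted once.
#'
#' @param changes A `change_set` (reference-strand from/to).
#' @param sites A `site_table` covering the at-risk census; must use the
#'   same site filters as `changes`.
#' @param stratum Name of the stratum column in `sites` (e.g.
#'   `"bound_any"`, `"cat_hns"`, `"timing_hns"`); `NULL` for a single
#'   pooled stratum.
#' @param site_classes Site classes to include (default 4-fold synonymous;
#'   add `"twofold"` when analyzing transitions).
#' @param types Mutation types to tabulate (default all twelve, or the six
#'   couples when collapsing).
#' @param collapse_couples Tabulate strand-collapsed couples instead of
#'   strand-specific types.
#' @return data.frame: type, stratum, n_changes, n_at_risk, rate.
#'   Strata with empty denominators are omitted with a warning.
#' @export
tabulate_mutability <- function(changes, sites, stratum = NULL,
                                site_classes = "fourfold",
                                types = NULL,
                                collapse_couples = FALSE) {
  keep <- sites$site_class %in% site_classes
  st <- sites[keep, , drop = FALSE]
  strat <- if (is.null(stratum)) rep("all", nrow(st)) else
    as.character(st[[stratum]])
  ch <- changes[changes$position %in% st$position, , drop = FALSE]
  idx <- match(ch$position, st$position)
  ch_strat <- strat[idx]
  rows <- list()
  if (collapse_couples) {
    couples <- mutation_couples()
    types <- types %||% names(couples)
    ref_type <- paste0(ch$from, ">", ch$to)
    pyr_base <- ifelse(st$base %in% c("C", "G"), "C:G", "A:T")
    for (cp in types) {
      members <- couples[[cp]]
      duplex <- sub(">.*", "", cp)  # "C:G" or "A:T"
      for (lev in unique(strat)) {
        n_at_risk <- sum(pyr_base == duplex & strat == lev)
        if (n_at_risk == 0) {
          warning("empty denominator for ", cp, " / ", lev, "; omitted")
          next
        }
        n_changes <- sum(ref_type %in% members & ch_strat == lev)
        rows[[length(rows) + 1L]] <- data.frame(
          type = cp, stratum = lev, n_changes = n_changes,
          n_at_risk = n_at_risk, rate = n_changes / n_at_risk)
      }
    }
  } else {
    types <- types %||% mutation_types()
    genic <- !is.na(st$sense_strand)
    # changes re-expressed on the sense strand of their gene
    ch_genic <- genic[idx]
    ch_sense <- ifelse(st$sense_strand[idx] == "-",
                       paste0(complement_base(ch$from), ">",
                              complement_base(ch$to)),
                       paste0(ch$from, ">", ch$to))
    for (tp in types) {
      from_b <- substr(tp, 1, 1)
      for (lev in unique(strat)) {
        n_at_risk <- sum(genic & st$sense_base == from_b & strat == lev)
        if (n_at_risk == 0) {
          warning("empty denominator for ", tp, " / ", lev, "; omitted")
          next
        }
        n_changes <- sum(ch_genic & ch_sense == tp & ch_strat == lev,
                         na.rm = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          type = tp, stratum = lev, n_changes = n_changes,
          n_at_risk = n_at_risk, rate = n_changes / n_at_risk)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), stratum = character(0),
               n_changes = integer(0), n_at_risk = integer(0),
               rate = numeric(0))
  class(out) <- c("mutability_estimates", "data.frame")
  out
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = [c2/(n2-c2)] / [c1/(n1-c1)]`, stratum 2 being the contrast's
#' numerator (e.g. unbound sequence, or early-bound in timing contrasts).
#' When any contingency cell is zero the Haldane-Anscombe correction adds
#' 0.5 to every cell. The CI is Woolf's log-scale normal interval.
#'
#' @param changed_1,at_risk_1 Changes and at-risk count in stratum 1
#'   (denominator stratum).
#' @param changed_2,at_risk_2 Same for stratum 2 (numerator stratum).
#' @param conf Confidence level.
#' @param orientation Free-text note recording which stratum is the
#'   numerator.
#' @return data.frame of class `odds_ratio_result`: or, ci_low, ci_high,
#'   orientation, undefined (TRUE when both strata have zero changes).
#' @export
#' @examples
#' odds_ratio_ci(10, 1000, 20, 1000)
odds_ratio_ci <- function(changed_1, at_risk_1, changed_2, at_risk_2,
                          conf = 0.95,
                          orientation = "stratum 2 vs stratum 1") {
  stopifnot(at_risk_1 >= changed_1, at_risk_2 >= changed_2,
            changed_1 >= 0, changed_2 >= 0)
  a <- changed_2; b <- at_risk_2 - changed_2
  c <- changed_1; d <- at_risk_1 - changed_1
  undefined <- (changed_1 == 0 && changed_2 == 0)
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf) / 2)
  out <- data.frame(or = or, ci_low = exp(log(or) - z * se),
                    ci_high = exp(log(or) + z * se),
                    orientation = orientation, undefined = undefined)
  class(out) <- c("odds_ratio_result", "data.frame")
  out
}

#' Expected-false-positive FDR estimate
#'
#' With `m` one-tailed tests at per-test threshold `alpha`, `alpha * m`
#' false positives are expected; dividing by the `k` observed positives
#' estimates the false discovery rate, capped at 1. The worked example from
#' the randomization analysis is `estimate_fdr(0.1, 6, 4)` = 0.15.
#'
#' @param alpha Per-test threshold in (0, 1).
#' @param m Number of tests performed.
#' @param k Number of tests positive at `alpha`.
#' @return data.frame of class `fdr_estimate`: alpha, m, k, fdr,
#'   undefined (TRUE when k = 0, fdr = NA).
#' @export
#' @examples
#' estimate_fdr(0.1, 6, 4)$fdr  # 0.15
estimate_fdr <- function(alpha, m, k) {
  stopifnot(alpha > 0, alpha < 1, m >= k, k >= 0)
  undefined <- k == 0
  fdr <- if (undefined) NA_real_ else min(1, alpha * m / k)
  out <- data.frame(alpha = alpha, m = m, k = k, fdr = fdr,
                    undefined = undefined)
  class(out) <- c("fdr_estimate", "data.frame")
  out
}

#' Context-resolved mutability at methylation focal sites
#'
#' Counts strand-resolved C>T changes at CCWGG and control focal cytosines
#' (reference-strand G>A for minus-strand focals) per protein and
#' exclusive-timing stratum, expressed as changes per context at risk.
#'
#' @param census A `context_census` from [scan_methylation_contexts()].
#' @param changes A `change_set`.
#' @param timing_flags data.frame with a `position` column plus one
#'   `timing_<key>` column per protein (values from
#'   [flag_exclusive_timing()]). Positions absent from `timing_flags` are
#'   dropped (e.g. masked sites).
#' @return data.frame: motif, protein, stratum, n_contexts, n_changes,
#'   rate.
#' @export
context_mutability <- function(census, changes, timing_flags) {
  tcols <- grep("^timing_", names(timing_flags), value = TRUE)
  if (length(tcols) == 0) stop("timing_flags has no timing_ columns")
  cen <- census[census$position %in% timing_flags$position, , drop = FALSE]
  tidx <- match(cen$position, timing_flags$position)
  want_to <- ifelse(cen$strand == "+", "T", "A")  # C>T on +, G>A on -
  key <- paste(changes$position, changes$from, changes$to)
  hit <- paste(cen$position, cen$ref_base, want_to) %in% key
  rows <- list()
  for (tc in tcols) {
    protein <- sub("^timing_", "", tc)
    fl <- timing_flags[[tc]][tidx]
    for (motif in c("CCWGG", "control")) {
      sel <- cen$motif == motif
      for (lev in c("exclusively_early", "exclusively_late", "unbound",
                    "neither")) {
        n_ctx <- sum(sel & fl == lev)
        if (n_ctx == 0) next
        n_ch <- sum(hit & sel & fl == lev)
        rows[[length(rows) + 1L]] <- data.frame(
          motif = motif, protein = protein, stratum = lev,
          n_contexts = n_ctx, n_changes = n_ch, rate = n_ch / n_ctx)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("context_mutability", "data.frame")
  out
}
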