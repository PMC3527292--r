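#' Assemble the per-site analysis table
#'
#' One row per analyzable (at-risk) site, combining the genome annotation
#' (base, sense strand, degeneracy class) with per-protein binding
#' categories, the any-NAP bound flag, per-protein exclusive-timing flags
#' and methylation-context focal flags. This is the backbone joining
#' denominators (at-risk counts) to numerators (observed changes).
#'
#' @param genome A `nap_genome`.
#' @param census Integer vector of analyzable reference positions (from
#'   [extract_analyzable_sites()]); default all genome positions.
#' @param profiles Optional `binding_profiles`.
#' @param contexts Optional `context_census` from
#'   [scan_methylation_contexts()].
#' @return data.frame of class `site_table`.
#' @export
build_site_table <- function(genome, census = NULL, profiles = NULL,
                             contexts = NULL) {
  stopifnot(inherits(genome, "nap_genome"))
  census <- census %||% seq_len(genome$length)
  st <- genome$sites[match(census, genome$sites$position), ]
  rownames(st) <- NULL
  if (!is.null(profiles)) {
    cats <- classify_binding_categories(st$position, profiles)
    for (protein in names(profiles$profiles)) {
      key <- protein_key(protein)
      st[[paste0("cat_", key)]] <- cats[[paste0("cat_", key)]]
      st[[paste0("timing_", key)]] <-
        flag_exclusive_timing(st$position, profiles, protein)
    }
    st$any_nap <- cats$any_nap
    st$bound_any <- factor(ifelse(st$any_nap, "bound", "unbound"),
                           levels = c("bound", "unbound"))
  }
  if (!is.null(contexts)) {
    for (motif in c("CCWGG", "control")) {
      for (strand in c("+", "-")) {
        cn <- paste0(if (motif == "CCWGG") "ccwgg" else "control",
                     if (strand == "+") "_plus" else "_minus")
        pos <- contexts$position[contexts$motif == motif &
                                   contexts$strand == strand]
        st[[cn]] <- st$position %in% pos
      }
    }
  }
  class(st) <- c("site_table", "data.frame")
  st
}
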