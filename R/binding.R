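#' Load binding profiles from BED files
#'
#' Reads per-(protein, phase) interval files named `<protein>_<phase>.bed`
#' (0-based half-open, as written by [write_binding_beds()]), merging
#' overlapping or abutting records per file.
#'
#' @param paths Character vector of BED paths, or a single directory
#'   containing them.
#' @param genome_length Genome length; defaults to the largest end seen.
#' @param proteins,phases Recognized protein and phase names for filename
#'   validation.
#' @return A `binding_profiles` object.
#' @export
load_binding_profiles <- function(paths, genome_length = NULL,
                                  proteins = nap_proteins(),
                                  phases = growth_phases()) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.bed$", full.names = TRUE)
  profiles <- list()
  max_end <- 0L
  for (path in paths) {
    stem <- sub("\\.bed$", "", basename(path))
    protein <- sub("_.*$", "", stem)
    phase <- sub("^[^_]*_", "", stem)
    if (!protein %in% proteins)
      stop("naming error: unknown protein '", protein, "' in ", basename(path))
    if (!phase %in% phases)
      stop("naming error: unknown phase '", phase, "' in ", basename(path))
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      ir <- IRanges::IRanges()
    } else {
      parts <- strsplit(lines, "\t")
      for (i in seq_along(parts)) {
        p <- parts[[i]]
        s <- suppressWarnings(as.integer(p[2]))
        e <- suppressWarnings(as.integer(p[3]))
        if (length(p) < 3 || is.na(s) || is.na(e) || e <= s)
          stop("parse error in ", basename(path), " line ", i)
      }
      s <- vapply(parts, function(p) as.integer(p[2]), integer(1))
      e <- vapply(parts, function(p) as.integer(p[3]), integer(1))
      # BED half-open 0-based -> 1-based closed
      ir <- IRanges::reduce(IRanges::IRanges(start = s + 1L, end = e))
    }
    max_end <- max(max_end, if (length(ir)) max(IRanges::end(ir)) else 0L)
    profiles[[protein]][[phase]] <- ir
  }
  structure(list(profiles = profiles,
                 genome_length = genome_length %||% max_end,
                 proteins = intersect(proteins, names(profiles)),
                 phase_names = phases),
            class = "binding_profiles")
}

# phases x positions membership for one protein; unassayed phases unbound
phase_membership <- function(positions, profiles, protein,
                             phases = growth_phases()) {
  sets <- profiles$profiles[[protein]]
  out <- matrix(FALSE, nrow = length(positions), ncol = length(phases),
                dimnames = list(NULL, phases))
  q <- IRanges::IRanges(start = positions, width = 1L)
  for (phase in intersect(phases, names(sets)))
    out[, phase] <- IRanges::overlapsAny(q, sets[[phase]])
  out
}

# the binding-category recode applied to one membership matrix
recode_membership <- function(mem) {
  n <- rowSums(mem)
  early <- (mem[, "mid_exponential"] & !mem[, "transition"] &
              !mem[, "stationary"]) &
    (n == 1L + mem[, "late_exponential"])
  late <- (mem[, "stationary"] & !mem[, "mid_exponential"] &
             !mem[, "late_exponential"]) &
    (n == 1L + mem[, "transition"])
  out <- rep("other", nrow(mem))
  out[n == 0L] <- "never"
  out[n == 4L] <- "always"
  out[early] <- "early"
  out[late] <- "late"
  out
}

#' Classify growth-phase binding per protein at genomic positions
#'
#' Recodes the four-phase membership pattern of every position into one of
#' five categories per protein: bound in all four phases (`always`), bound
#' during mid- or mid- and late exponential only (`early`), bound during
#' stationary or stationary and transition only (`late`), bound at no
#' assayed time point (`never`), and any other pattern (`other`).
#' Additionally flags whether any protein binds at any phase (`any_nap`).
#'
#' @param positions Integer vector of 1-based reference positions.
#' @param profiles A `binding_profiles` object.
#' @return data.frame with one `cat_<protein>` factor column per protein
#'   (levels [binding_categories()]) plus logical `any_nap`.
#' @export
#' @examples
#' bp <- simulate_binding_profiles(20000, sim_config(genome_length = 20000))
#' head(classify_binding_categories(1:10, bp))
classify_binding_categories <- function(positions, profiles) {
  stopifnot(inherits(profiles, "binding_profiles"))
  out <- data.frame(row.names = seq_along(positions))
  any_nap <- rep(FALSE, length(positions))
  for (protein in names(profiles$profiles)) {
    mem <- phase_membership(positions, profiles, protein,
                            profiles$phase_names)
    out[[paste0("cat_", protein_key(protein))]] <-
      factor(recode_membership(mem), levels = binding_categories())
    any_nap <- any_nap | rowSums(mem) > 0L
  }
  out$any_nap <- any_nap
  out$position <- positions
  out
}

#' Binding category of one position for one protein
#' @param position Single 1-based position.
#' @param profiles A `binding_profiles` object.
#' @param protein Protein name.
#' @return Character scalar, one of [binding_categories()].
#' @export
classify_site_binding <- function(position, profiles, protein) {
  mem <- phase_membership(position, profiles, protein, profiles$phase_names)
  recode_membership(mem)
}

#' Exclusive binding-timing flag of positions for one protein
#'
#' `exclusively_early`: bound in at least one exponential phase and in no
#' later phase. `exclusively_late`: bound in at least one of transition or
#' stationary and in no exponential phase. `unbound`: bound in no phase.
#' `neither`: bound in both eras.
#'
#' @param position Integer vector of 1-based positions.
#' @param profiles A `binding_profiles` object.
#' @param protein Protein name.
#' @return Character vector over
#'   `{exclusively_early, exclusively_late, unbound, neither}`.
#' @export
flag_exclusive_timing <- function(position, profiles, protein) {
  mem <- phase_membership(position, profiles, protein, profiles$phase_names)
  early_any <- mem[, "mid_exponential"] | mem[, "late_exponential"]
  late_any <- mem[, "transition"] | mem[, "stationary"]
  out <- rep("neither", length(position))
  out[early_any & !late_any] <- "exclusively_early"
  out[late_any & !early_any] <- "exclusively_late"
  out[!early_any & !late_any] <- "unbound"
  out
}

#' Coverage summary per protein, phase and category
#' @param profiles A `binding_profiles` object.
#' @return data.frame with protein, phase, n_intervals, bases, fraction.
#' @export
binding_coverage_summary <- function(profiles) {
  rows <- list()
  for (protein in names(profiles$profiles)) {
    for (phase in names(profiles$profiles[[protein]])) {
      ir <- profiles$profiles[[protein]][[phase]]
      rows[[length(rows) + 1L]] <- data.frame(
        protein = protein, phase = phase, n_intervals = length(ir),
        bases = sum(IRanges::width(ir)),
        fraction = sum(IRanges::width(ir)) / profiles$genome_length)
    }
  }
  do.call(rbind, rows)
}
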