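#' Simulate binding-interval profiles per protein and growth phase
#'
#' For every protein the latest assayed phase is generated first; each
#' earlier phase reuses a fraction `interphase_overlap` of the temporally
#' adjacent later phase's bound bases (whole intervals, the last one trimmed
#' so the shared base count is exact) and fills the rest with fresh
#' intervals that avoid every other phase of that protein. Sharing between
#' non-adjacent phases therefore decays roughly geometrically with temporal
#' distance, mirroring the observed pattern that temporally closer phases
#' share more binding. Fis receives profiles only for the two exponential
#' phases, as it is not detectable later in growth.
#'
#' @param genome A `nap_genome` or an integer genome length.
#' @param config A [sim_config()].
#' @return Object of class `binding_profiles`: list with `profiles`
#'   (protein -> phase -> [IRanges::IRanges]), `genome_length`, `proteins`,
#'   `phase_names`.
#' @export
#' @examples
#' bp <- simulate_binding_profiles(20000, sim_config(genome_length = 20000))
#' names(bp$profiles)
simulate_binding_profiles <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  L <- if (inherits(genome, "nap_genome")) genome$length else as.integer(genome)
  phases <- config$phase_names
  frac <- config$binding_fraction
  profiles <- list()
  with_seed(stage_seed(config$seed, "binding"), {
    for (protein in config$proteins) {
      avail <- if (protein == "Fis") phases[1:2] else phases
      if (frac * length(avail) >= 1)
        stop("requested coverage >= 1 for protein ", protein)
      target <- max(1L, round(frac * L))
      occupied <- logical(L)
      sets <- list()
      later_ivs <- NULL
      for (phase in rev(avail)) {
        ivs <- list()
        shared_target <- if (is.null(later_ivs)) 0L else
          as.integer(round(config$interphase_overlap * target))
        if (shared_target > 0L) {
          ord <- sample(length(later_ivs$start))
          cum <- 0L
          for (j in ord) {
            if (cum >= shared_target) break
            s <- later_ivs$start[j]; e <- later_ivs$end[j]
            w <- e - s + 1L
            if (cum + w > shared_target) e <- s + (shared_target - cum) - 1L
            ivs[[length(ivs) + 1L]] <- c(s, e)
            cum <- cum + (e - s + 1L)
          }
        }
        fresh_target <- target - min(shared_target, target)
        got <- 0L
        tries <- 0L
        max_tries <- 2000L + 400L * ceiling(fresh_target /
                                            config$interval_mean_length)
        while (got < fresh_target) {
          tries <- tries + 1L
          if (tries > max_tries)
            stop("could not place binding intervals for ", protein,
                 " (genome too crowded)")
          w <- min(rgeom(1L, 1 / config$interval_mean_length) + 1L,
                   fresh_target - got, L)
          s <- sample.int(L - w + 1L, 1L)
          e <- s + w - 1L
          if (any(occupied[s:e])) next
          occupied[s:e] <- TRUE
          ivs[[length(ivs) + 1L]] <- c(s, e)
          got <- got + w
        }
        m <- do.call(rbind, ivs)
        ir <- IRanges::reduce(IRanges::IRanges(start = m[, 1], end = m[, 2]))
        sets[[phase]] <- ir
        later_ivs <- list(start = m[, 1], end = m[, 2])
      }
      profiles[[protein]] <- sets[avail]
    }
    structure(list(profiles = profiles, genome_length = L,
                   proteins = config$proteins, phase_names = phases),
              class = "binding_profiles")
  })
}

#' Measured bound-base sharing between two growth phases
#'
#' Fraction of the bases bound by `protein` during the (later) phase
#' `denominator_phase` that are also bound during `phase`.
#'
#' @param profiles A `binding_profiles` object.
#' @param protein Protein name.
#' @param phase Earlier phase of interest.
#' @param denominator_phase Phase whose coverage forms the denominator.
#' @return Numeric fraction in `[0, 1]`.
#' @export
measure_interphase_overlap <- function(profiles, protein, phase,
                                       denominator_phase) {
  a <- profiles$profiles[[protein]][[phase]]
  b <- profiles$profiles[[protein]][[denominator_phase]]
  if (is.null(a) || is.null(b)) stop("phase not available for ", protein)
  denom <- sum(IRanges::width(b))
  if (denom == 0) return(NA_real_)
  sum(IRanges::width(IRanges::intersect(a, b))) / denom
}

#' Write binding profiles as BED files (0-based half-open)
#'
#' One file per (protein, phase), named `<protein>_<phase>.bed`.
#'
#' @param profiles A `binding_profiles` object.
#' @param dir Output directory (created if needed).
#' @param chrom Chromosome name to write.
#' @return Character vector of paths, invisibly.
#' @export
write_binding_beds <- function(profiles, dir, chrom = "genome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (protein in names(profiles$profiles)) {
    for (phase in names(profiles$profiles[[protein]])) {
      ir <- profiles$profiles[[protein]][[phase]]
      path <- file.path(dir, paste0(protein, "_", phase, ".bed"))
      df <- data.frame(chrom = chrom, start = IRanges::start(ir) - 1L,
                       end = IRanges::end(ir))
      write.table(df, path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}
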