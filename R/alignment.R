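#' Construct a strain alignment object
#'
#' Holds equal-length aligned sequences for all strains plus the outgroup,
#' with an optional block index mapping alignment columns to reference
#' coordinates (identity by default, as produced by the simulator).
#'
#' @param seqs Named character vector of aligned sequences (equal length).
#' @param outgroup Name of the outgroup sequence (must be present).
#' @param reference Name of the reference strain used for coordinates and
#'   at-risk bases; defaults to the first non-outgroup strain.
#' @param blocks Optional data.frame with columns `aln_start`, `aln_end`,
#'   `ref_start` (strictly increasing) mapping alignment columns to
#'   reference positions.
#' @return Object of class `strain_alignment`.
#' @export
strain_alignment <- function(seqs, outgroup = "outgroup",
                             reference = NULL, blocks = NULL) {
  if (is.null(names(seqs)) || anyNA(names(seqs)))
    stop("seqs must be named")
  w <- unique(nchar(seqs))
  if (length(w) != 1) stop("aligned sequences must have equal length")
  if (!outgroup %in% names(seqs))
    stop("data error: outgroup '", outgroup, "' missing from alignment")
  reference <- reference %||% setdiff(names(seqs), outgroup)[1]
  if (is.null(blocks)) {
    blocks <- data.frame(aln_start = 1L, aln_end = w, ref_start = 1L)
  }
  if (any(diff(blocks$ref_start) <= 0) && nrow(blocks) > 1)
    stop("reference coordinates must be strictly increasing across blocks")
  structure(list(seqs = toupper(seqs), width = w, outgroup = outgroup,
                 reference = reference, blocks = blocks),
            class = "strain_alignment")
}

#' Reference coordinate of each alignment column (NA outside blocks)
#' @param aln A [strain_alignment()].
#' @return Integer vector over alignment columns.
#' @export
alignment_ref_positions <- function(aln) {
  pos <- rep(NA_integer_, aln$width)
  for (i in seq_len(nrow(aln$blocks))) {
    b <- aln$blocks[i, ]
    idx <- b$aln_start:b$aln_end
    pos[idx] <- b$ref_start + (idx - b$aln_start)
  }
  pos
}

#' Extract analyzable sites from a strain alignment
#'
#' Applies the site filters used throughout: a column is analyzable
#' (counted in the at-risk census) when no strain or the outgroup carries a
#' gap or ambiguity and the column does not overlap the uniqueness mask.
#' Among analyzable columns, a site is polymorphic when the ingroup
#' (outgroup excluded) holds more than one base; columns where only the
#' outgroup differs count in the census but not as polymorphic.
#'
#' @param aln A [strain_alignment()].
#' @param mask Optional [IRanges::IRanges] of non-unique reference regions
#'   to exclude.
#' @return Object of class `analyzable_sites`: list with `census`
#'   (reference positions of all analyzable sites), `polymorphic`
#'   (reference positions of ingroup-polymorphic sites), `states`
#'   (character matrix strains x polymorphic sites, including the
#'   outgroup), and `ref_base` (named by census position).
#' @export
extract_analyzable_sites <- function(aln, mask = NULL) {
  stopifnot(inherits(aln, "strain_alignment"))
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- names(aln$seqs)
  ok <- colSums(m == "A" | m == "C" | m == "G" | m == "T") == nrow(m)
  refpos <- alignment_ref_positions(aln)
  ok <- ok & !is.na(refpos)
  if (!is.null(mask) && length(mask) > 0) {
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(start = refpos[ok], width = 1L), mask)
    ok[which(ok)[hit]] <- FALSE
  }
  ing <- setdiff(rownames(m), aln$outgroup)
  n_distinct <- apply(m[ing, ok, drop = FALSE], 2,
                      function(x) length(unique(x)))
  poly_cols <- which(ok)[n_distinct > 1]
  census_pos <- refpos[ok]
  structure(list(
    census = census_pos,
    polymorphic = refpos[poly_cols],
    states = m[, poly_cols, drop = FALSE],
    ref_base = setNames(m[aln$reference, ok], census_pos)
  ), class = "analyzable_sites")
}

#' Write / read a strain alignment (FASTA plus block-index TSV)
#' @param aln A [strain_alignment()].
#' @param fasta,blocks_tsv Output paths.
#' @return `fasta`, invisibly.
#' @export
write_alignment <- function(aln, fasta, blocks_tsv = NULL) {
  write_fasta(aln$seqs, fasta)
  if (!is.null(blocks_tsv))
    write.table(aln$blocks, blocks_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fasta)
}

#' @rdname write_alignment
#' @param outgroup,reference Passed to [strain_alignment()].
#' @export
read_alignment <- function(fasta, blocks_tsv = NULL, outgroup = "outgroup",
                           reference = NULL) {
  seqs <- read_fasta(fasta)
  blocks <- if (!is.null(blocks_tsv))
    read.table(blocks_tsv, header = TRUE, sep = "\t") else NULL
  strain_alignment(seqs, outgroup = outgroup, reference = reference,
                   blocks = blocks)
}
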