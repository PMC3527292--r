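#' Scan a genome for CCWGG methylation motifs and CCWHH controls
#'
#' The Dcm methyltransferase 5-methylates the second cytosine of CCWGG
#' (W = A/T); deamination of that 5-meC is a C>T hotspot. CCWHH
#' (H = A/C/T) serves as the local-context-matched control. Both strands are
#' scanned; the focal site of each occurrence is the second cytosine on the
#' occurrence's own strand, reported in reference coordinates with its
#' strand. Overlapping occurrences are all reported, and CCWGG focal sites
#' never double-count as control focals.
#'
#' @param sequence Character scalar over A/C/G/T (other codes are skipped
#'   with a warning).
#' @return Object of class `context_census`: data.frame with columns
#'   `position` (reference, 1-based), `strand` (`"+"`/`"-"`), `motif`
#'   (`"CCWGG"` or `"control"`), and `ref_base` (the reference-strand base at
#'   the focal site: C on `+`, G on `-`).
#' @export
#' @examples
#' scan_methylation_contexts("TCCAGGA")
scan_methylation_contexts <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  seq_u <- toupper(sequence)
  if (grepl("[^ACGT]", seq_u)) {
    warning("sequence contains ambiguity codes; affected windows skipped")
    seq_u <- gsub("[^ACGT]", "N", seq_u)
  }
  find <- function(pattern) {
    m <- gregexpr(paste0("(?=", pattern, ")"), seq_u, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  # CCWGG is its own reverse-complement class (CCAGG <-> CCTGG): every
  # occurrence yields a plus-strand focal (second C) and a minus-strand
  # focal (the complement of the second-from-last G).
  p <- find("CC[AT]GG")
  ccwgg <- data.frame(position = c(p + 1L, p + 3L),
                      strand = rep(c("+", "-"), each = length(p)),
                      motif = rep("CCWGG", 2L * length(p)),
                      stringsAsFactors = FALSE)
  qf <- find("CC[AT][ACT][ACT]")         # forward CCWHH, focal second C
  qr <- find("[AGT][AGT][AT]GG")         # reverse-strand CCWHH
  ctrl <- data.frame(position = c(qf + 1L, qr + 3L),
                     strand = c(rep("+", length(qf)), rep("-", length(qr))),
                     motif = rep("control", length(qf) + length(qr)),
                     stringsAsFactors = FALSE)
  key <- function(d) paste(d$position, d$strand)
  ctrl <- ctrl[!key(ctrl) %in% key(ccwgg), , drop = FALSE]
  out <- rbind(ccwgg, ctrl)
  out <- out[order(out$position, out$strand, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out$ref_base <- ifelse(out$strand == "+", "C", "G")
  class(out) <- c("context_census", "data.frame")
  out
}
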