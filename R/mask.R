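#' Compute the genome uniqueness mask
#'
#' Digests the genome into overlapping windows (default 300 nt, offset
#' 10 nt) and marks a window non-unique when it matches a second genomic
#' locale on either strand with at most `max_mismatch` mismatches —
#' mirroring the unique-mappability requirement of short-read binding
#' calls. Matching uses a pigeonhole seed-and-verify strategy: a window
#' within `k` mismatches of another locale must share at least one of its
#' `k + 1` equal-length chunks exactly, so exact chunk hits (found with
#' [Biostrings::matchPDict()]) are verified by full-window Hamming
#' distance.
#'
#' @param sequence Character scalar genome sequence.
#' @param window Window width in nt.
#' @param step Window offset in nt.
#' @param max_mismatch Maximum Hamming distance for a second-locale match.
#' @return [IRanges::IRanges] of the union of non-unique window spans
#'   (1-based, closed).
#' @export
#' @examples
#' s <- paste(sample(c("A","C","G","T"), 2000, TRUE), collapse = "")
#' length(compute_uniqueness_mask(s, window = 300, step = 10))
compute_uniqueness_mask <- function(sequence, window = 300L, step = 10L,
                                    max_mismatch = 2L) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  L <- nchar(sequence)
  if (window > L) stop("window exceeds sequence length")
  starts <- seq.int(1L, L - window + 1L, by = step)
  cw <- window %/% (max_mismatch + 1L)
  offsets <- (0:max_mismatch) * cw
  subj <- Biostrings::DNAString(sequence)
  rsubj <- Biostrings::reverseComplement(subj)
  a_raw <- charToRaw(sequence)
  r_raw <- charToRaw(as.character(rsubj))

  pat_start <- rep(starts, each = length(offsets)) +
    rep(offsets, times = length(starts))
  pats <- Biostrings::DNAStringSet(subj,
                                   start = pat_start, width = cw)
  pd <- Biostrings::PDict(pats)
  win_of <- rep(seq_along(starts), each = length(offsets))
  off_of <- rep(offsets, times = length(starts))

  ham_le <- function(x_raw, i, y_raw, j, n, k) {
    sum(x_raw[i:(i + n - 1L)] != y_raw[j:(j + n - 1L)]) <= k
  }
  bad <- logical(length(starts))

  collect <- function(y_raw, hits_by_pat, is_self) {
    for (p in seq_along(hits_by_pat)) {
      hs <- hits_by_pat[[p]]
      if (length(hs) == 0L) next
      w <- win_of[p]
      if (bad[w]) next
      s <- starts[w]
      cand <- unique(hs - off_of[p])
      cand <- cand[cand >= 1L & cand <= L - window + 1L]
      if (is_self) cand <- cand[cand != s]
      for (t in cand) {
        if (ham_le(a_raw, s, y_raw, t, window, max_mismatch)) {
          bad[w] <<- TRUE
          break
        }
      }
    }
  }
  fh <- Biostrings::matchPDict(pd, subj)
  collect(a_raw, Biostrings::startIndex(fh), is_self = TRUE)
  rh <- Biostrings::matchPDict(pd, rsubj)
  collect(r_raw, Biostrings::startIndex(rh), is_self = FALSE)

  if (!any(bad)) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = starts[bad], width = window))
}

#' Brute-force uniqueness mask (validation oracle)
#'
#' Direct all-shifts Hamming scan of every window against every alignment
#' position on both strands. Quadratic in genome length; intended only to
#' validate [compute_uniqueness_mask()] on small fixtures.
#'
#' @inheritParams compute_uniqueness_mask
#' @return [IRanges::IRanges] of non-unique window spans.
#' @export
naive_uniqueness_mask <- function(sequence, window = 300L, step = 10L,
                                  max_mismatch = 2L) {
  L <- nchar(sequence)
  if (window > L) stop("window exceeds sequence length")
  starts <- seq.int(1L, L - window + 1L, by = step)
  on_grid <- function(p) !is.na(p) & p >= 1L & ((p - 1L) %% step) == 0L &
    p <= L - window + 1L
  grid_idx <- function(p) (p - 1L) %/% step + 1L
  a <- strsplit(sequence, "")[[1]]
  b <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(sequence))), "")[[1]]
  bad <- logical(length(starts))
  mark <- function(p) {
    sel <- on_grid(p)
    bad[grid_idx(p[sel])] <<- TRUE
  }
  win_counts <- function(mm) {
    # mismatch count of every full window inside the overlap, via cumsum
    cs <- cumsum(c(0L, mm))
    n <- length(mm) - window + 1L
    if (n < 1L) return(integer(0))
    cs[(window + 1L):(window + n)] - cs[1:n]
  }
  # forward vs forward, all shifts d >= 1
  for (d in seq_len(L - window)) {
    mm <- a[1:(L - d)] != a[(1 + d):L]
    wc <- win_counts(mm)
    hit <- which(wc <= max_mismatch)
    if (length(hit)) {
      mark(hit)        # left copy at position hit
      mark(hit + d)    # right copy
    }
  }
  # forward vs reverse-complement strand, all relative offsets
  for (d in (-(L - window)):(L - window)) {
    i0 <- max(1L, 1L - d); i1 <- min(L, L - d)
    if (i1 - i0 + 1L < window) next
    mm <- a[i0:i1] != b[(i0 + d):(i1 + d)]
    wc <- win_counts(mm)
    hit <- which(wc <= max_mismatch)
    if (length(hit)) {
      i <- i0 + hit - 1L          # forward window start
      j <- i + d                  # window start on the rc strand
      mark(i)
      mark(L - (j + window - 1L) + 1L)  # the mirrored forward locale
    }
  }
  if (!any(bad)) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = starts[bad], width = window))
}
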