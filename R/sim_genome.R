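# Degeneracy of each codon position under the standard genetic code:
# fold[codon, pos] = number of bases (including the current one) that leave
# the encoded amino acid unchanged at that position.
codon_fold_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    code <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    codons <- names(code)
    m <- matrix(0L, length(codons), 3, dimnames = list(codons, NULL))
    for (cd in codons) {
      for (pos in 1:3) {
        alt <- vapply(bases, function(b) {
          x <- strsplit(cd, "")[[1]]
          x[pos] <- b
          unname(code[paste(x, collapse = "")])
        }, character(1))
        m[cd, pos] <- sum(alt == code[[cd]])
      }
    }
    tab <<- m
    tab
  }
})

#' Simulate an annotated circular genome
#'
#' Draws a random sequence at the configured GC content and places
#' non-overlapping genes of codon-multiple length on random strands. Every
#' position is classified by codon position and degeneracy (4-fold, 2-fold,
#' other coding, intergenic) from the standard genetic code.
#'
#' @param config A [sim_config()].
#' @return Object of class `nap_genome`: list with `sequence` (character),
#'   `length`, `genes` (data.frame: gene_id, start, end, strand, frame;
#'   1-based closed coordinates), and `sites` (per-position data.frame:
#'   position, base, sense_base, gene, codon_pos, fold, site_class,
#'   sense_strand).
#' @export
#' @examples
#' g <- simulate_genome(sim_config(genome_length = 5000, n_genes = 4))
#' table(g$sites$site_class)
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  with_seed(stage_seed(config$seed, "genome"), {
    gcp <- config$gc
    seq_v <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c((1 - gcp) / 2, gcp / 2, gcp / 2, (1 - gcp) / 2))
    genes <- place_genes(L, config$n_genes, config$gene_length_range)
    sites <- annotate_sites(seq_v, genes)
    structure(list(sequence = paste(seq_v, collapse = ""),
                   length = L, genes = genes, sites = sites),
              class = "nap_genome")
  })
}

place_genes <- function(L, n_genes, len_range) {
  if (n_genes == 0L) {
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0)))
  }
  lens <- sample(seq(len_range[1], len_range[2]), n_genes, replace = TRUE)
  lens <- pmax(3L, as.integer(lens %/% 3L * 3L))
  slack <- L - sum(lens)
  if (slack < 0)
    stop("gene placement error: genes do not fit in the genome")
  gaps <- tabulate(sample.int(n_genes + 1L, slack, replace = TRUE),
                   nbins = n_genes + 1L)
  starts <- integer(n_genes)
  pos <- 1L
  for (i in seq_len(n_genes)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
             start = starts, end = starts + lens - 1L,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             frame = (starts - 1L) %% 3L)
}

annotate_sites <- function(seq_v, genes) {
  L <- length(seq_v)
  gene <- rep(NA_character_, L)
  codon_pos <- rep(NA_integer_, L)
  fold <- rep(NA_integer_, L)
  sense_strand <- rep(NA_character_, L)
  sense_base <- seq_v
  ft <- codon_fold_table()
  for (i in seq_len(nrow(genes))) {
    s <- genes$start[i]; e <- genes$end[i]; st <- genes$strand[i]
    idx <- s:e
    gene[idx] <- genes$gene_id[i]
    sense_strand[idx] <- st
    if (st == "+") {
      off <- idx - s
      cp <- off %% 3L + 1L
      cod_start <- idx - (cp - 1L)
      cods <- paste0(seq_v[cod_start], seq_v[cod_start + 1L],
                     seq_v[cod_start + 2L])
    } else {
      off <- e - idx
      cp <- off %% 3L + 1L
      # codon read 5'->3' on the minus strand
      cod_start <- idx + (cp - 1L)  # reference coordinate of codon pos 1
      cods <- paste0(complement_base(seq_v[cod_start]),
                     complement_base(seq_v[cod_start - 1L]),
                     complement_base(seq_v[cod_start - 2L]))
      sense_base[idx] <- complement_base(seq_v[idx])
    }
    codon_pos[idx] <- cp
    fold[idx] <- ft[cbind(match(cods, rownames(ft)), cp)]
  }
  site_class <- ifelse(is.na(gene), "intergenic",
                ifelse(fold == 4L, "fourfold",
                ifelse(fold == 2L, "twofold", "coding_other")))
  data.frame(position = seq_len(L), base = seq_v, sense_base = sense_base,
             gene = gene, codon_pos = codon_pos, fold = fold,
             site_class = site_class, sense_strand = sense_strand,
             stringsAsFactors = FALSE)
}

#' Build an annotated genome object from sequence and gene table
#'
#' Used when the genome and annotation come from files rather than from
#' [simulate_genome()]; classifies every position by codon position and
#' degeneracy exactly as the simulator does.
#'
#' @param sequence Character scalar genome sequence.
#' @param genes data.frame with gene_id, start, end, strand, frame
#'   (1-based closed coordinates).
#' @return A `nap_genome` object.
#' @export
nap_genome <- function(sequence, genes) {
  seq_v <- strsplit(toupper(sequence), "")[[1]]
  structure(list(sequence = paste(seq_v, collapse = ""),
                 length = length(seq_v), genes = genes,
                 sites = annotate_sites(seq_v, genes)),
            class = "nap_genome")
}

#' Write a genome (or any named set of sequences) to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA as a named character vector
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write the gene table as TSV
#' @param genome A `nap_genome` (or a gene data.frame).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genome, path) {
  genes <- if (inherits(genome, "nap_genome")) genome$genes else genome
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
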