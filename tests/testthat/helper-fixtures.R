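# Shared fixtures: all generated in code, nothing stored on disk.

tiny_config <- function(...) {
  defaults <- list(genome_length = 12000, n_genes = 10, n_strains = 5,
                   seed = 11L)
  do.call(sim_config, modifyList(defaults, list(...)))
}

random_dna <- function(n, seed = 1) {
  with_seed <- getFromNamespace("with_seed", "napmut")
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                        collapse = ""))
}

# rooted 4-taxon + outgroup tree with per-node support labels
quartet_tree <- function(ab_support = 100, cd_support = 100) {
  txt <- sprintf(
    "(((A:0.05,B:0.05)%d:0.05,(C:0.05,D:0.05)%d:0.05)100:0.02,outgroup:0.02)100;",
    ab_support, cd_support)
  tr <- ape::read.tree(text = txt)
  attr(tr, "outgroup") <- "outgroup"
  tr
}

# random rooted tree with uniform-ish branch lengths and full supports
random_fixture_tree <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = TRUE,
                   br = function(n) runif(n, 0.02, 0.4))
  tr$tip.label <- paste0("s", seq_len(n_leaves))
  tr$node.label <- rep("100", tr$Nnode)
  tr
}

random_model <- function(seed) {
  set.seed(seed)
  pick <- sample(4, 1)
  if (pick == 1) model_jc()
  else if (pick == 2) model_k80(kappa = runif(1, 1, 6))
  else {
    f <- runif(4, 0.5, 2); f <- f / sum(f)
    if (pick == 3) model_hky(kappa = runif(1, 1, 6), freqs = f)
    else model_gtr(rates = runif(6, 0.3, 3), freqs = f)
  }
}

# brute-force count of 4-fold synonymous third positions, scanning codons
# directly against the genetic code (independent of codon_fold_table)
oracle_fourfold_count <- function(genome) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seq_v <- strsplit(genome$sequence, "")[[1]]
  n <- 0L
  for (i in seq_len(nrow(genome$genes))) {
    gi <- genome$genes[i, ]
    s <- if (gi$strand == "+") seq_v[gi$start:gi$end] else
      unname(comp[rev(seq_v[gi$start:gi$end])])
    for (c0 in seq(1, length(s) - 2, by = 3)) {
      cod <- s[c0:(c0 + 2)]
      aa <- vapply(bases, function(b)
        code[[paste(c(cod[1:2], b), collapse = "")]], character(1))
      if (all(aa == aa[cod[3]])) n <- n + 1L
    }
  }
  n
}

manual_profiles <- function(sets, genome_length = 1000) {
  structure(list(profiles = sets, genome_length = genome_length,
                 proteins = names(sets), phase_names = growth_phases()),
            class = "binding_profiles")
}

make_combo_fixture <- function(mut_e, mut_l, ctx_e, ctx_l) {
  data.frame(protein = rep(c("hns", "ihfa", "ihfb"), each = 2),
             motif = rep(c("CCWGG", "control"), 3),
             n_mut_early = mut_e, n_mut_late = mut_l,
             n_ctx_early = ctx_e, n_ctx_late = ctx_l)
}
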