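#' Evolve a strain alignment on a tree with known ground truth
#'
#' Places at most one substitution per site per branch by Bernoulli draws:
#' the probability of a change at a site on a branch is
#' `base_rate(type) * branch_length * binding_modifier * context_multiplier`.
#' The binding modifier is looked up from the configured `binding_effect`
#' via the focal protein's binding category at the site; the context
#' multiplier applies to C>T at plus-strand CCWGG focal cytosines and to
#' G>A (reference strand) at minus-strand focals, with contexts defined on
#' the ancestral genome. Every placed event is recorded as ground truth.
#'
#' @param genome A `nap_genome` from [simulate_genome()].
#' @param tree A rooted `phylo` from [make_strain_tree()]; the root sequence
#'   is the genome sequence.
#' @param profiles A `binding_profiles` from [simulate_binding_profiles()],
#'   or `NULL` for no binding modulation.
#' @param config A [sim_config()].
#' @return List with `alignment` (a [strain_alignment()] over all leaves
#'   including the outgroup) and `truth` (class `ground_truth`: `changes`
#'   data.frame with columns site, branch, from, to; `binding_effect`;
#'   `config`).
#' @export
evolve_alignment <- function(genome, tree, profiles, config) {
  stopifnot(inherits(genome, "nap_genome"), inherits(tree, "phylo"),
            inherits(config, "sim_config"))
  L <- genome$length
  bases <- c("A", "C", "G", "T")
  rates <- config$base_rates
  types <- mutation_types()

  # per-site, per-type multiplier
  mult <- matrix(1, nrow = L, ncol = 12, dimnames = list(NULL, types))
  if (!is.null(profiles)) {
    cat_f <- classify_binding_categories(seq_len(L), profiles)
    cats <- cat_f[[paste0("cat_", protein_key(config$focal_protein))]]
    mult <- config$binding_effect[cats, , drop = FALSE]
    dimnames(mult) <- list(NULL, types)
  }
  if (config$ccwgg_multiplier != 1) {
    ctx <- scan_methylation_contexts(genome$sequence)
    foc <- ctx[ctx$motif == "CCWGG", ]
    mult[foc$position[foc$strand == "+"], "C>T"] <-
      mult[foc$position[foc$strand == "+"], "C>T"] * config$ccwgg_multiplier
    mult[foc$position[foc$strand == "-"], "G>A"] <-
      mult[foc$position[foc$strand == "-"], "G>A"] * config$ccwgg_multiplier
  }

  # per-site total rate out of each base, and per-target weights
  lam <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, bases))
  wgt <- lapply(setNames(bases, bases), function(b) {
    tb <- paste0(b, ">", setdiff(bases, b))
    w <- sweep(mult[, tb, drop = FALSE], 2, rates[tb], `*`)
    colnames(w) <- setdiff(bases, b)
    w
  })
  for (b in bases) lam[, b] <- rowSums(wgt[[b]])

  edge <- tree$edge
  elen <- tree$edge.length
  max_p <- max(lam) * max(elen)
  if (max_p >= 0.5)
    stop("per-site per-branch change probability >= 0.5; ",
         "multiple-hit regime breaks single-event assumptions")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- strsplit(genome$sequence, "")[[1]]
  ord <- reorder(tree, "cladewise")  # preorder edges
  changes <- list()
  with_seed(stage_seed(config$seed, "evolve"), {
    for (k in seq_len(nrow(ord$edge))) {
      par <- ord$edge[k, 1]; child <- ord$edge[k, 2]
      len <- ord$edge.length[k]
      ps <- seqs[[par]]
      p <- lam[cbind(seq_len(L), match(ps, bases))] * len
      hits <- which(runif(L) < p)
      cs <- ps
      for (h in hits) {
        b <- ps[h]
        w <- wgt[[b]][h, ]
        to <- sample(names(w), 1L, prob = w)
        cs[h] <- to
        changes[[length(changes) + 1L]] <-
          data.frame(site = h, branch = node_label(tree, child),
                     from = b, to = to, stringsAsFactors = FALSE)
      }
      seqs[[child]] <- cs
    }
  })
  leaf_seqs <- vapply(seq_len(ntip),
                      function(i) paste(seqs[[i]], collapse = ""),
                      character(1))
  names(leaf_seqs) <- tree$tip.label
  truth <- structure(list(
    changes = if (length(changes)) do.call(rbind, changes) else
      data.frame(site = integer(0), branch = character(0),
                 from = character(0), to = character(0)),
    binding_effect = config$binding_effect,
    config = config
  ), class = "ground_truth")
  og <- attr(tree, "outgroup") %||% "outgroup"
  list(alignment = strain_alignment(leaf_seqs, outgroup = og),
       truth = truth)
}

#' Stable label for a tree node (tip name or `node<k>`)
#' @param tree A `phylo`.
#' @param id Node number (ape numbering).
#' @return Character label.
#' @export
node_label <- function(tree, id) {
  ntip <- ape::Ntip(tree)
  ifelse(id <= ntip, tree$tip.label[id], paste0("node", id))
}
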