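#' Simulate a rooted strain phylogeny with bootstrap supports
#'
#' Builds a rooted binary tree with `n_strains` ingroup leaves plus one
#' outgroup leaf attached at the root, exponential branch lengths, and a
#' bootstrap support value on every internal node. Supports are drawn from a
#' two-component mixture (high: 98-100, low: 50-97) so that the
#' support-based change filter has both classes to act on.
#'
#' The outgroup and ingroup stem edges are short (`outgroup_scale` times the
#' mean ingroup edge) by default: events on the two root-incident edges
#' produce no ingroup polymorphism and are invisible to any reconstruction,
#' so a close outgroup keeps the simulated truth observable while still
#' polarizing ancestral states.
#'
#' @param n_strains Number of ingroup leaves (>= 3).
#' @param seed Integer seed; identical `(n_strains, seed)` give
#'   byte-identical Newick output.
#' @param branch_mean Mean ingroup branch length.
#' @param outgroup_scale Outgroup/stem edge length relative to `branch_mean`.
#' @param low_support_fraction Probability an internal node draws its
#'   support from the low (50-97) component.
#' @param outgroup Outgroup tip label.
#' @return An [ape::read.tree()] style `phylo` object, rooted, with
#'   `node.label` holding integer bootstrap supports.
#' @export
#' @examples
#' tr <- make_strain_tree(5, seed = 1)
#' ape::Ntip(tr)
make_strain_tree <- function(n_strains, seed,
                             branch_mean = 0.02,
                             outgroup_scale = 0.2,
                             low_support_fraction = 0,
                             outgroup = "outgroup") {
  if (n_strains < 3) stop("n_strains must be >= 3")
  with_seed(seed, {
    ing <- ape::rtree(n_strains, rooted = TRUE,
                      br = function(n) rexp(n, rate = 1 / branch_mean))
    ing$tip.label <- sprintf("strain%02d", seq_len(n_strains))
    stem <- branch_mean * outgroup_scale
    nwk_in <- sub(";$", "", ape::write.tree(ing))
    nwk <- sprintf("(%s:%.10f,%s:%.10f);", nwk_in, stem, outgroup, stem)
    tr <- ape::read.tree(text = nwk)
    n_internal <- tr$Nnode
    low <- runif(n_internal) < low_support_fraction
    supp <- ifelse(low,
                   floor(runif(n_internal, 50, 98)),
                   floor(runif(n_internal, 98, 101)))
    supp <- pmin(supp, 100)
    # the root joins outgroup and ingroup; give it full support
    root_id <- ape::Ntip(tr) + 1L
    supp[1L] <- 100
    tr$node.label <- as.character(as.integer(supp))
    attr(tr, "outgroup") <- outgroup
    tr
  })
}

#' Bootstrap supports of a phylogeny as a numeric vector
#'
#' @param tree A `phylo` object whose `node.label` holds supports.
#' @return Numeric vector over internal nodes (ape numbering order).
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) stop("tree carries no node.label supports")
  s <- suppressWarnings(as.numeric(tree$node.label))
  if (anyNA(s)) stop("non-numeric node support labels")
  if (any(s < 0 | s > 100)) stop("supports must lie in [0, 100]")
  s
}
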