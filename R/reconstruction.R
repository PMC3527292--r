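#' Marginal ancestral state reconstruction by the pruning algorithm
#'
#' Computes, for every requested alignment site and every internal node of
#' a rooted tree, the exact marginal posterior distribution over the four
#' nucleotide states under a reversible substitution model: a Felsenstein
#' pruning (post-order) pass for inside partial likelihoods and a pre-order
#' outside pass, combined and normalized per node. Per-site likelihoods are
#' invariant to traversal order.
#'
#' @param aln A [strain_alignment()] (or a character matrix of states,
#'   strains x sites).
#' @param tree Rooted `phylo`; tip labels must match the alignment strains.
#' @param model A `subst_model`, e.g. [model_hky()]; defaults to an HKY
#'   model estimated from the alignment by [estimate_hky()].
#' @param sites Alignment columns to reconstruct (default: all).
#' @return Object of class `ancestral_reconstruction`: list with
#'   `posterior` (list over internal node numbers, each a 4 x n_sites
#'   matrix, columns normalized to 1), `sites`, `tree`, `model`,
#'   `loglik` (per-site log-likelihoods).
#' @export
marginal_ancestral_reconstruction <- function(aln, tree, model = NULL,
                                              sites = NULL) {
  states <- if (inherits(aln, "strain_alignment"))
    do.call(rbind, strsplit(aln$seqs, "")) else aln
  if (inherits(aln, "strain_alignment")) rownames(states) <- names(aln$seqs)
  if (is.null(model)) {
    if (!inherits(aln, "strain_alignment"))
      stop("model must be supplied when aln is a plain matrix")
    model <- estimate_hky(aln)
  }
  stopifnot(inherits(model, "subst_model"))
  if (!all(tree$tip.label %in% rownames(states)))
    stop("data error: tree leaves missing from alignment: ",
         paste(setdiff(tree$tip.label, rownames(states)), collapse = ", "))
  sites <- sites %||% seq_len(ncol(states))
  S <- length(sites)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L

  post_edges <- reorder(tree, "postorder")
  edge <- post_edges$edge
  elen <- post_edges$edge.length
  P <- lapply(seq_len(nrow(edge)),
              function(k) transition_matrix(model, elen[k]))
  # inside (pruning) partials, rescaled per node for stability
  inside <- vector("list", ntip + nnode)
  logscale <- numeric(S)
  for (i in seq_len(ntip)) {
    obs <- states[tree$tip.label[i], sites]
    m <- matrix(0, 4, S, dimnames = list(base_order, NULL))
    known <- obs %in% base_order
    m[cbind(match(obs[known], base_order), which(known))] <- 1
    m[, !known] <- 1  # gaps/ambiguity: uninformative
    inside[[i]] <- m
  }
  child_msg <- vector("list", ntip + nnode)  # P_e %*% inside[child]
  children <- vector("list", ntip + nnode)
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    children[[par]] <- c(children[[par]], ch)
    child_msg[[ch]] <- P[[k]] %*% inside[[ch]]
    if (is.null(inside[[par]])) inside[[par]] <- child_msg[[ch]]
    else inside[[par]] <- inside[[par]] * child_msg[[ch]]
  }
  # rescale internal partials (postorder node order = last edges per parent)
  for (v in unique(edge[, 1])) {
    mx <- apply(inside[[v]], 2, max)
    mx[mx == 0] <- 1
    inside[[v]] <- sweep(inside[[v]], 2, mx, `/`)
    if (v == root) logscale <- logscale + log(mx)
  }
  site_lik <- colSums(model$pi * inside[[root]])
  # outside pass (pre-order): outside[root] = pi; the outside message of a
  # child combines the parent's outside with its siblings' inside messages
  outside <- vector("list", ntip + nnode)
  outside[[root]] <- matrix(model$pi, 4, S)
  pre <- reorder(tree, "cladewise")
  pre_edge <- pre$edge
  pre_P <- lapply(seq_len(nrow(pre_edge)), function(k)
    transition_matrix(model, pre$edge.length[k]))
  for (k in seq_len(nrow(pre_edge))) {
    par <- pre_edge[k, 1]; ch <- pre_edge[k, 2]
    sib_prod <- matrix(1, 4, S)
    for (sb in children[[par]])
      if (sb != ch) sib_prod <- sib_prod * child_msg[[sb]]
    m <- t(pre_P[[k]]) %*% (outside[[par]] * sib_prod)
    mx <- apply(m, 2, max); mx[mx == 0] <- 1
    outside[[ch]] <- sweep(m, 2, mx, `/`)
  }
  posterior <- vector("list", ntip + nnode)
  for (v in (ntip + 1L):(ntip + nnode)) {
    m <- outside[[v]] * inside[[v]]
    tot <- colSums(m)
    tot[tot == 0] <- 1
    posterior[[v]] <- sweep(m, 2, tot, `/`)
  }
  structure(list(posterior = posterior, sites = sites, tree = tree,
                 model = model, loglik = log(site_lik) + logscale,
                 states = states[tree$tip.label, sites, drop = FALSE]),
            class = "ancestral_reconstruction")
}

#' Brute-force marginal posteriors by exhaustive enumeration (oracle)
#'
#' Enumerates all `4^n_internal` joint ancestral assignments and sums their
#' probabilities, yielding exact marginal posteriors for small trees.
#' Intended to validate [marginal_ancestral_reconstruction()]; refuses
#' trees with more than 8 internal nodes.
#'
#' @param states Character matrix (strains x sites) of leaf states.
#' @param tree Rooted `phylo`.
#' @param model A `subst_model`.
#' @param sites Columns to evaluate (default all).
#' @return List over internal node numbers of 4 x n_sites posterior
#'   matrices.
#' @export
enumerate_ancestral_posteriors <- function(states, tree, model,
                                           sites = NULL) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  if (nnode > 8) stop("state space too large for enumeration")
  sites <- sites %||% seq_len(ncol(states))
  S <- length(sites)
  root <- ntip + 1L
  edge <- tree$edge
  P <- lapply(seq_len(nrow(edge)),
              function(k) transition_matrix(model, tree$edge.length[k]))
  internal <- (ntip + 1L):(ntip + nnode)
  grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  colnames(grid) <- internal
  leaf_idx <- sapply(tree$tip.label, function(l)
    match(states[l, sites], base_order))
  leaf_idx <- matrix(leaf_idx, nrow = S)  # sites x tips
  post <- lapply(seq_len(ntip + nnode), function(i) NULL)
  for (v in internal) post[[v]] <- matrix(0, 4, S,
                                          dimnames = list(base_order, NULL))
  total <- numeric(S)
  for (g in seq_len(nrow(grid))) {
    assign_g <- grid[g, ]
    pr <- rep(model$pi[assign_g[as.character(root)]], S)
    for (k in seq_len(nrow(edge))) {
      par <- edge[k, 1]; ch <- edge[k, 2]
      sp <- assign_g[as.character(par)]
      if (ch <= ntip) {
        pr <- pr * P[[k]][sp, ][leaf_idx[, ch]]
      } else {
        pr <- pr * P[[k]][sp, assign_g[as.character(ch)]]
      }
    }
    total <- total + pr
    for (v in internal)
      post[[v]][assign_g[as.character(v)], ] <-
        post[[v]][assign_g[as.character(v)], ] + pr
  }
  for (v in internal) post[[v]] <- sweep(post[[v]], 2, total, `/`)
  post
}
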