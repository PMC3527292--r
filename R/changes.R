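# Tree scaffolding used by the parsimony routines: children lists, parent
# vector and a postorder node sequence, with optional collapsing of
# poorly-supported internal nodes into polytomies.
tree_scaffold <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  parent <- integer(ntip + nnode)
  children <- vector("list", ntip + nnode)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  post <- reorder(tree, "postorder")$edge
  # internal nodes in child-before-parent order, root last: a node appears
  # as a child in postorder only after its whole subtree was emitted
  ord <- c(post[, 2][post[, 2] > ntip], ntip + 1L)
  list(ntip = ntip, nnode = nnode, root = ntip + 1L,
       parent = parent, children = children, internal_postorder = ord)
}

collapse_scaffold <- function(tree, scaffold, supports, threshold) {
  ntip <- scaffold$ntip
  deleted <- rep(FALSE, ntip + scaffold$nnode)
  internal <- (ntip + 1L):(ntip + scaffold$nnode)
  deleted[internal] <- supports < threshold
  deleted[scaffold$root] <- FALSE
  eff_parent <- scaffold$parent
  for (v in c(seq_len(ntip), internal)) {
    if (v == scaffold$root) next
    p <- scaffold$parent[v]
    while (p != scaffold$root && deleted[p]) p <- scaffold$parent[p]
    eff_parent[v] <- p
  }
  children <- vector("list", ntip + scaffold$nnode)
  for (v in seq_along(eff_parent)) {
    if (v == scaffold$root || deleted[v]) next
    children[[eff_parent[v]]] <- c(children[[eff_parent[v]]], v)
  }
  ord <- scaffold$internal_postorder
  list(ntip = ntip, nnode = scaffold$nnode, root = scaffold$root,
       parent = eff_parent, children = children,
       internal_postorder = ord[!deleted[ord]], deleted = deleted)
}

# Hartigan's generalization of Fitch parsimony (exact on polytomies).
# leaf_state: integer 1..4 per tip. Returns the minimal event count, the
# per-node optimal state sets, and a deterministic most-parsimonious
# labeling (ties broken toward `prefer`, then ACGT order).
hartigan <- function(sc, leaf_state, prefer) {
  nn <- sc$ntip + sc$nnode
  V <- matrix(FALSE, nn, 4)
  V[cbind(seq_len(sc$ntip), leaf_state)] <- TRUE
  count <- 0L
  for (v in sc$internal_postorder) {
    kids <- sc$children[[v]]
    cnt <- colSums(V[kids, , drop = FALSE])
    K <- max(cnt)
    V[v, ] <- cnt == K
    count <- count + length(kids) - K
  }
  # top-down labeling
  label <- integer(nn)
  label[seq_len(sc$ntip)] <- leaf_state
  root_set <- V[sc$root, ]
  label[sc$root] <- if (root_set[prefer]) prefer else which(root_set)[1]
  for (v in rev(sc$internal_postorder)) {
    for (ch in sc$children[[v]]) {
      if (ch <= sc$ntip) next
      s <- V[ch, ]
      label[ch] <- if (s[label[v]]) label[v]
      else if (s[prefer]) prefer else which(s)[1]
    }
  }
  events <- list()
  for (v in sc$internal_postorder) {
    for (ch in sc$children[[v]]) {
      if (label[ch] != label[v])
        events[[length(events) + 1L]] <- c(parent = v, child = ch)
    }
  }
  list(count = count, V = V, label = label,
       events = if (length(events)) do.call(rbind, events) else
         matrix(integer(0), 0, 2, dimnames = list(NULL, c("parent", "child"))))
}

#' Call high-confidence single-nucleotide changes
#'
#' Applies the three change filters to reconstructed site histories:
#' (a) a single event suffices to explain the site's state distribution
#' (parsimony count of exactly one, Hartigan/Fitch with outgroup
#' polarization); (b) the ancestral node of the implicated branch supports
#' the ancestral base with posterior at least `posterior_threshold`;
#' (c) the inference survives collapsing all internal nodes with bootstrap
#' support below `support_threshold` into polytomies — the event count must
#' remain one and the implicated branch identical. Changes whose single
#' event would sit ambiguously on either side of the root are discarded.
#'
#' @param reconstruction An `ancestral_reconstruction` (must carry leaf
#'   `states`).
#' @param tree Rooted `phylo` with support `node.label`; defaults to the
#'   reconstruction's tree.
#' @param support_threshold Bootstrap support threshold (percent).
#' @param posterior_threshold Minimum posterior for the ancestral base.
#' @param positions Reference positions of the reconstructed sites
#'   (defaults to the alignment column indices).
#' @param outgroup Outgroup tip label used for ancestral-state tie breaks.
#' @return data.frame of class `change_set`: position, from, to, branch,
#'   posterior, fitch_count, min_support.
#' @export
call_high_confidence_changes <- function(reconstruction,
                                         tree = reconstruction$tree,
                                         support_threshold = 98,
                                         posterior_threshold = 0.9,
                                         positions = reconstruction$sites,
                                         outgroup = NULL) {
  states <- reconstruction$states
  if (is.null(states))
    stop("reconstruction does not carry leaf states")
  outgroup <- outgroup %||% (attr(tree, "outgroup") %||% "outgroup")
  if (!outgroup %in% tree$tip.label) stop("outgroup not in tree")
  supports <- node_supports(tree)
  sc <- tree_scaffold(tree)
  csc <- collapse_scaffold(tree, sc, supports, support_threshold)
  og_tip <- match(outgroup, tree$tip.label)
  S <- ncol(states)
  if (length(positions) != S) stop("positions/states length mismatch")
  leaf_idx <- matrix(match(states[tree$tip.label, , drop = FALSE],
                           base_order), nrow = length(tree$tip.label))
  rows <- list()
  for (j in seq_len(S)) {
    ls <- leaf_idx[, j]
    if (anyNA(ls)) next
    if (length(unique(ls)) == 1L) next  # no change possible
    fit <- hartigan(sc, ls, prefer = ls[og_tip])
    if (fit$count != 1L) next
    ev <- fit$events
    if (nrow(ev) != 1L) next
    par <- ev[1, "parent"]; ch <- ev[1, "child"]
    # event adjacent to the root with ambiguous root state: direction
    # would depend on arbitrary rooting of the event
    if (par == sc$root && sum(fit$V[sc$root, ]) > 1L) next
    from <- base_order[fit$label[par]]
    to <- base_order[fit$label[ch]]
    pp <- reconstruction$posterior[[par]][from, j]
    if (is.na(pp) || pp < posterior_threshold) next
    if (csc$deleted[ch]) next
    cfit <- hartigan(csc, ls, prefer = ls[og_tip])
    if (cfit$count != 1L || nrow(cfit$events) != 1L) next
    if (cfit$events[1, "child"] != ch) next
    min_support <- supports[par - sc$ntip]
    if (ch > sc$ntip) min_support <- min(min_support, supports[ch - sc$ntip])
    rows[[length(rows) + 1L]] <- data.frame(
      position = positions[j], from = from, to = to,
      branch = node_label(tree, ch), posterior = pp,
      fitch_count = 1L, min_support = min_support,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), from = character(0),
               to = character(0), branch = character(0),
               posterior = numeric(0), fitch_count = integer(0),
               min_support = numeric(0))
  class(out) <- c("change_set", "data.frame")
  out
}

#' Parsimony event count of one site (Hartigan/Fitch)
#' @param tree Rooted `phylo`.
#' @param states Named character vector of leaf states.
#' @param outgroup Outgroup tip label for tie-breaking.
#' @return Integer minimal event count.
#' @export
fitch_count <- function(tree, states, outgroup = "outgroup") {
  sc <- tree_scaffold(tree)
  ls <- match(states[tree$tip.label], base_order)
  hartigan(sc, ls, prefer = ls[match(outgroup, tree$tip.label)])$count
}
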