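# Reversible nucleotide substitution models. A model is a list with
# `Q` (4x4 rate matrix, rows sum to 0, scaled to one expected substitution
# per unit branch length) and `pi` (stationary frequencies, order ACGT).

base_order <- c("A", "C", "G", "T")

build_reversible_q <- function(exch, freqs) {
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  Q <- exch %*% diag(freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(base_order, base_order)
  Q
}

exch_matrix <- function(ac, ag, at, cg, ct, gt) {
  m <- matrix(0, 4, 4, dimnames = list(base_order, base_order))
  m["A", "C"] <- m["C", "A"] <- ac
  m["A", "G"] <- m["G", "A"] <- ag
  m["A", "T"] <- m["T", "A"] <- at
  m["C", "G"] <- m["G", "C"] <- cg
  m["C", "T"] <- m["T", "C"] <- ct
  m["G", "T"] <- m["T", "G"] <- gt
  m
}

new_subst_model <- function(name, exch, freqs) {
  freqs <- setNames(as.numeric(freqs), base_order)
  Q <- build_reversible_q(exch, freqs)
  if (max(abs(rowSums(Q))) > 1e-10) stop("non-stochastic model: rows of Q must sum to 0")
  # symmetric decomposition for stable matrix exponentials
  sp <- sqrt(freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(name = name, Q = Q, pi = freqs,
                 eig = eig, sqrt_pi = sp),
            class = "subst_model")
}

#' Nucleotide substitution models
#'
#' Reversible models usable by [marginal_ancestral_reconstruction()]:
#' Jukes-Cantor, Kimura two-parameter, HKY (transition/transversion ratio
#' `kappa` plus arbitrary base frequencies) and GTR (six exchangeabilities
#' plus frequencies). Rate matrices are scaled to one expected substitution
#' per unit branch length.
#'
#' @param kappa Transition/transversion rate ratio.
#' @param freqs Base frequencies in ACGT order (must sum to 1).
#' @param rates GTR exchangeabilities in order AC, AG, AT, CG, CT, GT.
#' @return Object of class `subst_model`.
#' @export
model_jc <- function() new_subst_model("JC", exch_matrix(1, 1, 1, 1, 1, 1),
                                       rep(0.25, 4))

#' @rdname model_jc
#' @export
model_k80 <- function(kappa = 2) {
  if (kappa <= 0) stop("kappa must be positive")
  new_subst_model("K80", exch_matrix(1, kappa, 1, 1, kappa, 1), rep(0.25, 4))
}

#' @rdname model_jc
#' @export
model_hky <- function(kappa = 2, freqs = rep(0.25, 4)) {
  if (kappa <= 0) stop("kappa must be positive")
  new_subst_model("HKY", exch_matrix(1, kappa, 1, 1, kappa, 1), freqs)
}

#' @rdname model_jc
#' @export
model_gtr <- function(rates, freqs = rep(0.25, 4)) {
  if (length(rates) != 6 || any(rates < 0))
    stop("GTR needs 6 non-negative exchangeabilities")
  new_subst_model("GTR", exch_matrix(rates[1], rates[2], rates[3],
                                     rates[4], rates[5], rates[6]), freqs)
}

#' Transition probability matrix P(t) of a model
#' @param model A `subst_model`.
#' @param t Branch length (expected substitutions per site).
#' @return 4x4 probability matrix (rows: from, ACGT order).
#' @export
transition_matrix <- function(model, t) {
  e <- model$eig
  P <- diag(1 / model$sqrt_pi) %*% e$vectors %*%
    diag(exp(e$values * t)) %*% t(e$vectors) %*% diag(model$sqrt_pi)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(base_order, base_order)
  P
}

#' Estimate an HKY model from an alignment by method of moments
#'
#' Base frequencies are empirical over all strains; kappa is derived from
#' the observed transition/transversion count over all strain pairs at
#' variable columns via the HKY expectation
#' `E[ts/tv] = kappa * (pA*pG + pC*pT) / sum(cross transversion terms)`.
#'
#' @param aln A [strain_alignment()].
#' @return A `subst_model` of type HKY.
#' @export
estimate_hky <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  v <- as.vector(m)
  v <- v[v %in% base_order]
  freqs <- table(factor(v, levels = base_order))
  freqs <- as.numeric(freqs) / sum(freqs)
  # pairwise mismatch classification on a sample of strain pairs
  nr <- nrow(m)
  ts <- 0; tv <- 0
  is_ts <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  for (i in seq_len(nr - 1)) {
    x <- m[i, ]; y <- m[i + 1, ]
    ok <- x %in% base_order & y %in% base_order & x != y
    ts <- ts + sum(is_ts(x[ok], y[ok]))
    tv <- tv + sum(ok) - sum(is_ts(x[ok], y[ok]))
  }
  ratio <- if (tv == 0) 2 else ts / max(tv, 1)
  p <- setNames(freqs, base_order)
  denom <- p["A"] * p["C"] + p["A"] * p["T"] + p["C"] * p["G"] +
    p["G"] * p["T"]
  kappa <- max(ratio * denom / (p["A"] * p["G"] + p["C"] * p["T"]), 0.1)
  model_hky(kappa = as.numeric(kappa), freqs = freqs)
}
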