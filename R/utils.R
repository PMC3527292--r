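#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so deterministic helpers do not perturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Mixes the global seed with the stage name so pipeline stages get
#' independent but reproducible streams. The result is always a positive
#' integer below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return Integer seed.
#' @export
#' @examples
#' stage_seed(1, "simulate")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((abs(seed) * 69069 + h * 977 + 1) %% 2147483562L + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The twelve strand-specific mutation types
#'
#' Ordered base pairs written `"X>Y"` on the strand of reference
#' (sense strand for genic sites).
#'
#' @return Character vector of length 12.
#' @export
mutation_types <- function() {
  b <- c("A", "C", "G", "T")
  unlist(lapply(b, function(x) paste0(x, ">", setdiff(b, x))))
}

#' The six strand-collapsed mutation couples
#'
#' Complementary type pairs labelled by their pyrimidine member, e.g.
#' `C:G>T:A` comprises `C>T` and `G>A`.
#'
#' @return Named list mapping couple label to its two strand-specific types.
#' @export
mutation_couples <- function() {
  list(
    "C:G>T:A" = c("C>T", "G>A"),
    "C:G>A:T" = c("C>A", "G>T"),
    "C:G>G:C" = c("C>G", "G>C"),
    "A:T>G:C" = c("A>G", "T>C"),
    "A:T>C:G" = c("A>C", "T>G"),
    "A:T>T:A" = c("A>T", "T>A")
  )
}

#' Transition mutation types
#' @return Character vector: the four strand-specific transitions.
#' @export
transition_types <- function() c("A>G", "G>A", "C>T", "T>C")

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

#' Growth phase labels in temporal order
#' @return Character vector of the four assayed growth phases.
#' @export
growth_phases <- function() {
  c("mid_exponential", "late_exponential", "transition", "stationary")
}

#' The four nucleoid-associated proteins
#' @return Character vector of protein names.
#' @export
nap_proteins <- function() c("Fis", "H-NS", "IhfA", "IhfB")

#' Column-safe key for a protein name
#' @param protein Character vector of protein names.
#' @return Lower-case alphanumeric keys (e.g. `"hns"` for `"H-NS"`).
#' @export
protein_key <- function(protein) {
  tolower(gsub("[^A-Za-z0-9]", "", protein))
}
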