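#' Random-forest classifier parameters
#'
#' Defaults follow the published settings: a very large forest (10,000
#' trees), depth capped at 10, K = 2 features per split, and a 5:1 weight
#' on the minority (changed) class. Tests and desk-scale analyses pass a
#' smaller `n_trees`.
#'
#' @param n_trees Number of trees.
#' @param max_depth Maximum tree depth.
#' @param k Features considered per split (ranger's `mtry`).
#' @param class_weights Named weights for the outcome classes.
#' @param seed Integer seed.
#' @return Object of class `classifier_params`.
#' @export
classifier_params <- function(n_trees = 10000, max_depth = 10, k = 2,
                              class_weights = c(changed = 5, unchanged = 1),
                              seed = 1L) {
  stopifnot(n_trees >= 1, k >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth), k = as.integer(k),
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "classifier_params")
}

#' Assemble a classifier dataset with 5:1 subsampling
#'
#' Keeps the changed class intact and subsamples the unchanged class
#' without replacement to exactly `ratio` times its size. If fewer
#' unchanged rows exist, all are used with a warning.
#'
#' @param site_table A `site_table` with a logical `changed` column (as
#'   from [simulate_site_table()]) or with `sense_base` columns for
#'   type-specific assembly.
#' @param mutation_type Optional type such as `"C>T"`: rows are restricted
#'   to at-risk sites (sense base equal to the type's from-base) and
#'   `changed` is recomputed for that type from a `change_type` column.
#' @param ratio Unchanged:changed target ratio.
#' @param seed Integer seed for the subsample.
#' @return Object of class `classifier_dataset`: list with `data` (outcome
#'   factor `outcome` in {unchanged, changed} plus features),
#'   `binding_cols`, `mutation_type`, `ratio`.
#' @export
assemble_dataset <- function(site_table, mutation_type = NULL, ratio = 5,
                             seed = 1L) {
  st <- as.data.frame(site_table)
  if (!is.null(mutation_type)) {
    from_b <- substr(mutation_type, 1, 1)
    if (!"sense_base" %in% names(st))
      stop("type-specific assembly needs a sense_base column")
    st <- st[!is.na(st$sense_base) & st$sense_base == from_b, , drop = FALSE]
    st$changed <- !is.na(st$change_type) & st$change_type == mutation_type
    st$change_type <- NULL
  }
  if (!"changed" %in% names(st)) stop("site table lacks a changed column")
  changed_rows <- which(st$changed)
  unchanged_rows <- which(!st$changed)
  if (length(changed_rows) == 0) stop("dataset error: zero changed rows")
  target <- ratio * length(changed_rows)
  sel <- if (length(unchanged_rows) < target) {
    warning("fewer unchanged than ", ratio, "x changed; using all")
    unchanged_rows
  } else {
    with_seed(stage_seed(seed, "subsample"),
              sort(sample(unchanged_rows, target)))
  }
  dat <- st[c(changed_rows, sel), , drop = FALSE]
  dat$outcome <- factor(ifelse(dat$changed, "changed", "unchanged"),
                        levels = c("unchanged", "changed"))
  dat$changed <- NULL
  dat$position <- NULL
  binding_cols <- grep("^(binding$|cat_)", names(dat), value = TRUE)
  structure(list(data = dat, binding_cols = binding_cols,
                 mutation_type = mutation_type, ratio = ratio),
            class = "classifier_dataset")
}

#' Area under the ROC curve from scores
#' @param scores Numeric predicted scores.
#' @param labels Logical (TRUE = positive) or the outcome factor.
#' @return AUC in [0, 1] (rank statistic; ties share credit).
#' @export
auc_from_scores <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "changed"
  ok <- !is.na(scores)
  scores <- scores[ok]; pos <- pos[ok]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit the random forest and score it by out-of-bag AUC
#'
#' Fits a probability forest with the configured size, depth cap, K and
#' class weights, and computes the AUC from out-of-bag predicted
#' probabilities of the changed class.
#'
#' @param dataset A `classifier_dataset`.
#' @param params A [classifier_params()].
#' @return Numeric out-of-bag AUC.
#' @export
fit_and_score <- function(dataset, params) {
  stopifnot(inherits(dataset, "classifier_dataset"),
            inherits(params, "classifier_params"))
  dat <- dataset$data
  if (length(unique(dat$outcome)) < 2)
    stop("fit error: single-class dataset")
  n_features <- ncol(dat) - 1L
  if (params$k > n_features)
    stop("K exceeds the number of features")
  cw <- params$class_weights[levels(dat$outcome)]
  fit <- ranger::ranger(
    dependent.variable.name = "outcome", data = dat,
    num.trees = params$n_trees, mtry = params$k,
    max.depth = params$max_depth, probability = TRUE,
    class.weights = as.numeric(cw), seed = params$seed,
    num.threads = 1, verbose = FALSE)
  scores <- fit$predictions[, "changed"]
  auc_from_scores(scores, dat$outcome)
}

#' Optimize K, the features considered per split
#'
#' Evaluates the out-of-bag AUC over a K grid for each mutation dataset,
#' min-max normalizes the AUC profile to [0, 1] within each dataset, and
#' returns the K maximizing the across-dataset mean; ties go to the
#' smallest K.
#'
#' @param datasets List of `classifier_dataset`s.
#' @param params A [classifier_params()] (its `k` is ignored).
#' @param k_grid Candidate K values (default 1..n_features).
#' @return List of class `k_optimization`: `k_star`, `auc` (datasets x K),
#'   `normalized`, `k_grid`.
#' @export
optimize_split_features <- function(datasets, params, k_grid = NULL) {
  stopifnot(length(datasets) >= 1)
  n_features <- ncol(datasets[[1]]$data) - 1L
  k_grid <- k_grid %||% seq_len(n_features)
  if (any(k_grid < 1 | k_grid > n_features)) stop("k_grid out of bounds")
  auc <- matrix(NA_real_, length(datasets), length(k_grid),
                dimnames = list(NULL, k_grid))
  for (i in seq_along(datasets)) {
    for (j in seq_along(k_grid)) {
      pj <- params
      pj$k <- as.integer(k_grid[j])
      pj$seed <- stage_seed(params$seed, paste0("kopt_", i, "_", k_grid[j]))
      auc[i, j] <- fit_and_score(datasets[[i]], pj)
    }
  }
  sel <- select_k(auc, k_grid)
  structure(list(k_star = sel$k_star, auc = auc, normalized = sel$normalized,
                 k_grid = k_grid), class = "k_optimization")
}

#' Aggregate an AUC grid into the optimal K
#'
#' The aggregation rule behind [optimize_split_features()]: min-max
#' normalize each dataset's AUC profile to [0, 1], average across
#' datasets, and take the argmax; ties (including the fully degenerate
#' constant-AUC case, which warns) resolve to the smallest K.
#'
#' @param auc Numeric matrix, datasets x K grid.
#' @param k_grid K values corresponding to the columns.
#' @return List with `k_star` and the `normalized` matrix.
#' @export
select_k <- function(auc, k_grid = seq_len(ncol(auc))) {
  norm <- t(apply(auc, 1, function(x) {
    rng <- max(x) - min(x)
    if (rng == 0) rep(0, length(x)) else (x - min(x)) / rng
  }))
  if (nrow(auc) == 1) norm <- matrix(norm, nrow = 1)
  if (all(norm == 0))
    warning("AUC constant across K in every dataset; returning smallest K")
  avg <- colMeans(norm)
  best <- abs(avg - max(avg)) < 1e-12
  list(k_star = k_grid[which(best)[1]], normalized = norm)
}

#' Binding-randomization significance test
#'
#' Refits the classifier `n_rand` times with all binding columns shuffled
#' jointly across rows (one permutation applied to the whole binding
#' block, preserving inter-protein correlation) and compares the observed
#' out-of-bag AUC to the approximately normal randomized AUCs via a
#' Z-score; the one-tailed P is the upper tail, since the only relevant
#' outcome is a drop in AUC upon randomization.
#'
#' @param dataset A `classifier_dataset` with at least one binding column.
#' @param params A [classifier_params()].
#' @param n_rand Number of randomizations.
#' @param seed Integer seed.
#' @return List of class `randomization_result`: `auc_observed`,
#'   `auc_randomized` (length `n_rand`), `z`, `p_one_tailed`,
#'   `sd_zero` flag.
#' @export
binding_randomization_test <- function(dataset, params, n_rand = 50,
                                       seed = 1L) {
  if (length(dataset$binding_cols) == 0)
    stop("dataset has no binding feature")
  p0 <- params
  p0$seed <- stage_seed(seed, "observed_fit")
  auc_obs <- fit_and_score(dataset, p0)
  n <- nrow(dataset$data)
  auc_rand <- numeric(n_rand)
  for (r in seq_len(n_rand)) {
    perm <- with_seed(stage_seed(seed, paste0("perm_", r)), sample.int(n))
    ds <- dataset
    ds$data[dataset$binding_cols] <-
      dataset$data[perm, dataset$binding_cols, drop = FALSE]
    pr <- params
    pr$seed <- stage_seed(seed, paste0("rand_fit_", r))
    auc_rand[r] <- fit_and_score(ds, pr)
  }
  s <- sd(auc_rand)
  sd_zero <- !is.finite(s) || s == 0
  z <- if (sd_zero) NA_real_ else (auc_obs - mean(auc_rand)) / s
  p <- if (sd_zero) NA_real_ else pnorm(z, lower.tail = FALSE)
  structure(list(auc_observed = auc_obs, auc_randomized = auc_rand,
                 z = z, p_one_tailed = p, sd_zero = sd_zero),
            class = "randomization_result")
}
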