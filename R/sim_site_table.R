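#' Configuration for the direct site-table simulator
#'
#' Parameters of the logistic shortcut generator that draws per-site
#' changed/unchanged outcomes directly from features, so classifier and
#' odds-ratio recovery analyses do not need full sequence evolution.
#'
#' @param n_sites Number of at-risk sites.
#' @param intercept Logit-scale intercept (baseline change probability
#'   `plogis(intercept)`).
#' @param binding_coef Either a single number (log-odds of being changed
#'   for any bound category versus `never`) or a named vector of log-odds
#'   per non-reference binding category.
#' @param binding_probs Named probabilities of the five binding categories.
#' @param confounder_coefs Named list of log-odds coefficients for the
#'   confounders: `log_expr` (applied to centred log expression, per
#'   phase), `lagging` (lagging versus leading strand), `origin_dist`
#'   (scaled 0-1 distance from the replication origin), `gc` (centred
#'   local GC), `twofold` (2-fold versus 4-fold degeneracy).
#' @param seed Integer seed.
#' @return Object of class `site_sim_config`.
#' @export
site_sim_config <- function(n_sites = 30000,
                            intercept = qlogis(0.05),
                            binding_coef = 0,
                            binding_probs = c(never = 0.45, early = 0.20,
                                              late = 0.15, always = 0.10,
                                              other = 0.10),
                            confounder_coefs = list(log_expr = -0.2,
                                                    lagging = 0.3,
                                                    origin_dist = -0.2,
                                                    gc = 0.5,
                                                    twofold = -0.1),
                            seed = 1L) {
  cats <- binding_categories()
  if (!setequal(names(binding_probs), cats))
    stop("binding_probs must be named over the five binding categories")
  if (abs(sum(binding_probs) - 1) > 1e-8)
    stop("binding_probs must sum to 1")
  bc <- setNames(rep(0, 4), setdiff(cats, "never"))
  if (length(binding_coef) == 1 && is.null(names(binding_coef))) {
    bc[] <- binding_coef
  } else {
    if (!all(names(binding_coef) %in% names(bc)))
      stop("binding_coef names must be bound categories")
    bc[names(binding_coef)] <- binding_coef
  }
  structure(list(n_sites = as.integer(n_sites), intercept = intercept,
                 binding_coef = bc, binding_probs = binding_probs[cats],
                 confounder_coefs = confounder_coefs,
                 seed = as.integer(seed)),
            class = "site_sim_config")
}

#' Simulate a site table directly from a logistic outcome model
#'
#' Draws independent per-site features (binding category, per-phase
#' expression, replication strand, origin distance, local GC, degeneracy
#' class) and a changed/unchanged outcome from a logistic model whose
#' coefficients are recorded as ground truth. Because binding enters the
#' linear predictor as a category coefficient, the true odds ratio of a
#' bound category versus `never` is exactly `exp(coefficient)`.
#'
#' @param config A [site_sim_config()].
#' @param seed Optional seed overriding the config's.
#' @return List with `sites` (data.frame of class `site_table`; outcome
#'   column `changed` is logical) and `truth` (class `ground_truth`,
#'   recording all coefficients).
#' @export
#' @examples
#' st <- simulate_site_table(site_sim_config(n_sites = 1000))
#' mean(st$sites$changed)
simulate_site_table <- function(config, seed = NULL) {
  stopifnot(inherits(config, "site_sim_config"))
  seed <- seed %||% config$seed
  n <- config$n_sites
  cc <- config$confounder_coefs
  with_seed(stage_seed(seed, "site_table"), {
    binding <- factor(sample(names(config$binding_probs), n, replace = TRUE,
                             prob = config$binding_probs),
                      levels = binding_categories())
    expr <- vapply(growth_phases(), function(p) rlnorm(n, 0, 1),
                   numeric(n))
    colnames(expr) <- paste0("expr_", growth_phases())
    strand <- factor(sample(c("leading", "lagging"), n, replace = TRUE),
                     levels = c("leading", "lagging"))
    origin_dist <- runif(n)
    gc <- pmin(pmax(rnorm(n, 0.5, 0.05), 0), 1)
    degeneracy <- factor(sample(c("fourfold", "twofold"), n, replace = TRUE,
                                prob = c(0.7, 0.3)),
                         levels = c("fourfold", "twofold"))
    lp <- config$intercept +
      ifelse(binding == "never", 0, config$binding_coef[as.character(binding)]) +
      cc$log_expr * log(expr[, 1]) +
      cc$lagging * (strand == "lagging") +
      cc$origin_dist * origin_dist +
      cc$gc * (gc - 0.5) * 10 +
      cc$twofold * (degeneracy == "twofold")
    p <- plogis(lp)
    if (any(p >= 0.5))
      stop("per-site change probability must lie in (0, 0.5); ",
           "lower the intercept or coefficients")
    changed <- runif(n) < p
    sites <- data.frame(position = seq_len(n), changed = changed,
                        binding = binding, expr, strand = strand,
                        origin_dist = origin_dist, gc = gc,
                        degeneracy = degeneracy)
    class(sites) <- c("site_table", "data.frame")
    truth <- structure(list(intercept = config$intercept,
                            binding_coef = config$binding_coef,
                            confounder_coefs = cc,
                            config = config),
                       class = "ground_truth")
    list(sites = sites, truth = truth)
  })
}
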