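write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build and validate a pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Global seed; stage seeds are derived from it with
#'   [stage_seed()].
#' @param simulate Generate all inputs with the synthetic-data module
#'   (`TRUE`) or load them from `paths` (`FALSE`).
#' @param sim Named list of [sim_config()] overrides.
#' @param mask Run the uniqueness-mask stage.
#' @param classifier Run the (slow) classifier randomization stage.
#' @param classifier_opts Options for that stage: `n_trees`, `n_rand`,
#'   `types`.
#' @param paths For `simulate = FALSE`: named list with `alignment`,
#'   `tree`, `beds` (directory), `genes`, optional `blocks`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, simulate = TRUE,
                            sim = list(), mask = TRUE, classifier = FALSE,
                            classifier_opts = list(n_trees = 200,
                                                   n_rand = 10,
                                                   types = "C>T"),
                            paths = list()) {
  cfg <- list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
              sim = sim, mask = mask, classifier = classifier,
              classifier_opts = classifier_opts, paths = paths)
  if (!simulate) {
    fields <- c("alignment", "tree", "beds", "genes")
    for (field in fields)
      if (is.null(paths[[field]]))
        stop("pipeline config missing field 'paths$", field, "'")
    for (field in fields)
      if (!file.exists(paths[[field]]))
        stop("pipeline config: paths$", field, " does not exist: ",
             paths[[field]])
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> uniqueness mask -> site filters ->
#' ancestral reconstruction -> change calling -> binding categories ->
#' stratified mutability and odds ratios -> methylation-context analysis
#' and permutation test -> optional classifier randomization, writing
#' every stage's outputs under `outdir` plus a manifest with parameters
#' and file checksums. Rerunning an identical configuration reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()], a named list of its arguments, or
#'   the path of a YAML file holding them.
#' @return The manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list())
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- res$summary
    res$value
  }

  # -- inputs: simulate or load ------------------------------------------
  inputs <- run_stage("inputs", function() {
    if (config$simulate) {
      sim <- do.call(sim_config,
                     modifyList(list(seed = stage_seed(config$seed, "sim")),
                                config$sim))
      tree <- make_strain_tree(sim$n_strains,
                               seed = stage_seed(config$seed, "tree"),
                               branch_mean = sim$branch_mean,
                               outgroup_scale = sim$outgroup_scale,
                               low_support_fraction = sim$low_support_fraction)
      genome <- simulate_genome(sim)
      profiles <- simulate_binding_profiles(genome, sim)
      ev <- evolve_alignment(genome, tree, profiles, sim)
      write_fasta(setNames(genome$sequence, "reference"),
                  file.path(out, "genome.fasta"))
      write_alignment(ev$alignment, file.path(out, "alignment.fasta"),
                      file.path(out, "blocks.tsv"))
      ape::write.tree(tree, file.path(out, "tree.nwk"))
      write_binding_beds(profiles, file.path(out, "beds"))
      write_gene_table(genome, file.path(out, "genes.tsv"))
      write_tsv(ev$truth$changes, file.path(out, "truth.tsv"))
      list(value = list(genome = genome, tree = tree, profiles = profiles,
                        aln = ev$alignment, truth = ev$truth),
           summary = list(n_strains = sim$n_strains,
                          genome_length = genome$length,
                          n_true_changes = nrow(ev$truth$changes)))
    } else {
      aln <- read_alignment(config$paths$alignment,
                            config$paths$blocks %||% NULL)
      tree <- ape::read.tree(config$paths$tree)
      profiles <- load_binding_profiles(config$paths$beds)
      genes <- read.table(config$paths$genes, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      refseq <- gsub("-", "", aln$seqs[[aln$reference]])
      genome <- nap_genome(refseq, genes)
      list(value = list(genome = genome, tree = tree, profiles = profiles,
                        aln = aln, truth = NULL),
           summary = list(n_strains = length(aln$seqs) - 1L,
                          genome_length = genome$length))
    }
  })

  # -- uniqueness mask ----------------------------------------------------
  mask <- run_stage("mask", function() {
    m <- if (config$mask)
      compute_uniqueness_mask(inputs$genome$sequence) else IRanges::IRanges()
    write_tsv(data.frame(chrom = rep("genome", length(m)),
                         start = IRanges::start(m) - 1L,
                         end = IRanges::end(m)),
              file.path(out, "mask.bed"))
    list(value = m,
         summary = list(masked_bases = sum(IRanges::width(m))))
  })

  # -- analyzable sites ---------------------------------------------------
  sites <- run_stage("sites", function() {
    s <- extract_analyzable_sites(inputs$aln, mask)
    write_tsv(data.frame(position = s$census, ref_base = s$ref_base),
              file.path(out, "census.tsv"))
    list(value = s, summary = list(n_census = length(s$census),
                                   n_polymorphic = length(s$polymorphic)))
  })

  # -- reconstruction and change calling ---------------------------------
  changes <- run_stage("changes", function() {
    poly_cols <- match(sites$polymorphic,
                       alignment_ref_positions(inputs$aln))
    recon <- marginal_ancestral_reconstruction(inputs$aln, inputs$tree,
                                               sites = poly_cols)
    ch <- call_high_confidence_changes(recon, inputs$tree,
                                       positions = sites$polymorphic)
    write_tsv(ch, file.path(out, "changes.tsv"))
    list(value = ch,
         summary = list(n_changes = nrow(ch),
                        model = recon$model$name,
                        kappa = unname(recon$model$Q["C", "T"] /
                                         recon$model$Q["C", "A"])))
  })

  # -- site table with binding and contexts ------------------------------
  site_tab <- run_stage("site_table", function() {
    ctx <- scan_methylation_contexts(inputs$genome$sequence)
    st <- build_site_table(inputs$genome, sites$census, inputs$profiles,
                           ctx)
    write_tsv(st, file.path(out, "site_table.tsv"))
    list(value = list(table = st, contexts = ctx),
         summary = list(n_sites = nrow(st),
                        n_ccwgg = sum(ctx$motif == "CCWGG")))
  })
  st <- site_tab$table

  # -- stratified mutability and odds ratios -----------------------------
  mut <- run_stage("mutability", function() {
    tab_any <- tabulate_mutability(changes, st, stratum = "bound_any",
                                   collapse_couples = TRUE)
    write_tsv(tab_any, file.path(out, "mutability_bound_vs_unbound.tsv"))
    ors <- list()
    for (cp in names(mutation_couples())) {
      b <- tab_any[tab_any$type == cp & tab_any$stratum == "bound", ]
      u <- tab_any[tab_any$type == cp & tab_any$stratum == "unbound", ]
      if (nrow(b) == 0 || nrow(u) == 0) next
      o <- odds_ratio_ci(b$n_changes, b$n_at_risk, u$n_changes, u$n_at_risk,
                         orientation = "unbound vs bound")
      o$type <- cp
      ors[[cp]] <- o
    }
    or_any <- do.call(rbind, ors)
    write_tsv(or_any, file.path(out, "or_bound_vs_unbound.tsv"))
    timing_rows <- list()
    for (key in protein_key(names(inputs$profiles$profiles))) {
      tc <- paste0("timing_", key)
      if (!tc %in% names(st)) next
      tab_t <- suppressWarnings(
        tabulate_mutability(changes, st, stratum = tc,
                            collapse_couples = TRUE))
      for (cp in names(mutation_couples())) {
        e <- tab_t[tab_t$type == cp & tab_t$stratum == "exclusively_early", ]
        l <- tab_t[tab_t$type == cp & tab_t$stratum == "exclusively_late", ]
        if (nrow(e) == 0 || nrow(l) == 0) next
        o <- odds_ratio_ci(l$n_changes, l$n_at_risk, e$n_changes,
                           e$n_at_risk,
                           orientation = "exclusively_early vs exclusively_late")
        o$type <- cp
        o$protein <- key
        timing_rows[[paste(key, cp)]] <- o
      }
    }
    or_timing <- if (length(timing_rows)) do.call(rbind, timing_rows) else
      data.frame()
    write_tsv(or_timing, file.path(out, "or_timing.tsv"))
    list(value = list(bound_vs_unbound = tab_any, or_any = or_any,
                      or_timing = or_timing),
         summary = list(n_or = nrow(or_any)))
  })

  # -- methylation contexts and permutation test -------------------------
  ctx_res <- run_stage("contexts", function() {
    timing_cols <- c("position", grep("^timing_", names(st), value = TRUE))
    ctx_tab <- context_mutability(site_tab$contexts, changes,
                                  st[timing_cols])
    write_tsv(ctx_tab, file.path(out, "context_mutability.tsv"))
    cc <- combo_counts(ctx_tab)
    write_tsv(cc, file.path(out, "combo_counts.tsv"))
    perm <- NULL
    if (!anyNA(observed_conformity_pattern(cc))) {
      perm <- permutation_pvalue(cc, n_reps = 100000,
                                 seed = stage_seed(config$seed, "perm"))
      jsonlite::write_json(
        list(p_value = perm$p_value, n_reps = perm$n_reps,
             n_all_conform = perm$n_all_conform,
             observed_conformity = as.list(perm$observed_conformity)),
        file.path(out, "permutation.json"), auto_unbox = TRUE)
    }
    list(value = list(context_tab = ctx_tab, combos = cc, perm = perm),
         summary = list(p_value = if (is.null(perm)) NA else perm$p_value))
  })

  # -- optional classifier randomization ---------------------------------
  if (config$classifier) {
    run_stage("classifier", function() {
      co <- config$classifier_opts
      cl_tab <- classifier_site_features(inputs$genome, st, changes)
      rows <- list()
      for (tp in co$types) {
        ds <- assemble_dataset(cl_tab, mutation_type = tp,
                               seed = stage_seed(config$seed, tp))
        params <- classifier_params(n_trees = co$n_trees %||% 200,
                                    seed = stage_seed(config$seed, "rf"))
        res <- binding_randomization_test(ds, params,
                                          n_rand = co$n_rand %||% 10,
                                          seed = stage_seed(config$seed,
                                                            paste0("bt_", tp)))
        rows[[tp]] <- data.frame(type = tp, auc_obs = res$auc_observed,
                                 auc_rand_mean = mean(res$auc_randomized),
                                 auc_rand_sd = sd(res$auc_randomized),
                                 z = res$z, p = res$p_one_tailed)
      }
      tab <- do.call(rbind, rows)
      write_tsv(tab, file.path(out, "classifier_results.tsv"))
      list(value = tab, summary = list(types = co$types))
    })
  }

  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest$files <- as.list(tools::md5sum(file.path(out, files)))
  names(manifest$files) <- files
  manifest$package_version <- as.character(utils::packageVersion("napmut"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Per-site feature table for the pipeline classifier stage
#'
#' Derives confounder features available from sequence alone: local GC
#' (401 bp window), scaled distance from the origin (position 1, circular),
#' gene strand, degeneracy class, plus the binding category columns from
#' the site table; attaches the observed sense-strand change type.
#'
#' @param genome A `nap_genome`.
#' @param site_table A `site_table` with binding categories.
#' @param changes A `change_set`.
#' @return data.frame ready for [assemble_dataset()].
#' @export
classifier_site_features <- function(genome, site_table, changes) {
  st <- site_table[!is.na(site_table$sense_strand) &
                     site_table$site_class %in% c("fourfold", "twofold"), ]
  seq_v <- strsplit(genome$sequence, "")[[1]]
  isgc <- as.integer(seq_v %in% c("G", "C"))
  cs <- cumsum(c(0L, isgc))
  L <- genome$length
  w <- 200L
  lo <- pmax(st$position - w, 1L)
  hi <- pmin(st$position + w, L)
  st$local_gc <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  d <- pmin(st$position - 1L, L - st$position + 1L)
  st$origin_dist <- d / (L / 2)
  st$gene_strand <- factor(st$sense_strand, levels = c("+", "-"))
  st$degeneracy <- factor(st$site_class, levels = c("fourfold", "twofold"))
  idx <- match(st$position, changes$position)
  from <- changes$from[idx]; to <- changes$to[idx]
  minus <- st$sense_strand == "-"
  from[minus & !is.na(from)] <- complement_base(from[minus & !is.na(from)])
  to[minus & !is.na(to)] <- complement_base(to[minus & !is.na(to)])
  st$change_type <- ifelse(is.na(from), NA, paste0(from, ">", to))
  keep <- c("position", "sense_base", "change_type", "local_gc",
            "origin_dist", "gene_strand", "degeneracy",
            grep("^cat_", names(st), value = TRUE))
  st[keep]
}
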