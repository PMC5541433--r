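# FNV-1a 32-bit hash of a string; used to stamp reports with a config
# fingerprint without depending on a hashing package.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); h is kept as a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime, split to stay inside the
    # exact-double range
    lo16 <- h %% 65536
    hi16 <- h %/% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

derive_seed <- function(master_seed, stage) {
  # deterministic per-stage seed, kept well below 2^31
  (as.integer(master_seed) * 10007L +
     sum(as.integer(charToRaw(stage)))) %% 2000000000L
}

#' Read and validate a pipeline run configuration
#'
#' Configurations are JSON with a `master_seed`, an `out_dir`, and one
#' block per requested stage (`simulate`, `maturity`, `reporter`,
#' `network`, `diversity`); stage parameters mirror the corresponding
#' function arguments and all have defaults. Only stages with a block are
#' run. Per-stage seeds are derived deterministically from the master seed.
#'
#' @param path JSON config file.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list (already parsed).
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$master_seed)) cfg$master_seed <- 1L
  cfg$master_seed <- as.integer(cfg$master_seed)
  if (is.null(cfg$out_dir)) stop("config needs 'out_dir'")
  known <- c("master_seed", "out_dir", "simulate", "maturity", "reporter",
             "network", "diversity")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config blocks: ", paste(unknown, collapse = ", "))
  stages <- intersect(names(cfg), known[-(1:2)])
  if (length(stages) == 0) stop("config requests no stages")
  structure(cfg, class = "run_config")
}

stage_error <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order (simulate -> maturity
#' -> reporter -> network -> diversity), writing TSV/JSON/GraphML outputs
#' into the config's `out_dir`. Every report is stamped with the config
#' hash and the per-stage seeds, so identical configs reproduce identical
#' bundles. A failing stage aborts the run with a stage-named error.
#'
#' @param config a `run_config` (or a path to a JSON config file).
#' @return invisibly, a list with the in-memory stage results and the
#'   report (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(unclass(config))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  stamp <- list(config_hash = fnv1a32(as.character(cfg_json)),
                master_seed = config$master_seed, seeds = list())
  results <- list()
  report <- list(stamp = stamp)
  log_line <- function(...) message(sprintf(...))

  # -- simulate ------------------------------------------------------------
  cohort <- NULL
  if (!is.null(config$simulate)) {
    seed <- derive_seed(config$master_seed, "simulate")
    report$stamp$seeds$simulate <- seed
    cohort <- tryCatch({
      sim <- config$simulate
      cc <- cohort_config(
        n_taxa = sim$n_taxa %||% 40,
        n_age_taxa = sim$n_age_taxa %||% 12,
        sampling_days = sim$sampling_days %||% seq(1, 42, by = 3),
        n_per_day = sim$n_per_day %||% 6,
        groups = if (!is.null(sim$groups)) unlist(sim$groups) else
          c(control = 1, probiotic = 2, antibiotic = 0.75),
        noise_sd = sim$noise_sd %||% 0.3,
        depth = sim$depth %||% 2490,
        seed = seed)
      generate_cohort(cc)
    }, error = function(e) stage_error("simulate", e))
    write_abundance_table(cohort$table, file.path(out_dir, "cohort_counts.tsv"))
    write_sample_metadata(cohort$metadata, file.path(out_dir, "cohort_metadata.tsv"))
    jsonlite::write_json(cohort$truth, file.path(out_dir, "cohort_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    results$simulate <- cohort
    log_line("stage simulate: %d samples written", ncol(cohort$table$values))
  }

  load_inputs <- function(block) {
    if (!is.null(block$table) && !is.null(block$metadata)) {
      list(table = read_abundance_table(block$table),
           metadata = read_sample_metadata(block$metadata))
    } else if (!is.null(cohort)) {
      list(table = cohort$table, metadata = cohort$metadata)
    } else stop("no input: provide 'table'/'metadata' paths or a simulate block")
  }

  # -- maturity ------------------------------------------------------------
  if (!is.null(config$maturity)) {
    seed <- derive_seed(config$master_seed, "maturity")
    report$stamp$seeds$maturity <- seed
    res <- tryCatch({
      blk <- config$maturity
      inp <- load_inputs(blk)
      cfg <- age_model_config(
        n_trees = blk$n_trees %||% 5000,
        n_importance_iters = blk$n_importance_iters %||% 100,
        cv_folds = blk$cv_folds %||% 10,
        cv_tolerance = blk$cv_tolerance %||% 0.05,
        seed = seed)
      run_maturity_analysis(inp$table, inp$metadata,
                            control_group = blk$control_group %||% "control",
                            config = cfg, delta = blk$delta %||% 0.05)
    }, error = function(e) stage_error("maturity", e))
    write.table(res$predictions, file.path(out_dir, "microbiota_age.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$maturity <- list(
      selected_taxa = res$model$selected_taxa$taxon,
      k = res$selection$k, train_r2 = res$model$train_r2,
      plateaus = lapply(res$curves, function(cv)
        list(plateau_age = cv$plateau_age, plateau_value = cv$plateau_value)),
      immi = lapply(res$immi, function(im)
        list(immi_days = im$immi_days, censored = im$censored)))
    results$maturity <- res
    log_line("stage maturity: k = %d, train R2 = %.3f", res$selection$k,
             res$model$train_r2)
  }

  # -- reporter ------------------------------------------------------------
  if (!is.null(config$reporter)) {
    seed <- derive_seed(config$master_seed, "reporter")
    report$stamp$seeds$reporter <- seed
    res <- tryCatch({
      blk <- config$reporter
      if (!is.null(blk$ko_table)) {
        tab <- read_ko_table(blk$ko_table)
        meta <- read_sample_metadata(blk$metadata)
        pathways <- read_pathway_map(blk$pathways)
      } else {
        ks <- generate_ko_study(ko_study_config(
          enriched_pathways = unlist(blk$enriched_pathways %||% character(0)),
          effect_size = blk$effect_size %||% 2, seed = seed))
        tab <- ks$table; meta <- ks$metadata; pathways <- ks$pathways
      }
      groups <- meta$group[match(sample_ids(tab), meta$sample_id)]
      reporter_scores(tab, groups, pathways,
                      threshold = blk$threshold %||% 1.6,
                      n_sets = blk$n_sets %||% 1000, seed = seed)
    }, error = function(e) stage_error("reporter", e))
    write.table(res$ko_results, file.path(out_dir, "ko_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$scores, file.path(out_dir, "reporter_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$reporter <- list(
      n_marker_kos = sum(res$ko_results$marker),
      significant_pathways = call_enriched_pathways(res))
    results$reporter <- res
    log_line("stage reporter: %d significant pathways",
             sum(res$scores$significant))
  }

  # -- network -------------------------------------------------------------
  if (!is.null(config$network)) {
    seed <- derive_seed(config$master_seed, "network")
    report$stamp$seeds$network <- seed
    res <- tryCatch({
      blk <- config$network
      inp <- load_inputs(blk)
      rel <- to_relative(inp$table)
      meta <- inp$metadata
      if (!is.null(blk$group)) {
        keep <- meta$sample_id[meta$group == blk$group]
        rel <- subset_table(rel, samples = keep, reclose = TRUE)
        meta <- meta[meta$group == blk$group, ]
      }
      temporal_networks(rel, meta,
                        periods = blk$periods %||% NULL,
                        n_permutations = blk$n_permutations %||% 999,
                        seed = seed,
                        min_abs_rho = blk$min_abs_rho %||% 0.3,
                        max_q = blk$max_q %||% 0.05)
    }, error = function(e) stage_error("network", e))
    write_edge_list(res$pooled, file.path(out_dir, "network_edges.tsv"))
    write_network_graphml(res$pooled, file.path(out_dir, "network.graphml"))
    report$network <- list(
      pooled = list(density = res$pooled$density,
                    centralization = res$pooled$centralization,
                    mean_abs_rho = res$pooled$mean_abs_rho),
      periods = lapply(res$periods, function(nt)
        list(density = nt$density, centralization = nt$centralization,
             mean_abs_rho = nt$mean_abs_rho)))
    results$network <- res
    log_line("stage network: pooled density %.3f", res$pooled$density)
  }

  # -- diversity -----------------------------------------------------------
  if (!is.null(config$diversity)) {
    seed <- derive_seed(config$master_seed, "diversity")
    report$stamp$seeds$diversity <- seed
    res <- tryCatch({
      blk <- config$diversity
      inp <- load_inputs(blk)
      if (inp$table$kind != "counts")
        stop("diversity stage requires a count table")
      tab <- if (isTRUE(blk$rarefy %||% TRUE))
        rarefy(inp$table, depth = blk$depth %||% 2490, seed = seed,
               drop_shallow = TRUE) else inp$table
      meta <- inp$metadata[inp$metadata$sample_id %in% sample_ids(tab), ]
      alpha <- alpha_diversity(tab)
      d <- beta_distance(tab, metric = blk$metric %||% "bray")
      grp <- meta$group[match(sample_ids(tab), meta$sample_id)]
      list(alpha = alpha,
           permanova = permanova(d, grp,
                                 n_permutations = blk$n_permutations %||% 999,
                                 seed = seed),
           anosim = anosim(d, grp,
                           n_permutations = blk$n_permutations %||% 999,
                           seed = seed),
           kruskal = genus_kruskal(tab, meta))
    }, error = function(e) stage_error("diversity", e))
    write.table(res$alpha, file.path(out_dir, "alpha_diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$diversity <- list(
      permanova = list(F = res$permanova$statistic, p = res$permanova$p),
      anosim = list(R = res$anosim$statistic, p = res$anosim$p))
    results$diversity <- res
    log_line("stage diversity: PERMANOVA F = %.3f (p = %.3g)",
             res$permanova$statistic, res$permanova$p)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(results = results, report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
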