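#' Configuration for a full pipeline run
#'
#' Collects every stage's settings: either a simulation config or paths
#' to input TSVs, the rare-taxon filter, the network edge thresholds,
#' the cohesion null-model settings and grouping, and the SEM path
#' list.
#'
#' @param simulate logical; generate the dataset with
#'   [simulate_dataset()] (default) instead of reading input files.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param input_dir directory holding `counts.tsv`, `metadata.tsv`,
#'   `traits.tsv` when `simulate = FALSE`.
#' @param min_prevalence,min_mean_relabund rare-taxon filter thresholds
#'   (see [filter_taxa()]).
#' @param cor_method correlation estimator for networks
#'   (`"spearman"` default).
#' @param r_min,alpha network edge thresholds (see [build_network()]).
#' @param cohesion_iters,cohesion_null cohesion null-model draws per
#'   orientation and null family.
#' @param cohesion_method correlation estimator inside cohesion
#'   (pipeline default `"spearman"`: rank-based, so latent negative
#'   associations survive the lognormal abundance scale).
#' @param cohesion_group metadata column grouping the cohesion
#'   estimation; NULL (default) estimates connectedness jointly from
#'   all samples, a column name (e.g. `"n_rate"`) estimates it within
#'   groups.
#' @param sem_paths character vector of `"parent -> child"` strings.
#' @param seed master seed; each stage derives its own stream.
#' @return an object of class `analysis_config` (validated list).
#' @export
analysis_config <- function(simulate = TRUE,
                            sim = sim_config(),
                            input_dir = NULL,
                            min_prevalence = 0.2,
                            min_mean_relabund = 0,
                            cor_method = "spearman",
                            r_min = 0.6,
                            alpha = 0.05,
                            cohesion_iters = 200,
                            cohesion_null = "taxa_shuffle",
                            cohesion_method = "spearman",
                            cohesion_group = NULL,
                            sem_paths = NULL,
                            seed = 1) {
  if (r_min <= 0 || r_min >= 1) {
    ngn_abort("r_min must lie in (0, 1)", "ngn_config_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    ngn_abort("alpha must lie in (0, 1)", "ngn_config_error")
  }
  if (!simulate && is.null(input_dir)) {
    ngn_abort("either simulate = TRUE or an input_dir is required",
              "ngn_config_error")
  }
  if (simulate) sim <- validate_sim_config(sim)
  cfg <- list(simulate = simulate, sim = sim, input_dir = input_dir,
              min_prevalence = min_prevalence,
              min_mean_relabund = min_mean_relabund,
              cor_method = cor_method, r_min = r_min, alpha = alpha,
              cohesion_iters = cohesion_iters,
              cohesion_null = cohesion_null,
              cohesion_method = cohesion_method,
              cohesion_group = cohesion_group,
              sem_paths = sem_paths, seed = as.integer(seed))
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [analysis_config()]; a `sim`
#' block mirrors [sim_config()].
#'
#' @param path YAML file path.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) {
    ngn_abort(sprintf("config file not found: %s", path), "ngn_io_error")
  }
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$n_levels)) {
    sim_args$n_levels <- as.numeric(unlist(sim_args$n_levels))
  }
  y$sim <- do.call(sim_config, sim_args)
  if (!is.null(y$sem_paths)) y$sem_paths <- unlist(y$sem_paths)
  do.call(analysis_config, y)
}

# assemble the per-sample table feeding trends, partials, and the SEM
sample_table <- function(bundle, relabund, coh, idx) {
  rich <- observed_richness(bundle$counts)
  meta <- bundle$metadata
  out <- meta
  out$n_dose <- n_dose(meta$n_rate)
  out <- dplyr::left_join(out, rich, by = "sample_id")
  out <- dplyr::left_join(
    out, dplyr::select(coh$cohesion, "sample_id", pos_cohesion = "pos",
                       neg_cohesion = "neg", total_cohesion = "total",
                       neg_pos_ratio = "neg_pos_ratio"),
    by = "sample_id")
  out <- dplyr::left_join(
    out, dplyr::select(idx, "sample_id", "copio_oligo_ratio", "cwm_rrn",
                       "cwm_gc", "rk_pc1"),
    by = "sample_id")
  out
}

#' Run the full nitrogen-gradient analysis pipeline
#'
#' Executes simulate/load -> validate -> filter -> per-level signed
#' networks and topology -> complexity PC1 -> cohesion -> life-history
#' trait indices -> gradient trends -> partial correlations ->
#' piecewise SEM, writing per-stage TSVs, a deterministic
#' `summary.json`, a `manifest.json` (paths, digests, timestamps), and
#' a plain-text log into `out_dir`. The summary contains no paths or
#' timestamps, so identical seeds give byte-identical summaries.
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory (created; must be empty of a
#'   previous COMPLETED manifest unless `overwrite = TRUE`).
#' @param overwrite logical; allow writing over an existing run.
#' @return the run manifest (list), invisibly; on stage failure the
#'   manifest is written with a FAILED marker and the error re-raised.
#' @export
run_full_pipeline <- function(config = analysis_config(), out_dir,
                              overwrite = FALSE) {
  if (!inherits(config, "analysis_config")) {
    ngn_abort("config must come from analysis_config()", "ngn_config_error")
  }
  if (missing(out_dir)) ngn_abort("out_dir is required", "ngn_config_error")
  if (!config$simulate) {
    for (f in c("counts.tsv", "metadata.tsv", "traits.tsv")) {
      if (!file.exists(file.path(config$input_dir, f))) {
        ngn_abort(sprintf("missing input file: %s",
                          file.path(config$input_dir, f)), "ngn_io_error")
      }
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!overwrite && file.exists(file.path(out_dir, "manifest.json"))) {
    ngn_abort("out_dir already holds a run; set overwrite = TRUE",
              "ngn_io_error")
  }
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("[%s] pipeline start, seed %d\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), config$seed),
      file = log_path)
  logmsg <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  stage <- "setup"
  outputs <- character(0)
  emit <- function(tbl, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(tbl, p, progress = FALSE)
    outputs <<- c(outputs, name)
    p
  }
  result <- tryCatch({
    stage <- "data"
    if (config$simulate) {
      sim <- config$sim
      sim$rng_seed <- derive_seed(config$seed, "simulate")
      class(sim) <- "sim_config"
      ds <- simulate_dataset(sim)
      bundle <- validate_bundle(ds$counts, ds$metadata, ds$traits)
      write_bundle(ds, out_dir)
      outputs <- c(outputs, "counts.tsv", "metadata.tsv", "traits.tsv",
                   "truth.json", "config.json")
    } else {
      bundle <- read_bundle(config$input_dir)
    }
    logmsg("data: %d taxa x %d samples", nrow(bundle$counts),
           nrow(bundle$metadata))

    stage <- "filter"
    filtered <- filter_taxa(bundle$counts, config$min_prevalence,
                            config$min_mean_relabund)
    bundle <- validate_bundle(filtered, bundle$metadata, bundle$traits)
    relabund <- to_relative_abundance(bundle$counts)
    emit(bundle$counts, "filtered_counts.tsv")
    logmsg("filter: %d taxa retained", nrow(bundle$counts))

    stage <- "network"
    levels <- sort(unique(bundle$metadata$n_rate))
    topo <- list()
    edges_all <- list()
    nodes_all <- list()
    for (lv in levels) {
      sid <- bundle$metadata$sample_id[bundle$metadata$n_rate == lv]
      corr <- pairwise_correlation(relabund[c("taxon_id", sid)],
                                   method = config$cor_method)
      net <- build_network(corr, r_min = config$r_min,
                           alpha = config$alpha)
      tp <- topology(net)
      tp$network_id <- as.character(lv)
      topo[[as.character(lv)]] <- tp
      if (nrow(net$edges) > 0) {
        e <- net$edges
        e$network_id <- as.character(lv)
        edges_all[[as.character(lv)]] <- e
      }
      if (nrow(net$nodes) > 0) {
        nd <- net$nodes
        nd$network_id <- as.character(lv)
        nodes_all[[as.character(lv)]] <- nd
      }
    }
    topo_tbl <- dplyr::bind_rows(topo)
    emit(topo_tbl, "topology.tsv")
    emit(dplyr::bind_rows(edges_all) %||%
           tibble(taxon_a = character(), taxon_b = character()),
         "edges.tsv")
    emit(dplyr::bind_rows(nodes_all) %||%
           tibble(taxon_id = character()), "nodes.tsv")
    logmsg("network: %d per-level networks", nrow(topo_tbl))

    stage <- "complexity_pca"
    pca <- complexity_pc1(topo_tbl)
    pc1 <- dplyr::left_join(tidy.complexity_pca(pca),
                            tibble(network_id = as.character(levels),
                                   n_rate = levels),
                            by = "network_id")
    emit(pc1, "network_pc1.tsv")

    stage <- "cohesion"
    coh <- compute_cohesion(relabund, bundle$metadata,
                            group = config$cohesion_group,
                            n_iter = config$cohesion_iters,
                            seed = derive_seed(config$seed, "cohesion"),
                            null = config$cohesion_null,
                            method = config$cohesion_method)
    emit(coh$cohesion, "cohesion.tsv")
    emit(coh$connectedness, "connectedness.tsv")
    logmsg("cohesion: %d samples", nrow(coh$cohesion))

    stage <- "traits"
    idx <- rk_strategy_pc1(trait_indices(relabund, bundle$traits))
    emit(idx, "trait_indices.tsv")
    guild_rich <- richness_by_guild(bundle$counts, bundle$traits)
    emit(guild_rich, "guild_richness.tsv")

    stage <- "trends"
    samp <- sample_table(bundle, relabund, coh, idx)
    emit(samp, "sample_table.tsv")
    trend_specs <- c("din", "ph", "plant_richness", "richness",
                     "pos_cohesion", "neg_cohesion", "total_cohesion",
                     "neg_pos_ratio", "copio_oligo_ratio", "cwm_rrn",
                     "cwm_gc", "rk_pc1")
    trends <- purrr::map_dfr(trend_specs, function(v) {
      trend_row(gradient_trend(samp, v))
    })
    trends <- dplyr::bind_rows(
      trends,
      trend_row(gradient_trend(pc1, "pc1")),
      {
        oli <- dplyr::filter(guild_rich, .data$guild == "oligotroph")
        oli <- dplyr::left_join(oli, bundle$metadata[c("sample_id",
                                                       "n_rate")],
                                by = "sample_id")
        tr <- trend_row(gradient_trend(oli, "richness"))
        tr$response <- "oligotroph_richness"
        tr
      })
    emit(trends, "trends.tsv")

    stage <- "partial_correlations"
    partials <- dplyr::bind_rows(
      partial_correlation(samp, "total_cohesion", "richness", "rk_pc1"),
      partial_correlation(samp, "total_cohesion", "rk_pc1", "richness")
    )
    emit(partials, "partial_correlations.tsv")

    stage <- "sem"
    spec <- if (is.null(config$sem_paths)) default_sem_spec() else
      sem_spec(config$sem_paths)
    sem <- fit_piecewise_sem(samp, spec)
    emit(sem$paths, "sem_paths.tsv")
    emit(sem$claims, "sem_claims.tsv")
    logmsg("sem: Fisher's C = %.3f (df %d, p %.3f)", sem$fit$fisher_c,
           sem$fit$df, sem$fit$p_value)

    stage <- "summary"
    summary <- list(
      seed = config$seed,
      settings = config_echo(config),
      topology = topo_tbl,
      network_pc1 = pc1,
      pc1_loadings = as.data.frame(pca$loadings[, 1, drop = FALSE]),
      cohesion = coh$cohesion,
      trait_indices = idx,
      trends = trends,
      partial_correlations = partials,
      sem = list(paths = sem$paths, r2 = sem$r2, claims = sem$claims,
                 fisher_c = sem$fit)
    )
    summary_path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = 10, dataframe = "rows", pretty = TRUE)
    outputs <- c(outputs, "summary.json")
    list(summary = summary, outputs = outputs)
  }, error = function(e) {
    manifest <- list(status = "FAILED", failed_stage = stage,
                     error = conditionMessage(e),
                     outputs = as.list(outputs),
                     package_version =
                       as.character(utils::packageVersion("ngradnet")),
                     timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    logmsg("FAILED at stage %s: %s", stage, conditionMessage(e))
    ngn_abort(sprintf("pipeline failed at stage %s: %s", stage,
                      conditionMessage(e)), "ngn_pipeline_error")
  })
  files <- file.path(out_dir, result$outputs)
  manifest <- list(
    status = "COMPLETED",
    seed = config$seed,
    settings = config_echo(config),
    outputs = as.list(result$outputs),
    digests = as.list(stats::setNames(
      unname(tools::md5sum(files)), result$outputs)),
    package_version = as.character(utils::packageVersion("ngradnet")),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logmsg("pipeline complete: %d outputs", length(result$outputs))
  invisible(manifest)
}

# config echo without paths, so summaries are location-independent
config_echo <- function(config) {
  list(
    simulate = config$simulate,
    sim = if (config$simulate) unclass(config$sim) else NULL,
    min_prevalence = config$min_prevalence,
    min_mean_relabund = config$min_mean_relabund,
    cor_method = config$cor_method,
    r_min = config$r_min, alpha = config$alpha,
    cohesion_iters = config$cohesion_iters,
    cohesion_null = config$cohesion_null,
    cohesion_method = config$cohesion_method,
    cohesion_group = config$cohesion_group,
    sem_paths = config$sem_paths
  )
}

#' One-page text report of a completed run
#'
#' Summarizes the gradient trends (direction and p), the cohesion
#' ratio trend, the SEM path table, and the Fisher's C line. A pure
#' function of the run directory contents: regenerating the report
#' gives identical text.
#'
#' @param run_dir directory written by [run_full_pipeline()] (or the
#'   path of its `manifest.json`).
#' @return the report as a character vector of lines, invisibly;
#'   printed to the console.
#' @export
summarize_report <- function(run_dir) {
  if (grepl("manifest\\.json$", run_dir)) run_dir <- dirname(run_dir)
  mp <- file.path(run_dir, "manifest.json")
  if (!file.exists(mp)) {
    ngn_abort(sprintf("no manifest found in %s", run_dir), "ngn_io_error")
  }
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (!identical(manifest$status, "COMPLETED")) {
    ngn_abort(sprintf("run is not complete (status %s, stage %s)",
                      manifest$status,
                      manifest$failed_stage %||% "?"), "ngn_validate_error")
  }
  s <- jsonlite::read_json(file.path(run_dir, "summary.json"),
                           simplifyVector = TRUE)
  fmt_trend <- function(row) {
    sprintf("  %-20s slope %+.4f  p = %.4g", row$response, row$slope,
            row$p_value)
  }
  trends <- s$trends
  lines <- c(
    "Nitrogen-gradient network analysis",
    sprintf("seed %d; %d N levels", s$seed, nrow(s$topology)),
    "",
    "Gradient trends (per unit log2(N+1)):",
    vapply(seq_len(nrow(trends)), function(i) fmt_trend(trends[i, ]),
           character(1)),
    "",
    sprintf("Cohesion negative:positive ratio trend: slope %+.4f (p = %.4g)",
            trends$slope[trends$response == "neg_pos_ratio"],
            trends$p_value[trends$response == "neg_pos_ratio"]),
    "",
    "Piecewise SEM standardized paths:",
    vapply(seq_len(nrow(s$sem$paths)), function(i) {
      p <- s$sem$paths[i, ]
      sprintf("  %-16s -> %-16s %+.3f  p = %.4g", p$parent, p$child,
              p$std_estimate, p$p_value)
    }, character(1)),
    "",
    sprintf("Fisher's C = %.3f (df = %d, p = %.3f)",
            s$sem$fisher_c$fisher_c, s$sem$fisher_c$df,
            s$sem$fisher_c$p_value)
  )
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
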