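#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the method's
#' standard defaults: top-100 hits, 20 co-regulators per hit, up to 50
#' connectors, MAS5 noise floor 15, both directions, and 100 random sets per
#' null distribution.
#'
#' @param h Hit-list size.
#' @param k Co-regulators per hit.
#' @param max_connectors Maximum connectors added per direction.
#' @param noise_floor Noise floor clamped onto expression values.
#' @param directions `"both"`, `"up"` or `"down"`.
#' @param n_null_sets Random sets per null distribution.
#' @param seed Master RNG seed; every random draw in the pipeline derives
#'   from it.
#' @param null_mode Expression randomization for the CoRegScore null, see
#'   [random_expression_datasets()].
#' @param connector_weighting Candidate weighting, see [rank_candidates()].
#' @param method Differential statistic, see [compute_differences()].
#' @param cond_a,cond_b Condition labels compared (`cond_a` vs `cond_b`).
#' @param config_file Optional YAML file whose entries provide defaults for
#'   any argument not given explicitly (explicit arguments win).
#' @return List of class `run_config` with all values resolved.
#' @export
run_config <- function(h = 100L, k = 20L, max_connectors = 50L,
                       noise_floor = 15, directions = c("both", "up", "down"),
                       n_null_sets = 100L, seed = 1L,
                       null_mode = c("permute_genes", "iid"),
                       connector_weighting = c("occurrence", "distinct"),
                       method = c("log2", "raw"),
                       cond_a = "A", cond_b = "B", config_file = NULL) {
  supplied <- names(match.call())[-1L]
  cfg <- list(h = h, k = k, max_connectors = max_connectors,
              noise_floor = noise_floor,
              directions = match.arg(directions),
              n_null_sets = n_null_sets, seed = seed,
              null_mode = match.arg(null_mode),
              connector_weighting = match.arg(connector_weighting),
              method = match.arg(method),
              cond_a = cond_a, cond_b = cond_b)
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    for (key in intersect(names(file_cfg), names(cfg))) {
      if (!key %in% supplied) cfg[[key]] <- file_cfg[[key]]
    }
  }
  cfg$h <- .sn_assert_scalar_count(cfg$h, "h")
  cfg$k <- .sn_assert_scalar_count(cfg$k, "k")
  cfg$max_connectors <- .sn_assert_scalar_count(cfg$max_connectors,
                                                "max_connectors")
  cfg$n_null_sets <- .sn_assert_scalar_count(cfg$n_null_sets, "n_null_sets",
                                             minimum = 2L)
  if (!is.numeric(cfg$noise_floor) || cfg$noise_floor < 0) {
    stop("noise_floor must be >= 0", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the full network-construction and evaluation pipeline
#'
#' Per direction: rank all genes by expression difference, take the top-h
#' hits, build the pair co-occurrence matrix from their top-k co-regulators,
#' compute the connectivity of the hit-only network, select up to
#' `max_connectors` connectors, recompute connectivity on the expanded
#' network, score the connectors (CoRegScore), and evaluate all three
#' parameters against their empirical nulls — random hit lists for the
#' connectivity parameters, randomized expression datasets for the
#' CoRegScore — reporting Z-scores and one-tailed p-values.
#'
#' @param expression An [expression_dataset()].
#' @param coreg A [coreg_table()].
#' @param config A [run_config()].
#' @param universe Optional [gene_universe()] for random hit lists; defaults
#'   to the genes of the expression dataset.
#' @param out_dir Optional directory; when given, writes per-direction
#'   Cytoscape exports, connector reports, a score report TSV, a JSON
#'   summary (`summary.json`) and a human-readable log (`run_log.txt`).
#' @return List of class `pipeline_report`: `config`, `n_genes`, and per
#'   direction a list with the ranking sizes, metrics, connectors, score and
#'   null statistics.
#' @export
run_pipeline <- function(expression, coreg, config = run_config(),
                         universe = NULL, out_dir = NULL) {
  stopifnot(inherits(expression, "expression_dataset"),
            inherits(coreg, "coreg_table"),
            inherits(config, "run_config"))
  if (is.null(universe)) {
    universe <- gene_universe(rownames(expression$values),
                              source_label = "expression dataset genes")
  }
  log_lines <- character(0L)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    .sn_log(line)
  }
  dirs <- if (config$directions == "both") c("up", "down") else
    config$directions
  note(sprintf(
    "pipeline start: h=%d k=%d max_connectors=%d noise_floor=%g seed=%d",
    config$h, config$k, config$max_connectors, config$noise_floor,
    config$seed))

  ds <- apply_noise_floor(expression, config$noise_floor)
  deltas <- compute_differences(ds, config$cond_a, config$cond_b,
                                method = config$method)
  seeds <- .sn_child_seeds(config$seed, 4L)
  names(seeds) <- c("null_conn_up", "null_score_up", "null_conn_down",
                    "null_score_down")

  results <- list()
  for (dir in dirs) {
    note("direction: ", dir)
    ranking <- rank_genes(deltas, direction = dir)
    hl <- top_hits(ranking, config$h)
    mat <- withCallingHandlers(
      build_pair_matrix(hl, coreg, k = config$k),
      message = function(m) {
        log_lines <<- c(log_lines, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    base_net <- assemble_network(mat, hl, deltas = deltas)
    base_metrics <- connectivity_metrics(base_net)
    candidates <- rank_candidates(mat, weighting = config$connector_weighting)
    connectors <- withCallingHandlers(
      select_connectors(candidates, max_c = config$max_connectors),
      message = function(m) {
        log_lines <<- c(log_lines, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
    expanded_net <- assemble_network(mat, hl, connectors = connectors,
                                     deltas = deltas)
    expanded_metrics <- connectivity_metrics(expanded_net)

    score <- if (length(connectors) > 0L) {
      coreg_score(ranking, config$h, connectors)
    } else {
      note("no connectors selected; CoRegScore unavailable for ", dir)
      NULL
    }

    conn_null <- suppressMessages(null_connectivity(
      universe, coreg, size = config$h, k = config$k,
      n_sets = config$n_null_sets,
      seed = seeds[[paste0("null_conn_", dir)]]))
    score_null <- suppressMessages(null_coreg_score(
      expression, coreg, config$cond_a, config$cond_b,
      h = config$h, k = config$k, max_c = config$max_connectors,
      direction = dir, n_sets = config$n_null_sets,
      seed = seeds[[paste0("null_score_", dir)]],
      mode = config$null_mode, noise_floor = config$noise_floor,
      weighting = config$connector_weighting))

    z_pct <- z_test(base_metrics$percent_included,
                    conn_null$percent_included)
    z_cph <- z_test(base_metrics$connections_per_hit,
                    conn_null$connections_per_hit)
    z_score <- if (!is.null(score) && score_null$score$sigma > 0) {
      z_test(score$score, score_null$score)
    } else NULL

    note(sprintf(
      "%s: %.1f%% hits included (null mu=%.1f sd=%.1f, Z=%.2f, p=%.3g)",
      dir, base_metrics$percent_included, conn_null$percent_included$mu,
      conn_null$percent_included$sigma, z_pct$Z, z_pct$p))
    note(sprintf(
      "%s: %.1f connections per hit (null mu=%.1f sd=%.1f, Z=%.2f, p=%.3g)",
      dir, base_metrics$connections_per_hit,
      conn_null$connections_per_hit$mu, conn_null$connections_per_hit$sigma,
      z_cph$Z, z_cph$p))
    if (!is.null(score)) {
      note(sprintf(
        "%s: CoRegScore %.1f over %d connectors%s", dir, score$score,
        score$C,
        if (!is.null(z_score)) sprintf(" (null mu=%.1f sd=%.1f, Z=%.2f, p=%.3g)",
                                       score_null$score$mu,
                                       score_null$score$sigma, z_score$Z,
                                       z_score$p)
        else ""))
    }

    results[[dir]] <- list(
      direction = dir, N = attr(ranking, "N"),
      hits = hl$genes,
      raw_pair_records = mat$raw_pair_records,
      n_pairs = nrow(mat$pairs),
      base_metrics = base_metrics,
      connectors = as.character(connectors),
      connector_threshold = attr(connectors, "threshold"),
      expanded_metrics = expanded_metrics,
      score = score,
      null_percent_included = conn_null$percent_included,
      null_connections_per_hit = conn_null$connections_per_hit,
      null_score = score_null$score,
      null_score_skipped = score_null$n_skipped,
      z_percent_included = z_pct,
      z_connections_per_hit = z_cph,
      z_score = z_score,
      ranking = ranking,
      network = expanded_net,
      candidates = candidates
    )
  }

  report <- structure(
    list(config = unclass(config), n_genes = nrow(expression$values),
         universe_size = length(universe$genes),
         directions = results),
    class = "pipeline_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (dir in names(results)) {
      res <- results[[dir]]
      export_cytoscape(res$network, file.path(out_dir, dir))
      rep_df <- connector_report(res$candidates, res$connectors,
                                 res$ranking)
      utils::write.table(rep_df,
                         file.path(out_dir, paste0(dir, "_connectors.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_score_report(report, file.path(out_dir, "score_report.tsv"))
    jsonlite::write_json(summarize_report(report),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"), useBytes = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d genes, directions: %s\n", x$n_genes,
              paste(names(x$directions), collapse = ", ")))
  for (res in x$directions) {
    cat(sprintf(
      "  %s: %.1f%% included, %.1f conn/hit, %d connectors, CoRegScore %s\n",
      res$direction, res$base_metrics$percent_included,
      res$base_metrics$connections_per_hit, length(res$connectors),
      if (is.null(res$score)) "NA" else sprintf("%.1f", res$score$score)))
  }
  invisible(x)
}

# Flatten a pipeline report into plain lists for JSON serialization.
#' @keywords internal
#' @noRd
summarize_report <- function(report) {
  list(
    config = report$config,
    n_genes = report$n_genes,
    universe_size = report$universe_size,
    directions = lapply(report$directions, function(res) {
      list(
        direction = res$direction,
        N = res$N,
        n_hits = length(res$hits),
        raw_pair_records = res$raw_pair_records,
        n_unique_pairs = res$n_pairs,
        percent_included = res$base_metrics$percent_included,
        connections_per_hit = res$base_metrics$connections_per_hit,
        n_connectors = length(res$connectors),
        connector_threshold = res$connector_threshold,
        percent_included_expanded = res$expanded_metrics$percent_included,
        connections_per_hit_expanded =
          res$expanded_metrics$connections_per_hit,
        coreg_score = if (is.null(res$score)) NULL else res$score$score,
        null_percent_included = unclass(res$null_percent_included),
        null_connections_per_hit = unclass(res$null_connections_per_hit),
        null_coreg_score = unclass(res$null_score),
        null_score_sets_skipped = res$null_score_skipped,
        z_percent_included = unclass(res$z_percent_included),
        z_connections_per_hit = unclass(res$z_connections_per_hit),
        z_coreg_score = if (is.null(res$z_score)) NULL else
          unclass(res$z_score)
      )
    })
  )
}

#' Write the per-direction score report as TSV
#'
#' Columns: `direction`, `h`, `C`, `N`, `S`, `score`, `mu_null`,
#' `sigma_null`, `Z`, `p` (NA where no connectors could be scored).
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  rows <- lapply(report$directions, function(res) {
    sc <- res$score
    zt <- res$z_score
    data.frame(
      direction = res$direction,
      h = length(res$hits),
      C = if (is.null(sc)) NA_integer_ else sc$C,
      N = res$N,
      S = if (is.null(sc)) NA_real_ else sc$S,
      score = if (is.null(sc)) NA_real_ else sc$score,
      mu_null = res$null_score$mu,
      sigma_null = res$null_score$sigma,
      Z = if (is.null(zt)) NA_real_ else zt$Z,
      p = if (is.null(zt)) NA_real_ else zt$p,
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
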