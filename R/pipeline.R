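# End-to-end pipeline: normalize -> QC -> thresholds -> calls ->
# corroboration -> (optional) network, with all tables, a JSON manifest and
# a log written to an output directory.

#' Run the full screen-analysis pipeline
#'
#' Executes every stage on a well-level table: per-plate normalization,
#' QC (Z-factors, control separation, cross-assay correlation), control
#' thresholds, direction-specific gene calls on the primary assay,
#' corroboration by the companion assays, median ranking, and — when an
#' edge list is supplied — interaction-network hub analysis of the
#' high-stringency hits. All tables are written as CSV, thresholds and QC
#' as JSON, and a manifest records the parameters, input checksums and
#' output files, so a re-run with identical inputs reproduces identical
#' tables.
#'
#' @param wells well records data.frame, or a path readable by
#'   [read_screen_table()].
#' @param out_dir output directory (created if needed).
#' @param annotation optional annotation data.frame or CSV path.
#' @param primary_assay assay driving hit calls (default `"caspase3_7"`).
#' @param direction primary call direction (default `"up"`, i.e. negative
#'   regulators of the pathway being silenced enhance the signal).
#' @param m minimum qualifying siRNAs (default 3); must not exceed the
#'   siRNAs available per gene.
#' @param edge_list optional interaction edge-list path for network
#'   analysis.
#' @param hub_degree hub threshold (default 7).
#' @param quiet suppress progress messages.
#' @return invisible list with the in-memory results (normalized table,
#'   control stats, calls, corroboration, ranking, qc, network, manifest).
#' @export
run_pipeline <- function(wells, out_dir, annotation = NULL,
                         primary_assay = "caspase3_7",
                         direction = "up", m = 3L,
                         edge_list = NULL, hub_degree = 7L,
                         quiet = FALSE) {
  input_path <- NULL
  if (is.character(wells) && length(wells) == 1L) {
    input_path <- wells
    wells <- read_screen_table(wells, quiet = quiet)
  }
  wells <- validate_well_records(wells)
  if (is.character(annotation) && length(annotation) == 1L)
    annotation <- read_annotation(annotation)
  n_sirnas_seen <- length(unique(
    wells$sirna_id[wells$sample_role == "experimental"]))
  if (m > n_sirnas_seen)
    stop_validation(sprintf(
      "m = %d exceeds the %d siRNAs per gene present in the data",
      m, n_sirnas_seen))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("normalizing %d wells", nrow(wells))
  norm <- normalize_to_plate_control(wells)
  agg <- aggregate_sirna(norm)

  say("quality control")
  qc <- qc_report(norm)
  corr <- tryCatch(cross_screen_correlation(agg, condition = "treated"),
                   screen_validation_error = function(e) NULL)

  assays_present <- sort(unique(norm$assay))
  say("calling genes on %s (%s)", primary_assay, direction)
  primary_calls <- call_screen(norm, annotation, assay = primary_assay,
                               direction = direction, m = m)
  viability_calls <- if ("viability" %in% assays_present)
    call_screen(norm, annotation, assay = "viability",
                direction = if (direction == "up") "down" else "up", m = m)
  caspase8_calls <- if ("caspase8" %in% assays_present)
    call_screen(norm, annotation, assay = "caspase8",
                direction = direction, m = m)
  corrob <- corroborate_calls(primary_calls, viability_calls, caspase8_calls)
  ranking <- rank_by_median(agg, assay = primary_assay)

  network <- NULL
  if (!is.null(edge_list)) {
    say("network analysis")
    graph <- read_edge_list(edge_list)
    hits <- primary_calls$gene_id[primary_calls$tier == "+"]
    sg <- hit_subgraph(graph, hits)
    nodes <- hub_nodes(sg$subgraph, min_degree = hub_degree,
                       corroboration = corrob)
    network <- list(subgraph = sg$subgraph, unmapped = sg$unmapped,
                    nodes = nodes)
    utils::write.csv(nodes, file.path(out_dir, "network_nodes.csv"),
                     row.names = FALSE)
    write_sif(sg$subgraph, file.path(out_dir, "hit_subgraph.sif"))
  }

  write_screen_table(norm, file.path(out_dir, "normalized.csv"))
  utils::write.csv(primary_calls, file.path(out_dir, "gene_calls.csv"),
                   row.names = FALSE)
  utils::write.csv(corrob, file.path(out_dir, "corroboration.csv"),
                   row.names = FALSE)
  utils::write.csv(ranking, file.path(out_dir, "ranking.csv"),
                   row.names = FALSE)

  stats_list <- attr(primary_calls, "control_stats")
  thresholds <- lapply(stats_list, function(s)
    list(assay = s$assay, condition = s$condition, n = s$n, mu = s$mu,
         sigma = s$sigma, t_up = as.list(s$t_up),
         t_down = as.list(s$t_down)))
  jsonlite::write_json(thresholds, file.path(out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(corr))
    utils::write.csv(corr$r, file.path(out_dir, "correlation.csv"))

  manifest <- list(
    parameters = list(primary_assay = primary_assay, direction = direction,
                      m = m, hub_degree = hub_degree,
                      k = c(1, 2)),
    input = list(path = input_path, n_wells = nrow(wells),
                 checksum = well_checksum(wells)),
    thresholds = thresholds,
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(normalized = norm, aggregated = agg,
                 control_stats = stats_list,
                 calls = primary_calls, viability_calls = viability_calls,
                 caspase8_calls = caspase8_calls,
                 corroboration = corrob, ranking = ranking, qc = qc,
                 correlation = corr, network = network,
                 manifest = manifest))
}

# order-independent content checksum of the well table
well_checksum <- function(wells) {
  key <- do.call(paste, c(wells[WELL_COLUMNS[1:8]],
                          list(signif(wells$raw_signal, 12), sep = "|")))
  sum(vapply(sort(key), function(s)
    sum(utf8ToInt(s) * seq_along(utf8ToInt(s))), numeric(1))) %% 2^31
}
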