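#' Run the end-to-end symptom-network analysis for one cohort
#'
#' Orchestrates the full pipeline for a single cohort: degeneracy
#' filtering, pairwise MI, surrogate-null edge inference with FDR
#' selection, and node-level characterization; writes all artifacts to
#' `out_dir` and a JSON manifest last. Outputs are deterministic for a
#' fixed configuration and seed (byte-identical across reruns).
#'
#' Artifacts written (prefixed by the cohort label):
#' `*_prevalence.tsv`, `*_exclusions.tsv`, `*_edges.csv`,
#' `*_network.graphml`, `*_node_metrics.tsv` (formatted 7-column layout),
#' `*_strongest_edges.tsv` (top significant pairs by MI), `*_manifest.json`.
#'
#' @param input a [symptom_matrix], or a path to a delimited matrix file.
#' @param out_dir output directory (created if absent).
#' @param cohort_label label used in file names and reports; defaults to
#'   the matrix's label or `"cohort"`.
#' @param config a [surrogate_config()].
#' @param min_minority_count degeneracy threshold, see
#'   [exclude_degenerate()].
#' @param betweenness_mode,gamma,restarts see [node_metric_table()].
#' @param top_edges number of strongest connections to summarize.
#' @param sep delimiter when `input` is a path.
#' @return (invisibly) a list with the network, metric table, edge list,
#'   manifest and artifact paths.
#' @export
run_pipeline <- function(input, out_dir,
                         cohort_label = NULL,
                         config = surrogate_config(),
                         min_minority_count = 2,
                         betweenness_mode = "unweighted",
                         gamma = 1, restarts = 100,
                         top_edges = 10, sep = "\t") {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(input)) {
    input <- read_symptom_matrix(input, sep = sep,
                                 cohort_label = cohort_label %||% "")
  }
  stopifnot(inherits(input, "symptom_matrix"))
  label <- cohort_label %||% attr(input, "cohort_label")
  if (is.null(label) || !nzchar(label)) label <- "cohort"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pfx <- function(name) file.path(out_dir, paste0(label, "_", name))

  prevalence <- prevalence_summary(input)
  filt <- exclude_degenerate(input, min_minority_count = min_minority_count)
  utils::write.table(prevalence, pfx("prevalence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(filt$exclusions, pfx("exclusions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  t1 <- proc.time()[["elapsed"]]
  net <- build_network(filt$matrix, config)
  t2 <- proc.time()[["elapsed"]]

  edges <- edge_list(net, significant_only = TRUE)
  utils::write.csv(edges, pfx("edges.csv"), row.names = FALSE, quote = FALSE)

  metrics <- node_metric_table(net, prevalence,
                               betweenness_mode = betweenness_mode,
                               gamma = gamma, restarts = restarts,
                               seed = config$seed)
  formatted <- format_node_metric_table(metrics)
  utils::write.table(formatted, pfx("node_metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  strongest <- utils::head(edges, top_edges)
  utils::write.table(strongest, pfx("strongest_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  node_attrs <- data.frame(variable = net$variable_names,
                           module = metrics$module[match(net$variable_names,
                                                         metrics$variable)],
                           core = ifelse(metrics$is_core[match(net$variable_names,
                                                               metrics$variable)],
                                         "Core", "Periphery"))
  write_network_graphml(net, pfx("network.graphml"), node_attrs = node_attrs)
  t3 <- proc.time()[["elapsed"]]

  manifest <- list(
    package_version = as.character(utils::packageVersion("symptomnet")),
    cohort_label = label,
    n_patients = nrow(input),
    n_variables_input = ncol(input),
    n_variables_analyzed = length(net$variable_names),
    exclusions = filt$exclusions,
    config = list(n_surrogates = config$n_surrogates,
                  fdr_q = config$fdr_q,
                  fdr_method = config$fdr_method,
                  seed = config$seed,
                  null_method = config$null_method,
                  scaled_down = config$n_surrogates < 5000,
                  min_minority_count = min_minority_count,
                  betweenness_mode = betweenness_mode,
                  gamma = gamma,
                  restarts = restarts),
    n_significant_edges = nrow(edges),
    n_modules = max(metrics$module, na.rm = TRUE),
    n_core = sum(metrics$is_core, na.rm = TRUE),
    stage_seconds = list(prefilter = t1 - t0, inference = t2 - t1,
                         metrics_and_export = t3 - t2)
  )
  jsonlite::write_json(manifest, pfx("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(network = net, metrics = metrics, edges = edges,
                 prevalence = prevalence, exclusions = filt$exclusions,
                 manifest = manifest,
                 paths = stats::setNames(
                   pfx(c("prevalence.tsv", "exclusions.tsv", "edges.csv",
                         "network.graphml", "node_metrics.tsv",
                         "strongest_edges.tsv", "manifest.json")),
                   c("prevalence", "exclusions", "edges", "graphml",
                     "node_metrics", "strongest_edges", "manifest"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare node metrics between two cohorts
#'
#' Produces the side-by-side descriptive comparison of two analyzed
#' cohorts: per-symptom degree, strength, betweenness, module and core
#' flag in each cohort, plus the symptoms that gained or lost core status
#' from cohort A to cohort B. Purely descriptive: no formal
#' network-difference test is performed.
#'
#' @param a,b results of [run_pipeline()] (or their `metrics` tables).
#' @param labels length-2 character labels for the two cohorts.
#' @return list with `table` (merged per-symptom metrics; suffixes from
#'   `labels`), `core_gained` and `core_lost` (character vectors, B
#'   relative to A).
#' @export
compare_cohorts <- function(a, b, labels = c("a", "b")) {
  ta <- if (is.data.frame(a)) a else a$metrics
  tb <- if (is.data.frame(b)) b else b$metrics
  stopifnot(inherits(ta, "data.frame"), inherits(tb, "data.frame"))
  common <- intersect(ta$variable, tb$variable)
  if (length(common) == 0) stop("cohorts share no variables")
  cols <- c("variable", "degree", "strength", "bc", "module", "is_core")
  merged <- merge(ta[cols], tb[cols], by = "variable",
                  suffixes = paste0("_", labels), sort = FALSE)
  ca <- merged[[paste0("is_core_", labels[1])]]
  cb <- merged[[paste0("is_core_", labels[2])]]
  list(table = merged,
       core_gained = merged$variable[!is.na(ca) & !is.na(cb) & !ca & cb],
       core_lost = merged$variable[!is.na(ca) & !is.na(cb) & ca & !cb])
}
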