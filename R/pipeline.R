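# End-to-end orchestration: read -> extract (GG, GCG) -> build -> metrics
# -> clusters -> annotate -> evaluate, with all artifacts written to an
# output directory. Deterministic given the seeds in the configuration.

#' Pipeline configuration
#'
#' Thresholds default to the ranking rules used throughout the package:
#' top-25 lists, a measure-value floor of 10 for the tie-prone measures,
#' and a minimum co-occurrence of 100 for implicit-discovery candidates.
#'
#' @param documents_path,citations_path corpus TSV paths (see
#'   [read_corpus()]).
#' @param reference_path optional interaction-reference TSV.
#' @param disease_map_path optional gene-to-disease TSV.
#' @param out_dir output directory.
#' @param top_k list length for top pairs / nodes.
#' @param node_value_min measure-value floor for degree, weighted degree
#'   and betweenness top lists.
#' @param pair_min_freq minimum weight for implicit-discovery candidates.
#' @param min_edge_weight minimum pair weight to become a network edge.
#' @param damping PageRank damping factor.
#' @param louvain_resolution,louvain_seed clustering parameters.
#' @param split_year optional temporal-holdout split year.
#' @return list of class `run_config`.
#' @export
run_config <- function(documents_path, citations_path,
                       reference_path = NULL, disease_map_path = NULL,
                       out_dir = "citegene-out", top_k = 25,
                       node_value_min = 10, pair_min_freq = 100,
                       min_edge_weight = 1, damping = 0.85,
                       louvain_resolution = 1.0, louvain_seed = 1L,
                       split_year = NULL) {
  stopifnot(top_k >= 1, node_value_min > 0, pair_min_freq >= 1,
            min_edge_weight >= 1)
  structure(list(documents_path = documents_path,
                 citations_path = citations_path,
                 reference_path = reference_path,
                 disease_map_path = disease_map_path,
                 out_dir = out_dir, top_k = top_k,
                 node_value_min = node_value_min,
                 pair_min_freq = pair_min_freq,
                 min_edge_weight = min_edge_weight, damping = damping,
                 louvain_resolution = louvain_resolution,
                 louvain_seed = as.integer(louvain_seed),
                 split_year = split_year),
            class = "run_config")
}

pipeline_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage over one corpus and writes: the GG and GCG pair
#' tables (TSV), per-network centrality tables (TSV), annotated GraphML
#' and GEXF exports, and a JSON report with corpus statistics, network
#' sizes, frequency shares, overlap and rank-agreement statistics,
#' modularity clustering summaries and (when a reference is configured)
#' matching rates, implicit-discovery candidates and the temporal-holdout
#' record. Two runs with the same configuration produce byte-identical
#' reports.
#'
#' @param config a [run_config()].
#' @param verbose log per-stage record counts via [message()].
#' @return invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  corpus <- read_corpus(config$documents_path, config$citations_path)
  stats <- corpus_stats(corpus)
  pipeline_log(verbose, "read", "%d documents, %d links (%d dropped)",
               stats$n_documents, stats$n_links,
               corpus$drop_report$dangling_links)

  gg <- extract_gg_pairs(corpus)
  gcg <- extract_gcg_pairs(corpus)
  write_pair_table(gg, out("gg_pairs.tsv"))
  write_pair_table(gcg, out("gcg_pairs.tsv"))
  pipeline_log(verbose, "extract", "GG %d pairs, GCG %d pairs",
               nrow(gg), nrow(gcg))

  dmap <- if (!is.null(config$disease_map_path))
    read_disease_map(config$disease_map_path) else NULL
  ref <- if (!is.null(config$reference_path))
    read_interaction_reference(config$reference_path) else NULL

  report <- list(corpus = stats, dropped = corpus$drop_report)
  networks <- list(GG = gg, GCG = gcg)
  combined <- list()
  for (kind in names(networks)) {
    tab <- networks[[kind]]
    key <- tolower(kind)
    if (nrow(tab) == 0L) {
      report[[key]] <- list(n_nodes = 0L, n_edges = 0L)
      next
    }
    net <- build_network(tab, min_edge_weight = config$min_edge_weight)
    cent <- centrality_table(net, damping = config$damping)
    cl <- louvain_clusters(net, resolution = config$louvain_resolution,
                           rng_seed = config$louvain_seed)
    utils::write.table(cent, out(sprintf("%s_centrality.tsv", key)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    igraph::V(net)$degree <- cent$degree
    igraph::V(net)$weighted_degree <- cent$weighted_degree
    igraph::V(net)$closeness <- cent$closeness
    igraph::V(net)$betweenness <- cent$betweenness
    igraph::V(net)$pagerank <- cent$pagerank
    igraph::V(net)$cluster <- unname(cl$membership[igraph::V(net)$name])
    if (!is.null(dmap)) {
      igraph::V(net)$disease <-
        dominant_disease(igraph::V(net)$name, dmap)$category
    }
    export_graphml(net, out(sprintf("%s_network.graphml", key)))
    export_gexf(net, out(sprintf("%s_network.gexf", key)))

    cmb <- combined_measure_pairs(net, cent, k = config$top_k,
                                  value_min = config$node_value_min)
    combined[[kind]] <- cmb
    cluster_sizes <- table(cl$membership)
    entry <- list(
      n_nodes = igraph::vcount(net),
      n_edges = igraph::ecount(net),
      frequency_share = frequency_share(tab, config$pair_min_freq),
      top_pairs = as.data.frame(top_pairs(tab, config$top_k)),
      modularity_q = cl$modularity_q,
      n_clusters = length(cluster_sizes),
      n_combined_measure_pairs = nrow(cmb),
      top_genes_all_measures = attr(cmb, "top_genes"))
    if (!is.null(ref)) {
      mr_top <- matching_rate(top_pairs(tab, config$top_k), ref)
      mr_cmb <- if (nrow(cmb) > 0) matching_rate(cmb, ref) else NULL
      entry$top_pair_matching <- mr_top[c("n_pairs", "n_matched",
                                          "matching_rate")]
      if (!is.null(mr_cmb)) {
        entry$combined_pair_matching <- mr_cmb[c("n_pairs", "n_matched",
                                                 "matching_rate")]
      }
    }
    if (!is.null(dmap)) {
      labels <- lapply(split(names(cl$membership), cl$membership),
                       cluster_disease_label, map = dmap)
      entry$cluster_labels <- labels
    }
    report[[key]] <- entry
    pipeline_log(verbose, "network",
                 "%s: %d nodes, %d edges, modularity %.3f", kind,
                 entry$n_nodes, entry$n_edges, entry$modularity_q)
  }

  if (nrow(gg) > 0 && nrow(gcg) > 0) {
    ov <- network_overlap(gg, gcg)
    report$overlap <- list(
      n_common = ov$n_common, n_union = ov$n_union,
      pct_common_of_union = 100 * ov$n_common / ov$n_union,
      weight_fraction_gg = ov$weight_fraction_a,
      weight_fraction_gcg = ov$weight_fraction_b)
    ov_top <- network_overlap(gg, gcg, k = config$top_k)
    report$overlap$n_common_top_k <- ov_top$n_common
    report$overlap$n_union_top_k <- ov_top$n_union
    if (ov$n_common >= 3L) {
      sp <- spearman_common_pairs(gg, gcg, scope = "common_all")
      report$spearman_common_all <- sp
    }
  }
  if (!is.null(ref) && nrow(gg) > 0 && nrow(gcg) > 0) {
    disc <- gcg_only_pairs(gg, gcg, ref, min_freq = config$pair_min_freq)
    report$gcg_only <- list(n_pairs = nrow(disc), pairs = disc)
    if (!is.null(config$split_year)) {
      th <- temporal_holdout(corpus, config$split_year, ref)
      report$temporal_holdout <- th[c("n_gcg_only_early",
                                      "n_with_known_interaction",
                                      "n_later_in_full_gg", "n_undated")]
    }
  }
  if (length(combined) == 2 && !is.null(ref)) {
    both <- intersect(pair_key(combined$GG$gene_a, combined$GG$gene_b),
                      pair_key(combined$GCG$gene_a, combined$GCG$gene_b))
    if (length(both) > 0) {
      parts <- strsplit(both, "\r", fixed = TRUE)
      mr <- matching_rate(data.frame(gene_a = vapply(parts, `[`, "", 1),
                                     gene_b = vapply(parts, `[`, "", 2)),
                          ref)
      report$combined_both_networks <- mr[c("n_pairs", "n_matched",
                                            "matching_rate")]
    }
  }

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "rows")
  writeLines(json, out("report.json"))
  pipeline_log(verbose, "done", "report written to %s", out("report.json"))
  invisible(report)
}
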