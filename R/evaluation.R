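# Benchmarking against an interaction reference, cross-network overlap,
# rank agreement, combined-measure pair sets, implicit-only discovery and
# the temporal holdout experiment.

#' Read an interaction reference
#'
#' Two-column TSV of known interacting gene pairs (an official-symbol
#' projection of an interaction repository export). Pairs are
#' canonicalized, self-pairs dropped, duplicates merged.
#'
#' @param path TSV path; the first two columns are used.
#' @return data.frame of class `interaction_reference` with columns
#'   `gene_a`, `gene_b`.
#' @export
read_interaction_reference <- function(path) {
  x <- utils::read.delim(path, colClasses = "character", quote = "")
  if (ncol(x) < 2) {
    stop("interaction reference needs two gene-symbol columns",
         call. = FALSE)
  }
  interaction_reference(x[[1]], x[[2]])
}

#' @rdname read_interaction_reference
#' @param gene_a,gene_b gene symbols of known interacting pairs.
#' @export
interaction_reference <- function(gene_a, gene_b) {
  cp <- canonical_pairs(canonical_symbol(gene_a), canonical_symbol(gene_b))
  key <- pair_key(cp$a, cp$b)
  keep <- !duplicated(key)
  out <- data.frame(gene_a = cp$a[keep], gene_b = cp$b[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("interaction_reference", "data.frame"))
}

ref_keys <- function(ref) pair_key(ref$gene_a, ref$gene_b)

#' Matching rate of candidate pairs against an interaction reference
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (a `pair_table`
#'   works); duplicates are merged before counting; must be non-empty.
#' @param ref an `interaction_reference`.
#' @return list with `n_pairs`, `n_matched`, `matching_rate` (a percentage
#'   in `[0, 100]`), and the `matched` / `unmatched` pair data.frames.
#' @export
matching_rate <- function(pairs, ref) {
  stopifnot(inherits(ref, "interaction_reference"))
  cp <- canonical_pairs(pairs$gene_a, pairs$gene_b)
  key <- pair_key(cp$a, cp$b)
  keep <- !duplicated(key)
  a <- cp$a[keep]; b <- cp$b[keep]; key <- key[keep]
  if (length(key) == 0L) {
    stop("matching rate is undefined for an empty pair set", call. = FALSE)
  }
  hit <- key %in% ref_keys(ref)
  list(n_pairs = length(key),
       n_matched = sum(hit),
       matching_rate = 100 * sum(hit) / length(key),
       matched = data.frame(gene_a = a[hit], gene_b = b[hit],
                            stringsAsFactors = FALSE),
       unmatched = data.frame(gene_a = a[!hit], gene_b = b[!hit],
                              stringsAsFactors = FALSE))
}

#' Overlap between two pair tables
#'
#' Intersection and union of the pair sets of two tables (optionally
#' restricted to each table's top `k` pairs first), plus the fraction of
#' each full table's total weight carried by the common pairs.
#'
#' @param a,b `pair_table`s.
#' @param k when given, intersect only the top-`k` pairs of each table;
#'   weight fractions are still taken over the full tables.
#' @return list with `n_a`, `n_b`, `n_common`, `n_union`, `common`
#'   (data.frame of pairs with both weights) and `weight_fraction_a`,
#'   `weight_fraction_b`.
#' @export
network_overlap <- function(a, b, k = NULL) {
  stopifnot(inherits(a, "pair_table"), inherits(b, "pair_table"))
  ra <- if (is.null(k)) a else top_pairs(a, k)
  rb <- if (is.null(k)) b else top_pairs(b, k)
  ka <- pair_key(ra$gene_a, ra$gene_b)
  kb <- pair_key(rb$gene_a, rb$gene_b)
  common <- intersect(ka, kb)
  ia <- match(common, pair_key(a$gene_a, a$gene_b))
  ib <- match(common, pair_key(b$gene_a, b$gene_b))
  common_df <- data.frame(gene_a = a$gene_a[ia], gene_b = a$gene_b[ia],
                          weight_a = a$weight[ia], weight_b = b$weight[ib],
                          stringsAsFactors = FALSE)
  list(n_a = length(ka), n_b = length(kb),
       n_common = length(common),
       n_union = length(union(ka, kb)),
       common = common_df,
       weight_fraction_a = if (sum(a$weight) > 0)
         sum(a$weight[ia]) / sum(a$weight) else 0,
       weight_fraction_b = if (sum(b$weight) > 0)
         sum(b$weight[ib]) / sum(b$weight) else 0)
}

#' Spearman rank agreement of common pairs
#'
#' Spearman correlation between the two weight vectors over pairs common
#' to both tables, with average-rank tie handling and the t-approximation
#' p-value.
#'
#' @param a,b `pair_table`s.
#' @param scope `"common_all"` correlates all common pairs; `"top_k"`
#'   correlates only pairs common to both tables' top-`k` lists.
#' @param k list length for `scope = "top_k"`.
#' @return list with `rho`, `p_value` and `n_common`.
#' @export
spearman_common_pairs <- function(a, b, scope = c("common_all", "top_k"),
                                  k = 25) {
  scope <- match.arg(scope)
  ov <- network_overlap(a, b, k = if (scope == "top_k") k else NULL)
  if (ov$n_common < 3L) {
    stop("need at least 3 common pairs for a rank correlation; got ",
         ov$n_common, call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(ov$common$weight_a,
                                         ov$common$weight_b,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_common = ov$n_common)
}

#' Gene pairs among the combined top-ranked nodes
#'
#' Pools the top-`k` node lists of all five centrality measures (degree,
#' weighted degree and betweenness thresholded at `value_min` because of
#' their large tie groups; closeness and PageRank unthresholded) and
#' returns the network edges whose two endpoints both lie in the pooled
#' node set.
#'
#' @param net an igraph network.
#' @param centrality its [centrality_table()].
#' @param k per-measure list length.
#' @param value_min measure-value threshold for degree, weighted degree
#'   and betweenness lists.
#' @return `pair_table`-like data.frame of qualifying edges with weights,
#'   plus attribute `top_genes` (the pooled node set).
#' @export
combined_measure_pairs <- function(net, centrality, k = 25, value_min = 10) {
  thresholded <- c("degree", "weighted_degree", "betweenness")
  free <- c("closeness", "pagerank")
  pick <- function(measure, min_value) {
    v <- stats::setNames(centrality[[measure]], centrality$gene)
    top_nodes(v, k = k, min_value = min_value)$gene
  }
  genes <- unique(c(unlist(lapply(thresholded, pick, min_value = value_min)),
                    unlist(lapply(free, pick, min_value = NULL))))
  el <- igraph::as_edgelist(net)
  keep <- el[, 1] %in% genes & el[, 2] %in% genes
  cp <- canonical_pairs(el[keep, 1], el[keep, 2])
  o <- order(cp$a, cp$b)
  out <- data.frame(gene_a = cp$a[o], gene_b = cp$b[o],
                    weight = igraph::E(net)$weight[keep][o],
                    stringsAsFactors = FALSE)
  attr(out, "top_genes") <- sort(genes)
  out
}

#' Reference-confirmed pairs found only in the citation-mediated table
#'
#' Pairs present in the GCG table but absent from the GG table, confirmed
#' by the interaction reference, with GCG weight at or above `min_freq` —
#' the implicit-discovery candidates.
#'
#' @param gg,gcg `pair_table`s.
#' @param ref an `interaction_reference`.
#' @param min_freq minimum GCG co-occurrence weight.
#' @return data.frame of qualifying pairs with their GCG weights, sorted
#'   by weight descending (ties lexicographic).
#' @export
gcg_only_pairs <- function(gg, gcg, ref, min_freq = 100) {
  stopifnot(inherits(gg, "pair_table"), inherits(gcg, "pair_table"),
            inherits(ref, "interaction_reference"))
  kg <- pair_key(gg$gene_a, gg$gene_b)
  kc <- pair_key(gcg$gene_a, gcg$gene_b)
  keep <- !(kc %in% kg) & (kc %in% ref_keys(ref)) & gcg$weight >= min_freq
  out <- as.data.frame(gcg)[keep, , drop = FALSE]
  out <- out[order(-out$weight, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Temporal holdout: do implicit-only pairs become explicit later?
#'
#' Builds GG and GCG pair tables on the early slice of the corpus
#' (documents with `year <= split_year`; citation links kept only when
#' both endpoints survive; undated documents are excluded from the slice
#' and counted), takes the pairs found only in the early GCG table, checks
#' them against the interaction reference, and counts how many of the
#' confirmed ones appear in the GG table built over the whole corpus —
#' i.e. implicit early signals that later became explicit co-occurrences.
#'
#' @param corpus a `gcg_corpus` with documents on both sides of the split.
#' @param split_year last year of the early slice.
#' @param ref an `interaction_reference`.
#' @return list with `n_gcg_only_early`, `n_with_known_interaction`,
#'   `n_later_in_full_gg`, the corresponding pair data.frames, and
#'   `n_undated` (documents excluded from the slice for lack of a year).
#' @export
temporal_holdout <- function(corpus, split_year, ref) {
  stopifnot(inherits(corpus, "gcg_corpus"),
            inherits(ref, "interaction_reference"))
  yr <- corpus$documents$year
  early <- !is.na(yr) & yr <= split_year
  late <- !is.na(yr) & yr > split_year
  if (!any(early) || !any(late)) {
    stop("temporal holdout needs documents on both sides of split_year ",
         split_year, call. = FALSE)
  }
  docs_early <- corpus$documents[early, , drop = FALSE]
  sub <- new_corpus(docs_early, corpus$links)  # dangling links drop here
  gg_early <- extract_gg_pairs(sub)
  gcg_early <- extract_gcg_pairs(sub)
  k_gg <- pair_key(gg_early$gene_a, gg_early$gene_b)
  k_gcg <- pair_key(gcg_early$gene_a, gcg_early$gene_b)
  only <- !(k_gcg %in% k_gg)
  s <- as.data.frame(gcg_early)[only, , drop = FALSE]
  s_key <- k_gcg[only]
  confirmed <- s_key %in% ref_keys(ref)
  gg_full <- extract_gg_pairs(corpus)
  later <- confirmed & (s_key %in% pair_key(gg_full$gene_a, gg_full$gene_b))
  rownames(s) <- NULL
  list(n_gcg_only_early = nrow(s),
       n_with_known_interaction = sum(confirmed),
       n_later_in_full_gg = sum(later),
       gcg_only_early = s,
       with_known_interaction = s[confirmed, , drop = FALSE],
       later_in_full_gg = s[later, , drop = FALSE],
       n_undated = sum(is.na(yr)))
}
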