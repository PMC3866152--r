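# Transcribed literature fixtures: the published top-25 lists (pair
# frequency, weighted degree, closeness) shipped as plain-text data, and
# recomputation of every printed aggregate derivable from them.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "citegene")
  if (!nzchar(p)) stop("fixture not found: ", file, call. = FALSE)
  p
}

#' Load the top-25 pair-frequency fixture
#'
#' The published top 25 gene pairs by co-occurrence frequency for the GG
#' and GCG networks, each pair carrying a curation remark (`Interaction`,
#' `Same gene family`, `Literature-confirmed`, `No interaction`).
#'
#' @return list with data.frames `gg` and `gcg` (columns `gene_a`,
#'   `gene_b`, `freq`, `remark`, 25 rows each, frequency non-increasing).
#' @export
load_pair_frequency_fixture <- function() {
  x <- utils::read.delim(fixture_path("top25_pair_frequency.tsv"),
                         comment.char = "#", quote = "",
                         stringsAsFactors = FALSE)
  split_fixture <- function(net) {
    d <- x[x$network == net, c("gene_a", "gene_b", "freq", "remark")]
    rownames(d) <- NULL
    d
  }
  fix <- list(gg = split_fixture("GG"), gcg = split_fixture("GCG"))
  for (d in fix) {
    if (nrow(d) != 25L) stop("pair fixture must have 25 rows per network",
                             call. = FALSE)
    if (is.unsorted(rev(d$freq))) {
      stop("pair fixture frequencies must be non-increasing", call. = FALSE)
    }
    bad <- setdiff(d$remark, c("Interaction", "Same gene family",
                               "Literature-confirmed", "No interaction"))
    if (length(bad) > 0) stop("unknown remark: ", bad[1], call. = FALSE)
  }
  fix
}

#' Load a top-25 gene-list fixture
#'
#' The published top 25 genes by a centrality measure, per network, with
#' each gene's dominant disease category (empty = no record) and its
#' supporting paper count.
#'
#' @param measure `"weighted_degree"` or `"closeness"`.
#' @return list with data.frames `gg` and `gcg` (columns `gene`, `value`,
#'   `category`, `paper_count`) and element `measure`.
#' @export
load_gene_list_fixture <- function(measure = c("weighted_degree",
                                               "closeness")) {
  measure <- match.arg(measure)
  file <- paste0("top25_", measure, ".tsv")
  x <- utils::read.delim(fixture_path(file), comment.char = "#", quote = "",
                         na.strings = NULL, stringsAsFactors = FALSE)
  split_fixture <- function(net) {
    d <- x[x$network == net, c("gene", "value", "category", "paper_count")]
    if (nrow(d) != 25L) stop("gene-list fixture must have 25 rows per ",
                             "network", call. = FALSE)
    rownames(d) <- NULL
    d
  }
  list(gg = split_fixture("GG"), gcg = split_fixture("GCG"),
       measure = measure)
}

#' Gene-to-disease map distilled from the gene-list fixtures
#'
#' The dominant (gene, category, paper count) records printed in the two
#' gene-list fixtures, merged into a [disease_map()]. This is a partial
#' map (dominant categories only) sufficient to reproduce the fixtures'
#' category counts.
#'
#' @return a `disease_map`.
#' @export
fixture_disease_map <- function() {
  rows <- do.call(rbind, lapply(c("weighted_degree", "closeness"),
                                function(m) {
    fix <- load_gene_list_fixture(m)
    rbind(fix$gg, fix$gcg)[, c("gene", "category", "paper_count")]
  }))
  rows <- rows[nzchar(rows$category), , drop = FALSE]
  rows <- rows[!duplicated(paste(rows$gene, rows$category, sep = "\r")), ,
               drop = FALSE]
  disease_map(rows$gene, rows$category, rows$paper_count)
}

#' Aggregates of the pair-frequency fixture
#'
#' Recomputes every printed aggregate derivable from the top-25
#' pair-frequency lists: the size of their intersection and union (over
#' canonicalized pairs), how many common pairs have the higher frequency
#' on the citation-mediated side, and per-network remark rates — the
#' percentage of pairs reported in the interaction repository
#' (`pct_repository`) and the percentage with any known interaction once
#' same-family and literature-confirmed pairs are credited
#' (`pct_known_interaction`).
#'
#' @param fix result of [load_pair_frequency_fixture()].
#' @return list with `n_common`, `n_union`, `n_common_higher_gcg`, and
#'   per-network lists `gg` / `gcg` of remark counts and rates.
#' @export
pair_fixture_aggregates <- function(fix = load_pair_frequency_fixture()) {
  key <- function(d) {
    cp <- canonical_pairs(canonical_symbol(d$gene_a),
                          canonical_symbol(d$gene_b))
    pair_key(cp$a, cp$b)
  }
  kg <- key(fix$gg); kc <- key(fix$gcg)
  common <- intersect(kg, kc)
  ig <- match(common, kg); ic <- match(common, kc)
  rates <- function(d) {
    n <- nrow(d)
    tab <- table(factor(d$remark, levels = c("Interaction",
                                             "Same gene family",
                                             "Literature-confirmed",
                                             "No interaction")))
    list(n = n,
         remark_counts = c(tab),
         pct_repository = 100 * tab[["Interaction"]] / n,
         pct_known_interaction = 100 * (n - tab[["No interaction"]]) / n)
  }
  list(n_common = length(common),
       n_union = length(union(kg, kc)),
       n_common_higher_gcg = sum(fix$gcg$freq[ic] > fix$gg$freq[ig]),
       gg = rates(fix$gg),
       gcg = rates(fix$gcg))
}

#' Aggregates of a gene-list fixture pair
#'
#' Overlap between the two networks' top-25 gene lists (count and
#' percentage of the list length) and per-network disease-category counts,
#' computed with [count_category_in_list()] over a map built from the
#' fixture's own disease column.
#'
#' @param fix result of [load_gene_list_fixture()].
#' @param categories categories to count (default: all appearing).
#' @return list with `n_overlap`, `pct_overlap` and per-network named
#'   count vectors `category_counts_gg` / `category_counts_gcg`.
#' @export
gene_list_aggregates <- function(fix, categories = NULL) {
  rows <- rbind(fix$gg, fix$gcg)
  rows <- rows[nzchar(rows$category), , drop = FALSE]
  rows <- rows[!duplicated(paste(rows$gene, rows$category, sep = "\r")), ,
               drop = FALSE]
  map <- disease_map(rows$gene, rows$category, rows$paper_count)
  if (is.null(categories)) categories <- sort(unique(rows$category))
  counts <- function(d) {
    stats::setNames(vapply(categories, function(cat) {
      count_category_in_list(d$gene, map, cat)
    }, 0L), categories)
  }
  ov <- intersect(fix$gg$gene, fix$gcg$gene)
  list(n_overlap = length(ov),
       pct_overlap = 100 * length(ov) / nrow(fix$gg),
       overlap_genes = sort(ov),
       category_counts_gg = counts(fix$gg),
       category_counts_gcg = counts(fix$gcg))
}
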