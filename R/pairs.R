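# GG (within-document) and GCG (across-citation) weighted pair tables.
#
# Counting is document-level for GG (each document contributes at most 1 to
# a pair, whatever the within-abstract mention multiplicity) and binary per
# citation link for GCG (a pair realized by either or both orientations of
# a link contributes exactly 1 for that link), keeping the two weight
# scales comparable.

pair_key <- function(a, b) paste(a, b, sep = "\r")

canonical_pairs <- function(a, b, drop_self = TRUE) {
  a <- as.character(a); b <- as.character(b)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  if (drop_self) {
    keep <- a != b
    a <- a[keep]; b <- b[keep]
  }
  list(a = a, b = b)
}

#' Construct a pair table
#'
#' A pair table maps canonically ordered unordered gene pairs to positive
#' integer co-occurrence weights. Rows are sorted by weight descending,
#' ties broken lexicographically by pair — the deterministic ranking order
#' used throughout the package.
#'
#' @param gene_a,gene_b gene symbols (any order; canonicalized so that
#'   `gene_a < gene_b`); self-pairs are forbidden.
#' @param weight positive integer weights; duplicate pairs are summed.
#' @param kind `"GG"` (within-document) or `"GCG"` (across-citation).
#' @return data.frame of class `pair_table` with columns `gene_a`,
#'   `gene_b`, `weight` and attribute `kind`.
#' @export
pair_table <- function(gene_a = character(0), gene_b = character(0),
                       weight = integer(0), kind = c("GG", "GCG")) {
  kind <- match.arg(kind)
  stopifnot(length(gene_a) == length(gene_b),
            length(gene_a) == length(weight))
  if (any(gene_a == gene_b)) stop("self-pairs are not allowed", call. = FALSE)
  if (any(weight < 1)) stop("weights must be >= 1", call. = FALSE)
  cp <- canonical_pairs(gene_a, gene_b)
  if (length(cp$a) == 0L) {
    return(structure(data.frame(gene_a = character(0),
                                gene_b = character(0),
                                weight = integer(0),
                                stringsAsFactors = FALSE),
                     kind = kind, class = c("pair_table", "data.frame")))
  }
  key <- pair_key(cp$a, cp$b)
  w <- tapply(as.integer(weight), key, sum)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                    gene_b = vapply(parts, `[`, "", 2L),
                    weight = as.integer(w),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, kind = kind, class = c("pair_table", "data.frame"))
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("%s pair table: %d pairs, total weight %d\n",
              attr(x, "kind"), nrow(x), sum(x$weight)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# Tally a vector of pair keys into a pair_table.
keys_to_table <- function(keys, kind) {
  if (length(keys) == 0L) return(pair_table(kind = kind))
  w <- table(keys)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  pair_table(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L),
             as.integer(w), kind = kind)
}

#' Extract within-document (GG) gene pairs
#'
#' Every unordered pair of distinct genes co-occurring in a document
#' contributes exactly 1 per document; weights accumulate over documents.
#' All documents contribute, seeds and references alike.
#'
#' @param corpus a `gcg_corpus`.
#' @return a `pair_table` of kind `"GG"`.
#' @export
extract_gg_pairs <- function(corpus) {
  stopifnot(inherits(corpus, "gcg_corpus"))
  gsets <- corpus$documents$genes
  gsets <- gsets[lengths(gsets) >= 2L]
  if (length(gsets) == 0L) return(pair_table(kind = "GG"))
  keys <- unlist(lapply(gsets, function(g) {
    m <- utils::combn(g, 2L)  # g is sorted unique, so pairs are canonical
    pair_key(m[1L, ], m[2L, ])
  }), use.names = FALSE)
  keys_to_table(keys, "GG")
}

#' Extract across-citation (GCG) gene pairs
#'
#' For every citation link, every unordered pair of distinct genes with one
#' member in the citing document and the other in the cited document
#' contributes exactly 1 for that link (binary per link: a pair realized by
#' both orientations still counts once). Citation direction is ignored;
#' a gene appearing on both sides of a link forms no self-pair.
#'
#' @param corpus a `gcg_corpus`.
#' @return a `pair_table` of kind `"GCG"`.
#' @export
extract_gcg_pairs <- function(corpus) {
  stopifnot(inherits(corpus, "gcg_corpus"))
  links <- corpus$links
  if (nrow(links) == 0L) return(pair_table(kind = "GCG"))
  gsets <- corpus$documents$genes
  names(gsets) <- corpus$documents$doc_id
  ga <- gsets[links$citing]
  gb <- gsets[links$cited]
  keys <- unlist(lapply(seq_len(nrow(links)), function(i) {
    x <- ga[[i]]; y <- gb[[i]]
    if (length(x) == 0L || length(y) == 0L) return(character(0))
    cp <- canonical_pairs(rep(x, times = length(y)),
                          rep(y, each = length(x)))
    unique(pair_key(cp$a, cp$b))
  }), use.names = FALSE)
  keys_to_table(keys, "GCG")
}

#' Top pairs by weight
#'
#' @param table a `pair_table`.
#' @param k number of pairs to return (the whole table if smaller).
#' @return the first `min(k, nrow)` rows in ranking order (weight
#'   descending, ties lexicographic by pair).
#' @export
top_pairs <- function(table, k) {
  stopifnot(inherits(table, "pair_table"), k >= 1)
  utils::head(table, k)
}

#' Frequency share of heavy pairs
#'
#' How much of a pair table is carried by its heavy pairs: the number of
#' pairs with weight at or above a cut-off, the fraction of pairs they
#' represent, and the fraction of total co-occurrence weight they carry.
#'
#' @param table a non-empty `pair_table`.
#' @param min_weight weight cut-off (>= 1).
#' @return list with `n_pairs_at_or_above`, `fraction_of_pairs`,
#'   `fraction_of_total_weight`.
#' @export
frequency_share <- function(table, min_weight) {
  stopifnot(inherits(table, "pair_table"), min_weight >= 1)
  if (nrow(table) == 0L) {
    stop("frequency share is undefined for an empty pair table",
         call. = FALSE)
  }
  heavy <- table$weight >= min_weight
  list(n_pairs_at_or_above = sum(heavy),
       fraction_of_pairs = sum(heavy) / nrow(table),
       fraction_of_total_weight = sum(table$weight[heavy]) /
         sum(table$weight))
}

#' Read / write a pair table as TSV
#'
#' Three columns (`gene_a`, `gene_b`, `weight`), canonically ordered,
#' sorted by weight descending then pair.
#'
#' @param table a `pair_table`.
#' @param path TSV path.
#' @param kind pair kind for reading (`"GG"` or `"GCG"`).
#' @return the written table (invisibly) / the read `pair_table`.
#' @export
write_pair_table <- function(table, path) {
  stopifnot(inherits(table, "pair_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path, kind = c("GG", "GCG")) {
  kind <- match.arg(kind)
  x <- utils::read.delim(path, colClasses = c("character", "character",
                                              "integer"), quote = "")
  miss <- setdiff(c("gene_a", "gene_b", "weight"), names(x))
  if (length(miss) > 0) {
    stop("pair table file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pair_table(x$gene_a, x$gene_b, x$weight, kind = kind)
}
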