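# Corpus model: documents with annotated gene sets plus 1-depth citation links.

#' Canonicalize gene symbols
#'
#' Gene identity throughout the package is the canonical symbol string:
#' uppercase, no surrounding or internal whitespace. Symbols that are empty
#' after trimming are rejected.
#'
#' @param x character vector of raw symbols.
#' @return character vector of canonical symbols.
#' @export
canonical_symbol <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(!nzchar(x))) stop("gene symbols must be non-empty", call. = FALSE)
  if (any(grepl("[[:space:]]", x))) {
    stop("gene symbols must not contain whitespace", call. = FALSE)
  }
  x
}

#' Construct a citation corpus
#'
#' A corpus holds a document table (one row per abstract, with its set of
#' normalized gene symbols) and a citation edge list. Construction enforces
#' the corpus invariants: unique document ids, 4-digit years where present,
#' gene sets with set semantics, and links whose endpoints both resolve to
#' documents. Self-citations, duplicate links and dangling links are dropped
#' and counted in the `drop_report`.
#'
#' @param documents data.frame with columns `doc_id` (character), `year`
#'   (integer or `NA`), `is_seed` (logical) and `genes` (list column of
#'   character vectors).
#' @param links data.frame with character columns `citing` and `cited`.
#' @return object of class `gcg_corpus`: a list with elements `documents`,
#'   `links` and `drop_report` (counts of dropped self-citations, duplicate
#'   links and dangling links).
#' @export
new_corpus <- function(documents, links = data.frame(citing = character(),
                                                     cited = character())) {
  stopifnot(is.data.frame(documents), is.data.frame(links))
  need <- c("doc_id", "year", "is_seed", "genes")
  miss <- setdiff(need, names(documents))
  if (length(miss) > 0) {
    stop("documents table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  documents$doc_id <- as.character(documents$doc_id)
  if (anyDuplicated(documents$doc_id)) {
    stop("duplicate doc_id in documents table: ",
         paste(unique(documents$doc_id[duplicated(documents$doc_id)]),
               collapse = ", "), call. = FALSE)
  }
  documents$year <- suppressWarnings(as.integer(documents$year))
  bad_year <- !is.na(documents$year) &
    (documents$year < 1000 | documents$year > 9999)
  if (any(bad_year)) {
    stop("year must be a 4-digit positive integer or absent", call. = FALSE)
  }
  documents$is_seed <- as.logical(documents$is_seed)
  documents$genes <- lapply(documents$genes, function(g) {
    g <- g[!is.na(g) & nzchar(g)]
    if (length(g) == 0) return(character(0))
    sort(unique(canonical_symbol(g)))
  })

  links$citing <- as.character(links$citing)
  links$cited <- as.character(links$cited)
  n0 <- nrow(links)
  self <- links$citing == links$cited
  links <- links[!self, , drop = FALSE]
  dup <- duplicated(paste(links$citing, links$cited, sep = "\r"))
  links <- links[!dup, , drop = FALSE]
  dangling <- !(links$citing %in% documents$doc_id) |
    !(links$cited %in% documents$doc_id)
  links <- links[!dangling, , drop = FALSE]
  rownames(documents) <- NULL
  rownames(links) <- NULL

  structure(
    list(documents = documents,
         links = links,
         drop_report = list(self_citations = sum(self),
                            duplicate_links = sum(dup),
                            dangling_links = sum(dangling),
                            links_in = n0)),
    class = "gcg_corpus")
}

#' @export
print.gcg_corpus <- function(x, ...) {
  s <- corpus_stats(x)
  cat(sprintf(paste0("citation corpus: %d documents (%d with genes), ",
                     "%d distinct genes, %d citation links\n"),
              s$n_documents, s$n_documents_with_genes,
              s$n_distinct_genes, s$n_links))
  invisible(x)
}

#' Read a corpus from TSV files
#'
#' The document file must have a header row with columns `doc_id`, `year`,
#' `genes` (semicolon-separated symbols, may be empty) and `is_seed`; the
#' citation file has columns `citing` and `cited`. One record per line, no
#' quoting. Dangling links, duplicate links and self-citations are dropped
#' and counted (see [new_corpus()]).
#'
#' @param documents_path,citations_path paths to the two TSV files.
#' @return a `gcg_corpus`.
#' @export
read_corpus <- function(documents_path, citations_path) {
  docs <- utils::read.delim(documents_path, colClasses = "character",
                            quote = "", na.strings = NULL,
                            check.names = FALSE)
  need <- c("doc_id", "year", "genes", "is_seed")
  miss <- setdiff(need, names(docs))
  if (length(miss) > 0) {
    stop("documents file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  links <- utils::read.delim(citations_path, colClasses = "character",
                             quote = "", na.strings = NULL,
                             check.names = FALSE)
  miss <- setdiff(c("citing", "cited"), names(links))
  if (length(miss) > 0) {
    stop("citations file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  documents <- data.frame(doc_id = docs$doc_id, stringsAsFactors = FALSE)
  documents$year <- ifelse(nzchar(docs$year), docs$year, NA)
  documents$is_seed <- toupper(docs$is_seed) %in% c("TRUE", "T", "1", "YES")
  documents$genes <- lapply(strsplit(docs$genes, ";", fixed = TRUE),
                            function(g) g[nzchar(g)])
  new_corpus(documents, links)
}

#' Write a corpus to TSV files
#'
#' Inverse of [read_corpus()]: a written corpus reads back field-for-field
#' identical (links are already deduplicated and resolved).
#'
#' @param corpus a `gcg_corpus`.
#' @param documents_path,citations_path output paths.
#' @return invisibly, the corpus.
#' @export
write_corpus <- function(corpus, documents_path, citations_path) {
  stopifnot(inherits(corpus, "gcg_corpus"))
  d <- corpus$documents
  out <- data.frame(
    doc_id = d$doc_id,
    year = ifelse(is.na(d$year), "", as.character(d$year)),
    genes = vapply(d$genes, paste, "", collapse = ";"),
    is_seed = ifelse(d$is_seed, "TRUE", "FALSE"),
    stringsAsFactors = FALSE)
  utils::write.table(out, documents_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(corpus$links, citations_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(corpus)
}

#' Read a mention lexicon
#'
#' The lexicon stands in for concept-level normalization of raw entity
#' mentions: each mention string maps to a preferred gene symbol, carries a
#' semantic-type label, and a flag saying whether the term is backed by the
#' gene ontology. Columns: `mention`, `symbol`, `semantic_type`,
#' `in_ontology`.
#'
#' @param path TSV path.
#' @return data.frame of class `gene_lexicon`.
#' @export
read_lexicon <- function(path) {
  lex <- utils::read.delim(path, colClasses = "character", quote = "",
                           na.strings = NULL, check.names = FALSE)
  miss <- setdiff(c("mention", "symbol", "semantic_type", "in_ontology"),
                  names(lex))
  if (length(miss) > 0) {
    stop("lexicon file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  new_lexicon(lex$mention, lex$symbol, lex$semantic_type,
              toupper(lex$in_ontology) %in% c("TRUE", "T", "1", "YES"))
}

#' Construct a mention lexicon
#'
#' @param mention character vector of unique mention strings.
#' @param symbol preferred gene symbol per mention.
#' @param semantic_type semantic-type label per mention (e.g. "gene",
#'   "genome", "protein").
#' @param in_ontology logical: is the term backed by the gene ontology?
#' @return data.frame of class `gene_lexicon`.
#' @export
new_lexicon <- function(mention, symbol, semantic_type, in_ontology) {
  if (anyDuplicated(mention)) {
    stop("lexicon mention strings must be unique", call. = FALSE)
  }
  structure(
    data.frame(mention = as.character(mention),
               symbol = canonical_symbol(symbol),
               semantic_type = as.character(semantic_type),
               in_ontology = as.logical(in_ontology),
               stringsAsFactors = FALSE),
    class = c("gene_lexicon", "data.frame"))
}

#' @rdname read_lexicon
#' @param lexicon a `gene_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(as.data.frame(lexicon), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(lexicon)
}

#' Normalize raw entity mentions to gene symbols
#'
#' Keeps only mentions whose lexicon entry has semantic type `gene` or
#' `genome` *and* is ontology-backed, maps each surviving mention to its
#' preferred symbol, and merges duplicates (synonyms collapsing to one
#' symbol yield one set element). Unknown mentions are silently excluded
#' and counted.
#'
#' @param raw_mentions character vector of mention strings (order and
#'   duplication are irrelevant).
#' @param lexicon a `gene_lexicon` (non-empty).
#' @return sorted character vector of gene symbols, with attributes
#'   `n_unknown` (mentions absent from the lexicon) and `n_filtered`
#'   (mentions present but failing the semantic-type/ontology filter).
#' @export
normalize_document <- function(raw_mentions, lexicon) {
  stopifnot(inherits(lexicon, "gene_lexicon"))
  if (nrow(lexicon) == 0) stop("lexicon must be non-empty", call. = FALSE)
  raw_mentions <- as.character(raw_mentions)
  idx <- match(raw_mentions, lexicon$mention)
  unknown <- is.na(idx)
  keep <- !unknown &
    lexicon$semantic_type[idx] %in% c("gene", "genome") &
    lexicon$in_ontology[idx]
  out <- sort(unique(lexicon$symbol[idx[keep]]))
  attr(out, "n_unknown") <- sum(unknown)
  attr(out, "n_filtered") <- sum(!unknown & !keep)
  out
}

#' Corpus summary statistics
#'
#' @param corpus a `gcg_corpus`.
#' @return list with `n_documents`, `n_documents_with_genes`,
#'   `n_distinct_genes` and `n_links`.
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "gcg_corpus"))
  ng <- lengths(corpus$documents$genes)
  list(n_documents = nrow(corpus$documents),
       n_documents_with_genes = sum(ng > 0),
       n_distinct_genes = length(unique(unlist(corpus$documents$genes))),
       n_links = nrow(corpus$links))
}
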