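# Gene -> disease-category annotation in the style of the Genetic
# Association Database (GAD): each gene may carry several disease
# categories, each supported by a number of association studies; the
# dominant category is the best-supported one.

#' The closed disease-category vocabulary
#'
#' The GAD disease-class taxonomy, plus `PSYCH` (the abbreviation commonly
#' printed for PSYCHIATRIC in gene tables) and `UNKNOWN` for unannotated
#' genes.
#'
#' @return character vector of category names.
#' @export
gad_categories <- function() {
  c("AGING", "CANCER", "CARDIOVASCULAR", "CHEMDEPENDENCY", "DEVELOPMENTAL",
    "HEMATOLOGICAL", "IMMUNE", "INFECTION", "METABOLIC", "MITOCHONDRIAL",
    "NEUROLOGICAL", "NORMAL VARIATION", "OTHER", "PHARMACOGENOMIC",
    "PSYCHIATRIC", "PSYCH", "RENAL", "REPRODUCTION", "UNKNOWN", "VISION")
}

#' Construct / read a gene-to-disease map
#'
#' TSV columns: `gene`, `category` (from [gad_categories()]),
#' `paper_count` (positive integer: number of studies reporting the
#' association). At most one record per (gene, category).
#'
#' @param gene,category,paper_count record fields.
#' @return data.frame of class `disease_map`.
#' @export
disease_map <- function(gene = character(0), category = character(0),
                        paper_count = integer(0)) {
  gene <- canonical_symbol(gene)
  category <- toupper(trimws(as.character(category)))
  bad <- setdiff(unique(category), gad_categories())
  if (length(bad) > 0) {
    stop("unknown disease categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  paper_count <- as.integer(paper_count)
  if (any(is.na(paper_count)) || any(paper_count < 1)) {
    stop("paper_count must be a positive integer", call. = FALSE)
  }
  if (anyDuplicated(paste(gene, category, sep = "\r"))) {
    stop("at most one record per (gene, category)", call. = FALSE)
  }
  out <- data.frame(gene = gene, category = category,
                    paper_count = paper_count, stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$category), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("disease_map", "data.frame"))
}

#' @rdname disease_map
#' @param path TSV path.
#' @export
read_disease_map <- function(path) {
  x <- utils::read.delim(path, colClasses = "character", quote = "",
                         comment.char = "#")
  miss <- setdiff(c("gene", "category", "paper_count"), names(x))
  if (length(miss) > 0) {
    stop("disease map file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  disease_map(x$gene, x$category, as.integer(x$paper_count))
}

#' Dominant disease category per gene
#'
#' The category with the largest supporting paper count, ties broken
#' alphabetically; genes absent from the map get `("UNKNOWN", 0)`.
#'
#' @param genes character vector of gene symbols.
#' @param map a `disease_map`.
#' @return data.frame with columns `gene`, `category`, `paper_count`, one
#'   row per input gene in input order.
#' @export
dominant_disease <- function(genes, map) {
  stopifnot(inherits(map, "disease_map"))
  genes <- canonical_symbol(genes)
  one <- function(g) {
    rec <- map[map$gene == g, , drop = FALSE]
    if (nrow(rec) == 0L) return(list(category = "UNKNOWN", paper_count = 0L))
    rec <- rec[order(-rec$paper_count, rec$category), , drop = FALSE]
    list(category = rec$category[1], paper_count = rec$paper_count[1])
  }
  picks <- lapply(genes, one)
  data.frame(gene = genes,
             category = vapply(picks, `[[`, "", "category"),
             paper_count = vapply(picks, `[[`, 0L, "paper_count"),
             stringsAsFactors = FALSE)
}

#' Salient disease labels for a gene cluster
#'
#' For each disease category, the fraction of cluster genes annotated with
#' it (a gene may carry several categories; genes with no annotation count
#' as `UNKNOWN`). Returns the `top_m` categories by fraction, ties broken
#' alphabetically.
#'
#' @param cluster_genes non-empty character vector of gene symbols.
#' @param map a `disease_map`.
#' @param top_m number of labels to return.
#' @return data.frame with columns `category` and `gene_fraction`, in
#'   descending fraction order.
#' @export
cluster_disease_label <- function(cluster_genes, map, top_m = 3) {
  stopifnot(inherits(map, "disease_map"))
  cluster_genes <- unique(canonical_symbol(cluster_genes))
  if (length(cluster_genes) == 0L) {
    stop("cluster must contain at least one gene", call. = FALSE)
  }
  rec <- map[map$gene %in% cluster_genes, , drop = FALSE]
  unannotated <- setdiff(cluster_genes, rec$gene)
  counts <- c(table(rec$category))
  if (length(unannotated) > 0L) {
    counts["UNKNOWN"] <- sum(counts["UNKNOWN"], length(unannotated),
                             na.rm = TRUE)
  }
  frac <- counts / length(cluster_genes)
  o <- order(-frac, names(frac))
  utils::head(data.frame(category = names(frac)[o],
                         gene_fraction = unname(frac[o]),
                         stringsAsFactors = FALSE), top_m)
}

#' Count genes in a list whose dominant disease is a given category
#'
#' @param genes character vector (an ordered top-gene list, typically).
#' @param map a `disease_map`.
#' @param category queried category.
#' @return integer count.
#' @export
count_category_in_list <- function(genes, map, category) {
  if (length(genes) == 0L) return(0L)
  sum(dominant_disease(genes, map)$category == toupper(category))
}
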