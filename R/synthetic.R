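# Synthetic 1-depth citation corpora with planted interacting gene pairs.
#
# The generator emulates the structure of a seed-plus-references abstract
# collection: a heavy-tailed (Zipf) background of gene mentions, seed
# articles each citing several reference articles (with bibliographic
# reuse of references between seeds), and a planted set of "truly
# interacting" gene pairs injected at elevated rates either within single
# documents (explicit co-occurrence signal) or across citation links
# (implicit, citation-mediated signal).

with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe a corpus of roughly two thousand abstracts: 1000 seed
#' articles each citing one reference (with 20% bibliographic reuse of
#' references between seeds), a Zipf(1.8) background over 800 gene symbols
#' with on average 1.5 background gene draws per document (most documents
#' carry few or no gene mentions, as in real abstract collections), and 25
#' planted vertex-disjoint interacting pairs injected within documents and
#' across citation links at rate 0.3 each. The sparse citation fan-out
#' keeps each planted pair's per-link injection rate well above the
#' background co-reachability of even the most popular genes, so the
#' implicit signal is identifiable by construction.
#'
#' @param n_genes number of gene symbols in the universe.
#' @param n_seed_docs number of seed articles.
#' @param refs_per_seed references cited by each seed (distinct within a
#'   seed; may be shared between seeds).
#' @param genes_per_doc_mean Poisson mean of background gene draws per
#'   document (draws are i.i.d. from the Zipf popularity distribution and
#'   deduplicated, so the realized set is typically slightly smaller).
#' @param zipf_exponent exponent of the Zipf popularity distribution over
#'   gene ranks (larger = more skewed).
#' @param n_planted_pairs number of planted interacting pairs; the pairs
#'   are vertex-disjoint, so `2 * n_planted_pairs <= n_genes` is required.
#' @param p_within probability, per document and planted pair, that the
#'   pair is co-injected into that document.
#' @param p_cross probability, per citation link and planted pair, that
#'   the pair is injected across the link (one gene into the citing
#'   document, the other into the cited one, side chosen by fair coin).
#' @param ref_reuse_prob probability that a reference slot reuses an
#'   already-generated reference article instead of creating a new one.
#' @param year_range inclusive integer interval for publication years,
#'   drawn uniformly.
#' @param rng_seed integer seed; generation is fully reproducible from it.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 800, n_seed_docs = 1000,
                             refs_per_seed = 1, genes_per_doc_mean = 1.5,
                             zipf_exponent = 1.8, n_planted_pairs = 25,
                             p_within = 0.3, p_cross = 0.3,
                             ref_reuse_prob = 0.2,
                             year_range = c(2000L, 2011L), rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_seed_docs = as.integer(n_seed_docs),
              refs_per_seed = as.integer(refs_per_seed),
              genes_per_doc_mean = as.numeric(genes_per_doc_mean),
              zipf_exponent = as.numeric(zipf_exponent),
              n_planted_pairs = as.integer(n_planted_pairs),
              p_within = as.numeric(p_within),
              p_cross = as.numeric(p_cross),
              ref_reuse_prob = as.numeric(ref_reuse_prob),
              year_range = as.integer(year_range),
              rng_seed = as.integer(rng_seed))
  if (cfg$n_genes < 2 || cfg$n_seed_docs < 1) {
    stop("n_genes must be >= 2 and n_seed_docs >= 1", call. = FALSE)
  }
  if (cfg$refs_per_seed < 0) stop("refs_per_seed must be >= 0", call. = FALSE)
  if (cfg$genes_per_doc_mean < 0) {
    stop("genes_per_doc_mean must be >= 0", call. = FALSE)
  }
  if (cfg$zipf_exponent <= 0) stop("zipf_exponent must be > 0", call. = FALSE)
  probs <- c(cfg$p_within, cfg$p_cross, cfg$ref_reuse_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("p_within, p_cross and ref_reuse_prob must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$n_planted_pairs < 0 ||
      2L * cfg$n_planted_pairs > cfg$n_genes) {
    stop("need 0 <= n_planted_pairs and 2*n_planted_pairs <= n_genes ",
         "(planted pairs are vertex-disjoint)", call. = FALSE)
  }
  if (length(cfg$year_range) != 2L || cfg$year_range[1] > cfg$year_range[2]) {
    stop("year_range must be an inclusive integer interval", call. = FALSE)
  }
  if (cfg$refs_per_seed == 0L && cfg$p_cross > 0) {
    stop("cross-injection requested (p_cross > 0) but refs_per_seed = 0: ",
         "no citation links to inject across", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# Gene universe and Zipf popularity distribution over ranks.
zipf_probs <- function(cfg) {
  w <- (seq_len(cfg$n_genes))^(-cfg$zipf_exponent)
  w / sum(w)
}

gene_universe <- function(cfg) {
  sprintf("G%05d", seq_len(cfg$n_genes))
}

# Planted pairs are the first RNG consumption of generate_corpus(), so
# expected_pair_rates() can re-derive the same pairs from the seed alone.
sample_planted <- function(cfg) {
  genes <- gene_universe(cfg)
  if (cfg$n_planted_pairs == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  picked <- sample(genes, 2L * cfg$n_planted_pairs)
  a <- picked[seq(1L, length(picked), by = 2L)]
  b <- picked[seq(2L, length(picked), by = 2L)]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  o <- order(a, b)
  data.frame(gene_a = a[o], gene_b = b[o], stringsAsFactors = FALSE)
}

#' Generate a synthetic 1-depth citation corpus
#'
#' See [synthetic_config()] for the generative model. Two calls with the
#' same configuration produce bit-identical output; the caller's RNG state
#' is left untouched.
#'
#' @param config a `synthetic_config`.
#' @return list with elements `corpus` (a `gcg_corpus`), `truth` (a
#'   data.frame of planted canonical pairs, the ground-truth interaction
#'   reference), `lexicon` (identity + lowercase-alias `gene_lexicon`) and
#'   `stats` (generator-side tallies: document/link counts and per-document
#'   gene counts before corpus construction).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_rng_seed(cfg$rng_seed, {
    genes <- gene_universe(cfg)
    pz <- zipf_probs(cfg)
    planted <- sample_planted(cfg)

    # Citation skeleton: each seed cites refs_per_seed distinct references;
    # a reference slot reuses an existing reference with ref_reuse_prob.
    seed_ids <- sprintf("S%05d", seq_len(cfg$n_seed_docs))
    ref_pool <- character(0)
    citing <- character(0)
    cited <- character(0)
    if (cfg$refs_per_seed > 0L) {
      citing <- rep(seed_ids, each = cfg$refs_per_seed)
      cited <- character(length(citing))
      k <- 0L
      for (s in seq_len(cfg$n_seed_docs)) {
        chosen <- character(0)
        for (j in seq_len(cfg$refs_per_seed)) {
          pick <- NULL
          if (length(ref_pool) > 0L && stats::runif(1) < cfg$ref_reuse_prob) {
            cand <- setdiff(ref_pool, chosen)
            if (length(cand) > 0L) pick <- sample(cand, 1L)
          }
          if (is.null(pick)) {
            pick <- sprintf("R%05d", length(ref_pool) + 1L)
            ref_pool <- c(ref_pool, pick)
          }
          chosen <- c(chosen, pick)
          k <- k + 1L
          cited[k] <- pick
        }
      }
    }
    doc_ids <- c(seed_ids, ref_pool)
    n_docs <- length(doc_ids)
    n_links <- length(citing)

    # Background mentions: per-document Poisson number of i.i.d. Zipf draws.
    n_bg <- stats::rpois(n_docs, cfg$genes_per_doc_mean)
    bg_draws <- sample(genes, sum(n_bg), replace = TRUE, prob = pz)
    doc_genes <- split(bg_draws, rep.int(seq_len(n_docs), n_bg))
    gsets <- vector("list", n_docs)
    gsets[as.integer(names(doc_genes))] <- doc_genes
    gsets[vapply(gsets, is.null, TRUE)] <- list(character(0))

    # Within-document co-injection of planted pairs.
    np <- nrow(planted)
    if (np > 0L && cfg$p_within > 0) {
      hit <- matrix(stats::runif(n_docs * np) < cfg$p_within, n_docs, np)
      for (j in seq_len(np)) {
        docs_j <- which(hit[, j])
        if (length(docs_j) > 0L) {
          add <- c(planted$gene_a[j], planted$gene_b[j])
          gsets[docs_j] <- lapply(gsets[docs_j], c, add)
        }
      }
    }

    # Cross-link injection: one gene into the citing side, one into the
    # cited side, side assignment by fair coin.
    if (np > 0L && cfg$p_cross > 0 && n_links > 0L) {
      doc_index <- match(c(citing, cited), doc_ids)
      citing_idx <- doc_index[seq_len(n_links)]
      cited_idx <- doc_index[n_links + seq_len(n_links)]
      hit <- matrix(stats::runif(n_links * np) < cfg$p_cross, n_links, np)
      flip <- matrix(stats::runif(n_links * np) < 0.5, n_links, np)
      for (j in seq_len(np)) {
        lk <- which(hit[, j])
        if (length(lk) == 0L) next
        a_side <- ifelse(flip[lk, j], citing_idx[lk], cited_idx[lk])
        b_side <- ifelse(flip[lk, j], cited_idx[lk], citing_idx[lk])
        for (i in seq_along(lk)) {
          gsets[[a_side[i]]] <- c(gsets[[a_side[i]]], planted$gene_a[j])
          gsets[[b_side[i]]] <- c(gsets[[b_side[i]]], planted$gene_b[j])
        }
      }
    }

    years <- sample(seq(cfg$year_range[1], cfg$year_range[2]),
                    n_docs, replace = TRUE)
    documents <- data.frame(doc_id = doc_ids, stringsAsFactors = FALSE)
    documents$year <- years
    documents$is_seed <- doc_ids %in% seed_ids
    documents$genes <- gsets
    corpus <- new_corpus(documents,
                         data.frame(citing = citing, cited = cited,
                                    stringsAsFactors = FALSE))

    mentioned <- sort(unique(unlist(corpus$documents$genes)))
    lexicon <- new_lexicon(
      mention = c(mentioned, tolower(mentioned)),
      symbol = c(mentioned, mentioned),
      semantic_type = "gene",
      in_ontology = TRUE)

    list(corpus = corpus,
         truth = planted,
         lexicon = lexicon,
         stats = list(n_documents = n_docs,
                      n_seed_docs = cfg$n_seed_docs,
                      n_ref_docs = length(ref_pool),
                      n_links = n_links,
                      n_documents_with_genes = sum(lengths(gsets) > 0L)))
  })
}

#' Closed-form expected pair weights for a synthetic configuration
#'
#' Analytic companion to [generate_corpus()] for recovery tests. Because the
#' number of background draws per document is Poisson and draws are i.i.d.,
#' the background occurrence indicator of gene `g` in a document is
#' Bernoulli with `q_g = 1 - exp(-lambda * p_g)`, independent across genes
#' and documents. The returned expectations are
#' `E[GG]  = n_docs  * (p_within + (1 - p_within) * q_a * q_b)` and
#' `E[GCG] = n_links * (p_cross  + (1 - p_cross) * (2 q_a q_b - (q_a q_b)^2))`
#' per planted pair, plus the mean background expectation over all gene
#' pairs. The formulas neglect presence inflation caused by cross-injection
#' from *other* links incident to a document and by injection of other
#' planted pairs sharing a document; they are exact when `ref_reuse_prob =
#' 0` with `refs_per_seed = 1` (for GCG, with `p_within = 0`) and when
#' `p_cross = 0` (for GG). The expected document count uses
#' `E[n_docs] = n_seed + 1 + (n_links - 1) * (1 - ref_reuse_prob)`.
#'
#' @param config a `synthetic_config`.
#' @return list with `planted` (data.frame: pair, `expected_gg`,
#'   `expected_gcg`), `background_gg_mean`, `background_gcg_mean`,
#'   `n_docs_expected` and `n_links`.
#' @export
expected_pair_rates <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  planted <- with_rng_seed(cfg$rng_seed, sample_planted(cfg))
  pz <- zipf_probs(cfg)
  genes <- gene_universe(cfg)
  q <- 1 - exp(-cfg$genes_per_doc_mean * pz)
  names(q) <- genes

  n_links <- cfg$n_seed_docs * cfg$refs_per_seed
  n_docs <- if (n_links == 0L) cfg$n_seed_docs else
    cfg$n_seed_docs + 1 + (n_links - 1) * (1 - cfg$ref_reuse_prob)

  qa <- q[planted$gene_a]
  qb <- q[planted$gene_b]
  planted$expected_gg <- n_docs *
    (cfg$p_within + (1 - cfg$p_within) * qa * qb)
  planted$expected_gcg <- n_links *
    (cfg$p_cross + (1 - cfg$p_cross) * (2 * qa * qb - (qa * qb)^2))
  rownames(planted) <- NULL

  # Means over all C(n_genes, 2) unordered pairs via power sums.
  s1 <- sum(q); s2 <- sum(q^2)
  t1 <- sum(q^2); t2 <- sum(q^4)
  n_pairs <- choose(cfg$n_genes, 2)
  mean_qq <- (s1^2 - s2) / 2 / n_pairs
  mean_qq2 <- (t1^2 - t2) / 2 / n_pairs
  list(planted = planted,
       background_gg_mean = n_docs * mean_qq,
       background_gcg_mean = n_links * (2 * mean_qq - mean_qq2),
       n_docs_expected = n_docs,
       n_links = n_links)
}

#' Write the outputs of [generate_corpus()] to a directory
#'
#' Writes `documents.tsv`, `citations.tsv`, `truth.tsv` and `lexicon.tsv`.
#'
#' @param sim result of [generate_corpus()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("documents.tsv", "citations.tsv",
                            "truth.tsv", "lexicon.tsv"))
  write_corpus(sim$corpus, paths[1], paths[2])
  utils::write.table(sim$truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_lexicon(sim$lexicon, paths[4])
  invisible(paths)
}
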