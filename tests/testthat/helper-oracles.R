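# Independent brute-force oracles and random-input generators used across
# the suite. Everything here is deliberately naive (Floyd-Warshall, nested
# loops, dense solves) and shares no code with the implementation paths it
# checks.

pkey <- function(d) paste(d$gene_a, d$gene_b)

# --- random weighted graphs ----------------------------------------------

rand_graph <- function(n, p_edge = 0.4, max_w = 5) {
  el <- t(utils::combn(n, 2))
  el <- el[stats::runif(nrow(el)) < p_edge, , drop = FALSE]
  list(n = n, el = el,
       w = sample(max_w, nrow(el), replace = TRUE))
}

igraph_from_rand <- function(rg) {
  g <- igraph::make_empty_graph(rg$n, directed = FALSE)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(rg$n))
  if (nrow(rg$el) > 0) {
    g <- igraph::add_edges(g, as.vector(t(rg$el)), weight = rg$w)
  }
  g
}

adj_from_rand <- function(rg) {
  a <- matrix(0, rg$n, rg$n)
  for (i in seq_len(nrow(rg$el))) {
    a[rg$el[i, 1], rg$el[i, 2]] <- rg$w[i]
    a[rg$el[i, 2], rg$el[i, 1]] <- rg$w[i]
  }
  a
}

# --- all-pairs shortest paths (Floyd-Warshall, hop metric) ----------------

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_closeness <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    if (length(reach) == 0) 0 else length(reach) / sum(d[v, reach])
  }, 0)
}

# Shortest-path betweenness by explicit path counting (BFS per source).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  cnt <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    cnt[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) for (v in which(adj[u, ] > 0)) {
        if (!is.finite(d[s, v])) {
          d[s, v] <- d[s, u] + 1
          nxt <- c(nxt, v)
        }
        if (d[s, v] == d[s, u] + 1) cnt[s, v] <- cnt[s, v] + cnt[s, u]
      }
      frontier <- unique(nxt)
    }
  }
  vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s < t && s != v && t != v && is.finite(d[s, t]) &&
          is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        tot <- tot + cnt[s, v] * cnt[v, t] / cnt[s, t]
      }
    }
    tot
  }, 0)
}

# Weighted PageRank as the solution of the dense linear system
# (I - damping * M^T) p = (1 - damping) / n, with dangling rows uniform.
oracle_pagerank <- function(adj, damping = 0.85) {
  n <- nrow(adj)
  s <- rowSums(adj)
  m <- matrix(1 / n, n, n)
  ok <- s > 0
  m[ok, ] <- adj[ok, , drop = FALSE] / s[ok]
  p <- solve(diag(n) - damping * t(m), rep((1 - damping) / n, n))
  p / sum(p)
}

# --- random corpora and brute-force pair extraction ----------------------

rand_corpus <- function(n_docs = 12, n_genes = 8, n_links = 10,
                        p_gene = 0.3, p_na_year = 0.1) {
  genes <- sprintf("X%02d", seq_len(n_genes))
  gsets <- lapply(seq_len(n_docs), function(i) {
    genes[stats::runif(n_genes) < p_gene]
  })
  ids <- sprintf("D%03d", seq_len(n_docs))
  documents <- data.frame(doc_id = ids, stringsAsFactors = FALSE)
  yr <- sample(2000:2011, n_docs, replace = TRUE)
  yr[stats::runif(n_docs) < p_na_year] <- NA
  documents$year <- yr
  documents$is_seed <- stats::runif(n_docs) < 0.5
  documents$genes <- gsets
  pairs <- t(utils::combn(n_docs, 2))
  take <- sample(nrow(pairs), min(n_links, nrow(pairs)))
  new_corpus(documents,
             data.frame(citing = ids[pairs[take, 1]],
                        cited = ids[pairs[take, 2]],
                        stringsAsFactors = FALSE))
}

brute_gg <- function(corpus) {
  keys <- character(0)
  for (g in corpus$documents$genes) {
    g <- sort(unique(g))
    if (length(g) < 2) next
    for (i in seq_len(length(g) - 1)) for (j in (i + 1):length(g)) {
      keys <- c(keys, paste(g[i], g[j]))
    }
  }
  sort_table(keys)
}

brute_gcg <- function(corpus) {
  gsets <- corpus$documents$genes
  names(gsets) <- corpus$documents$doc_id
  keys <- character(0)
  for (i in seq_len(nrow(corpus$links))) {
    link_keys <- character(0)
    for (x in gsets[[corpus$links$citing[i]]]) {
      for (y in gsets[[corpus$links$cited[i]]]) {
        if (x == y) next
        link_keys <- c(link_keys, paste(min(x, y), max(x, y)))
      }
    }
    keys <- c(keys, unique(link_keys))
  }
  sort_table(keys)
}

sort_table <- function(keys) {
  if (length(keys) == 0) {
    return(data.frame(key = character(0), weight = integer(0)))
  }
  tab <- table(keys)
  out <- data.frame(key = names(tab), weight = as.integer(tab),
                    stringsAsFactors = FALSE)
  `rownames<-`(out[order(out$key), , drop = FALSE], NULL)
}

as_key_table <- function(pt) {
  out <- data.frame(key = pkey(pt), weight = pt$weight,
                    stringsAsFactors = FALSE)
  o <- order(out$key)
  `rownames<-`(out[o, , drop = FALSE], NULL)
}
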