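ptab <- function(a, b, w, kind = "GG") pair_table(a, b, w, kind = kind)

test_that("matching rate counts deduplicated reference hits", {
  ref <- interaction_reference(c("A", "C"), c("B", "D"))
  all_in <- matching_rate(data.frame(gene_a = c("A", "C"),
                                     gene_b = c("B", "D")), ref)
  expect_equal(all_in$matching_rate, 100)
  none <- matching_rate(data.frame(gene_a = "X", gene_b = "Y"), ref)
  expect_equal(none$matching_rate, 0)
  # order/duplication invariant, canonicalization applied
  dup <- matching_rate(data.frame(gene_a = c("B", "A", "A"),
                                  gene_b = c("A", "B", "Z")), ref)
  expect_equal(dup$n_pairs, 2)
  expect_equal(dup$n_matched, 1)
  expect_equal(dup$matching_rate, 50)
  expect_error(matching_rate(data.frame(gene_a = character(0),
                                        gene_b = character(0)), ref),
               "empty")
  set.seed(401)
  for (i in 1:10) {
    cand <- data.frame(gene_a = sample(LETTERS[1:6], 8, replace = TRUE),
                       gene_b = sample(LETTERS[7:12], 8, replace = TRUE))
    got <- matching_rate(cand, ref)
    keys <- unique(paste(pmin(cand$gene_a, cand$gene_b),
                         pmax(cand$gene_a, cand$gene_b)))
    expect_equal(got$n_matched, length(intersect(keys, pkey(ref))))
  }
})

test_that("network overlap reports intersection, union and weight shares", {
  a <- ptab(c("A", "C", "E"), c("B", "D", "F"), c(5L, 3L, 2L))
  same <- network_overlap(a, ptab(c("A", "C", "E"), c("B", "D", "F"),
                                  c(1L, 1L, 1L), kind = "GCG"))
  expect_equal(same$n_common, 3)
  expect_equal(same$n_union, 3)
  expect_equal(same$weight_fraction_a, 1)
  disj <- network_overlap(a, ptab("X", "Y", 9L, kind = "GCG"))
  expect_equal(disj$n_common, 0)
  expect_equal(disj$weight_fraction_a, 0)
  b <- ptab(c("A", "X"), c("B", "Y"), c(7L, 1L), kind = "GCG")
  ov <- network_overlap(a, b)
  expect_equal(ov$n_common, 1)
  expect_equal(ov$n_union, 4)
  expect_equal(ov$weight_fraction_a, 5 / 10)
  expect_equal(ov$weight_fraction_b, 7 / 8)
  # top-k restriction intersects prefixes only
  ovk <- network_overlap(a, b, k = 1)
  expect_equal(ovk$n_common, 1)  # {A,B} tops both
})

test_that("Spearman agreement reproduces the rank formula", {
  a <- ptab(c("A", "C", "E", "G"), c("B", "D", "F", "H"),
            c(40L, 30L, 20L, 10L))
  same <- spearman_common_pairs(a, a)
  expect_equal(same$rho, 1)
  rev <- ptab(c("A", "C", "E", "G"), c("B", "D", "F", "H"),
              c(10L, 20L, 30L, 40L), kind = "GCG")
  expect_equal(spearman_common_pairs(a, rev)$rho, -1)
  expect_error(spearman_common_pairs(a, ptab("A", "B", 1L, kind = "GCG")),
               "at least 3")
  # hand computation via the classical rank-difference formula (no ties)
  b <- ptab(c("A", "C", "E", "G"), c("B", "D", "F", "H"),
            c(25L, 45L, 15L, 35L), kind = "GCG")
  got <- spearman_common_pairs(a, b)
  ra <- rank(c(40, 30, 20, 10))
  rb <- rank(c(25, 45, 15, 35))
  n <- 4
  expect_equal(got$rho, 1 - 6 * sum((ra - rb)^2) / (n * (n^2 - 1)),
               tolerance = 1e-12)
})

test_that("combined-measure pairs are edges among pooled top nodes", {
  # star: center qualifies on degree; leaves fail the threshold but enter
  # via the unthresholded measures, so all edges qualify
  star <- build_network(ptab(rep("C", 12), sprintf("L%02d", 1:12),
                             rep(1L, 12)))
  cent <- centrality_table(star)
  cmb <- combined_measure_pairs(star, cent, k = 25, value_min = 10)
  expect_equal(nrow(cmb), 12)
  # all thresholds unmet and k tiny: pairs restricted to the pooled set
  set.seed(402)
  for (i in 1:8) {
    rg <- rand_graph(7, p_edge = 0.5)
    if (nrow(rg$el) == 0) next
    g <- igraph_from_rand(rg)
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
    cent <- centrality_table(g)
    cmb <- combined_measure_pairs(g, cent, k = 3, value_min = 2)
    genes <- attr(cmb, "top_genes")
    el <- igraph::as_edgelist(g)
    brute <- el[el[, 1] %in% genes & el[, 2] %in% genes, , drop = FALSE]
    expect_equal(nrow(cmb), nrow(brute))
    expect_true(all(cmb$gene_a %in% genes & cmb$gene_b %in% genes))
  }
})

test_that("implicit-only discovery applies the three-way filter", {
  gg <- ptab(c("A", "C"), c("B", "D"), c(5L, 200L))
  gcg <- ptab(c("A", "E", "G", "I"), c("B", "F", "H", "J"),
              c(300L, 250L, 150L, 50L), kind = "GCG")
  ref <- interaction_reference(c("E", "I", "A"), c("F", "J", "B"))
  got <- gcg_only_pairs(gg, gcg, ref, min_freq = 100)
  # {A,B} is in gg; {G,H} not in ref; {I,J} below min_freq
  expect_equal(got$gene_a, "E")
  expect_equal(got$weight, 250L)
  expect_equal(nrow(gcg_only_pairs(gcg, gcg, ref)), 0)
  set.seed(403)
  for (i in 1:10) {
    mk <- function(n, kind) {
      cp <- t(utils::combn(LETTERS[1:8], 2))
      take <- sample(nrow(cp), n)
      ptab(cp[take, 1], cp[take, 2],
           sample(c(50L, 150L), n, replace = TRUE), kind = kind)
    }
    gg <- mk(6, "GG"); gcg <- mk(10, "GCG")
    cp <- t(utils::combn(LETTERS[1:8], 2))
    take <- sample(nrow(cp), 12)
    ref <- interaction_reference(cp[take, 1], cp[take, 2])
    got <- gcg_only_pairs(gg, gcg, ref, min_freq = 100)
    brute <- gcg[!(pkey(gcg) %in% pkey(gg)) &
                   (pkey(gcg) %in% pkey(ref)) & gcg$weight >= 100, ]
    expect_equal(sort(pkey(got)), sort(pkey(brute)))
  }
})

th_corpus <- function() {
  d <- data.frame(doc_id = c("e1", "e2", "l1", "l2"),
                  stringsAsFactors = FALSE)
  d$year <- c(2003L, 2004L, 2008L, 2009L)
  d$is_seed <- c(TRUE, FALSE, TRUE, FALSE)
  d$genes <- list(c("A"), c("B"), c("A", "B"), c("C"))
  new_corpus(d, data.frame(citing = c("e1", "l1"), cited = c("e2", "l2")))
}

test_that("temporal holdout finds implicit-early pairs that turn explicit", {
  corp <- th_corpus()
  ref <- interaction_reference("A", "B")
  got <- temporal_holdout(corp, 2005, ref)
  # early slice: link e1->e2 gives GCG-only pair {A,B}; it is confirmed
  # and co-occurs in l1, i.e. in the full-corpus GG table
  expect_equal(got$n_gcg_only_early, 1)
  expect_equal(got$n_with_known_interaction, 1)
  expect_equal(got$n_later_in_full_gg, 1)
  expect_error(temporal_holdout(corp, 2020, ref), "both sides")
})

test_that("early-slice pair sets are disjoint from early GG and inside full GG", {
  set.seed(404)
  for (i in 1:8) {
    corp <- rand_corpus(n_docs = 14, n_genes = 7, n_links = 16,
                        p_gene = 0.4)
    yr <- corp$documents$year
    if (!any(!is.na(yr) & yr <= 2005) || !any(!is.na(yr) & yr > 2005)) next
    ref <- interaction_reference("X01", "X02")
    got <- temporal_holdout(corpus = corp, split_year = 2005, ref = ref)
    early <- new_corpus(corp$documents[!is.na(yr) & yr <= 2005, ,
                                       drop = FALSE], corp$links)
    gg_early <- extract_gg_pairs(early)
    gg_full <- extract_gg_pairs(corp)
    expect_length(intersect(pkey(got$gcg_only_early), pkey(gg_early)), 0)
    expect_true(all(pkey(gg_early) %in% pkey(gg_full)))
    # brute recount of the three-way counts
    gcg_early <- extract_gcg_pairs(early)
    s <- setdiff(pkey(gcg_early), pkey(gg_early))
    expect_equal(got$n_gcg_only_early, length(s))
    expect_equal(got$n_with_known_interaction,
                 length(intersect(s, pkey(ref))))
    expect_equal(got$n_later_in_full_gg,
                 length(intersect(intersect(s, pkey(ref)), pkey(gg_full))))
  }
})
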