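# Corpus with controlled pair statistics for genes A = nusA, B = infB:
# n_fused genomes with the pair adjacent at zero gap, then n_adj - n_fused
# adjacent at positive gap, n_same - n_adj in one cassette but separated,
# n_both - n_same co-resident in different cassettes.
pair_corpus <- function(n_both, n_same, n_adj, n_fused = 0) {
  specs <- c(
    rep(list(list(c("nusA", "infB"))), n_fused),
    rep(list(list(c("nusA", "infB"))), n_adj - n_fused),
    rep(list(list(c("nusA", "zzM", "infB"))), n_same - n_adj),
    rep(list(list(c("nusA", "zzA"), c("infB", "zzB"))), n_both - n_same))
  gaps <- c(rep(0L, n_fused), rep(20L, n_both - n_fused))
  gids <- sprintf("G%03d", seq_along(specs))
  built <- lapply(seq_along(specs), function(i)
    make_genome(gids[i], specs[[i]], gap_within = gaps[i]))
  anns <- stats::setNames(lapply(built, `[[`, "annotation"), gids)
  ops <- stats::setNames(lapply(built, `[[`, "operons"), gids)
  assemble_corpus(anns, ops)
}

test_that("channel scores equal their planted genome fractions", {
  cat_ <- the_catalog()
  corpus <- pair_corpus(n_both = 40, n_same = 32, n_adj = 26, n_fused = 24)
  expect_equal(cooccurrence_score("nusA", "infB", corpus, cat_), 32 / 40)
  expect_equal(neighborhood_score("nusA", "infB", corpus, cat_), 26 / 40)
  expect_equal(fusion_score("nusA", "infB", corpus, cat_), 24 / 40)
  # extremes
  all_fused <- pair_corpus(10, 10, 10, 10)
  expect_equal(fusion_score("nusA", "infB", all_fused, cat_), 1.0)
  expect_equal(fusion_score("nusA", "rplK", all_fused, cat_), 0)  # absent
  apart <- pair_corpus(10, 0, 0, 0)
  expect_equal(cooccurrence_score("nusA", "infB", apart, cat_), 0)
})

test_that("a fused locus annotated with both identities counts as fusion", {
  cat_ <- the_catalog()
  genes <- rbind(
    gene_record("G001", "t1", "nusA", synonyms = "infB",
                product = "NusA-IF2 fusion", start = 100, end = 2000,
                strand = "+"),
    gene_record("G001", "t2", "zzA", start = 3000, end = 3500,
                strand = "+"))
  ann <- genome_annotation("G001", genes)
  ops <- list(G001 = data.frame(cassette_id = "op01",
                                locus_tag = c("t1", "t2"), rank = 1:2,
                                stringsAsFactors = FALSE))
  corpus <- assemble_corpus(list(G001 = ann), ops)
  expect_equal(fusion_score("nusA", "infB", corpus, cat_), 1.0)
})

test_that("channel scores are symmetric and nested on single-copy corpora", {
  cat_ <- the_catalog()
  cfg <- simulation_config(
    n_genomes = 25, seed = 13,
    planted = list(list(query = c("rplK", "nusG"), n_exact = 10,
                        n_reordered = 6, n_subset = 0)),
    genes_per_genome = c(10, 14))
  sim <- simulate_corpus(cfg)
  resolved <- cassette_gene_table(sim$corpus, cat_)
  rg <- resolve_annotations(sim$corpus, cat_)
  pairs <- list(c("rplK", "nusG"), c("rplK", "rplA"), c("nusG", "secE"))
  for (p in pairs) {
    f <- fusion_score(p[1], p[2], sim$corpus, cat_, resolved, rg)
    nb <- neighborhood_score(p[1], p[2], sim$corpus, cat_, resolved, rg)
    co <- cooccurrence_score(p[1], p[2], sim$corpus, cat_, resolved, rg)
    expect_lte(f, nb + 1e-12)
    expect_lte(nb, co + 1e-12)
    expect_equal(fusion_score(p[2], p[1], sim$corpus, cat_, resolved, rg), f)
    expect_equal(cooccurrence_score(p[2], p[1], sim$corpus, cat_, resolved,
                                    rg), co)
  }
})

test_that("confidence uses strict > at the threshold", {
  g <- structure(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(geneA = c("a", "a", "b"), geneB = c("b", "c", "c"),
                       fusion = c(0.7, 0, 0),
                       neighborhood = c(0.7, 0.71, 0),
                       cooccurrence = c(0.7, 1, 0.69),
                       combined = c(0.7, 1, 0.69),
                       stringsAsFactors = FALSE),
    threshold = 0.7, combine = "max"), class = "linkage_graph")
  conf <- confident_edges(g)
  expect_false(any(unlist(conf[1, ])))        # exactly 0.7 is not confident
  expect_true(conf$neighborhood[2])
  expect_false(conf$cooccurrence[3])
  g$threshold <- 1.01
  expect_false(any(unlist(confident_edges(g))))
})

test_that("candidates are the per-channel components of confident edges", {
  cat_ <- the_catalog()
  # two disjoint planted cliques: {nusA,infB} and {rplK,nusG} always
  # co-operonic; cross pairs never share a cassette
  specs <- rep(list(list(c("nusA", "infB"), c("rplK", "nusG"))), 12)
  corpus <- make_corpus(specs)
  graph <- build_linkage_graph(c("nusA", "infB", "rplK", "nusG"),
                               corpus, cat_)
  cand <- extract_candidates(graph, corpus, cat_, denominator = 12)
  sets <- sort(unique(cand$genes))
  expect_equal(sets, c("infB,nusA", "nusG,rplK"))
  expect_true(all(cand$genome_count == 12L))
  expect_true(all(cand$frequency == 1))
  # genome counts agree with a direct recount
  rep1 <- count_genomes(cassette_query(c("nusA", "infB")), corpus, cat_)
  expect_equal(unique(cand$genome_count[cand$genes == "infB,nusA"]),
               rep1$genome_count)
  expect_error(build_linkage_graph("nusA", corpus, cat_), "at least 2")
})

test_that("bipartition finds the optimal 2-partition", {
  mk_graph <- function(nodes, score_fun) {
    pr <- t(utils::combn(nodes, 2))
    edges <- data.frame(geneA = pr[, 1], geneB = pr[, 2],
                        fusion = 0, neighborhood = 0,
                        cooccurrence = apply(pr, 1, score_fun),
                        stringsAsFactors = FALSE)
    edges$combined <- edges$cooccurrence
    structure(list(nodes = nodes, edges = edges, threshold = 0.7,
                   combine = "max"), class = "linkage_graph")
  }
  # planted blocks: within 0.9, across 0.05
  block <- function(p) {
    inA <- p %in% c("a1", "a2", "a3")
    if (xor(inA[1], inA[2])) 0.05 else 0.9
  }
  g <- mk_graph(c("a1", "a2", "a3", "b1", "b2"), function(p) block(p))
  bp <- bipartition(g, seed = 1)
  expect_equal(bp$clusters[[1]], c("a1", "a2", "a3"))
  expect_equal(bp$clusters[[2]], c("b1", "b2"))
  # brute-force optimality on random <=10-node instances
  wss_of <- function(m, grp) {
    s <- 0
    for (k in 1:2) {
      rows <- m[grp == k, , drop = FALSE]
      if (!nrow(rows)) next
      s <- s + sum(sweep(rows, 2, colMeans(rows))^2)
    }
    s
  }
  set.seed(5)
  for (trial in 1:5) {
    n <- sample(4:8, 1)
    nodes <- sprintf("g%02d", 1:n)
    sc <- stats::runif(n * (n - 1) / 2)
    k <- 0
    g2 <- mk_graph(nodes, function(p) { k <<- k + 1; sc[k] })
    m <- diag(1, n); dimnames(m) <- list(nodes, nodes)
    m[cbind(g2$edges$geneA, g2$edges$geneB)] <- g2$edges$combined
    m[cbind(g2$edges$geneB, g2$edges$geneA)] <- g2$edges$combined
    best <- Inf
    for (code in 1:(2^n - 2)) {
      grp <- as.integer(intToBits(code))[1:n] + 1L
      if (length(unique(grp)) < 2) next
      best <- min(best, wss_of(m, grp))
    }
    bp2 <- bipartition(g2, seed = trial)
    expect_equal(bp2$withinss, best, tolerance = 1e-9)
  }
  # determinism and tie handling with identical rows
  g3 <- mk_graph(c("x", "y", "z"), function(p) 0.5)
  expect_identical(bipartition(g3, seed = 2), bipartition(g3, seed = 2))
  expect_true("x" %in% bipartition(g3, seed = 2)$clusters[[1]])
  expect_error(bipartition(mk_graph(c("x", "y"), function(p) 1),
                           k = 3), "only k = 2")
})
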