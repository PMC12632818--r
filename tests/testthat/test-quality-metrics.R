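net_of <- function(...) {
  rows <- list(...)
  edge_network(data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(tf = r[[1]], gene = r[[2]], weight = r[[3]])
  })))
}

test_that("graph union keeps the maximum weight per edge", {
  a <- net_of(list("a", "g", 0.2))
  b <- net_of(list("a", "g", 0.7))
  u <- graph_union(list(a, b))
  expect_equal(u$weight, 0.7)

  empty <- edge_network(data.table::data.table(
    tf = character(), gene = character(), weight = numeric()))
  u2 <- graph_union(list(a, empty))
  expect_equal(as.data.table(u2), as.data.table(a), ignore_attr = TRUE)
})

test_that("graph union is commutative and associative on random triples", {
  set.seed(4)
  nets <- lapply(1:3, function(i) {
    dt <- data.table::CJ(tf = paste0("t", 1:4), gene = paste0("g", 1:6))
    dt <- dt[sample(.N, 10)][, weight := round(runif(.N), 3)]
    edge_network(dt)
  })
  u1 <- graph_union(nets)
  u2 <- graph_union(list(nets[[3]], nets[[1]], nets[[2]]))
  u3 <- graph_union(list(graph_union(nets[1:2]), nets[[3]]))
  for (u in list(u2, u3)) {
    expect_equal(as.data.table(u1), as.data.table(u), ignore_attr = TRUE)
  }
})

test_that("mixed weight semantics refuse to union", {
  a <- edge_network(data.table::data.table(tf = "a", gene = "g",
                                           weight = 0.5),
                    semantics = "probability")
  b <- edge_network(data.table::data.table(tf = "a", gene = "g",
                                           weight = 2), semantics = "prior")
  expect_error(graph_union(list(a, b)), "mixed")
})

test_that("external-network preprocessing drops self-edges, non-coding targets, extra TFs", {
  # raw external networks may carry self-edges, so use a plain table
  n <- data.table::data.table(tf = c("t1", "t1", "t1", "t2"),
                              gene = c("t1", "g1", "gX", "g2"), weight = 1)
  out <- preprocess_network(n, coding_genes = c("g1", "g2", "t1"),
                            common_tfs = c("t1"))
  expect_equal(as.data.table(out)[, paste(tf, gene)], "t1 g1")
  empty <- preprocess_network(n, coding_genes = c("g1"),
                              common_tfs = character())
  expect_equal(nrow(empty), 0)
})

test_that("top-k threshold scales with TF count and breaks ties deterministically", {
  set.seed(9)
  dt <- data.table::CJ(tf = sprintf("t%03d", 1:200),
                       gene = sprintf("g%04d", 1:150))
  dt[, weight := runif(.N)]
  net <- edge_network(dt)
  topk <- threshold_topk(net, 100)
  expect_equal(nrow(topk), 20000)  # 200 TFs x 100 targets per TF
  expect_gte(min(topk$weight), max(setdiff(net$weight, topk$weight)))

  small <- net_of(list("a", "g1", 1), list("a", "g2", 0.5))
  expect_equal(nrow(threshold_topk(small, 10)), 2)  # k beyond edge count

  tie <- net_of(list("b", "g1", 1), list("a", "g9", 0.5),
                list("a", "g2", 0.5))
  kept <- threshold_topk(tie, 1)  # 2 TFs x 1 = 2 edges, tie at 0.5
  expect_equal(as.data.table(kept)[, paste(tf, gene)],
               c("b g1", "a g2"))
})

test_that("binding metric matches enumeration and its analytic expectation", {
  net <- net_of(list("t1", "g1", 0.9), list("t1", "g2", 0.8),
                list("t1", "g3", 0.7), list("t2", "g1", 0.6),
                list("t2", "g4", 0.5), list("t1", "g5", 0.4),
                list("t2", "g2", 0.3), list("t2", "g5", 0.2),
                list("t1", "g4", 0.15), list("t2", "g3", 0.1))
  support <- data.table::data.table(tf = c("t1", "t1", "t2", "t2"),
                                    gene = c("g1", "g3", "g4", "g2"))
  bm <- binding_metric(net, support)
  expect_equal(bm$value, 0.4)  # 4 of 10 supported, by enumeration
  cand <- data.table::CJ(tf = c("t1", "t2"), gene = paste0("g", 1:5))
  bm2 <- binding_metric(net, support, candidate_edges = cand)
  expect_equal(bm2$random_expectation, 4 / 10)

  all_sup <- data.table::CJ(tf = c("t1", "t2"), gene = paste0("g", 1:5))
  expect_equal(binding_metric(net, all_sup)$value, 1.0)

  # TFs without binding data excluded from numerator and denominator
  bm3 <- binding_metric(net, support, tfs_with_binding = "t1")
  expect_equal(bm3$value, 2 / 5)
  expect_equal(bm3$n_edges, 5)
})

test_that("hypergeometric p-values match direct tail summation to 1e-10 relative", {
  cases <- list(c(5, 20, 1000, 30), c(1, 5, 50, 10), c(10, 300, 5000, 100),
                c(3, 3, 40, 9), c(0, 10, 100, 10), c(7, 12, 200, 25))
  for (cs in cases) {
    got <- hypergeom_test(cs[1], cs[2], cs[3], cs[4])
    want <- oracle_hypergeom(cs[1], cs[2], cs[3], cs[4])
    expect_lt(abs(got - want) / max(want, 1e-300), 1e-10)
  }
})

test_that("GO enrichment scores a planted term and applies the size filter", {
  universe <- sprintf("g%04d", 1:1000)
  term_genes <- universe[1:20]
  go_map <- list("GO:planted" = term_genes,
                 "GO:tiny" = universe[1:3],          # size < 5, never tested
                 "GO:background" = universe[500:560])
  net <- edge_network(data.table::data.table(
    tf = "tfA", gene = term_genes, weight = 1))
  res <- go_enrichment_score(net, go_map, universe)
  expect_equal(res$per_tf$best_term, "GO:planted")
  # all 20 targets inside a 20-gene term: p = hypergeometric tail at k = 20
  p_exact <- oracle_hypergeom(20, 20, 1000, 20)
  expect_equal(res$per_tf$best_neglogp, -log10(p_exact), tolerance = 1e-8)
  expect_equal(res$score, res$per_tf$best_neglogp)

  # tiny term is never the best even when fully covered
  net2 <- edge_network(data.table::data.table(
    tf = "tfB", gene = universe[1:3], weight = 1))
  res2 <- go_enrichment_score(net2, go_map, universe)
  expect_false(identical(res2$per_tf$best_term, "GO:tiny"))
})

test_that("a TF with no significant term scores zero", {
  universe <- sprintf("g%04d", 1:200)
  go_map <- list("GO:a" = universe[1:30])
  net <- edge_network(data.table::data.table(
    tf = "tfA", gene = universe[101:110], weight = 1))  # disjoint targets
  res <- go_enrichment_score(net, go_map, universe)
  expect_equal(res$per_tf$best_neglogp, 0)
  expect_true(is.na(res$per_tf$best_term))
  expect_error(go_enrichment_score(net, go_map, character()), "universe")
})

test_that("GO-directness enumerates binding support over best-term targets", {
  universe <- sprintf("g%03d", 1:100)
  go_map <- list("GO:m" = universe[1:10])
  net <- edge_network(data.table::data.table(
    tf = "tfA", gene = universe[1:10], weight = 1))
  enr <- go_enrichment_score(net, go_map, universe)
  support <- data.table::data.table(tf = "tfA", gene = universe[1:5])
  gd <- go_directness(net, enr, go_map, support)
  expect_equal(gd$value, 0.5)  # 5 of the 10 term targets supported

  all_sup <- data.table::data.table(tf = "tfA", gene = universe)
  expect_equal(go_directness(net, enr, go_map, all_sup)$value, 1.0)

  # no significant term anywhere -> undefined, reported as missing
  net2 <- edge_network(data.table::data.table(
    tf = "tfB", gene = universe[60:64], weight = 1))
  enr2 <- go_enrichment_score(net2, go_map, universe)
  expect_true(is.na(go_directness(net2, enr2, go_map, support)$value))
})

test_that("PPI metric computes Jaccard similarity and top-pair support", {
  net <- net_of(list("t1", "a", 1), list("t1", "b", 1), list("t1", "c", 1),
                list("t2", "b", 1), list("t2", "c", 1), list("t2", "d", 1),
                list("t3", "x", 1), list("t3", "y", 1))
  pm <- ppi_metric(net, data.table::data.table(tf1 = "t1", tf2 = "t2"))
  pairs <- pm$pairs
  expect_equal(pairs[tf1 == "t1" & tf2 == "t2", jaccard], 0.5)  # 2/4
  expect_equal(pairs[tf1 == "t1" & tf2 == "t3", jaccard], 0)    # disjoint
  # identical target sets give Jaccard 1
  net_same <- net_of(list("t1", "a", 1), list("t2", "a", 1))
  pm_same <- ppi_metric(net_same, data.table::data.table(
    tf1 = character(), tf2 = character()))
  expect_equal(pm_same$pairs$jaccard, 1)
  # fewer pairs than requested: use all, flagged
  expect_equal(pm$n_pairs, 3)
  expect_true(pm$used_all_pairs)
  expect_equal(pm$value, 1 / 3)
  expect_equal(pm$random_expectation, 1 / 3)
})

test_that("score permutations preserve the weight multiset and reproduce", {
  set.seed(5)
  dt <- data.table::CJ(tf = paste0("t", 1:5), gene = paste0("g", 1:20))
  dt <- dt[tf != gene][, weight := runif(.N)]
  net <- edge_network(dt)
  nulls <- permuted_nulls(net, n = 10, seed = 3)
  for (nn in nulls) {
    expect_equal(sort(nn$weight), sort(net$weight))
    expect_equal(nn[, .(tf, gene)], net[, .(tf, gene)], ignore_attr = TRUE)
  }
  nulls2 <- permuted_nulls(net, n = 10, seed = 3)
  expect_equal(lapply(nulls, as.data.table), lapply(nulls2, as.data.table),
               ignore_attr = TRUE)
  expect_false(identical(nulls[[1]]$weight, nulls[[2]]$weight))
})

test_that("binding metric over permuted nulls concentrates on the random expectation", {
  set.seed(11)
  dt <- data.table::CJ(tf = sprintf("t%02d", 1:6),
                       gene = sprintf("g%03d", 1:80))
  dt[, weight := runif(.N)]
  net <- edge_network(dt)
  support <- dt[sample(.N, 96), .(tf, gene)]  # 20% of edges supported
  cand <- dt[, .(tf, gene)]
  p0 <- nrow(support) / nrow(cand)
  nulls <- permuted_nulls(net, n = 50, seed = 7)
  vals <- vapply(nulls, function(nn) {
    binding_metric(threshold_topk(nn, 20), support,
                   candidate_edges = cand)$value
  }, 0)
  k <- 6 * 20
  se <- sqrt(p0 * (1 - p0) / (k * length(nulls)))
  expect_lt(abs(mean(vals) - p0), 3 * se)
})

test_that("the four metrics equal brute-force recomputation on a small instance", {
  set.seed(21)
  tfs <- paste0("t", 1:4)
  genes <- paste0("g", 1:12)
  dt <- data.table::CJ(tf = tfs, gene = genes)
  dt <- dt[sample(.N, 28)][, weight := round(runif(.N), 4)]
  net <- edge_network(dt)
  topk <- threshold_topk(net, 5)

  # brute force top-k: sort and cut by hand
  o <- order(-dt$weight, dt$tf, dt$gene)
  manual <- dt[o][seq_len(min(4 * 5, nrow(dt)))]
  expect_equal(as.data.table(topk), manual, ignore_attr = TRUE)

  support <- dt[sample(.N, 10), .(tf, gene)]
  bm <- binding_metric(topk, support)
  manual_frac <- mean(apply(as.data.table(topk)[, .(tf, gene)], 1,
                            function(r) {
    any(support$tf == r[1] & support$gene == r[2])
  }))
  expect_equal(bm$value, manual_frac)

  go_map <- list(A = genes[1:6], B = genes[5:12])
  universe <- genes
  enr <- go_enrichment_score(topk, go_map, universe, min_term = 2,
                             max_term = 300)
  for (i in seq_len(nrow(enr$per_tf))) {
    t <- enr$per_tf$tf[i]
    targ <- as.data.table(topk)[tf == t, gene]
    ps <- vapply(go_map, function(tg) {
      oracle_hypergeom(length(intersect(tg, targ)), length(tg),
                       length(universe), length(targ))
    }, 0)
    sig <- ps[pmin(ps * length(ps), 1) < 0.05]
    want <- if (length(sig)) max(-log10(sig)) else 0
    expect_equal(enr$per_tf$best_neglogp[i], want, tolerance = 1e-9)
  }

  pm <- ppi_metric(topk, data.table::data.table(tf1 = "t1", tf2 = "t3"),
                   top_pairs = 3)
  td <- as.data.table(topk)
  jac <- function(a, b) {
    A <- td[tf == a, gene]; B <- td[tf == b, gene]
    length(intersect(A, B)) / length(union(A, B))
  }
  combs <- utils::combn(sort(unique(td$tf)), 2)
  js <- apply(combs, 2, function(cc) jac(cc[1], cc[2]))
  ord <- order(-js, combs[1, ], combs[2, ])
  top3 <- combs[, ord[1:3], drop = FALSE]
  manual_ppi <- mean(apply(top3, 2, function(cc) {
    all(cc == c("t1", "t3"))
  }))
  expect_equal(pm$value, manual_ppi)
})
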