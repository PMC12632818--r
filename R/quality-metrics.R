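#' Graph union of edge networks
#'
#' Union of node and edge sets, keeping the maximum weight for each edge.
#' All inputs must share the same weight semantics.
#'
#' @param networks list of `edge_network`s (or tf/gene/weight tables).
#' @return an `edge_network`.
#' @export
graph_union <- function(networks) {
  stopifnot(length(networks) >= 1L)
  sems <- unique(vapply(networks, net_semantics, ""))
  if (length(sems) > 1L)
    data_error("cannot union networks with mixed weight semantics: ",
               paste(sems, collapse = ", "))
  all_edges <- rbindlist(lapply(networks, function(n) {
    as.data.table(n)[, .(tf, gene, weight)]
  }))
  merged <- all_edges[, .(weight = max(weight)), by = .(tf, gene)]
  setorder(merged, tf, gene)
  edge_network(merged, tissue = net_tissue(networks[[1L]]),
               semantics = sems)
}

#' Standard preprocessing of an external network
#'
#' Restricts targets to a coding-gene set, drops self-regulatory edges and
#' keeps only TFs common to the comparison.
#'
#' @param net an `edge_network`.
#' @param coding_genes allowed target gene ids.
#' @param common_tfs allowed TF ids.
#' @return the filtered `edge_network`.
#' @export
preprocess_network <- function(net, coding_genes, common_tfs) {
  dt <- as.data.table(net)[tf != gene][gene %in% coding_genes][
    tf %in% common_tfs]
  edge_network(dt, tissue = net_tissue(net), semantics = net_semantics(net))
}

#' Keep the top-k edges scaled to targets per TF
#'
#' Keeps the top `n_tfs_in_net * targets_per_tf` edges by weight,
#' descending, globally over the whole network (so individual TFs may end
#' up with more or fewer targets than the average). Ties at the cutoff are
#' broken deterministically by (weight desc, tf, gene).
#'
#' @param net an `edge_network`.
#' @param targets_per_tf average number of targets per TF to retain.
#' @return the thresholded `edge_network`.
#' @export
threshold_topk <- function(net, targets_per_tf) {
  if (!(targets_per_tf >= 1)) config_error("targets_per_tf must be positive")
  dt <- as.data.table(net)
  k <- length(unique(dt$tf)) * targets_per_tf
  setorder(dt, -weight, tf, gene)
  out <- dt[seq_len(min(k, nrow(dt)))]
  edge_network(out, tissue = net_tissue(net), semantics = net_semantics(net))
}

#' Binding support metric
#'
#' Fraction of a (thresholded) network's edges supported by TF binding
#' evidence, together with the random expectation: the probability that a
#' uniformly drawn candidate edge is supported. TFs lacking binding data
#' can be excluded from both numerator and denominator.
#'
#' @param net_topk thresholded `edge_network`.
#' @param support `data.table` (`tf`, `gene`) of binding-supported pairs.
#' @param candidate_edges all candidate (`tf`, `gene`) pairs used for the
#'   random expectation; defaults to TFs in `net_topk` crossed with the
#'   union of genes in `net_topk` and `support`.
#' @param tfs_with_binding TFs that have binding data; edges of other TFs
#'   are ignored. `NULL` means all.
#' @return list with `value`, `random_expectation`, `n_edges`.
#' @export
binding_metric <- function(net_topk, support, candidate_edges = NULL,
                           tfs_with_binding = NULL) {
  dt <- as.data.table(net_topk)[, .(tf, gene)]
  support <- as.data.table(support)[, .(tf, gene)]
  if (!is.null(tfs_with_binding)) {
    dt <- dt[tf %in% tfs_with_binding]
    support <- support[tf %in% tfs_with_binding]
  }
  if (is.null(candidate_edges)) {
    genes <- sort(unique(c(dt$gene, support$gene)))
    candidate_edges <- CJ(tf = sort(unique(dt$tf)), gene = genes)[tf != gene]
  } else {
    candidate_edges <- as.data.table(candidate_edges)[, .(tf, gene)]
    if (!is.null(tfs_with_binding))
      candidate_edges <- candidate_edges[tf %in% tfs_with_binding]
  }
  n_sup <- nrow(dt[support, on = c("tf", "gene"), nomatch = 0L])
  exp_sup <- nrow(candidate_edges[support, on = c("tf", "gene"),
                                  nomatch = 0L]) / nrow(candidate_edges)
  list(value = if (nrow(dt)) n_sup / nrow(dt) else NA_real_,
       random_expectation = exp_sup, n_edges = nrow(dt))
}

#' Hypergeometric over-representation p-value
#'
#' One-sided upper-tail probability of observing `overlap` or more
#' annotated genes among `n_targets` draws from a universe of `n_universe`
#' genes of which `term_size` are annotated.
#'
#' @param overlap annotated targets observed.
#' @param term_size annotated genes in the universe.
#' @param n_universe universe size.
#' @param n_targets target-set size.
#' @return p-value.
#' @export
hypergeom_test <- function(overlap, term_size, n_universe, n_targets) {
  phyper(overlap - 1L, term_size, n_universe - term_size, n_targets,
         lower.tail = FALSE)
}

#' GO over-representation score of a network
#'
#' For each TF in the (thresholded) network, tests every GO term for
#' over-representation among the TF's targets with a one-sided
#' hypergeometric test. Terms are size-filtered on their annotated count
#' within the analysis universe (default 5 to 300). A term is significant
#' if its Bonferroni-adjusted p (within the TF's tested terms) is below
#' `alpha`; the TF's score is the maximum `-log10 p` over significant
#' terms, or 0 if none is significant. The network score is the median of
#' TF scores across all TFs in the network.
#'
#' @param net_topk thresholded `edge_network`.
#' @param go_map named list: term -> character vector of annotated genes.
#' @param universe all genes eligible as targets.
#' @param min_term,max_term term-size bounds (inclusive), counted within
#'   the universe.
#' @param alpha significance level after Bonferroni adjustment.
#' @return list with `score` (network median), and `per_tf` (`data.table`:
#'   `tf`, `best_term`, `best_neglogp`, `n_significant`).
#' @export
go_enrichment_score <- function(net_topk, go_map, universe, min_term = 5L,
                                max_term = 300L, alpha = 0.05) {
  if (length(universe) == 0L) data_error("empty universe")
  universe <- unique(universe)
  n_u <- length(universe)
  term_genes <- lapply(go_map, function(g) intersect(g, universe))
  sizes <- lengths(term_genes)
  keep_terms <- names(term_genes)[sizes >= min_term & sizes <= max_term]
  dt <- as.data.table(net_topk)
  tfs <- sort(unique(dt$tf))
  per_tf <- rbindlist(lapply(tfs, function(t) {
    targ <- intersect(dt[tf == t, gene], universe)
    if (length(targ) == 0L || length(keep_terms) == 0L) {
      return(data.table(tf = t, best_term = NA_character_,
                        best_neglogp = 0, n_significant = 0L))
    }
    p <- vapply(keep_terms, function(tm) {
      k <- length(intersect(term_genes[[tm]], targ))
      hypergeom_test(k, length(term_genes[[tm]]), n_u, length(targ))
    }, 0)
    sig <- which(pmin(p * length(p), 1) < alpha)
    if (length(sig) == 0L) {
      return(data.table(tf = t, best_term = NA_character_,
                        best_neglogp = 0, n_significant = 0L))
    }
    best <- sig[which.max(-log10(p[sig]))]
    data.table(tf = t, best_term = keep_terms[best],
               best_neglogp = -log10(p[best]),
               n_significant = length(sig))
  }))
  list(score = median(per_tf$best_neglogp), per_tf = per_tf)
}

#' GO-directness metric
#'
#' For each TF whose target set has a significant best GO term, takes the
#' TF's thresholded targets annotated with that term and measures the
#' fraction with binding support; the network value is the mean over such
#' TFs. When no TF has a significant term the metric is undefined and `NA`
#' is returned.
#'
#' @param net_topk thresholded `edge_network`.
#' @param enrichment output of [go_enrichment_score()].
#' @param go_map the term -> gene map used for the enrichment.
#' @param support binding-supported (`tf`, `gene`) pairs.
#' @return list with `value` (mean fraction or `NA`) and `per_tf`.
#' @export
go_directness <- function(net_topk, enrichment, go_map, support) {
  dt <- as.data.table(net_topk)
  support <- as.data.table(support)[, .(tf, gene)]
  hits <- enrichment$per_tf[!is.na(best_term)]
  if (nrow(hits) == 0L) return(list(value = NA_real_, per_tf = NULL))
  per_tf <- rbindlist(lapply(seq_len(nrow(hits)), function(i) {
    t <- hits$tf[i]
    term <- hits$best_term[i]
    targ <- intersect(dt[tf == t, gene], go_map[[term]])
    sup <- sum(targ %in% support[tf == t, gene])
    data.table(tf = t, term = term, n_term_targets = length(targ),
               frac_supported = if (length(targ)) sup / length(targ)
                                else NA_real_)
  }))
  list(value = mean(per_tf$frac_supported, na.rm = TRUE), per_tf = per_tf)
}

#' PPI support metric
#'
#' Computes the Jaccard similarity between the target sets of every
#' unordered pair of TFs in the thresholded network, ranks pairs by
#' similarity (ties by pair id) and reports the fraction of the top
#' `top_pairs` supported by physical interactions, plus the random
#' expectation (fraction of all present TF pairs supported).
#'
#' @param net_topk thresholded `edge_network`.
#' @param ppi_pairs `data.table` with `tf1`, `tf2` (optionally `score`;
#'   filtering by score happens at I/O, not here).
#' @param top_pairs number of top pairs scored (all pairs if fewer exist,
#'   flagged by `used_all_pairs`).
#' @return list with `value`, `random_expectation`, `n_pairs`,
#'   `used_all_pairs` and the ranked `pairs` table.
#' @export
ppi_metric <- function(net_topk, ppi_pairs, top_pairs = 100L) {
  dt <- as.data.table(net_topk)
  tfs <- sort(unique(dt$tf))
  if (length(tfs) < 2L) {
    return(list(value = NA_real_, random_expectation = NA_real_,
                n_pairs = 0L, used_all_pairs = TRUE, pairs = NULL))
  }
  tsets <- lapply(setNames(tfs, tfs), function(t) unique(dt[tf == t, gene]))
  pairs <- CJ(tf1 = tfs, tf2 = tfs)[tf1 < tf2]
  pairs[, jaccard := vapply(seq_len(.N), function(i) {
    a <- tsets[[tf1[i]]]; b <- tsets[[tf2[i]]]
    u <- length(union(a, b))
    if (u == 0L) 0 else length(intersect(a, b)) / u
  }, 0)]
  pp <- as.data.table(ppi_pairs)
  pp <- unique(rbind(pp[, .(tf1, tf2)],
                     pp[, .(tf1 = tf2, tf2 = tf1)]))[tf1 < tf2]
  pairs[, supported := FALSE]
  pairs[pp, supported := TRUE, on = c("tf1", "tf2")]
  setorder(pairs, -jaccard, tf1, tf2)
  n_use <- min(top_pairs, nrow(pairs))
  top <- pairs[seq_len(n_use)]
  list(value = mean(top$supported),
       random_expectation = mean(pairs$supported),
       n_pairs = n_use,
       used_all_pairs = n_use < top_pairs,
       pairs = pairs[])
}

#' Score-permutation null networks
#'
#' Generates `n` copies of the fully connected network with edge scores
#' randomly shuffled across the whole edge set (endpoints preserved, the
#' multiset of weights preserved). Each null should then be thresholded
#' exactly like the real network.
#'
#' @param full_net the unthresholded `edge_network`.
#' @param n number of permuted networks.
#' @param seed integer seed.
#' @return list of `edge_network`s.
#' @export
permuted_nulls <- function(full_net, n = 50L, seed = 1L) {
  dt <- as.data.table(full_net)
  seeds <- sub_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    w <- with_seed(seeds[i], sample(dt$weight))
    edge_network(data.table(tf = dt$tf, gene = dt$gene, weight = w),
                 tissue = net_tissue(full_net),
                 semantics = net_semantics(full_net))
  })
}
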