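#' eQTL support and count for a network in one tissue
#'
#' An edge (TF, gene) is supported by an eQTL record when the record's
#' gene matches the edge's target and its position falls inside an
#' interval that is simultaneously one of the target's regulatory elements
#' and one of the TF's retained (q <= `q_max`) peaks. Two metrics are
#' returned: the fraction of edges with at least one qualifying eQTL, and
#' the total number of qualifying eQTLs summed over edges.
#'
#' @param net an `edge_network` (already thresholded if desired).
#' @param eqtls `data.table` (`chrom`, `pos`, `gene`) of one tissue's
#'   significant eQTLs; a `tissue` column, if present, is ignored.
#' @param peaks per-TF peak table (`tf`, `chrom`, `start`, `end`,
#'   `q_value`).
#' @param elements element table (`gene`, `chrom`, `start`, `end`).
#' @param q_max peak q-value cutoff applied before overlap.
#' @return list with `support` (fraction in \[0, 1\]), `count` (integer)
#'   and `per_edge` (`data.table`: `tf`, `gene`, `n_eqtl`).
#' @export
eqtl_metrics <- function(net, eqtls, peaks, elements, q_max = 0.01) {
  dt <- as.data.table(net)[, .(tf, gene)]
  eqtls <- as.data.table(eqtls)
  peaks <- filter_peaks(as.data.table(peaks), q_max)
  elements <- as.data.table(elements)
  per_edge <- copy(dt)[, n_eqtl := 0L]
  if (nrow(eqtls) > 0L && nrow(dt) > 0L && nrow(peaks) > 0L) {
    # eQTLs inside an element of their own gene
    in_el <- positions_in(eqtls, elements)
    in_el <- in_el[eqtls$gene[query] == elements$gene[subject]]
    in_el <- unique(data.table(eqtl_idx = in_el$query,
                               gene = elements$gene[in_el$subject]))
    # eQTLs inside a peak, per TF
    in_pk <- positions_in(eqtls, peaks)
    in_pk <- unique(data.table(eqtl_idx = in_pk$query,
                               tf = peaks$tf[in_pk$subject]))
    qual <- merge(in_el, in_pk, by = "eqtl_idx", allow.cartesian = TRUE)
    if (nrow(qual)) {
      counts <- qual[, .(n_eqtl = .N), by = .(tf, gene)]
      per_edge[counts, n_eqtl := i.n_eqtl, on = c("tf", "gene")]
    }
  }
  list(support = if (nrow(per_edge)) mean(per_edge$n_eqtl > 0L) else 0,
       count = sum(per_edge$n_eqtl), per_edge = per_edge[])
}

# ranks within each tissue row: rank 1 = highest metric, average on ties
rank_matrix <- function(metric_matrix) {
  t(apply(metric_matrix, 1L, function(r) rank(-r, ties.method = "average")))
}

#' Matching-rank permutation test of tissue specificity
#'
#' Given a tissues x networks metric matrix with a declared matching
#' (tissue i corresponds to network i, identified by shared dimnames when
#' present), networks are ranked within each tissue (rank 1 = highest
#' metric) and the observed statistic `S_obs` sums the matching ranks; a
#' smaller sum indicates better overall specificity. Each permutation
#' shuffles the network labels once, globally, and re-sums the newly
#' matching ranks; the empirical p-value is the proportion of permutations
#' with `S_perm <= S_obs`. With `method = "exhaustive"` all label
#' permutations are enumerated instead of sampled.
#'
#' @param metric_matrix square numeric matrix, tissues in rows, networks in
#'   columns; when dimnames are present, columns are matched to rows by
#'   name.
#' @param n_perm permutations (ignored for exhaustive enumeration).
#' @param seed integer seed.
#' @param method `"sample"` (default) or `"exhaustive"` (requires <= 8
#'   networks).
#' @param add_one use the (b+1)/(n+1) conservative estimator instead of the
#'   literal proportion.
#' @return list with `S_obs`, `p`, `n_perm`, and the matching `ranks`.
#' @export
specificity_permutation_test <- function(metric_matrix, n_perm = 10000L,
                                         seed = 1L,
                                         method = c("sample", "exhaustive"),
                                         add_one = FALSE) {
  method <- match.arg(method)
  m <- as.matrix(metric_matrix)
  if (nrow(m) != ncol(m)) data_error("metric matrix must be square")
  n <- nrow(m)
  if (!is.null(rownames(m)) && !is.null(colnames(m))) {
    if (!setequal(rownames(m), colnames(m)))
      data_error("row and column names do not describe a matching")
    # canonical tissue order so the sampled permutation stream does not
    # depend on how the caller ordered rows
    ord <- sort(rownames(m))
    m <- m[ord, ord, drop = FALSE]
  }
  rk <- rank_matrix(m)
  s_obs <- sum(rk[cbind(seq_len(n), seq_len(n))])
  if (method == "exhaustive") {
    if (n > 8L) config_error("exhaustive enumeration limited to 8 networks")
    perms <- all_permutations(n)
    s_perm <- vapply(perms, function(p) sum(rk[cbind(seq_len(n), p)]), 0)
  } else {
    seeds <- sub_seeds(seed, 1L)
    s_perm <- with_seed(seeds, vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      sum(rk[cbind(seq_len(n), p)])
    }, 0))
  }
  b <- sum(s_perm <= s_obs)
  p <- if (add_one) (b + 1) / (length(s_perm) + 1) else b / length(s_perm)
  list(S_obs = s_obs, p = p, n_perm = length(s_perm),
       ranks = rk[cbind(seq_len(n), seq_len(n))])
}

# all permutations of 1..n as a list
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Wilcoxon signed-rank comparison of matching ranks
#'
#' Two-sided paired signed-rank test on per-tissue matching ranks of two
#' networks. Zero differences are dropped; `W` is the sum of ranks of
#' positive differences. For `n <= 25` retained pairs the exact null
#' distribution is computed by dynamic programming over the (possibly
#' tied, hence half-integer) ranks; otherwise a normal approximation with
#' continuity and tie corrections is used. Degenerate input (all
#' differences zero) returns `p = 1` with a warning.
#'
#' @param ranks_a,ranks_b paired numeric vectors (e.g. matching ranks per
#'   tissue).
#' @return list with `W`, `p`, `n_used`, `method`.
#' @export
wilcoxon_compare <- function(ranks_a, ranks_b) {
  stopifnot(length(ranks_a) == length(ranks_b))
  d <- ranks_a - ranks_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; test degenerate, p = 1")
    return(list(W = 0, p = 1, n_used = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= 25L) {
    # exact distribution over all 2^n sign assignments, DP on doubled
    # ranks (average ranks are multiples of 1/2)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1L)  # dist[w + 1] = #assignments with W2 = w
    dist[1L] <- 1
    for (x in r2) {
      shifted <- c(rep(0, x), dist[seq_len(total + 1L - x)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * w_pos))
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(W = w_pos, p = p, n_used = n, method = method)
}

#' IQR-based tissue-specific edge filtering
#'
#' For each edge, computes the median and interquartile range of its
#' weight across all tissues (quartiles by linear interpolation, the
#' standard type-7 convention) and the specificity score
#' `s = (w(t) - median) / IQR`. Edges with `s > threshold` in a tissue are
#' called specific to that tissue. Edges with zero IQR are never called
#' and are reported in the `dropped` attribute.
#'
#' @param weights_by_tissue `data.table` with `tf`, `gene`, `tissue`,
#'   `weight` covering every edge in every tissue, or a numeric matrix
#'   (edges x tissues) with `"tf|gene"` rownames.
#' @param threshold specificity cutoff (default 2).
#' @return `data.table` (`tf`, `gene`, `tissue`, `s`) of tissue-specific
#'   calls, with attribute `dropped` listing zero-IQR edges.
#' @export
iqr_filter <- function(weights_by_tissue, threshold = 2) {
  if (is.matrix(weights_by_tissue)) {
    dt <- as.data.table(as.table(weights_by_tissue))
    setnames(dt, c("edge", "tissue", "weight"))
    dt[, c("tf", "gene") := tstrsplit(edge, "|", fixed = TRUE)]
    dt[, edge := NULL]
  } else {
    dt <- as.data.table(weights_by_tissue)[, .(tf, gene, tissue, weight)]
  }
  stats <- dt[, .(med = median(weight),
                  iqr = quantile(weight, 0.75, type = 7) -
                        quantile(weight, 0.25, type = 7)),
              by = .(tf, gene)]
  dt <- merge(dt, stats, by = c("tf", "gene"))
  dropped <- unique(dt[iqr == 0, .(tf, gene)])
  calls <- dt[iqr > 0][, s := (weight - med) / iqr][s > threshold,
                                                    .(tf, gene, tissue, s)]
  setorder(calls, tf, gene, tissue)
  setattr(calls, "dropped", dropped[])
  calls[]
}
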