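# Independent brute-force oracles used to check the package's optimized
# implementations on small instances. These deliberately share no code
# with the implementation: plain loops, exhaustive enumeration, direct
# tail summation.

# element and gene binding scores by exhaustive all-pairs overlap scan;
# global transitive peak clusters, winner by confidence then leftmost start
oracle_gene_scores <- function(peaks, elements) {
  peaks <- as.data.frame(peaks)
  elements <- as.data.frame(elements)
  np <- nrow(peaks)
  genes <- sort(unique(elements$gene))
  scores <- setNames(numeric(length(genes)), genes)
  if (np == 0) return(scores)
  # transitive closure of pairwise overlap (same chrom)
  cluster <- seq_len(np)
  repeat {
    changed <- FALSE
    for (i in seq_len(np)) {
      for (j in seq_len(np)) {
        if (i == j) next
        if (peaks$chrom[i] == peaks$chrom[j] &&
            peaks$start[i] < peaks$end[j] && peaks$start[j] < peaks$end[i]) {
          cl <- min(cluster[i], cluster[j])
          if (cluster[i] != cl || cluster[j] != cl) {
            cluster[i] <- cl; cluster[j] <- cl; changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  winners <- integer(0)
  for (cl in unique(cluster)) {
    members <- which(cluster == cl)
    best <- members[order(-peaks$confidence[members],
                          peaks$start[members])][1]
    winners <- c(winners, best)
  }
  for (e in seq_len(nrow(elements))) {
    for (w in winners) {
      if (peaks$chrom[w] != elements$chrom[e]) next
      ov <- min(peaks$end[w], elements$end[e]) -
            max(peaks$start[w], elements$start[e])
      if (ov > 0) {
        g <- elements$gene[e]
        scores[g] <- scores[g] + peaks$confidence[w] * ov
      }
    }
  }
  scores
}

# upper-tail hypergeometric probability by direct log-binomial summation
oracle_hypergeom <- function(overlap, term_size, n_universe, n_targets) {
  i <- overlap:min(term_size, n_targets)
  if (overlap > min(term_size, n_targets)) return(0)
  sum(exp(lchoose(term_size, i) + lchoose(n_universe - term_size,
                                          n_targets - i) -
          lchoose(n_universe, n_targets)))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, 0)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# exhaustive matching-rank permutation p-value
oracle_matching_perm <- function(metric_matrix) {
  n <- nrow(metric_matrix)
  rk <- t(apply(metric_matrix, 1, function(r) rank(-r,
                                                   ties.method = "average")))
  s_obs <- sum(diag(rk))
  perms <- gtools_permutations(n)
  s <- apply(perms, 1, function(p) sum(rk[cbind(1:n, p)]))
  mean(s <= s_obs)
}

# all permutations of 1..n as a matrix (n! x n), plain recursion
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (k in 1:n) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# small deterministic peak/element fixtures built in code
make_elements <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(element_id = r[[1]], gene = r[[2]], kind = r[[3]],
                           chrom = r[[4]], start = r[[5]], end = r[[6]])
  }))
}

make_peaks <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(tf = r[[1]], chrom = r[[2]], start = r[[3]],
                           end = r[[4]], confidence = r[[5]],
                           q_value = r[[6]])
  }))
}

# random small peak/element instance for property tests
random_binding_instance <- function(seed, n_peaks = 12, n_genes = 4) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  el <- data.table::rbindlist(lapply(seq_len(n_genes), function(i) {
    off <- (i - 1) * 2000
    n_el <- sample(1:3, 1)
    starts <- off + cumsum(sample(100:400, n_el))
    data.table::data.table(
      element_id = sprintf("%s_e%d", genes[i], seq_len(n_el)),
      gene = genes[i], kind = "promoter", chrom = "chr1",
      start = starts, end = starts + sample(100:300, n_el, replace = TRUE))
  }))
  pk <- data.table::data.table(
    tf = "tfX", chrom = "chr1",
    start = sample(0:(n_genes * 2000), n_peaks, replace = TRUE))
  pk$end <- pk$start + sample(50:500, n_peaks, replace = TRUE)
  pk$confidence <- round(runif(n_peaks, 0.5, 10), 2)
  pk$q_value <- 0.005
  list(elements = el, peaks = pk)
}
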