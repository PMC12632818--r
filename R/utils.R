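#' Derive independent sub-seeds from a master seed
#'
#' Each evidence layer of the synthetic world (and each stochastic pipeline
#' stage) consumes its own RNG stream, derived once from the master seed, so
#' changing one layer's parameters cannot perturb the draws of another.
#'
#' @param seed integer master seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`, each a valid `set.seed()` argument.
#' @export
sub_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

#' Counts per million
#'
#' @param counts nonnegative gene x sample count matrix.
#' @return matrix of the same shape with each column scaled to sum 1e6.
#' @export
cpm <- function(counts) {
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("cpm: sample(s) with zero library size: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  sweep(counts, 2L, lib, "/") * 1e6
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with average ranks on ties.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 labels.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision
#'
#' Area under the precision-recall curve computed as the mean of precision
#' at each positive, in descending score order. Ties are broken by original
#' row order so the value is deterministic.
#'
#' @inheritParams auroc
#' @return average precision in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels)
  if (n_pos == 0L) return(NA_real_)
  o <- order(-scores, seq_along(scores))
  lab <- labels[o]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab == 1L]) / n_pos
}

# run expr with a local RNG state seeded at `seed`, restoring global state
with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# internal: stop with a consistent prefix for configuration errors
config_error <- function(...) stop("configuration error: ", ..., call. = FALSE)
data_error <- function(...) stop("data error: ", ..., call. = FALSE)

# deterministic per-id seed: a polynomial hash of the id folded into the
# master seed, so per-gene RNG streams do not depend on gene order
id_seed <- function(seed, id) {
  v <- utf8ToInt(id)
  h <- sum(v * (seq_along(v) * 131)) %% 1000003
  as.integer((as.numeric(seed) * 31 + h) %% 2147483646L) + 1L
}
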