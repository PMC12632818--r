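#' Remove lowly expressed genes
#'
#' A gene is removed iff its counts-per-million are at or below
#' `cpm_threshold` in at least `sample_fraction` of samples. The returned
#' kept set should be applied to both the counts and the TPM matrices.
#'
#' @param counts gene x sample count matrix (or an `expression_matrix`, in
#'   which case its `counts` component is used).
#' @param cpm_threshold CPM at or below which a sample counts as
#'   non-expressing.
#' @param sample_fraction fraction of non-expressing samples at or above
#'   which the gene is removed.
#' @return character vector of gene ids to keep.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 3,
                                  sample_fraction = 0.985) {
  if (inherits(counts, "expression_matrix")) counts <- counts$counts
  cm <- cpm(counts)
  low_frac <- rowMeans(cm <= cpm_threshold)
  rownames(counts)[low_frac < sample_fraction]
}

# shared input handling for the two regression feature extractors
prep_regression_input <- function(expr, tf_set, tissue, min_samples) {
  stopifnot(inherits(expr, "expression_matrix"))
  samples <- expr$samples
  if (!is.null(tissue)) {
    sel <- samples[["tissue"]] %in% tissue  # arg, not the column
    samples <- samples[sel, ]
  }
  ids <- samples$sample_id
  if (length(ids) < min_samples) {
    data_error(sprintf(
      "%d samples available but at least %d required for regression features",
      length(ids), min_samples))
  }
  x <- log2(expr$tpm[, ids, drop = FALSE] + 1)
  tf_set <- intersect(tf_set, rownames(x))
  list(logtpm = x, tfs = tf_set)
}

#' LASSO coefficient features
#'
#' For each gene, fits an L1-penalized linear regression of the gene's
#' log2(TPM+1) on the log2(TPM+1) of all TFs (the gene itself excluded from
#' its own predictors when it is a TF) and records the signed coefficient
#' of every TF at the cross-validated penalty. Coefficients shrunk to zero
#' and absent pairs are 0.
#'
#' @param expr an `expression_matrix` already restricted to filtered genes.
#' @param tf_set character vector of TF gene ids.
#' @param genes genes to model; defaults to all genes in `expr`.
#' @param tissue tissue id(s) to restrict samples to, or `NULL` for all
#'   samples (tissue-aggregate features).
#' @param penalty `"lambda.1se"` (default) or `"lambda.min"`.
#' @param nfolds folds for the internal penalty cross-validation.
#' @param min_samples refuse to fit with fewer samples than this.
#' @param seed seed controlling the CV fold assignment.
#' @return `data.table` with `tf`, `gene`, `value` (only nonzero entries).
#' @export
lasso_features <- function(expr, tf_set, genes = NULL, tissue = NULL,
                           penalty = c("lambda.1se", "lambda.min"),
                           nfolds = 5L, min_samples = 20L, seed = 1L) {
  penalty <- match.arg(penalty)
  inp <- prep_regression_input(expr, tf_set, tissue, min_samples)
  x <- inp$logtpm
  tfs <- inp$tfs
  if (is.null(genes)) genes <- rownames(x)
  n <- ncol(x)
  res <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    preds <- setdiff(tfs, g)
    if (length(preds) == 0L) next
    xm <- t(x[preds, , drop = FALSE])
    y <- x[g, ]
    if (sd(y) == 0) next
    co <- with_seed(id_seed(seed, g), {
      if (length(preds) < 2L) {
        # glmnet needs >= 2 predictors; fall back to ordinary least squares
        fit <- stats::lm.fit(cbind(1, xm), y)
        setNames(fit$coefficients[-1L], preds)
      } else {
        foldid <- sample(rep_len(seq_len(nfolds), n))
        cv <- glmnet::cv.glmnet(xm, y, alpha = 1, foldid = foldid,
                                standardize = TRUE)
        cf <- as.matrix(coef(cv, s = penalty))
        setNames(cf[-1L, 1L], rownames(cf)[-1L])
      }
    })
    co[!is.finite(co)] <- 0
    nz <- co[co != 0]
    if (length(nz)) {
      res[[gi]] <- data.table(tf = names(nz), gene = g, value = unname(nz))
    }
  }
  out <- rbindlist(res[!vapply(res, is.null, TRUE)])
  if (nrow(out) == 0L) {
    out <- data.table(tf = character(), gene = character(), value = numeric())
  }
  setorder(out, tf, gene)
  out[]
}

#' Tree-ensemble relatedness features
#'
#' For each gene, fits a sum-of-trees regression of the gene's log2(TPM+1)
#' on all TFs' log2(TPM+1) (self excluded) and records, per TF, the
#' fraction of splitting rules across the ensemble that use that TF — the
#' variable-inclusion proportion. The ensemble is a bagged sum of shallow
#' regression trees (bootstrap resampling per tree, greedy splits over all
#' TFs), the nonparametric tree-ensemble family that captures threshold
#' and saturating TF effects a linear fit misses. Values lie in \[0, 1\]
#' and sum to at most 1 per gene.
#'
#' @inheritParams lasso_features
#' @param num_trees trees in the ensemble.
#' @param max_depth maximum tree depth; shallow trees concentrate splits on
#'   genuinely predictive TFs.
#' @param min_node_size minimum node size.
#' @return `data.table` with `tf`, `gene`, `value` (nonzero inclusion
#'   proportions).
#' @export
bart_features <- function(expr, tf_set, genes = NULL, tissue = NULL,
                          num_trees = 50L, max_depth = 3L,
                          min_node_size = 5L, min_samples = 20L, seed = 1L) {
  inp <- prep_regression_input(expr, tf_set, tissue, min_samples)
  x <- inp$logtpm
  tfs <- inp$tfs
  if (is.null(genes)) genes <- rownames(x)
  res <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    preds <- setdiff(tfs, g)
    if (length(preds) == 0L) next
    xm <- t(x[preds, , drop = FALSE])
    y <- x[g, ]
    if (sd(y) == 0) next
    rf <- ranger::ranger(
      x = xm, y = y, num.trees = num_trees, max.depth = max_depth,
      min.node.size = min_node_size, mtry = length(preds),
      seed = id_seed(seed, g), num.threads = 1L, verbose = FALSE)
    sv <- unlist(lapply(seq_len(num_trees), function(i) {
      ranger::treeInfo(rf, i)$splitvarName
    }))
    sv <- sv[!is.na(sv)]
    if (length(sv) == 0L) next
    tab <- table(sv) / length(sv)
    res[[gi]] <- data.table(tf = names(tab), gene = g,
                            value = as.numeric(tab))
  }
  out <- rbindlist(res[!vapply(res, is.null, TRUE)])
  if (nrow(out) == 0L) {
    out <- data.table(tf = character(), gene = character(), value = numeric())
  }
  setorder(out, tf, gene)
  out[]
}

#' Assemble the five-feature instance table for one tissue
#'
#' One row per (TF, gene) instance, where the instance universe is the TFs
#' with binding labels intersected with TFs present in the expression data,
#' crossed with the filtered genes, minus self-pairs. The five predictor
#' columns are `motif_prior` (the tissue's prior-network weight, 0 when the
#' edge is absent), `lasso_ts`, `bart_ts` (tissue-specific regression
#' features) and `lasso_ta`, `bart_ta` (tissue-aggregate), followed by the
#' binary binding `label`. Rows are ordered by (tf, gene) so identical
#' inputs yield byte-identical tables.
#'
#' @param motif_network the tissue's prior `edge_network` (or any tf/gene/
#'   weight table).
#' @param ts_feats list with `lasso` and `bart` tissue-specific feature
#'   tables (`tf`, `gene`, `value`).
#' @param ta_feats same, computed on all samples pooled.
#' @param labels `data.table` with `tf`, `gene`, `label` for every instance.
#' @param genes filtered candidate gene universe.
#' @param tissue tissue label recorded on the table.
#' @return `data.table` with columns `tf`, `gene`, `tissue`, `motif_prior`,
#'   `lasso_ts`, `bart_ts`, `lasso_ta`, `bart_ta`, `label`.
#' @export
assemble_feature_table <- function(motif_network, ts_feats, ta_feats, labels,
                                   genes, tissue = NA_character_) {
  labels <- as.data.table(labels)
  tfs <- sort(intersect(unique(labels$tf), unique(c(
    ts_feats$lasso$tf, ts_feats$bart$tf, ta_feats$lasso$tf, ta_feats$bart$tf,
    labels$tf))))
  tab <- CJ(tf = tfs, gene = sort(genes))[tf != gene]
  fill <- function(tab, feats, col) {
    f <- as.data.table(feats)[, .(tf, gene, value)]
    tab[, (col) := 0]
    tab[f, (col) := i.value, on = c("tf", "gene")]
    tab
  }
  mp <- as.data.table(motif_network)[, .(tf, gene, value = weight)]
  tab <- fill(tab, mp, "motif_prior")
  tab <- fill(tab, ts_feats$lasso, "lasso_ts")
  tab <- fill(tab, ts_feats$bart, "bart_ts")
  tab <- fill(tab, ta_feats$lasso, "lasso_ta")
  tab <- fill(tab, ta_feats$bart, "bart_ta")
  tab[labels, label := i.label, on = c("tf", "gene")]
  if (anyNA(tab$label)) {
    miss <- tab[is.na(label)][1L]
    data_error(sprintf("instance (%s, %s) has no label", miss$tf, miss$gene))
  }
  feat_cols <- c("motif_prior", "lasso_ts", "bart_ts", "lasso_ta", "bart_ta")
  for (cc in feat_cols) {
    if (anyNA(tab[[cc]])) data_error("missing values in feature ", cc)
  }
  tissue_label <- tissue
  tab[, tissue := tissue_label]
  setcolorder(tab, c("tf", "gene", "tissue", feat_cols, "label"))
  setorder(tab, tf, gene)
  tab[]
}

#' Feature column names
#' @return the five predictor column names in canonical order.
#' @export
feature_columns <- function() {
  c("motif_prior", "lasso_ts", "bart_ts", "lasso_ta", "bart_ta")
}
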