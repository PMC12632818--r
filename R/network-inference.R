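#' Stratified nested cross-validation plan
#'
#' Partitions the instance table into `k_outer` disjoint outer folds,
#' stratified by the binding label so per-fold label proportions stay
#' within a seat or two of the global rate, and further partitions each
#' outer training set into `k_inner` stratified inner folds for
#' hyperparameter tuning.
#'
#' @param table feature table with a `label` column (see
#'   [assemble_feature_table()]).
#' @param k_outer outer folds (default 10).
#' @param k_inner inner folds per outer training set (default 5).
#' @param seed integer seed; the same seed reproduces the same plan.
#' @return a `cv_plan`: list with `outer` (fold id per row), `inner` (per
#'   outer fold, a `data.table` of training row indices and inner fold
#'   ids), `k_outer`, `k_inner`, `seed`.
#' @export
make_cv_plan <- function(table, k_outer = 10L, k_inner = 5L, seed = 1L) {
  lab <- as.integer(table$label)
  if (sum(lab == 1L) < 10L || sum(lab == 0L) < 10L) {
    data_error("need at least 10 instances of each label class to stratify")
  }
  n <- length(lab)
  stratified_assign <- function(idx, k, perm_seed) {
    with_seed(perm_seed, {
      out <- integer(length(idx))
      for (cl in unique(lab[idx])) {
        rows <- idx[lab[idx] == cl]
        out[match(rows, idx)] <- sample(rep_len(seq_len(k), length(rows)))
      }
      out
    })
  }
  seeds <- sub_seeds(seed, k_outer + 1L)
  outer <- stratified_assign(seq_len(n), k_outer, seeds[1L])
  inner <- lapply(seq_len(k_outer), function(f) {
    idx <- which(outer != f)
    data.table(idx = idx,
               fold = stratified_assign(idx, k_inner, seeds[f + 1L]))
  })
  structure(list(outer = outer, inner = inner, k_outer = k_outer,
                 k_inner = k_inner, seed = seed),
            class = "cv_plan")
}

#' Feature columns used by a named model variant
#'
#' The full model uses all five features; ablations drop the motif prior
#' (expression-only), one regression family, or one sample scope:
#' * `METANet`: all five features.
#' * `ETANet`: the four expression features (no motif prior).
#' * `META-LASSO`: motif prior + the two LASSO features.
#' * `META-BART`: motif prior + the two tree-relatedness features.
#' * `META-TSEx`: motif prior + tissue-specific expression features.
#' * `META-TAEx`: motif prior + tissue-aggregate expression features.
#'
#' @param name variant name.
#' @return character vector of feature column names.
#' @export
variant_spec <- function(name = c("METANet", "ETANet", "META-LASSO",
                                  "META-BART", "META-TSEx", "META-TAEx")) {
  name <- match.arg(name)
  switch(name,
    "METANet" = feature_columns(),
    "ETANet" = c("lasso_ts", "bart_ts", "lasso_ta", "bart_ta"),
    "META-LASSO" = c("motif_prior", "lasso_ts", "lasso_ta"),
    "META-BART" = c("motif_prior", "bart_ts", "bart_ta"),
    "META-TSEx" = c("motif_prior", "lasso_ts", "bart_ts"),
    "META-TAEx" = c("motif_prior", "lasso_ta", "bart_ta")
  )
}

fit_xgb <- function(x, y, params, seed = 1L) {
  booster_params <- list(
    objective = "binary:logistic",
    eta = params$eta, max_depth = as.integer(params$max_depth),
    subsample = params$subsample,
    colsample_bytree = params$colsample_bytree,
    min_child_weight = params$min_child_weight,
    alpha = params$alpha, lambda = params$lambda,
    nthread = 1L, seed = as.integer(seed)
  )
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(params = booster_params, data = dtrain,
                     nrounds = as.integer(params$nrounds), verbose = 0)
}

#' Tune hyperparameters on one outer training set
#'
#' Runs the TPE search where each trial's objective is the mean inner-fold
#' average precision: for every inner fold the candidate setting is trained
#' on the remaining inner folds and scored on the held-out one.
#'
#' @param x feature matrix for the outer training rows.
#' @param y 0/1 labels for the outer training rows.
#' @param inner_fold inner fold id per training row.
#' @param n_trials TPE trials.
#' @param seed integer seed for both the search and the fits.
#' @param space search space, see [tpe_space()].
#' @return list with `best`, `best_value` and the `trials` log.
#' @export
tune_hyperparameters <- function(x, y, inner_fold, n_trials = 25L, seed = 1L,
                                 space = tpe_space()) {
  if (n_trials < 1L) config_error("n_trials must be >= 1")
  folds <- sort(unique(inner_fold))
  objective <- function(params) {
    ap <- vapply(folds, function(f) {
      tr <- inner_fold != f
      m <- fit_xgb(x[tr, , drop = FALSE], y[tr], params, seed = seed)
      p <- predict(m, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
      v <- average_precision(p, y[!tr])
      if (is.na(v)) 0 else v
    }, 0)
    mean(ap)
  }
  tpe_optimize(objective, space = space, n_trials = n_trials, seed = seed)
}

#' Train the edge-score model under nested CV and score every instance
#'
#' For each outer fold, hyperparameters are tuned on the remaining nine
#' folds via the inner 5-fold TPE search, a model is fit on those nine
#' folds, and the held-out fold is scored. Every instance is therefore
#' scored exactly once, by a model whose training data excluded it; the
#' out-of-fold predicted probabilities are the edge scores.
#'
#' @param table feature table from [assemble_feature_table()].
#' @param variant variant name (see [variant_spec()]) or a character vector
#'   of feature columns.
#' @param plan a [make_cv_plan()] for `table`.
#' @param n_trials TPE trials per outer fold.
#' @param seed integer seed.
#' @return an `edge_network` with probability weights, carrying attributes
#'   `folds` (outer fold per row), `fold_models` (per fold: chosen
#'   hyperparameters, training row indices) and `variant`.
#' @export
train_and_score <- function(table, variant = "METANet", plan, n_trials = 25L,
                            seed = 1L) {
  cols <- if (length(variant) == 1L && variant %in%
              c("METANet", "ETANet", "META-LASSO", "META-BART",
                "META-TSEx", "META-TAEx")) {
    variant_spec(variant)
  } else as.character(variant)
  if (!all(cols %in% names(table))) {
    config_error("feature columns missing from table: ",
                 paste(setdiff(cols, names(table)), collapse = ", "))
  }
  x <- as.matrix(table[, cols, with = FALSE])
  if (anyNA(x)) {
    bad <- which(rowSums(is.na(x)) > 0)
    data_error("NaN/NA features in rows: ",
               paste(head(bad, 10L), collapse = ", "))
  }
  y <- as.numeric(table$label)
  stopifnot(length(plan$outer) == nrow(table))
  prob <- rep(NA_real_, nrow(table))
  fold_models <- vector("list", plan$k_outer)
  fold_seeds <- sub_seeds(seed, plan$k_outer)
  for (f in seq_len(plan$k_outer)) {
    tr_idx <- plan$inner[[f]]$idx
    te_idx <- which(plan$outer == f)
    tuned <- tune_hyperparameters(
      x[tr_idx, , drop = FALSE], y[tr_idx], plan$inner[[f]]$fold,
      n_trials = n_trials, seed = fold_seeds[f])
    m <- fit_xgb(x[tr_idx, , drop = FALSE], y[tr_idx], tuned$best,
                 seed = fold_seeds[f])
    prob[te_idx] <- predict(m, xgboost::xgb.DMatrix(x[te_idx, , drop = FALSE]))
    fold_models[[f]] <- list(params = tuned$best,
                             inner_ap = tuned$best_value,
                             train_idx = tr_idx, test_idx = te_idx,
                             seed = fold_seeds[f])
  }
  stopifnot(!anyNA(prob))
  net <- edge_network(
    data.table(tf = table$tf, gene = table$gene, weight = prob),
    tissue = if ("tissue" %in% names(table)) table$tissue[1L] else NA_character_,
    semantics = "probability")
  setattr(net, "folds", plan$outer)
  setattr(net, "fold_models", fold_models)
  setattr(net, "variant", paste(cols, collapse = "+"))
  net
}

#' Train all ablation variants on a shared CV plan
#'
#' Applies [train_and_score()] to each requested variant with the same
#' folds, so downstream comparisons between variants are paired.
#'
#' @inheritParams train_and_score
#' @param variants variant names.
#' @return named list of `edge_network`s.
#' @export
run_all_variants <- function(table, plan, n_trials = 25L, seed = 1L,
                             variants = c("METANet", "ETANet", "META-LASSO",
                                          "META-BART", "META-TSEx",
                                          "META-TAEx")) {
  setNames(lapply(variants, function(v) {
    train_and_score(table, v, plan, n_trials = n_trials, seed = seed)
  }), variants)
}

#' Audit the no-leakage contract of an out-of-fold scored network
#'
#' Checks that the outer folds partition the instance set and that no
#' instance appears in the training rows of the model that scored it.
#'
#' @param net output of [train_and_score()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
audit_no_leakage <- function(net) {
  folds <- attr(net, "folds")
  fm <- attr(net, "fold_models")
  stopifnot(!is.null(folds), !is.null(fm))
  n <- nrow(net)
  covered <- sort(unlist(lapply(fm, `[[`, "test_idx")))
  if (!identical(covered, seq_len(n)))
    stop("outer test folds do not partition the instance set")
  for (f in seq_along(fm)) {
    if (length(intersect(fm[[f]]$train_idx, fm[[f]]$test_idx)) > 0L)
      stop("fold ", f, ": instance present in both training and test rows")
    if (!setequal(union(fm[[f]]$train_idx, fm[[f]]$test_idx), seq_len(n)))
      stop("fold ", f, ": training and test rows do not cover the table")
  }
  invisible(TRUE)
}
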