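# small expression fixture: n TFs driving chosen targets on the log2 scale
make_expr <- function(n_tfs = 4, n_genes = 20, n_samples = 120, noise = 0,
                      drivers = list(), seed = 1, tissues = "T1") {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  tfs <- genes[seq_len(n_tfs)]
  per_t <- n_samples %/% length(tissues)
  samples <- data.table::data.table(
    sample_id = sprintf("%s_s%03d", rep(tissues, each = per_t),
                        seq_len(per_t)),
    tissue = rep(tissues, each = per_t))
  z <- matrix(rnorm(n_tfs * nrow(samples)), n_tfs,
              dimnames = list(tfs, samples$sample_id))
  y <- matrix(5, n_genes, nrow(samples), dimnames = list(genes,
                                                         samples$sample_id))
  y[tfs, ] <- y[tfs, ] + z
  for (d in drivers) {
    y[d$gene, ] <- y[d$gene, ] + d$f(z[d$tf, ])
  }
  if (noise > 0) y <- y + rnorm(length(y), sd = noise)
  tpm <- 2^y - 1  # so that log2(tpm + 1) recovers y exactly
  tpm[tpm < 0] <- 0
  counts <- round(tpm * 30)
  structure(list(counts = counts, tpm = tpm, samples = samples,
                 silent_genes = character()), class = "expression_matrix")
}

test_that("CPM filter removes genes low in at least 98.5% of samples", {
  counts <- matrix(1000L, 5, 200,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:200)))
  # g1: CPM below threshold everywhere -> removed
  counts["g1", ] <- 0L
  # g2: CPM ~ 50 everywhere -> kept (library ~ 5000 counts per sample)
  # g3: low in exactly 197/200 = 98.5% of samples -> removed (boundary >=)
  counts["g3", ] <- 1000L
  counts["g3", 1:197] <- 0L
  # g4: low in 196/200 < 98.5% -> kept
  counts["g4", ] <- 1000L
  counts["g4", 1:196] <- 0L
  kept <- filter_low_expression(counts)
  expect_false("g1" %in% kept)
  expect_true("g2" %in% kept)
  expect_false("g3" %in% kept)
  expect_true("g4" %in% kept)
})

test_that("zero-library samples are a data error for CPM", {
  counts <- matrix(0L, 2, 3, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  expect_error(filter_low_expression(counts), "zero library")
})

test_that("LASSO recovers a planted linear coefficient, checked against OLS", {
  ex <- make_expr(n_tfs = 4, n_genes = 20, n_samples = 200,
                  drivers = list(list(tf = "g01", gene = "g10",
                                      f = function(z) 2 * z)))
  tfs <- sprintf("g%02d", 1:4)
  feats <- lasso_features(ex, tfs, genes = "g10", seed = 7)
  b <- feats[tf == "g01" & gene == "g10", value]
  # independent ordinary-least-squares oracle on the same data
  lt <- log2(ex$tpm + 1)
  ols <- coef(lm(lt["g10", ] ~ t(lt[tfs, ])))[["t(lt[tfs, ])g01"]]
  expect_equal(ols, 2, tolerance = 0.01)  # noiseless up to TPM clipping at 0
  expect_lt(abs(b - ols) / ols, 0.1)
  # no other TF picked up
  expect_equal(nrow(feats[gene == "g10" & tf != "g01"]), 0)
})

test_that("a gene that is a TF is excluded from its own predictors", {
  ex <- make_expr(n_tfs = 4, n_genes = 12, n_samples = 80)
  tfs <- sprintf("g%02d", 1:4)
  feats <- lasso_features(ex, tfs, seed = 3)
  expect_equal(nrow(feats[tf == gene]), 0)
  featsb <- bart_features(ex, tfs, num_trees = 10, seed = 3)
  expect_equal(nrow(featsb[tf == gene]), 0)
})

test_that("a constant-expression TF never receives a LASSO coefficient", {
  ex <- make_expr(n_tfs = 4, n_genes = 15, n_samples = 100,
                  drivers = list(list(tf = "g02", gene = "g08",
                                      f = function(z) 1.5 * z)))
  ex$tpm["g01", ] <- 7  # zero variance predictor
  feats <- lasso_features(ex, sprintf("g%02d", 1:4), seed = 4)
  expect_equal(nrow(feats[tf == "g01"]), 0)
})

test_that("too few samples is refused with diagnostics", {
  ex <- make_expr(n_samples = 10)
  expect_error(lasso_features(ex, c("g01", "g02")), "10 samples")
  expect_error(bart_features(ex, c("g01", "g02")), "10 samples")
})

test_that("tree relatedness ranks a thresholded driver first", {
  ex <- make_expr(n_tfs = 5, n_genes = 20, n_samples = 150,
                  drivers = list(list(tf = "g03", gene = "g12",
                                      f = function(z) 2 * (z > 0.3))))
  feats <- bart_features(ex, sprintf("g%02d", 1:5), genes = "g12", seed = 5)
  top <- feats[gene == "g12"][order(-value)][1]
  expect_equal(top$tf, "g03")
  expect_gt(top$value, 0.5)
})

test_that("relatedness under the null stays near uniform and sums to one", {
  ex <- make_expr(n_tfs = 10, n_genes = 30, n_samples = 150, noise = 1,
                  seed = 9)
  null_genes <- sprintf("g%02d", 25:30)  # pure-noise targets
  feats <- bart_features(ex, sprintf("g%02d", 1:10), genes = null_genes,
                         seed = 10)
  shares <- feats[, .(total = sum(value), top = max(value)), by = gene]
  expect_true(all(abs(shares$total - 1) < 1e-9))
  # no TF runs away with the splits on pure noise (3x the uniform share)
  expect_true(all(shares$top <= 3 / 10))
})

test_that("feature extraction is invariant to gene row order", {
  ex <- make_expr(n_tfs = 3, n_genes = 12, n_samples = 80,
                  drivers = list(list(tf = "g02", gene = "g09",
                                      f = function(z) z)))
  ex2 <- ex
  perm <- rev(rownames(ex$tpm))
  ex2$tpm <- ex2$tpm[perm, ]
  ex2$counts <- ex2$counts[perm, ]
  tfs <- sprintf("g%02d", 1:3)
  f1 <- lasso_features(ex, tfs, seed = 11)
  f2 <- lasso_features(ex2, tfs, seed = 11)
  data.table::setkey(f1, tf, gene); data.table::setkey(f2, tf, gene)
  expect_equal(f1, f2)
})

test_that("the assembled table has one row per non-self instance and exact columns", {
  ex <- make_expr(n_tfs = 3, n_genes = 10, n_samples = 60)
  tfs <- sprintf("g%02d", 1:3)
  genes <- rownames(ex$tpm)
  labels <- data.table::CJ(tf = tfs, gene = genes)[tf != gene][, label := 0L]
  labels[tf == "g01" & gene == "g05", label := 1L]
  motif <- edge_network(data.table::data.table(
    tf = "g01", gene = "g05", weight = 0.8), tissue = "T1",
    semantics = "prior")
  fmap <- data.table::data.table(tf = "g02", gene = "g07", value = 1.5)
  empty <- fmap[0]
  tab <- assemble_feature_table(motif, list(lasso = fmap, bart = empty),
                                list(lasso = empty, bart = empty),
                                labels, genes, tissue = "T1")
  expect_equal(nrow(tab), 3 * 10 - 3)
  expect_identical(names(tab), c("tf", "gene", "tissue", "motif_prior",
                                 "lasso_ts", "bart_ts", "lasso_ta",
                                 "bart_ta", "label"))
  expect_equal(tab[tf == "g01" & gene == "g05", motif_prior], 0.8)
  expect_equal(tab[tf == "g02" & gene == "g07", lasso_ts], 1.5)
  expect_equal(sum(tab$motif_prior != 0), 1)  # absent pairs default to 0
  # deterministic: identical inputs give identical tables
  tab2 <- assemble_feature_table(motif, list(lasso = fmap, bart = empty),
                                 list(lasso = empty, bart = empty),
                                 labels, genes, tissue = "T1")
  expect_identical(tab, tab2)
})

test_that("an instance without a label is a data error", {
  ex <- make_expr(n_tfs = 2, n_genes = 6, n_samples = 60)
  genes <- rownames(ex$tpm)
  labels <- data.table::CJ(tf = "g01", gene = genes[1:4])[tf != gene]
  labels[, label := 0L]  # labels missing for g01 x {g05, g06}
  empty <- data.table::data.table(tf = character(), gene = character(),
                                  value = numeric())
  motif <- edge_network(data.table::data.table(
    tf = "g01", gene = "g03", weight = 1))
  expect_error(
    assemble_feature_table(motif, list(lasso = empty, bart = empty),
                           list(lasso = empty, bart = empty),
                           labels, genes),
    "no label")
})

test_that("planted linear edges outrank non-edges by |lasso|, nonlinear by relatedness", {
  drivers <- list(
    list(tf = "g01", gene = "g11", f = function(z) 1.2 * z),
    list(tf = "g02", gene = "g12", f = function(z) 1.8 * (z > 0.2)))
  ex <- make_expr(n_tfs = 6, n_genes = 20, n_samples = 150, noise = 0.3,
                  drivers = drivers, seed = 21)
  tfs <- sprintf("g%02d", 1:6)
  la <- lasso_features(ex, tfs, genes = c("g11", "g12"), seed = 22)
  ba <- bart_features(ex, tfs, genes = c("g11", "g12"), seed = 23)
  # linear edge: top |lasso| coefficient identifies the driver
  expect_equal(la[gene == "g11"][order(-abs(value))][1, tf], "g01")
  # nonlinear edge: relatedness identifies the driver
  expect_equal(ba[gene == "g12"][order(-value)][1, tf], "g02")
})

test_that("tissue-aggregate features attenuate for single-tissue edges", {
  # edge active only in tissue A: simulate two tissues, signal in A only
  set.seed(31)
  cfg <- synth_config(n_tfs = 3, n_genes = 30, n_tissues = 2,
                      samples_per_tissue = 80, noise_sd = 0.2,
                      silent_gene_frac = 0, seed = 31)
  tr <- data.table::data.table(tf = "G0001", gene = "G0020", tissues = "T1",
                               kind = "linear", form = "linear", effect = 1.5)
  ex <- simulate_expression(tr, cfg)
  tfs <- sprintf("G%04d", 1:3)
  ts <- lasso_features(ex, tfs, genes = "G0020", tissue = "T1",
                       penalty = "lambda.min", seed = 32)
  ta <- lasso_features(ex, tfs, genes = "G0020", penalty = "lambda.min",
                       seed = 33)
  b_ts <- ts[tf == "G0001" & gene == "G0020", value]
  b_ta <- ta[tf == "G0001" & gene == "G0020", value]
  expect_gt(b_ts, 1)          # near the planted effect in the active tissue
  expect_lt(b_ta, b_ts - 0.3) # pooled estimate attenuated
})
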