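#' Draw a planted ground-truth regulatory network
#'
#' Samples `round(edge_density * n_tfs * n_genes)` directed TF->gene edges
#' uniformly over all non-self pairs (TFs are the first `n_tfs` genes, so a
#' TF may regulate another TF but never itself). A `tissue_specific_fraction`
#' of edges is assigned to exactly one tissue, the rest to all tissues;
#' `nonlinear_fraction` of edges act through a hill-type saturation or a
#' hard threshold instead of linearly. A `coreg_fraction` of TFs is arranged
#' in pairs whose target sets overlap by roughly 70%, giving the
#' protein-interaction evidence layer something real to report.
#'
#' @param config a [synth_config()].
#' @return `data.table` with columns `tf`, `gene`, `tissues` (comma-joined
#'   tissue ids), `kind` (`linear`/`nonlinear`), `form` (`linear`, `hill` or
#'   `threshold`) and signed `effect`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  genes <- gene_ids(config)
  tfs <- tf_ids(config)
  tiss <- tissue_ids(config)
  with_seed(layer_seed(config, "truth"), {
    grid_tf <- rep(seq_len(config$n_tfs), times = config$n_genes)
    grid_gene <- rep(seq_len(config$n_genes), each = config$n_tfs)
    allowed <- which(grid_tf != grid_gene)
    n_edges <- round(config$edge_density * config$n_tfs * config$n_genes)
    n_edges <- min(n_edges, length(allowed))
    pick <- sample(allowed, n_edges)
    edges <- data.table(tf = tfs[grid_tf[pick]], gene = genes[grid_gene[pick]])

    # co-regulating TF pairs: the second member of each pair inherits ~70%
    # of the first member's targets
    n_pairs <- floor(config$coreg_fraction * config$n_tfs / 2)
    if (n_pairs >= 1L) {
      for (p in seq_len(n_pairs)) {
        a <- tfs[2L * p - 1L]
        b <- tfs[2L * p]
        ta <- edges[tf == a, gene]
        tb <- edges[tf == b, gene]
        if (length(ta) < 2L || length(tb) < 2L) next
        n_share <- ceiling(0.7 * length(tb))
        shared <- sample(setdiff(ta, b), min(n_share, length(setdiff(ta, b))))
        keep_own <- sample(setdiff(tb, shared),
                           max(0L, length(tb) - length(shared)))
        edges <- edges[tf != b]
        edges <- rbind(edges,
                       data.table(tf = b, gene = unique(c(shared, keep_own))))
      }
      edges <- unique(edges)
    }

    n <- nrow(edges)
    single <- runif(n) < config$tissue_specific_fraction
    tset <- ifelse(single, sample(tiss, n, replace = TRUE),
                   paste(tiss, collapse = ","))
    nonlin <- runif(n) < config$nonlinear_fraction
    form <- ifelse(nonlin, sample(c("hill", "threshold"), n, replace = TRUE),
                   "linear")
    effect <- ifelse(runif(n) < 0.75, 1, -1) * runif(n, 0.75, 1.5)
    edges[, `:=`(tissues = tset,
                 kind = ifelse(nonlin, "nonlinear", "linear"),
                 form = form, effect = effect)]
    setorder(edges, tf, gene)
    edges[]
  })
}

# response of a target to a regulator's centred log-activity z
edge_response <- function(z, effect, form) {
  switch(form,
    linear = effect * z,
    hill = effect * 2 * (1 / (1 + exp(-1.5 * z)) - 0.5),
    threshold = effect * 1.5 * ((z > 0.3) - 0.3821),
    stop("unknown effect form: ", form)
  )
}

#' Simulate tissue-specific expression from a planted network
#'
#' TF log2 activities are drawn i.i.d. standard normal around a log-normal
#' baseline; each target's log2 expression is its baseline plus the sum of
#' the responses of its active incoming edges (linear, saturating or
#' thresholded in the regulator's activity) plus Gaussian noise. An edge
#' contributes only in samples of tissues where it is active. TPM is the
#' exponentiated log2 expression (abundance units; no per-sample
#' renormalization, see the methods vignette); counts are Poisson draws of
#' the TPM composition scaled to a random per-sample library size. A
#' `silent_gene_frac` fraction of untargeted genes is made near-silent so
#' the CPM filter has work to do.
#'
#' @param truth output of [simulate_truth()].
#' @param config a [synth_config()].
#' @return an `expression_matrix`: list with `counts` and `tpm` (gene x
#'   sample matrices), `samples` (`data.table` mapping `sample_id` to
#'   `tissue`) and `silent_genes` (character vector).
#' @export
simulate_expression <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  genes <- gene_ids(config)
  tfs <- tf_ids(config)
  tiss <- tissue_ids(config)
  if (!all(truth$tf %in% tfs) || !all(truth$gene %in% genes))
    config_error("truth is not consistent with config")
  n_s <- config$n_tissues * config$samples_per_tissue
  samples <- data.table(
    sample_id = sprintf("%s_S%03d", rep(tiss, each = config$samples_per_tissue),
                        rep(seq_len(config$samples_per_tissue),
                            config$n_tissues)),
    tissue = rep(tiss, each = config$samples_per_tissue)
  )
  with_seed(layer_seed(config, "expression"), {
    mu <- rnorm(config$n_genes, mean = 6, sd = 1.5)
    names(mu) <- genes
    untargeted <- setdiff(setdiff(genes, tfs), unique(truth$gene))
    n_silent <- min(length(untargeted),
                    floor(config$silent_gene_frac *
                          (config$n_genes - config$n_tfs)))
    silent <- if (n_silent > 0L) sample(untargeted, n_silent) else character()
    mu[silent] <- -8

    z <- matrix(rnorm(config$n_tfs * n_s), nrow = config$n_tfs,
                dimnames = list(tfs, samples$sample_id))
    y <- matrix(rep(mu, n_s), nrow = config$n_genes,
                dimnames = list(genes, samples$sample_id))
    y[tfs, ] <- y[tfs, ] + z

    tissue_of <- samples$tissue
    for (i in seq_len(nrow(truth))) {
      e <- truth[i]
      active <- tissue_of %in% strsplit(e$tissues, ",")[[1]]
      if (!any(active)) next
      y[e$gene, active] <- y[e$gene, active] +
        edge_response(z[e$tf, active], e$effect, e$form)
    }
    if (config$noise_sd > 0) {
      y <- y + matrix(rnorm(length(y), sd = config$noise_sd), nrow = nrow(y))
    }
    tpm <- 2^y
    lib <- runif(n_s, 2e6, 4e6)
    prob <- sweep(tpm, 2L, colSums(tpm), "/")
    counts <- matrix(rpois(length(tpm), t(t(prob) * lib)), nrow = nrow(tpm),
                     dimnames = dimnames(tpm))
    structure(list(counts = counts, tpm = tpm, samples = samples,
                   silent_genes = silent),
              class = "expression_matrix")
  })
}

#' Simulate regulatory elements and ChIP-seq peaks
#'
#' Lays genes out on a synthetic linear genome (10 kb territory per gene),
#' gives each gene one promoter and 0-3 enhancers, and emits per-TF peaks:
#' each true edge yields, with probability `1 - peak_fn_rate`, a peak
#' overlapping one of the target's elements by at least 50 bp with a
#' confidence score and q-value <= 0.01 (a `q_fail_frac` fraction gets a
#' failing q-value to exercise the q filter); false-positive peaks land on
#' elements of non-target genes at rate `peak_fp_rate` per gene.
#'
#' @inheritParams simulate_expression
#' @return list with `elements` (`data.table`: `element_id`, `gene`, `kind`,
#'   `chrom`, `start`, `end`; 0-based half-open) and `peaks` (`data.table`:
#'   `tf`, `chrom`, `start`, `end`, `confidence`, `q_value`).
#' @export
simulate_binding_evidence <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  genes <- gene_ids(config)
  with_seed(layer_seed(config, "binding"), {
    territory <- 10000L
    offs <- (seq_len(config$n_genes) - 1L) * territory
    el <- list(data.table(
      element_id = paste0(genes, "_prom"), gene = genes, kind = "promoter",
      chrom = "chr1", start = offs, end = offs + 1000L))
    n_enh <- sample(0:3, config$n_genes, replace = TRUE)
    for (j in 1:3) {
      has <- which(n_enh >= j)
      if (length(has) == 0L) next
      len <- round(runif(length(has), 500, 1500))
      st <- offs[has] + 2000L * j
      el[[j + 1L]] <- data.table(
        element_id = sprintf("%s_enh%d", genes[has], j), gene = genes[has],
        kind = "enhancer", chrom = "chr1", start = st, end = st + len)
    }
    elements <- rbindlist(el)
    setorder(elements, start)

    emit_peak <- function(tf, el_row, conf, q) {
      plen <- round(runif(1, 200, 400))
      lo <- max(0, el_row$start - plen + 50L)
      hi <- el_row$end - 50L
      st <- round(runif(1, lo, hi))
      data.table(tf = tf, chrom = el_row$chrom, start = st, end = st + plen,
                 confidence = conf, q_value = q)
    }

    pk <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      if (runif(1) < config$peak_fn_rate) next
      e <- truth[i]
      els <- elements[gene == e$gene]
      el_row <- els[sample(.N, 1L)]
      q <- if (runif(1) < config$q_fail_frac) runif(1, 0.02, 0.5)
           else runif(1, 0, 0.01)
      pk[[i]] <- emit_peak(e$tf, el_row, runif(1, 1, 10), q)
    }
    fp <- list()
    if (config$peak_fp_rate > 0) {
      for (tf_i in tf_ids(config)) {
        n_fp <- rbinom(1, config$n_genes, config$peak_fp_rate)
        if (n_fp == 0L) next
        cand <- elements[!gene %in% c(truth[tf == tf_i, gene], tf_i)]
        rows <- cand[sample(.N, min(n_fp, .N))]
        fp[[tf_i]] <- rbindlist(lapply(seq_len(nrow(rows)), function(r) {
          emit_peak(tf_i, rows[r], runif(1, 0.5, 5), runif(1, 0, 0.01))
        }))
      }
    }
    peaks <- rbindlist(c(pk[!vapply(pk, is.null, TRUE)], fp))
    if (nrow(peaks) == 0L) {
      peaks <- data.table(tf = character(), chrom = character(),
                          start = integer(), end = integer(),
                          confidence = numeric(), q_value = numeric())
    }
    setorder(peaks, tf, start)
    list(elements = elements, peaks = peaks[])
  })
}

#' Simulate motif priors, GO annotations, PPI pairs and eQTLs
#'
#' Evidence layers consistent with the planted truth: per-tissue motif
#' networks score active edges 1 plus Gaussian noise (truncated at 0, zero
#' scores dropped) with a `motif_spurious_frac` of non-edges given small
#' spurious scores; GO terms are built around each TF's target set, plus
#' background terms and deliberately under- and over-sized terms to
#' exercise the 5-300 size filter; PPI pairs are emitted for TF pairs
#' sharing more than half of their targets (overlap coefficient > 0.5);
#' eQTLs are placed, per tissue, inside intersections of a target's
#' elements with its regulator's retained peaks, plus positional decoys.
#'
#' @inheritParams simulate_expression
#' @param elements,peaks output of [simulate_binding_evidence()].
#' @return list with `motif_networks` (per-tissue list of edge tables),
#'   `go_map` (named list term -> gene vector), `ppi` (`data.table`: `tf1`,
#'   `tf2`, `score`) and `eqtls` (`data.table`: `tissue`, `chrom`, `pos`,
#'   `gene`).
#' @export
simulate_priors_and_validation <- function(truth, elements, peaks, config) {
  stopifnot(inherits(config, "synth_config"))
  genes <- gene_ids(config)
  tfs <- tf_ids(config)
  tiss <- tissue_ids(config)
  with_seed(layer_seed(config, "priors"), {
    motif_networks <- setNames(lapply(tiss, function(t) {
      active <- vapply(strsplit(truth$tissues, ","), function(x) t %in% x,
                       TRUE)
      w <- pmax(as.numeric(active) +
                  rnorm(nrow(truth), sd = config$motif_noise_sd), 0)
      net <- data.table(tf = truth$tf, gene = truth$gene, weight = w)
      n_non <- config$n_tfs * config$n_genes - config$n_tfs - nrow(truth)
      n_spur <- round(config$motif_spurious_frac * n_non)
      if (n_spur > 0L) {
        spur <- data.table(tf = sample(tfs, n_spur, replace = TRUE),
                           gene = sample(genes, n_spur, replace = TRUE))
        spur <- spur[tf != gene]
        spur <- spur[!net, on = c("tf", "gene")]
        spur <- unique(spur)
        spur[, weight := abs(rnorm(.N, sd = config$motif_noise_sd))]
        net <- rbind(net, spur)
      }
      net <- net[weight > 0]
      setorder(net, tf, gene)
      edge_network(net, tissue = t, semantics = "prior")
    }), tiss)

    go_map <- list()
    for (tf_i in tfs) {
      targ <- truth[tf == tf_i, gene]
      if (length(targ) < 5L) next
      core <- sample(targ, ceiling(0.8 * length(targ)))
      pad <- sample(setdiff(genes, core), round(0.1 * length(targ)))
      go_map[[paste0("GO:SET_", tf_i)]] <- sort(unique(c(core, pad)))
    }
    bg_max <- min(100L, max(10L, config$n_genes %/% 4L))
    for (b in seq_len(20)) {
      go_map[[sprintf("GO:BG_%02d", b)]] <-
        sort(sample(genes, sample(10:bg_max, 1)))
    }
    for (b in 1:3) {  # below the minimum term size
      go_map[[sprintf("GO:TINY_%d", b)]] <- sort(sample(genes, 3))
    }
    if (config$n_genes >= 310L) {  # above the maximum term size
      go_map[["GO:HUGE_1"]] <- sort(sample(genes, 310))
    }

    tsets <- lapply(setNames(tfs, tfs), function(t) truth[tf == t, gene])
    ppi <- list()
    for (i in seq_len(config$n_tfs - 1L)) {
      for (j in (i + 1L):config$n_tfs) {
        a <- tsets[[i]]; b <- tsets[[j]]
        if (length(a) == 0L || length(b) == 0L) next
        ov <- length(intersect(a, b)) / min(length(a), length(b))
        if (ov > 0.5) {
          ppi[[length(ppi) + 1L]] <- data.table(
            tf1 = tfs[i], tf2 = tfs[j], score = runif(1, 0.7, 0.999))
        }
      }
    }
    ppi <- if (length(ppi)) rbindlist(ppi) else
      data.table(tf1 = character(), tf2 = character(), score = numeric())
    n_decoy <- min(5L, config$n_tfs %/% 2L)
    if (n_decoy > 0L && config$n_tfs >= 4L) {
      dec <- data.table(tf1 = sample(tfs, n_decoy, replace = TRUE),
                        tf2 = sample(tfs, n_decoy, replace = TRUE))
      dec <- dec[tf1 < tf2]
      dec <- dec[!ppi, on = c("tf1", "tf2")]
      if (nrow(dec)) {
        dec[, score := runif(.N, 0.3, 0.699)]
        ppi <- rbind(ppi, dec)
      }
    }
  })

  retained <- peaks[q_value <= 0.01]
  eqtls <- with_seed(layer_seed(config, "eqtl"), {
    out <- list()
    for (t in tiss) {
      act <- truth[vapply(strsplit(tissues, ","), function(x) t %in% x, TRUE)]
      for (i in seq_len(nrow(act))) {
        if (runif(1) >= config$eqtl_rate) next
        e <- act[i]
        els <- elements[gene == e$gene]
        pks <- retained[tf == e$tf]
        if (nrow(els) == 0L || nrow(pks) == 0L) next
        ov <- overlap_pairs(pks, els)
        if (nrow(ov) == 0L) next
        k <- sample(1:3, 1)
        for (q in seq_len(k)) {
          r <- ov[sample(.N, 1L)]
          lo <- max(pks$start[r$query], els$start[r$subject])
          hi <- min(pks$end[r$query], els$end[r$subject])
          out[[length(out) + 1L]] <- data.table(
            tissue = t, chrom = els$chrom[r$subject],
            pos = sample(lo:(hi - 1L), 1L), gene = e$gene)
        }
      }
      # positional decoys: inside an element, usually outside any peak
      n_here <- sum(vapply(out, function(x) x$tissue[1] == t, TRUE))
      n_decoy <- round(0.5 * max(n_here, 1L))
      rows <- elements[sample(.N, min(n_decoy, .N))]
      for (r in seq_len(nrow(rows))) {
        out[[length(out) + 1L]] <- data.table(
          tissue = t, chrom = rows$chrom[r],
          pos = sample(rows$start[r]:(rows$end[r] - 1L), 1L),
          gene = rows$gene[r])
      }
    }
    if (length(out)) rbindlist(out) else
      data.table(tissue = character(), chrom = character(), pos = integer(),
                 gene = character())
  })
  setorder(eqtls, tissue, chrom, pos)
  list(motif_networks = motif_networks, go_map = go_map, ppi = ppi,
       eqtls = eqtls)
}

#' Generate a complete synthetic regulatory world
#'
#' Runs all four generator layers under independent RNG streams split from
#' the master seed and bundles their outputs. Regenerating with an
#' identical config reproduces an identical world.
#'
#' @param config a [synth_config()].
#' @return a `synthetic_world` list: `config`, `truth`, `expression`,
#'   `elements`, `peaks`, `motif_networks`, `go_map`, `ppi`, `eqtls`,
#'   `seed`.
#' @export
simulate_world <- function(config) {
  truth <- simulate_truth(config)
  expression <- simulate_expression(truth, config)
  be <- simulate_binding_evidence(truth, config)
  pv <- simulate_priors_and_validation(truth, be$elements, be$peaks, config)
  structure(list(config = config, truth = truth, expression = expression,
                 elements = be$elements, peaks = be$peaks,
                 motif_networks = pv$motif_networks, go_map = pv$go_map,
                 ppi = pv$ppi, eqtls = pv$eqtls, seed = config$seed),
            class = "synthetic_world")
}

#' Planted edge set active in a given tissue
#'
#' @param truth output of [simulate_truth()].
#' @param tissue tissue id, or `NULL` for all edges regardless of tissue.
#' @return `data.table` with columns `tf`, `gene`.
#' @export
true_edges <- function(truth, tissue = NULL) {
  if (is.null(tissue)) return(truth[, .(tf, gene)])
  truth[vapply(strsplit(tissues, ","), function(x) tissue %in% x, TRUE),
        .(tf, gene)]
}
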