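#' Retain high-confidence peaks by FDR q-value
#'
#' @param peaks `data.table` with at least `q_value`; typically the `peaks`
#'   component of a synthetic world or [read_bed_peaks()] output.
#' @param q_max maximum q-value retained (inclusive).
#' @return the retained peaks, original order preserved.
#' @export
filter_peaks <- function(peaks, q_max = 0.01) {
  if (!(q_max > 0 && q_max <= 1)) config_error("q_max must be in (0, 1]")
  peaks[q_value <= q_max]
}

#' Continuous gene binding scores for one TF
#'
#' Maps a TF's (already q-filtered) peaks onto gene-annotated regulatory
#' elements. Peaks are first de-duplicated: transitively overlapping peaks
#' form a cluster and only the cluster's highest-confidence peak (ties:
#' leftmost start, then input order) is retained. Each element is then
#' scored as the sum over retained peaks of `confidence * overlap_bp`, and
#' a gene's score is the sum over its elements. Genes with no overlapping
#' retained peak score 0. Clustering is done per chromosome over the whole
#' peak set (not within each element) so that scores are additive over
#' element subdivisions.
#'
#' @param peaks `data.table`: `chrom`, `start`, `end`, `confidence` (one TF).
#' @param elements `data.table`: `element_id`, `gene`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return `data.table` with `gene` and `score`, one row per gene present
#'   in `elements` (zero scores included).
#' @export
score_gene_binding <- function(peaks, elements) {
  if (any(elements$start >= elements$end))
    data_error("element with start >= end")
  genes <- sort(unique(elements$gene))
  out <- data.table(gene = genes, score = 0)
  if (nrow(peaks) == 0L) return(out)
  if (any(peaks$start >= peaks$end)) data_error("peak with start >= end")

  peaks <- copy(as.data.table(peaks))
  # transitive overlap clusters per chromosome; winner = max confidence,
  # ties by leftmost start then input order
  pk_gr <- as_granges0(peaks)
  cl <- GenomicRanges::findOverlaps(
    pk_gr, GenomicRanges::reduce(pk_gr, min.gapwidth = 0L))
  peaks[, cluster := paste0(peaks$chrom, "_", S4Vectors::subjectHits(cl))]
  peaks[, keep := FALSE]
  peaks[peaks[, .I[order(-confidence, start)][1L], by = cluster]$V1,
        keep := TRUE]
  winners <- peaks[keep == TRUE]

  ov <- overlap_pairs(winners, as.data.table(elements))
  if (nrow(ov) == 0L) return(out)
  ov[, `:=`(gene = elements$gene[subject],
            contrib = winners$confidence[query] * overlap)]
  gs <- ov[, .(score = sum(contrib)), by = gene]
  out[gs, score := i.score, on = "gene"]
  out[]
}

#' Binarize gene binding scores into labels
#'
#' Genes with positive score are candidate positives; if they exceed
#' `ceil(top_fraction * n_genes)` (10% of all candidate genes by default),
#' only the top-scoring ones up to that cap are labeled 1, ties broken by
#' gene id ascending. Everything else is labeled 0.
#'
#' @param scores `data.table` with `gene` and `score` covering one TF
#'   across all candidate genes (output of [score_gene_binding()]).
#' @param top_fraction cap on the positive fraction.
#' @return `data.table` with `gene` and `label` (0/1).
#' @export
binarize_labels <- function(scores, top_fraction = 0.10) {
  n_genes <- nrow(scores)
  cap <- ceiling(top_fraction * n_genes)
  dt <- as.data.table(scores)[, .(gene, score)]
  setorder(dt, -score, gene)
  pos <- dt[score > 0]
  if (nrow(pos) > cap) pos <- pos[seq_len(cap)]
  out <- data.table(gene = sort(dt$gene), label = 0L)
  out[gene %in% pos$gene, label := 1L]
  out[]
}

#' Binding labels for every TF in a peak set
#'
#' Convenience wrapper running [filter_peaks()], [score_gene_binding()] and
#' [binarize_labels()] per TF.
#'
#' @param peaks `data.table` with `tf` plus peak columns.
#' @param elements element table as in [score_gene_binding()].
#' @param q_max q-value cutoff.
#' @param top_fraction positive-label cap.
#' @return list with `scores` and `labels`, each a `data.table` keyed by
#'   (`tf`, `gene`).
#' @export
binding_label_matrix <- function(peaks, elements, q_max = 0.01,
                                 top_fraction = 0.10) {
  retained <- filter_peaks(peaks, q_max)
  tfs <- sort(unique(peaks$tf))
  scores <- rbindlist(lapply(tfs, function(t) {
    s <- score_gene_binding(retained[tf == t], elements)
    s[, tf := t]
    s
  }))
  labels <- rbindlist(lapply(tfs, function(t) {
    l <- binarize_labels(scores[tf == t, .(gene, score)], top_fraction)
    l[, tf := t]
    l
  }))
  setcolorder(scores, c("tf", "gene", "score"))
  setcolorder(labels, c("tf", "gene", "label"))
  list(scores = scores[], labels = labels[])
}
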