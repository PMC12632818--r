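# Readers and writers for the plain-text exchange formats: BED6+ for
# elements and peaks, TSV for expression/networks/PPI/eQTLs, GMT for GO
# maps. Coordinates on disk are BED (0-based half-open), matching the
# internal convention, so no shifting happens here.

#' Write a synthetic world to a directory of plain-text files
#'
#' Emits `elements.bed` and `peaks.bed` (BED6+), `expression_counts.tsv`,
#' `expression_tpm.tsv`, `sample_map.tsv`, one `motif_<tissue>.tsv` per
#' tissue, `go_map.gmt`, `go_map.tsv`, `ppi.tsv`, `eqtls.tsv`, `truth.tsv`
#' and a `world.json` manifest recording the generating config and seed.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  el <- world$elements[, .(chrom, start, end, name = element_id, score = 0L,
                           strand = ".", gene, kind)]
  fwrite(el, file.path(dir, "elements.bed"), sep = "\t")
  pk <- world$peaks[, .(chrom, start, end,
                        name = sprintf("peak_%05d", .I), score = confidence,
                        strand = ".", tf, q_value)]
  fwrite(pk, file.path(dir, "peaks.bed"), sep = "\t")
  fwrite(data.table(gene = rownames(world$expression$counts),
                    world$expression$counts),
         file.path(dir, "expression_counts.tsv"), sep = "\t")
  fwrite(data.table(gene = rownames(world$expression$tpm),
                    world$expression$tpm),
         file.path(dir, "expression_tpm.tsv"), sep = "\t")
  fwrite(world$expression$samples, file.path(dir, "sample_map.tsv"),
         sep = "\t")
  for (t in names(world$motif_networks)) {
    write_edge_network(world$motif_networks[[t]],
                       file.path(dir, sprintf("motif_%s.tsv", t)))
  }
  write_gmt(world$go_map, file.path(dir, "go_map.gmt"))
  fwrite(rbindlist(lapply(names(world$go_map), function(tm) {
    data.table(term = tm, gene = world$go_map[[tm]])
  })), file.path(dir, "go_map.tsv"), sep = "\t")
  fwrite(world$ppi, file.path(dir, "ppi.tsv"), sep = "\t")
  fwrite(world$eqtls, file.path(dir, "eqtls.tsv"), sep = "\t")
  fwrite(world$truth, file.path(dir, "truth.tsv"), sep = "\t")
  jsonlite::write_json(
    list(config = unclass(world$config), seed = world$seed),
    file.path(dir, "world.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read gene-annotated regulatory elements from BED6+
#'
#' Expects columns chrom, start, end, name, score, strand, gene, kind.
#'
#' @param path BED file.
#' @return `data.table` with `element_id`, `gene`, `kind`, `chrom`,
#'   `start`, `end`.
#' @export
read_bed_elements <- function(path) {
  dt <- fread(path, sep = "\t")
  setnames(dt, seq_len(8L),
           c("chrom", "start", "end", "element_id", "score", "strand",
             "gene", "kind"))
  if (any(dt$start >= dt$end)) data_error("element with start >= end in ", path)
  if (any(!nzchar(dt$gene))) data_error("element with empty gene id in ", path)
  dt[, .(element_id, gene, kind, chrom, start, end)]
}

#' Read scored ChIP-seq peaks from BED6+
#'
#' Expects columns chrom, start, end, name, score (confidence), strand,
#' tf, q_value.
#'
#' @param path BED file.
#' @return `data.table` with `tf`, `chrom`, `start`, `end`, `confidence`,
#'   `q_value`.
#' @export
read_bed_peaks <- function(path) {
  dt <- fread(path, sep = "\t")
  setnames(dt, seq_len(8L),
           c("chrom", "start", "end", "name", "confidence", "strand", "tf",
             "q_value"))
  if (any(dt$start >= dt$end)) data_error("peak with start >= end in ", path)
  dt[, .(tf, chrom, start, end, confidence, q_value)]
}

#' Read an expression matrix plus its sample-to-tissue map
#'
#' @param counts_path,tpm_path gene x sample TSVs with a leading `gene`
#'   column.
#' @param sample_map_path two-column TSV (`sample_id`, `tissue`).
#' @return an `expression_matrix`.
#' @export
read_expression <- function(counts_path, tpm_path, sample_map_path) {
  read_mat <- function(p) {
    dt <- fread(p, sep = "\t")
    m <- as.matrix(dt[, -1L])
    rownames(m) <- dt[[1L]]
    m
  }
  counts <- read_mat(counts_path)
  tpm <- read_mat(tpm_path)
  samples <- fread(sample_map_path, sep = "\t")
  setnames(samples, seq_len(2L), c("sample_id", "tissue"))
  missing <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing)) {
    data_error("samples missing from tissue map: ",
               paste(head(missing, 5L), collapse = ", "))
  }
  structure(list(counts = counts, tpm = tpm, samples = samples,
                 silent_genes = character()),
            class = "expression_matrix")
}

#' Write an edge network as 3-column TSV
#' @param net an `edge_network`.
#' @param path output path.
#' @export
write_edge_network <- function(net, path) {
  fwrite(as.data.table(net)[, .(tf, gene, weight)], path, sep = "\t")
  invisible(path)
}

#' Read an edge network from 3-column TSV
#' @param path input TSV (tf, gene, weight).
#' @param tissue tissue label to attach.
#' @param semantics weight semantics tag.
#' @return an `edge_network`.
#' @export
read_edge_network <- function(path, tissue = NA_character_,
                              semantics = "generic") {
  dt <- fread(path, sep = "\t")
  setnames(dt, seq_len(3L), c("tf", "gene", "weight"))
  edge_network(dt, tissue = tissue, semantics = semantics)
}

#' Write a term -> genes map as GMT
#' @param go_map named list of gene vectors.
#' @param path output path.
#' @export
write_gmt <- function(go_map, path) {
  lines <- vapply(names(go_map), function(tm) {
    paste(c(tm, tm, go_map[[tm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT file into a term -> genes map
#' @param path GMT file.
#' @return named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L]
  }, "")
  out
}

#' Read TF-pair physical interactions
#'
#' When a score column is present, only pairs at or above `min_score`
#' (high-confidence interactions) are retained.
#'
#' @param path TSV with `tf1`, `tf2` and optionally `score`.
#' @param min_score confidence cutoff applied when scores are present.
#' @return `data.table` with `tf1`, `tf2` (and `score` when present).
#' @export
read_ppi <- function(path, min_score = 0.7) {
  dt <- fread(path, sep = "\t")
  setnames(dt, 1:2, c("tf1", "tf2"))
  if (ncol(dt) >= 3L) {
    setnames(dt, 3L, "score")
    dt <- dt[score >= min_score]
  }
  dt
}

#' Read per-tissue eQTL records
#' @param path TSV with `tissue`, `chrom`, `pos`, `gene`.
#' @return `data.table`.
#' @export
read_eqtls <- function(path) {
  dt <- fread(path, sep = "\t")
  setnames(dt, seq_len(4L), c("tissue", "chrom", "pos", "gene"))
  if (any(dt$pos < 0)) data_error("negative eQTL position in ", path)
  dt
}
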