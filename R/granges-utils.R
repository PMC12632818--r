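# Interval helpers. All package-internal coordinates are 0-based,
# half-open (BED convention); GRanges is 1-based closed, so conversion
# happens only inside these helpers.

# data.frame with chrom/start/end -> GRanges
as_granges0 <- function(df) {
  if (any(df$start >= df$end)) data_error("interval with start >= end")
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# overlaps between two 0-based interval tables; returns data.table with
# queryHits, subjectHits and overlap width in bp
overlap_pairs <- function(a, b, min_overlap = 1L) {
  gra <- as_granges0(a)
  grb <- as_granges0(b)
  hits <- GenomicRanges::findOverlaps(gra, grb, minoverlap = min_overlap)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (length(qh) == 0L) {
    return(data.table::data.table(query = integer(), subject = integer(),
                                  overlap = integer()))
  }
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gra)[qh], IRanges::ranges(grb)[sh]))
  data.table::data.table(query = qh, subject = sh, overlap = ov)
}

# positions (0-based bp) inside intervals (0-based half-open)
positions_in <- function(pos_df, iv_df) {
  if (nrow(pos_df) == 0L || nrow(iv_df) == 0L) {
    return(data.table::data.table(query = integer(), subject = integer()))
  }
  grp <- GenomicRanges::GRanges(pos_df$chrom,
                                IRanges::IRanges(pos_df$pos + 1L, width = 1L))
  gri <- as_granges0(iv_df)
  hits <- GenomicRanges::findOverlaps(grp, gri)
  data.table::data.table(query = S4Vectors::queryHits(hits),
                         subject = S4Vectors::subjectHits(hits))
}
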