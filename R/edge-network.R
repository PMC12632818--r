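#' Weighted directed TF->gene edge list
#'
#' Light S3 container: a `data.table` with columns `tf`, `gene`, `weight`
#' plus a `tissue` attribute and a `semantics` tag describing what the
#' weights mean (`"probability"` for model edge scores in \[0, 1\],
#' `"prior"` for motif prior scores, `"generic"` otherwise).
#'
#' @param edges data.frame with columns `tf`, `gene`, `weight`.
#' @param tissue tissue label (or `NA`).
#' @param semantics one of `"probability"`, `"prior"`, `"generic"`.
#' @return an `edge_network` object.
#' @export
edge_network <- function(edges, tissue = NA_character_,
                         semantics = c("generic", "probability", "prior")) {
  semantics <- match.arg(semantics)
  dt <- as.data.table(edges)[, .(tf = as.character(tf),
                                 gene = as.character(gene),
                                 weight = as.numeric(weight))]
  if (any(dt$tf == dt$gene)) data_error("edge network contains self-edges")
  if (anyDuplicated(dt[, .(tf, gene)]))
    data_error("edge network contains duplicate (tf, gene) pairs")
  if (semantics == "probability" &&
      (any(dt$weight < 0) || any(dt$weight > 1)))
    data_error("probability-tagged network has weights outside [0, 1]")
  setattr(dt, "tissue", tissue)
  setattr(dt, "semantics", semantics)
  setattr(dt, "class", c("edge_network", class(dt)))
  dt
}

net_semantics <- function(net) attr(net, "semantics") %||% "generic"
net_tissue <- function(net) attr(net, "tissue") %||% NA_character_

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.edge_network <- function(x, ...) {
  cat(sprintf("<edge_network> tissue=%s semantics=%s edges=%d\n",
              net_tissue(x), net_semantics(x), nrow(x)))
  NextMethod()
}
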