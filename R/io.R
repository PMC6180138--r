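# Reading raw response tables and serializing networks, partitions and
# result tables.

#' Read a Likert (or binary) response table from CSV
#'
#' Expects a header `participant_id, time_point, <instrument: item>, ...`
#' with `time_point` in \{PRE, POST\} and item columns following the
#' `"<instrument>: <item>"` label convention.
#'
#' @param path CSV file path.
#' @return Data frame with `check.names = FALSE` column labels.
#' @export
read_response_csv <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "time_point") %in% names(tab)))
    stop("expected columns 'participant_id' and 'time_point' in ", path)
  split_response_table(tab)  # validates
  tab
}

#' Write / read a network as edge list + JSON sidecar
#'
#' `write_network()` writes `<prefix>_edges.tsv` (columns `node_a`,
#' `node_b`, `weight`, `sign`) and `<prefix>_meta.json` (labels,
#' thresholds, scalar metadata). `read_network()` reassembles the
#' [ising_network()].
#'
#' @param net An [ising_network()].
#' @param prefix Path prefix for the two files.
#' @return `write_network()`: the two file paths, invisibly;
#'   `read_network()`: the network.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "ising_network"))
  W <- net$weights
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  edges <- data.frame(
    node_a = net$labels[ut[, 1]], node_b = net$labels[ut[, 2]],
    weight = W[ut],
    sign = ifelse(W[ut] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  f_edges <- paste0(prefix, "_edges.tsv")
  f_meta <- paste0(prefix, "_meta.json")
  utils::write.table(edges, f_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- net$meta
  meta$directed <- NULL
  meta$signed_weights <- NULL
  jsonlite::write_json(
    list(labels = net$labels,
         thresholds = as.numeric(net$thresholds),
         meta = meta),
    f_meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f_edges, f_meta))
}

#' @rdname write_network
#' @export
read_network <- function(prefix) {
  edges <- read.csv(paste0(prefix, "_edges.tsv"), sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  p <- length(side$labels)
  W <- matrix(0, p, p, dimnames = list(side$labels, side$labels))
  for (k in seq_len(nrow(edges)))
    W[edges$node_a[k], edges$node_b[k]] <-
      W[edges$node_b[k], edges$node_a[k]] <- edges$weight[k]
  ising_network(W, side$thresholds, side$labels,
                meta = as.list(side$meta))
}
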