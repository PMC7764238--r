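#' Regional BOLD time-series container
#'
#' Bundles a node-by-volume matrix of regional BOLD signals with its
#' acquisition metadata. All preprocessing and connectome functions accept
#' and return this class, so a pipeline stage can always be applied to the
#' output of the previous one.
#'
#' @param data Numeric matrix, nodes (rows) by volumes (columns).
#' @param tr Repetition time in seconds (time between consecutive volumes).
#' @param node_labels Character vector of unique ROI names, one per row.
#' @param subject_id Subject identifier (scalar character).
#' @param session Session label, one of `"T0"`, `"T1"`, `"T2"`.
#'
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(data, tr, node_labels = rownames(data),
                   subject_id = NA_character_, session = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(node_labels)) {
    node_labels <- sprintf("ROI%03d", seq_len(nrow(data)))
  }
  stopifnot(is.numeric(tr), length(tr) == 1L, tr > 0)
  if (length(node_labels) != nrow(data)) {
    stop("node_labels length (", length(node_labels),
         ") does not match number of rows (", nrow(data), ")")
  }
  if (anyDuplicated(node_labels)) {
    stop("node labels must be unique")
  }
  if (!all(is.finite(data))) {
    stop("time-series data must be finite")
  }
  rownames(data) <- node_labels
  structure(
    list(data = data, tr = as.numeric(tr),
         node_labels = as.character(node_labels),
         subject_id = as.character(subject_id),
         session = as.character(session)),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d nodes x %d volumes, TR = %gs", nrow(x$data),
              ncol(x$data), x$tr))
  if (!is.na(x$subject_id)) cat(sprintf("  [%s/%s]", x$subject_id, x$session))
  cat("\n")
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

n_volumes <- function(series) ncol(series$data)
n_nodes <- function(series) nrow(series$data)

#' Physiological phase recording
#'
#' Cardiac and respiratory phase traces sampled at volume acquisition times,
#' as produced by pulse-oximeter / respiratory-belt phase extraction (or by
#' [add_physio()] for synthetic data). Phases are in radians and unwrapped
#' (monotone increasing for a positive rate).
#'
#' @param cardiac_phase,respiratory_phase Numeric vectors of equal length,
#'   one phase value per volume.
#' @return An object of class `physio_recording`.
#' @export
physio_recording <- function(cardiac_phase, respiratory_phase) {
  if (length(cardiac_phase) != length(respiratory_phase)) {
    stop("cardiac and respiratory phase traces must have equal length")
  }
  if (!all(is.finite(cardiac_phase)) || !all(is.finite(respiratory_phase))) {
    stop("phase traces must be finite")
  }
  structure(list(cardiac_phase = as.numeric(cardiac_phase),
                 respiratory_phase = as.numeric(respiratory_phase)),
            class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("<physio_recording> %d volumes\n", length(x$cardiac_phase)))
  invisible(x)
}

#' Thresholded weighted connectivity graph
#'
#' A symmetric, zero-diagonal matrix of edge weights in `[0, 1]` retained at
#' the connectedness-preserving (percolation) threshold, together with the
#' threshold itself. Weights below the threshold are exactly zero; the graph
#' on the retained edges spans all nodes in a single connected component.
#'
#' @param weights Symmetric numeric matrix with zero diagonal.
#' @param threshold The edge-weight threshold that was applied.
#' @param node_labels Character vector of node names.
#' @param subject_id,session Provenance metadata.
#' @return An object of class `conn_graph`.
#' @export
conn_graph <- function(weights, threshold, node_labels = rownames(weights),
                       subject_id = NA_character_, session = NA_character_) {
  weights <- as.matrix(weights)
  if (is.null(node_labels)) {
    node_labels <- sprintf("ROI%03d", seq_len(nrow(weights)))
  }
  stopifnot(nrow(weights) == ncol(weights))
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 0))) {
    stop("weight matrix must be exactly symmetric")
  }
  if (any(diag(weights) != 0)) stop("weight matrix must have zero diagonal")
  if (any(weights < 0) || any(weights > 1)) {
    stop("weights must lie in [0, 1]")
  }
  dimnames(weights) <- list(node_labels, node_labels)
  structure(list(weights = weights, threshold = as.numeric(threshold),
                 node_labels = as.character(node_labels),
                 subject_id = as.character(subject_id),
                 session = as.character(session)),
            class = "conn_graph")
}

#' @export
print.conn_graph <- function(x, ...) {
  n <- nrow(x$weights)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<conn_graph> %d nodes, %d edges, threshold = %.4f\n",
              n, m, x$threshold))
  invisible(x)
}

#' AAL-116 region labels
#'
#' The 116 cortical, subcortical and cerebellar region names of the
#' Automated Anatomical Labeling atlas, in standard numerical order
#' (odd = left, even = right for the 90 cerebral regions, then cerebellar
#' hemispheres and vermis lobules).
#'
#' @return Character vector of length 116.
#' @export
#' @examples
#' head(aal116_labels())
aal116_labels <- function() {
  path <- system.file("extdata", "aal116_labels.tsv", package = "fconnet",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$label[order(tab$index)]
}
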