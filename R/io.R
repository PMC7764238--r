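#' Write / read an ROI time-series table
#'
#' The on-disk layout is volumes (rows) by nodes (columns) with ROI labels
#' as the header, tab-separated. Metadata (TR, subject, session) travels in
#' a JSON sidecar named `<file>.json`.
#'
#' @param series A [roi_ts] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_roi_tsv <- function(series, path) {
  stopifnot(inherits(series, "roi_ts"))
  tab <- as.data.frame(t(series$data))
  names(tab) <- series$node_labels
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(tr = series$tr, subject_id = series$subject_id,
         session = series$session, n_volumes = ncol(series$data),
         n_nodes = nrow(series$data)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_roi_tsv
#' @param tr Repetition time to use when no sidecar is present.
#' @export
read_roi_tsv <- function(path, tr = 3) {
  tab <- utils::read.delim(path, check.names = FALSE)
  meta <- list(tr = tr, subject_id = NA_character_, session = NA_character_)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE))
  }
  roi_ts(t(as.matrix(tab)), tr = meta$tr, node_labels = names(tab),
         subject_id = meta$subject_id, session = meta$session)
}

#' Write / read a physiological recording
#'
#' One two-column table per modality (`time_s`, `phase_radians`); the two
#' modalities are stored side by side as four columns.
#'
#' @param physio A [physio_recording].
#' @param path Output TSV path.
#' @param tr Repetition time used to reconstruct volume times.
#' @return `path`, invisibly.
#' @export
write_physio_tsv <- function(physio, path, tr = 3) {
  stopifnot(inherits(physio, "physio_recording"))
  v <- length(physio$cardiac_phase)
  tab <- data.frame(time_s = (seq_len(v) - 1) * tr,
                    cardiac_phase = physio$cardiac_phase,
                    respiratory_phase = physio$respiratory_phase)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_physio_tsv
#' @export
read_physio_tsv <- function(path) {
  tab <- utils::read.delim(path)
  physio_recording(tab$cardiac_phase, tab$respiratory_phase)
}

#' Write / read a cohort design table
#' @param cohort Cohort data frame from [make_cohort()].
#' @param path Output TSV path.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read the long metric table
#' @param metrics Long metric table from [metrics_table()].
#' @param path Output TSV path.
#' @return `path` (write) or the table (read).
#' @export
write_metrics_tsv <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_tsv
#' @export
read_metrics_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read toy NIfTI volumes
#'
#' Thin wrappers around the `RNifti` package (suggested dependency) for the
#' 4D data volume and the 3D integer atlas produced by
#' [render_toy_nifti()].
#'
#' @param x 3D or 4D numeric array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path` (write) or an array (read).
#' @export
write_nifti <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI I/O requires the 'RNifti' package")
  }
  RNifti::writeNifti(x, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI I/O requires the 'RNifti' package")
  }
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Write / read a thresholded adjacency matrix
#'
#' Dense, labeled, tab-separated weight matrix with a JSON sidecar holding
#' the threshold, edge count and provenance.
#'
#' @param graph A [conn_graph].
#' @param path Output TSV path.
#' @return `path` (write) or a [conn_graph] (read).
#' @export
write_adjacency_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "conn_graph"))
  tab <- as.data.frame(graph$weights)
  utils::write.table(cbind(node = graph$node_labels, tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(threshold = graph$threshold,
         n_edges = sum(graph$weights[upper.tri(graph$weights)] > 0),
         subject_id = graph$subject_id, session = graph$session),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_adjacency_tsv
#' @export
read_adjacency_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  labels <- tab$node
  w <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(w) <- list(labels, labels)
  w <- (w + t(w)) / 2
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  conn_graph(w, threshold = meta$threshold, node_labels = labels,
             subject_id = meta$subject_id, session = meta$session)
}
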