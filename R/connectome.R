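#' Squared-correlation similarity matrix
#'
#' Computes the node-by-node similarity as the square of the Pearson
#' correlation between regional time series. Squaring discards the sign, so
#' strong positive and strong negative coupling are treated alike; this
#' accommodates sign flips introduced by heterogeneous hemodynamics. The
#' diagonal is set to zero.
#'
#' @param series A [roi_ts] with at least 3 volumes.
#' @return Symmetric numeric matrix in `[0, 1]` with zero diagonal.
#' @export
similarity_matrix <- function(series) {
  stopifnot(inherits(series, "roi_ts"))
  if (n_volumes(series) < 3L) stop("need at least 3 volumes")
  sds <- apply(series$data, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series for node(s): ",
         paste(series$node_labels[sds == 0], collapse = ", "))
  }
  s <- stats::cor(t(series$data))^2
  diag(s) <- 0
  s <- (s + t(s)) / 2
  dimnames(s) <- list(series$node_labels, series$node_labels)
  s
}

# is the graph with edges {w >= tau} connected? (breadth-first search)
is_connected_at <- function(w, tau) {
  n <- nrow(w)
  seen <- logical(n)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    reach <- if (length(frontier) == 1L) w[frontier, ] >= tau else
      colSums(w[frontier, , drop = FALSE] >= tau) > 0L
    nxt <- which(reach & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Threshold a similarity matrix at the percolation point
#'
#' Finds the largest threshold `tau` such that the graph retaining only
#' edges with weight `>= tau` is still globally connected (a single
#' component spanning all nodes), and returns the weighted graph with all
#' weaker edges removed. Edge weights are retained, not binarized. The
#' candidate thresholds are the sorted distinct edge weights; the search is
#' a binary search over that list, so the returned `tau` always equals one
#' of the observed weights, and retaining exactly the edges with `w == tau`
#' is what keeps the graph connected.
#'
#' `tau` equals the bottleneck (minimum) edge weight of the maximum
#' spanning tree of the similarity matrix; the test suite asserts this
#' equivalence against an independent spanning-tree oracle.
#'
#' @param similarity Symmetric matrix with zero diagonal (e.g. from
#'   [similarity_matrix()]).
#' @param node_labels Node names (defaults to the matrix dimnames).
#' @param subject_id,session Provenance metadata.
#' @return A [conn_graph] with the threshold recorded.
#' @export
percolation_threshold <- function(similarity, node_labels = rownames(similarity),
                                  subject_id = NA_character_,
                                  session = NA_character_) {
  similarity <- as.matrix(similarity)
  stopifnot(nrow(similarity) == ncol(similarity))
  if (max(abs(similarity - t(similarity))) > 1e-12) {
    stop("similarity matrix must be symmetric")
  }
  similarity <- (similarity + t(similarity)) / 2
  if (any(diag(similarity) != 0)) stop("similarity diagonal must be zero")
  n <- nrow(similarity)
  if (n < 2L) stop("need at least 2 nodes")
  deg <- rowSums(similarity > 0)
  if (any(deg == 0)) {
    iso <- if (!is.null(node_labels)) node_labels[deg == 0] else
      which(deg == 0)
    stop("cannot connect graph: node(s) with no positive-weight edges: ",
         paste(iso, collapse = ", "))
  }
  cand <- sort(unique(similarity[upper.tri(similarity)]))
  cand <- cand[cand > 0]
  if (!is_connected_at(similarity, cand[1L])) {
    stop("cannot connect graph even with all positive edges retained")
  }
  lo <- 1L                      # known connected
  hi <- length(cand)
  while (lo < hi) {             # largest index still connected
    mid <- (lo + hi + 1L) %/% 2L
    if (is_connected_at(similarity, cand[mid])) lo <- mid else hi <- mid - 1L
  }
  tau <- cand[lo]
  w <- similarity
  w[w < tau] <- 0
  conn_graph(w, threshold = tau, node_labels = node_labels,
             subject_id = subject_id, session = session)
}

#' Node strength (weighted degree)
#'
#' Sum of incident edge weights per node. On a weighted,
#' connectedness-thresholded graph this is the weighted reading of degree
#' centrality; the binary degree at the same threshold is available from
#' [binary_degree()].
#'
#' @param graph A [conn_graph].
#' @return Named numeric vector.
#' @export
node_strength <- function(graph) {
  stopifnot(inherits(graph, "conn_graph"))
  rowSums(graph$weights)
}

#' Binary degree at the retained threshold
#' @param graph A [conn_graph].
#' @return Named integer vector of retained-edge counts per node.
#' @export
binary_degree <- function(graph) {
  stopifnot(inherits(graph, "conn_graph"))
  rowSums(graph$weights > 0)
}

#' Eigenvector centrality
#'
#' Entries of the principal eigenvector of the weight matrix, normalized to
#' unit Euclidean norm. For a connected graph with non-negative weights the
#' principal eigenvector is unique up to sign and entrywise non-negative
#' (Perron-Frobenius); the sign is fixed so all entries are `>= 0`.
#'
#' @param graph A [conn_graph].
#' @return Named numeric vector with unit Euclidean norm.
#' @export
eigenvector_centrality <- function(graph) {
  stopifnot(inherits(graph, "conn_graph"))
  es <- eigen(graph$weights, symmetric = TRUE)
  v <- es$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  if (min(v) < -1e-8) {
    stop("principal eigenvector has negative entries; ",
         "is the graph connected with non-negative weights?")
  }
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  names(v) <- graph$node_labels
  v
}

#' Weighted betweenness centrality
#'
#' Fraction of weighted shortest paths passing through each node, with edge
#' length `1 / weight` (strong similarity = short distance) and
#' normalization by `(N - 1)(N - 2) / 2`, the number of node pairs excluding
#' the node itself. Multiple shortest paths between a pair are counted
#' fractionally.
#'
#' @param graph A [conn_graph].
#' @return Named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(graph) {
  stopifnot(inherits(graph, "conn_graph"))
  g <- igraph::graph_from_adjacency_matrix(graph$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  b <- igraph::betweenness(g, weights = len, normalized = TRUE)
  stats::setNames(as.numeric(b), graph$node_labels)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Geometric-mean triangle intensity around each node:
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3)`
#' over ordered neighbour pairs, where `w' = w / max(w)` normalizes weights
#' to the graph's maximum and `k_i` is the number of retained neighbours.
#' Nodes with fewer than two neighbours get `C_i = 0`.
#'
#' @param graph A [conn_graph].
#' @return Named numeric vector in `[0, 1]`.
#' @export
clustering_coef <- function(graph) {
  stopifnot(inherits(graph, "conn_graph"))
  w <- graph$weights
  mx <- max(w)
  if (mx == 0) return(stats::setNames(rep(0, nrow(w)), graph$node_labels))
  w3 <- (w / mx)^(1 / 3)
  num <- diag(w3 %*% w3 %*% w3)
  k <- rowSums(w > 0)
  c_i <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  stats::setNames(as.numeric(c_i), graph$node_labels)
}

#' All node metrics of one graph
#'
#' @param graph A [conn_graph].
#' @return Data frame with columns `node`, `strength`, `degree`,
#'   `eigenvector`, `betweenness`, `clustering`.
#' @export
node_metrics <- function(graph) {
  data.frame(node = graph$node_labels,
             strength = as.numeric(node_strength(graph)),
             degree = as.numeric(binary_degree(graph)),
             eigenvector = as.numeric(eigenvector_centrality(graph)),
             betweenness = as.numeric(betweenness_centrality(graph)),
             clustering = as.numeric(clustering_coef(graph)),
             stringsAsFactors = FALSE)
}

#' Long-format metric table across subjects and sessions
#'
#' Collects node metrics of many graphs into the long format consumed by
#' the group-statistics stage. Missing subject/session combinations are
#' simply absent (no NA filling).
#'
#' @param graphs List of [conn_graph] objects with `subject_id` and
#'   `session` set; all must share the same node labels.
#' @param cohort Optional cohort table (from [make_cohort()]) used to
#'   attach the `group` column by `subject_id`.
#' @param metrics Character subset of
#'   `c("strength", "degree", "eigenvector", "betweenness", "clustering")`.
#' @return Data frame with columns `subject`, `session`, `group`, `node`,
#'   `metric`, `value`.
#' @export
metrics_table <- function(graphs, cohort = NULL,
                          metrics = c("strength", "degree", "eigenvector",
                                      "betweenness", "clustering")) {
  stopifnot(length(graphs) >= 1L)
  labels <- graphs[[1L]]$node_labels
  pieces <- lapply(graphs, function(g) {
    stopifnot(inherits(g, "conn_graph"))
    if (!identical(g$node_labels, labels)) {
      stop("inconsistent node label sets across graphs (subject ",
           g$subject_id, ", session ", g$session, ")")
    }
    nm <- node_metrics(g)[, c("node", metrics), drop = FALSE]
    long <- stats::reshape(nm, direction = "long", varying = metrics,
                           v.names = "value", timevar = "metric",
                           times = metrics, idvar = "node")
    data.frame(subject = g$subject_id, session = g$session,
               node = long$node, metric = long$metric, value = long$value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (!is.null(cohort)) {
    out$group <- cohort$group[match(out$subject, cohort$subject_id)]
    if (anyNA(out$group)) {
      stop("subject(s) missing from cohort table: ",
           paste(unique(out$subject[is.na(out$group)]), collapse = ", "))
    }
    out <- out[, c("subject", "session", "group", "node", "metric", "value")]
  }
  out
}
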