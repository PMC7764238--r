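#' Ground-truth covariance model for synthetic cohorts
#'
#' Constructs a modular (block-structured) correlation model for regional
#' BOLD signals, optionally carrying group-by-timepoint covariance
#' perturbations ("planted effects") that alter specific node-level graph
#' metrics once the data have been pushed through the full connectome
#' pipeline. Effects are planted in covariance space, never by manipulating
#' the metrics directly, so that metric recovery is a genuine end-to-end
#' test of the pipeline.
#'
#' Within-module correlations are drawn uniformly from `base_within`,
#' between-module correlations from `base_between`; the matrix is then
#' projected to the nearest symmetric positive-definite correlation matrix
#' (eigenvalue clipping followed by rescaling to unit diagonal).
#'
#' @param n_nodes Number of regions (default 116, the AAL atlas size).
#' @param n_modules Number of covariance modules; nodes are assigned to
#'   modules in contiguous, near-equal blocks.
#' @param effect_spec `NULL`, or a data frame with columns `group`
#'   (`"OMT"`/`"P"`), `timepoint` (`"T0"`/`"T1"`/`"T2"`), `node` (label or
#'   1-based index), `effect` (one of `"betweenness_up"`,
#'   `"betweenness_down"`, `"clustering_up"`, `"clustering_down"`) and
#'   `magnitude` (in `[0, 1]`).
#' @param ar_coefficient Lag-1 temporal autocorrelation of the simulated
#'   BOLD signal, in `[0, 1)`.
#' @param base_within,base_between Ranges (length-2) of within- and
#'   between-module correlations.
#' @param node_labels Optional node names; defaults to [aal116_labels()]
#'   when `n_nodes == 116`, else `ROI001...`.
#' @param seed Integer seed; the model is fully reproducible given it.
#'
#' @return An object of class `fc_ground_truth` with elements `n_nodes`,
#'   `modules` (integer module assignment), `base_covariance`, `effect_map`,
#'   `ar_coefficient`, `node_labels`, `seed`.
#' @export
#' @examples
#' gt <- make_ground_truth(n_nodes = 12, n_modules = 3, seed = 1)
#' eigen(gt$base_covariance, only.values = TRUE)$values[12] > 0
make_ground_truth <- function(n_nodes = 116, n_modules = 8,
                              effect_spec = NULL, ar_coefficient = 0.3,
                              base_within = c(0.35, 0.6),
                              base_between = c(0.05, 0.2),
                              node_labels = NULL, seed = 1) {
  stopifnot(n_modules >= 2, n_nodes >= 3 * n_modules,
            ar_coefficient >= 0, ar_coefficient < 1)
  if (is.null(node_labels)) {
    node_labels <- if (n_nodes == 116) aal116_labels() else
      sprintf("ROI%03d", seq_len(n_nodes))
  }
  stopifnot(length(node_labels) == n_nodes)

  set.seed(as.integer(seed))
  modules <- sort(rep_len(seq_len(n_modules), n_nodes))

  same <- outer(modules, modules, "==")
  r <- matrix(0, n_nodes, n_nodes)
  ut <- upper.tri(r)
  n_ut <- sum(ut)
  rw <- stats::runif(n_ut, base_within[1], base_within[2])
  rb <- stats::runif(n_ut, base_between[1], base_between[2])
  r[ut] <- ifelse(same[ut], rw, rb)
  r <- r + t(r)
  diag(r) <- 1
  r <- nearest_spd_correlation(r)
  dimnames(r) <- list(node_labels, node_labels)

  effect_map <- normalize_effect_spec(effect_spec, node_labels)

  model <- structure(
    list(n_nodes = n_nodes, modules = modules, base_covariance = r,
         effect_map = effect_map, ar_coefficient = ar_coefficient,
         node_labels = node_labels, seed = as.integer(seed)),
    class = "fc_ground_truth"
  )
  # fail early if any planted magnitude breaks positive-definiteness
  if (nrow(effect_map)) {
    conds <- unique(effect_map[, c("group", "timepoint")])
    for (i in seq_len(nrow(conds))) {
      covariance_for(model, conds$group[i], conds$timepoint[i])
    }
  }
  model
}

#' @export
print.fc_ground_truth <- function(x, ...) {
  cat(sprintf("<fc_ground_truth> %d nodes, %d modules, AR(1) = %g, %d planted effect(s)\n",
              x$n_nodes, max(x$modules), x$ar_coefficient, nrow(x$effect_map)))
  invisible(x)
}

normalize_effect_spec <- function(effect_spec, node_labels) {
  kinds <- c("betweenness_up", "betweenness_down",
             "clustering_up", "clustering_down")
  if (is.null(effect_spec) || NROW(effect_spec) == 0L) {
    return(data.frame(group = character(), timepoint = character(),
                      node = integer(), effect = character(),
                      magnitude = numeric(), stringsAsFactors = FALSE))
  }
  effect_spec <- as.data.frame(effect_spec, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "timepoint", "node", "effect", "magnitude") %in%
                  names(effect_spec)))
  node <- effect_spec$node
  if (is.character(node)) {
    idx <- match(node, node_labels)
    if (anyNA(idx)) stop("unknown effect node(s): ",
                         paste(node[is.na(idx)], collapse = ", "))
    node <- idx
  }
  node <- as.integer(node)
  if (any(node < 1L) || any(node > length(node_labels))) {
    stop("effect node index out of range")
  }
  if (!all(effect_spec$effect %in% kinds)) {
    stop("effect kind must be one of: ", paste(kinds, collapse = ", "))
  }
  if (any(effect_spec$magnitude < 0) || any(effect_spec$magnitude > 1)) {
    stop("effect magnitude must lie in [0, 1]")
  }
  data.frame(group = as.character(effect_spec$group),
             timepoint = as.character(effect_spec$timepoint),
             node = node, effect = as.character(effect_spec$effect),
             magnitude = as.numeric(effect_spec$magnitude),
             stringsAsFactors = FALSE)
}

#' Condition-specific covariance of a ground-truth model
#'
#' Applies all planted effects registered for the given group and timepoint
#' to the base covariance and re-projects to a positive-definite correlation
#' matrix. With no matching effects (or all magnitudes zero) the base
#' covariance is returned unchanged.
#'
#' Effect kinds act in correlation space:
#' \describe{
#'   \item{clustering_down}{scales correlations among the target node's
#'     within-module neighbours (excluding the node itself) by
#'     `1 - magnitude`, thinning the node's neighbourhood.}
#'   \item{clustering_up}{moves those same neighbour-neighbour correlations
#'     toward 0.8 by fraction `magnitude`.}
#'   \item{betweenness_up}{moves the target node's correlations with a few
#'     nodes in every module (its own included) toward 0.75, making the
#'     node an inter-module shortcut that shortest paths must cross.}
#'   \item{betweenness_down}{scales all of the target node's correlations by
#'     `1 - magnitude`, pushing it to the network periphery.}
#' }
#'
#' @param model An `fc_ground_truth` object.
#' @param group,timepoint Condition selectors.
#' @return Symmetric positive-definite correlation matrix.
#' @export
covariance_for <- function(model, group, timepoint) {
  stopifnot(inherits(model, "fc_ground_truth"))
  r <- model$base_covariance
  em <- model$effect_map
  hit <- em[em$group == group & em$timepoint == timepoint, , drop = FALSE]
  if (nrow(hit) == 0L || all(hit$magnitude == 0)) {
    return(r)
  }
  for (i in seq_len(nrow(hit))) {
    v <- hit$node[i]
    m <- hit$magnitude[i]
    if (m == 0) next
    mod_v <- model$modules[v]
    nbr <- setdiff(which(model$modules == mod_v), v)
    r <- switch(
      hit$effect[i],
      clustering_down = {
        r[nbr, nbr] <- r[nbr, nbr] * (1 - m)
        diag(r)[nbr] <- 1
        r
      },
      clustering_up = {
        blk <- r[nbr, nbr]
        blk <- blk + m * (0.8 - blk)
        diag(blk) <- 1
        r[nbr, nbr] <- blk
        r
      },
      betweenness_up = {
        # strengthen links from v into every other module (and its own),
        # turning v into the short-path shortcut between modules
        other <- setdiff(seq_len(max(model$modules)), mod_v)
        bridge <- unlist(lapply(other, function(b) {
          utils::head(which(model$modules == b), 4L)
        }))
        tgt <- union(bridge, utils::head(nbr, 4L))
        r[v, tgt] <- r[v, tgt] + m * (0.75 - r[v, tgt])
        r[tgt, v] <- r[v, tgt]
        r
      },
      betweenness_down = {
        r[v, -v] <- r[v, -v] * (1 - m)
        r[-v, v] <- r[v, -v]
        r
      },
      stop("unknown effect kind: ", hit$effect[i])
    )
  }
  r <- nearest_spd_correlation(r)
  dimnames(r) <- dimnames(model$base_covariance)
  r
}

# Project a symmetric matrix to a positive-definite correlation matrix by
# clipping eigenvalues at a small floor and rescaling to unit diagonal.
# Errors if the result is still not usable (e.g. clipping destroyed it).
nearest_spd_correlation <- function(r, eig_floor = 1e-4) {
  r <- (r + t(r)) / 2
  es <- eigen(r, symmetric = TRUE)
  if (min(es$values) < eig_floor) {
    vals <- pmax(es$values, eig_floor)
    r <- es$vectors %*% (vals * t(es$vectors))
    d <- sqrt(diag(r))
    r <- r / tcrossprod(d)
    diag(r) <- 1
    r <- (r + t(r)) / 2
  }
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-8)) {
    stop("covariance perturbation could not be projected to a valid ",
         "correlation matrix; reduce the effect magnitude")
  }
  ev_min <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    stop("matrix is not positive-definite after re-projection; ",
         "reduce the effect magnitude")
  }
  r
}
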