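# Independent oracles and small fixtures used across the suite.
# These deliberately re-derive quantities by brute force (path enumeration,
# triple loops, spanning trees, textbook sums of squares) so they share no
# code with the implementation they check.

# exhaustive weighted betweenness: enumerate all simple paths per pair,
# keep the shortest (edge length = 1/weight), count fractionally
bf_betweenness <- function(w) {
  n <- nrow(w)
  counts <- numeric(n)
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(to))
    out <- list()
    for (nxt in which(w[from, ] > 0)) {
      if (!nxt %in% visited) {
        for (p in all_paths(nxt, to, c(visited, nxt))) {
          out[[length(out) + 1L]] <- c(from, p)
        }
      }
    }
    out
  }
  path_len <- function(p) {
    sum(1 / w[cbind(p[-length(p)], p[-1])])
  }
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t, s)
      lens <- vapply(paths, path_len, 0)
      best <- min(lens)
      sp <- paths[lens < best + 1e-9]
      through <- table(unlist(lapply(sp, function(p) setdiff(p, c(s, t)))))
      counts[as.integer(names(through))] <-
        counts[as.integer(names(through))] + as.numeric(through) / length(sp)
    }
  }
  counts / ((n - 1) * (n - 2) / 2)
}

# direct triple-loop Onnela clustering with within-graph max normalization
bf_clustering <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  out <- numeric(n)
  for (i in 1:n) {
    nbrs <- which(w[i, ] > 0)
    k <- length(nbrs)
    if (k < 2) next
    acc <- 0
    for (j in nbrs) {
      for (h in nbrs) {
        if (j != h) acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
      }
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

# bottleneck (minimum) edge weight of the maximum spanning tree
mst_bottleneck <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, weights = -igraph::E(g)$weight)
  min(igraph::E(mst)$weight)
}

# symmetric zero-diagonal similarity-like matrix from random data
random_similarity <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * (n + 5)), n + 5, n)
  s <- cor(x)^2
  diag(s) <- 0
  s
}

# random connected small weighted graph (keeps edges with prob p over a
# random spanning-tree backbone)
random_small_graph <- function(n, seed, p = 0.5) {
  set.seed(seed)
  w <- matrix(0, n, n)
  perm <- sample(n)
  for (i in 2:n) {       # spanning tree: attach each node to a predecessor
    j <- perm[sample(i - 1, 1)]
    w[perm[i], j] <- w[j, perm[i]] <- runif(1, 0.1, 1)
  }
  extra <- which(upper.tri(w) & w == 0)
  on <- extra[runif(length(extra)) < p]
  w[on] <- runif(length(on), 0.1, 1)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  conn_graph(w, threshold = min(w[w > 0]),
             node_labels = sprintf("n%02d", 1:n))
}

# mixed-design interaction F via stats::aov with an Error stratum
aov_interaction_f <- function(df) {
  df$subject <- factor(df$subject)
  df$group <- factor(df$group)
  df$session <- factor(df$session)
  fit <- stats::aov(value ~ group * session + Error(subject / session),
                    data = df)
  s <- summary(fit)
  tab <- s[["Error: subject:session"]][[1]]
  row <- grep("group:session", rownames(tab))
  list(F = tab[row, "F value"], df_num = tab[row, "Df"],
       df_den = tab[nrow(tab), "Df"], p = tab[row, "Pr(>F)"])
}

# long metric table with one synthetic metric drawn i.i.d. per observation
fake_metric_table <- function(n_per_group, sessions = c("T0", "T1", "T2"),
                              nodes = c("A", "B"), metric = "betweenness",
                              seed = 1) {
  set.seed(seed)
  subj <- c(sprintf("O%02d", seq_len(n_per_group)),
            sprintf("P%02d", seq_len(n_per_group)))
  grp <- rep(c("OMT", "P"), each = n_per_group)
  out <- expand.grid(subject = subj, session = sessions, node = nodes,
                     metric = metric, stringsAsFactors = FALSE)
  out$group <- grp[match(out$subject, subj)]
  out$value <- rnorm(nrow(out))
  out
}
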