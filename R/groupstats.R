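#' Group-by-time interaction F from a mixed-design repeated-measures ANOVA
#'
#' For every node and metric, fits the classical split-plot decomposition
#' with one between-subject factor (group) and one within-subject factor
#' (session/timepoint) on complete cases (subjects observed at every
#' session), and returns the group-by-time interaction F statistic with
#' numerator df `(t - 1)(k - 1)` and denominator df `(N - k)(t - 1)`, where
#' `t` is the number of sessions, `k` the number of groups and `N` the
#' number of complete-case subjects. With `k = 2` groups and `t = 3`
#' sessions this is the familiar `F(2, 2(N - 2))` — e.g. `F(2, 32)` for 18
#' complete subjects. The computation is vectorized across nodes and
#' metrics (mass-univariate), and each sum-of-squares agrees with
#' `stats::aov` with an `Error(subject/session)` stratum, which the test
#' suite asserts.
#'
#' @param metric_table Long table with columns `subject`, `session`,
#'   `group`, `node`, `metric`, `value` (see [metrics_table()]).
#' @param fdr_by Scope of the Benjamini-Hochberg correction: `"metric"`
#'   (default; across nodes within each metric) or `"all"` (across all
#'   node-metric combinations).
#' @return Data frame with one row per node-metric: `node`, `metric`, `F`,
#'   `df_num`, `df_den`, `p`, `p_fdr`, plus attributes `n_complete` and
#'   `groups`.
#' @export
rm_anova_interaction <- function(metric_table, fdr_by = c("metric", "all")) {
  fdr_by <- match.arg(fdr_by)
  mt <- as.data.frame(metric_table)
  needed <- c("subject", "session", "group", "node", "metric", "value")
  stopifnot(all(needed %in% names(mt)))
  sessions <- sort(unique(mt$session))
  t_lev <- length(sessions)
  if (t_lev < 2L) stop("need at least 2 sessions")

  # complete cases: subjects observed at every session
  subj_sess <- unique(mt[, c("subject", "session")])
  cnt <- table(subj_sess$subject)
  complete <- names(cnt)[cnt == t_lev]
  mt <- mt[mt$subject %in% complete, , drop = FALSE]
  sg <- unique(mt[, c("subject", "group")])
  if (anyDuplicated(sg$subject)) stop("a subject appears in two groups")
  k <- length(unique(sg$group))
  if (k < 2L) stop("need at least 2 groups with complete cases")
  n_g <- table(sg$group)
  if (any(n_g < 2L)) {
    stop("group(s) with fewer than 2 complete-case subjects: ",
         paste(names(n_g)[n_g < 2L], collapse = ", "))
  }
  n_subj <- nrow(sg)

  # wide matrix: rows = subject x session, columns = node x metric
  key <- interaction(mt$node, mt$metric, drop = TRUE, sep = "\r")
  row_key <- interaction(mt$subject, mt$session, drop = TRUE, sep = "\r")
  y <- matrix(NA_real_, nlevels(row_key), nlevels(key),
              dimnames = list(levels(row_key), levels(key)))
  y[cbind(as.integer(row_key), as.integer(key))] <- mt$value
  if (anyNA(y)) stop("metric table is not complete over node x metric cells")

  rk <- do.call(rbind, strsplit(rownames(y), "\r", fixed = TRUE))
  subj <- rk[, 1L]
  grp <- sg$group[match(subj, sg$subject)]

  # subject-center (removes subject and group main effects)
  subj_mean <- rowsum(y, subj) / t_lev
  d <- y - subj_mean[subj, , drop = FALSE]

  cell <- interaction(grp, rk[, 2L], drop = TRUE, sep = "\r")  # group x session
  n_cell <- as.vector(table(cell))
  cell_mean <- rowsum(d, cell) / n_cell
  ss_cells <- colSums(cell_mean^2 * n_cell)
  sess_of_cell <- vapply(strsplit(rownames(cell_mean), "\r", fixed = TRUE),
                         `[`, "", 2L)
  time_mean <- rowsum(cell_mean * n_cell, sess_of_cell) / n_subj
  ss_time <- colSums(time_mean^2) * n_subj
  ss_gt <- pmax(ss_cells - ss_time, 0)
  ss_err <- colSums((d - cell_mean[as.integer(cell), , drop = FALSE])^2)

  df_num <- (t_lev - 1L) * (k - 1L)
  df_den <- (n_subj - k) * (t_lev - 1L)
  f <- (ss_gt / df_num) / (ss_err / df_den)
  p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)

  ck <- do.call(rbind, strsplit(colnames(y), "\r", fixed = TRUE))
  out <- data.frame(node = ck[, 1L], metric = ck[, 2L], F = as.numeric(f),
                    df_num = df_num, df_den = df_den, p = as.numeric(p),
                    stringsAsFactors = FALSE)
  out$p_fdr <- if (fdr_by == "metric") {
    stats::ave(out$p, out$metric, FUN = fdr_adjust)
  } else {
    fdr_adjust(out$p)
  }
  rownames(out) <- NULL
  attr(out, "n_complete") <- n_subj
  attr(out, "groups") <- sort(unique(as.character(grp)))
  out
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper around
#' [stats::p.adjust()] with `method = "BH"` kept as a named pipeline stage.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Baseline-controlled post-hoc contrast on change scores
#'
#' For a session pair `(B, E)` computes each subject's change score
#' `delta = metric(E) - metric(B)` and compares treatment against placebo
#' with a Welch two-sample t test, per node and metric. The reported
#' `delta` is `mean(change | OMT) - mean(change | P)` — positive when the
#' treated group increased more than placebo relative to baseline (the
#' "(E_OS - B_OS) - (E_PS - B_PS)" reading of the interaction).
#'
#' @param metric_table Long metric table with a `group` column containing
#'   `treat_level` and one other level.
#' @param pair Character length-2: baseline and end session, e.g.
#'   `c("T0", "T1")`.
#' @param treat_level Group label of the treated arm (default `"OMT"`).
#' @return Data frame: `node`, `metric`, `delta`, `statistic` (Welch t),
#'   `df`, `p`, `n_treat`, `n_control`.
#' @export
posthoc_contrast <- function(metric_table, pair = c("T0", "T1"),
                             treat_level = "OMT") {
  stopifnot(length(pair) == 2L)
  mt <- as.data.frame(metric_table)
  mt <- mt[mt$session %in% pair, , drop = FALSE]
  # subjects with both sessions of the pair
  cnt <- table(unique(mt[, c("subject", "session")])$subject)
  keep <- names(cnt)[cnt == 2L]
  mt <- mt[mt$subject %in% keep, , drop = FALSE]
  if (!treat_level %in% mt$group) {
    stop("no complete-pair subjects in group ", treat_level)
  }
  if (all(mt$group == treat_level)) {
    stop("no complete-pair subjects in the control group")
  }

  b <- mt[mt$session == pair[1L], ]
  e <- mt[mt$session == pair[2L], ]
  key <- function(d) paste(d$subject, d$node, d$metric, sep = "\r")
  e <- e[match(key(b), key(e)), ]
  delta <- data.frame(subject = b$subject, group = b$group, node = b$node,
                      metric = b$metric, delta = e$value - b$value,
                      stringsAsFactors = FALSE)

  res <- lapply(split(delta, list(delta$node, delta$metric), drop = TRUE),
                function(dd) {
    x <- dd$delta[dd$group == treat_level]
    y <- dd$delta[dd$group != treat_level]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      tt <- list(statistic = c(t = if (mean(x) == mean(y)) 0 else Inf),
                 parameter = c(df = NA_real_),
                 p.value = if (mean(x) == mean(y)) 1 else 0)
    } else {
      tt <- stats::t.test(x, y)
    }
    data.frame(node = dd$node[1L], metric = dd$metric[1L],
               delta = mean(x) - mean(y),
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n_treat = length(x), n_control = length(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "pair") <- pair
  attr(out, "delta_table") <- delta
  out
}

#' Per-subject change scores for one session pair
#'
#' @param metric_table Long metric table.
#' @param pair Baseline and end session labels.
#' @return Data frame `subject`, `group`, `node`, `metric`, `delta` for
#'   subjects observed at both sessions.
#' @export
change_scores <- function(metric_table, pair = c("T0", "T1")) {
  attr(posthoc_contrast(metric_table, pair), "delta_table")
}

#' Correlation between somatic-dysfunction count and connectivity change
#'
#' Pearson (or Spearman) correlation between each treated subject's number
#' of somatic dysfunctions and their per-node change score, with a
#' two-sided p value. Degenerate counts (zero variance) yield `NA` with a
#' warning.
#'
#' @param counts Named numeric vector of dysfunction counts, names =
#'   subject ids (treated subjects).
#' @param delta_table Change-score table from [change_scores()]; only rows
#'   whose subjects appear in `names(counts)` are used.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame `node`, `metric`, `r`, `p`, `n`.
#' @export
dysfunction_correlation <- function(counts, delta_table,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  dt <- as.data.frame(delta_table)
  dt <- dt[dt$subject %in% names(counts), , drop = FALSE]
  if (nrow(dt) == 0L) stop("no change scores for the supplied subjects")
  degenerate <- stats::var(counts[unique(dt$subject)]) == 0
  if (degenerate) {
    warning("dysfunction counts have zero variance; correlations are NA")
  }
  res <- lapply(split(dt, list(dt$node, dt$metric), drop = TRUE),
                function(dd) {
    x <- counts[dd$subject]
    if (degenerate || stats::sd(dd$delta) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(as.numeric(x), dd$delta, method = method,
                            exact = FALSE)
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(node = dd$node[1L], metric = dd$metric[1L], r = r, p = p,
               n = nrow(dd), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test for two independent samples
#'
#' Exact U distribution for small samples (both `n <= 20`, no ties),
#' otherwise the normal approximation with tie correction; two-sided.
#' Wraps [stats::wilcox.test()], whose `W` statistic is the Mann-Whitney U
#' of the first sample.
#'
#' @param sample_a,sample_b Numeric vectors (non-empty).
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 1L, length(sample_b) >= 1L)
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0L
  exact <- !ties && length(sample_a) <= 20L && length(sample_b) <= 20L
  wt <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact, correct = !exact)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance independent-samples t test computed from group means,
#' SDs and sizes, as used for demographic comparisons reported only as
#' summaries. The statistic is for `group2 - group1`, with
#' `df = n1 + n2 - 2` and the 95% CI of the mean difference.
#'
#' @param mean1,sd1,n1 First group's mean, SD, size.
#' @param mean2,sd2,n2 Second group's mean, SD, size.
#' @return List with `t`, `df`, `p` (two-sided), `ci95` (length 2), and
#'   `diff` (`mean2 - mean1`).
#' @export
#' @examples
#' # age comparison: treated 28.0 +/- 5.5 vs placebo 25.4 +/- 3.2, n = 15 each
#' summary_ttest(28.0, 5.5, 15, 25.4, 3.2, 15)$t
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  diff <- mean2 - mean1
  t <- diff / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  ci <- diff + c(-1, 1) * stats::qt(0.975, df) * se
  list(t = t, df = df, p = p, ci95 = ci, diff = diff)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, as conventional for demographic
#' comparisons of two randomized arms.
#'
#' @param a,b First row of the table (e.g. males / females in group 1).
#' @param c,d Second row (group 2).
#' @return List with `chisq`, `df` (= 1), `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  stopifnot(all(tab >= 0), sum(tab) > 0)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square test undefined: a table marginal is zero")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Required sample size for a paired-samples t test
#'
#' Smallest number of pairs `n` such that a paired t test with
#' noncentrality `d * sqrt(n)` and `n - 1` degrees of freedom attains the
#' requested power at the requested alpha, computed from the noncentral t
#' distribution.
#'
#' @param effect_size_d Cohen's d of the paired difference (> 0).
#' @param alpha Type-I error rate (default 0.05).
#' @param power Target power (default 0.80).
#' @param tails 1 or 2.
#' @param n_max Search cap.
#' @return Integer: the minimal required n (total subjects in a
#'   one-sample/paired design).
#' @export
#' @examples
#' paired_sample_size(0.55, alpha = 0.05, power = 0.80, tails = 1)  # 22
paired_sample_size <- function(effect_size_d, alpha = 0.05, power = 0.80,
                               tails = 1, n_max = 1e6) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, tails %in% c(1, 2))
  if (effect_size_d <= 0) {
    stop("effect size must be positive; the target power is unattainable")
  }
  for (n in 2:n_max) {
    if (paired_t_power(n, effect_size_d, alpha, tails) >= power) {
      return(n)
    }
  }
  stop("required n exceeds ", n_max)
}

#' Achieved power of a paired t test at a given n
#' @inheritParams paired_sample_size
#' @param n Number of pairs.
#' @return Achieved power in `(0, 1)`.
#' @export
paired_t_power <- function(n, effect_size_d, alpha = 0.05, tails = 1) {
  stopifnot(n >= 2)
  ncp <- effect_size_d * sqrt(n)
  crit <- stats::qt(1 - alpha / tails, df = n - 1)
  pow <- stats::pt(crit, df = n - 1, ncp = ncp, lower.tail = FALSE)
  if (tails == 2) {
    pow <- pow + stats::pt(-crit, df = n - 1, ncp = ncp)
  }
  pow
}
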