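#' Default pipeline configuration
#'
#' Returns the configuration list used by [run_pipeline()]. The defaults
#' mirror the trial design the package emulates: 15 subjects per arm,
#' three sessions (T0, T1, T2) with the trial's attrition pattern, 116
#' atlas regions, 240 volumes at TR = 3 s with the first five discarded,
#' a 0.01-0.15 Hz pass band, and planted group-by-time effects in the
#' treated arm at the regions reported for betweenness and clustering
#' changes.
#'
#' @param n_nodes,n_modules,n_per_group,n_volumes,tr,n_discard,band_hz,despike_z,head_radius_mm,ar_coefficient,effect_magnitude,fdr_alpha,seed
#'   Overrides for individual entries.
#' @param dropout One of `"trial"` (default attrition) or `"none"`.
#' @param physio Logical: inject and regress physiological artifacts.
#' @param motion Logical: inject motion and regress FWD.
#' @param effects One of `"trial"` (planted effects at the reported
#'   regions), `"none"`, or a custom effect-spec data frame.
#' @param metrics Metric subset for the group analysis.
#' @param contrasts List of session pairs for the post-hoc contrast.
#' @return Named list.
#' @export
default_config <- function(n_nodes = 116, n_modules = 8, n_per_group = 15,
                           n_volumes = 240, tr = 3, n_discard = 5,
                           band_hz = c(0.01, 0.15), despike_z = 4,
                           head_radius_mm = 50, ar_coefficient = 0.3,
                           dropout = "trial", physio = TRUE, motion = TRUE,
                           effects = "trial", effect_magnitude = 0.5,
                           metrics = c("strength", "eigenvector",
                                       "betweenness", "clustering"),
                           contrasts = list(c("T0", "T1"), c("T1", "T2")),
                           fdr_alpha = 0.05, seed = 1) {
  list(n_nodes = n_nodes, n_modules = n_modules, n_per_group = n_per_group,
       n_volumes = n_volumes, tr = tr, n_discard = n_discard,
       band_hz = band_hz, despike_z = despike_z,
       head_radius_mm = head_radius_mm, ar_coefficient = ar_coefficient,
       dropout = dropout, physio = physio, motion = motion,
       effects = effects, effect_magnitude = effect_magnitude,
       metrics = metrics, contrasts = contrasts, fdr_alpha = fdr_alpha,
       seed = seed)
}

#' Planted effects mirroring the reported group-by-time findings
#'
#' Betweenness up at the right precentral gyrus and clustering down at the
#' left amygdala and left middle temporal gyrus in the treated arm at T1;
#' betweenness down at the left caudate and clustering up at the left
#' amygdala and vermis III at T2.
#'
#' @param magnitude Covariance perturbation magnitude in `[0, 1]`
#'   (default 0.5).
#' @param node_labels Labels the targets must belong to; with fewer than
#'   116 generic nodes, targets fall back to evenly spaced node indices.
#' @return Effect-spec data frame for [make_ground_truth()].
#' @export
trial_effects <- function(magnitude = 0.5, node_labels = aal116_labels()) {
  targets <- c("Precentral_R", "Amygdala_L", "Temporal_Mid_L",
               "Caudate_L", "Amygdala_L", "Vermis_3")
  if (!all(targets %in% node_labels)) {
    idx <- round(seq(2, length(node_labels) - 1, length.out = 5))
    targets <- node_labels[idx][c(1, 2, 3, 4, 2)]
    targets <- c(targets, node_labels[idx][5])
  }
  data.frame(
    group = "OMT",
    timepoint = c("T1", "T1", "T1", "T2", "T2", "T2"),
    node = targets,
    effect = c("betweenness_up", "clustering_down", "clustering_down",
               "betweenness_down", "clustering_up", "clustering_up"),
    magnitude = magnitude,
    stringsAsFactors = FALSE
  )
}

resolve_effects <- function(config, node_labels) {
  eff <- config$effects
  if (is.data.frame(eff)) return(eff)
  if (identical(eff, "none") || is.null(eff)) return(NULL)
  if (identical(eff, "trial")) {
    return(trial_effects(config$effect_magnitude, node_labels))
  }
  stop("effects must be 'trial', 'none', or an effect-spec data frame")
}

# deterministic per-(subject, session) stream seed below 2^31
derive_seed <- function(master, i_subj, i_sess, salt = 0L) {
  (as.integer(master) * 1009L + i_subj * 101L + i_sess * 17L + salt) %%
    2147483563L + 1L
}

#' Simulate a full study (cohort, ground truth, per-session recordings)
#'
#' @param config Configuration list from [default_config()].
#' @return List with `truth`, `cohort` and `sessions` (a list of
#'   `list(series, physio, motion)` keyed by `"subject/session"`).
#' @export
simulate_study <- function(config = default_config()) {
  labels <- if (config$n_nodes == 116) aal116_labels() else
    sprintf("ROI%03d", seq_len(config$n_nodes))
  truth <- make_ground_truth(
    n_nodes = config$n_nodes, n_modules = config$n_modules,
    effect_spec = resolve_effects(config, labels),
    ar_coefficient = config$ar_coefficient, node_labels = labels,
    seed = derive_seed(config$seed, 0L, 0L, 1L)
  )
  dropout <- if (identical(config$dropout, "none")) {
    default_dropout()[0, ]
  } else {
    default_dropout()
  }
  cohort <- make_cohort(n_per_group = config$n_per_group,
                        dropout_spec = dropout,
                        seed = derive_seed(config$seed, 0L, 0L, 2L))
  avail <- available_sessions(cohort)
  sessions <- list()
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]
    for (s in avail[[sid]]) {
      i_sess <- match(s, c("T0", "T1", "T2"))
      bold <- simulate_bold(truth, group = cohort$group[i], timepoint = s,
                            n_volumes = config$n_volumes,
                            tr_seconds = config$tr, subject_id = sid,
                            session = s,
                            seed = derive_seed(config$seed, i, i_sess, 3L))
      physio <- NULL
      if (isTRUE(config$physio)) {
        cont <- add_physio(bold,
                           seed = derive_seed(config$seed, i, i_sess, 4L))
        bold <- cont$series
        physio <- cont$physio
      }
      motion <- NULL
      if (isTRUE(config$motion)) {
        motion <- simulate_motion(config$n_volumes,
                                  seed = derive_seed(config$seed, i, i_sess,
                                                     5L))
      }
      sessions[[paste(sid, s, sep = "/")]] <-
        list(series = bold, physio = physio, motion = motion)
    }
  }
  list(truth = truth, cohort = cohort, sessions = sessions)
}

#' Compute the metric table of a simulated or loaded study
#'
#' Runs preprocessing (optional) and the connectome stage on every session
#' and collects the long metric table.
#'
#' @param study List with `cohort` and `sessions` as from
#'   [simulate_study()].
#' @param config Configuration list.
#' @param preprocess Logical; if `FALSE` the connectome stage runs on the
#'   raw series (appropriate when no confounds were injected).
#' @return List with `metrics` (long table) and `graph_info` (per-session
#'   threshold and edge count).
#' @export
study_metrics <- function(study, config = default_config(),
                          preprocess = TRUE) {
  graphs <- vector("list", length(study$sessions))
  info <- vector("list", length(study$sessions))
  for (i in seq_along(study$sessions)) {
    sess <- study$sessions[[i]]
    series <- sess$series
    if (preprocess) {
      series <- preprocess_session(series, physio = sess$physio,
                                   motion = sess$motion,
                                   n_discard = config$n_discard,
                                   band_hz = config$band_hz,
                                   despike_z = config$despike_z,
                                   head_radius_mm = config$head_radius_mm)
    }
    g <- percolation_threshold(similarity_matrix(series),
                               node_labels = series$node_labels,
                               subject_id = series$subject_id,
                               session = series$session)
    graphs[[i]] <- g
    info[[i]] <- data.frame(subject = g$subject_id, session = g$session,
                            threshold = g$threshold,
                            n_edges = sum(g$weights[upper.tri(g$weights)] > 0),
                            stringsAsFactors = FALSE)
  }
  metrics <- metrics_table(graphs, cohort = study$cohort,
                           metrics = config$metrics)
  list(metrics = metrics, graph_info = do.call(rbind, info))
}

#' Run the full pipeline and write all stage outputs
#'
#' Synthesize -> preprocess -> connectome -> group statistics, writing
#' TSV/JSON outputs and a manifest to `out_dir`. Deterministic given
#' `config$seed`.
#'
#' @param config Configuration list (see [default_config()]) or a path to
#'   a YAML/JSON file holding one.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `metrics`, `anova`, `contrasts`,
#'   `graph_info`, `cohort` and `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  defaults <- default_config()
  config <- utils::modifyList(defaults, config)
  stopifnot(is.numeric(config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  study <- stage("simulate", simulate_study(config))
  write_cohort_tsv(study$cohort, file.path(out_dir, "cohort.tsv"))

  sm <- stage("preprocess+connectome",
              study_metrics(study, config,
                            preprocess = isTRUE(config$physio) ||
                              isTRUE(config$motion)))
  write_metrics_tsv(sm$metrics, file.path(out_dir, "metrics.tsv"))
  utils::write.table(sm$graph_info, file.path(out_dir, "graphs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  anova <- stage("groupstats", rm_anova_interaction(sm$metrics))
  utils::write.table(anova, file.path(out_dir, "anova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  contrasts <- lapply(config$contrasts, function(pair) {
    res <- stage("groupstats", posthoc_contrast(sm$metrics, pair))
    res$pair <- paste(pair, collapse = ":")
    res
  })
  contrasts <- do.call(rbind, contrasts)
  utils::write.table(contrasts, file.path(out_dir, "contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sig <- anova[anova$p_fdr < config$fdr_alpha, c("node", "metric", "F",
                                                 "df_num", "df_den", "p",
                                                 "p_fdr")]
  manifest <- list(
    package_version = as.character(utils::packageVersion("fconnet")),
    r_version = R.version.string,
    parameters = config[setdiff(names(config), "effects")],
    effects = {
      eff <- resolve_effects(config, study$truth$node_labels)
      if (is.null(eff)) list() else eff
    },
    n_sessions = length(study$sessions),
    n_significant_fdr = nrow(sig),
    input_hashes = list(
      metrics = unname(tools_md5(file.path(out_dir, "metrics.tsv"))),
      cohort = unname(tools_md5(file.path(out_dir, "cohort.tsv")))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(metrics = sm$metrics, anova = anova, contrasts = contrasts,
                 graph_info = sm$graph_info, cohort = study$cohort,
                 out_dir = out_dir))
}

tools_md5 <- function(path) as.character(tools::md5sum(path))

read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Validate a set of study inputs
#'
#' Checks shape and metadata consistency of a study list (as produced by
#' [simulate_study()] or assembled from disk): constant volume counts and
#' TR, identical node label sets, recognized session labels, and
#' physiological/motion traces aligned to the volumes. Reports issues, and
#' never throws.
#'
#' @param study List with `sessions` (and optionally `cohort`).
#' @return Data frame with columns `where` and `issue`; zero rows when
#'   everything is consistent.
#' @export
validate_inputs <- function(study) {
  issues <- list()
  note <- function(where, issue) {
    issues[[length(issues) + 1L]] <<- data.frame(where = where, issue = issue,
                                                 stringsAsFactors = FALSE)
  }
  sessions <- study$sessions
  if (length(sessions) == 0L) {
    note("study", "no sessions present")
  } else {
    vc <- vapply(sessions, function(s) ncol(s$series$data), 0L)
    trs <- vapply(sessions, function(s) s$series$tr, 0)
    labs <- lapply(sessions, function(s) s$series$node_labels)
    if (length(unique(vc)) > 1L) {
      bad <- names(sessions)[vc != stats::median(vc)]
      for (b in bad) note(b, sprintf("volume count %d differs from median %d",
                                     vc[[b]], as.integer(stats::median(vc))))
    }
    if (length(unique(trs)) > 1L) {
      bad <- names(sessions)[trs != stats::median(trs)]
      for (b in bad) note(b, sprintf("TR %g differs from median %g",
                                     trs[[b]], stats::median(trs)))
    }
    ref <- labs[[1L]]
    for (nm in names(sessions)) {
      if (!identical(labs[[nm]], ref)) {
        note(nm, "node label set differs from first session")
      }
      s <- sessions[[nm]]
      sess_label <- s$series$session
      if (!sess_label %in% c("T0", "T1", "T2")) {
        note(nm, sprintf("unknown session label '%s'", sess_label))
      }
      if (!is.null(s$physio) &&
          length(s$physio$cardiac_phase) != ncol(s$series$data)) {
        note(nm, "physio trace length differs from volume count")
      }
      if (!is.null(s$motion) && nrow(s$motion) != ncol(s$series$data)) {
        note(nm, "motion trace length differs from volume count")
      }
    }
    if (!is.null(study$cohort)) {
      subj <- vapply(sessions, function(s) s$series$subject_id, "")
      unknown <- setdiff(unique(subj), study$cohort$subject_id)
      for (u in unknown) note(u, "subject not present in cohort table")
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(where = character(), issue = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
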