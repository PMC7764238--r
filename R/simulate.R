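#' Simulate regional BOLD time series
#'
#' Draws a node-by-volume matrix from the condition-specific covariance of a
#' ground-truth model with AR(1) temporal structure: each node's marginal
#' series is a stationary AR(1) process with the model's lag-1 coefficient,
#' and the lag-0 cross-covariance equals the model covariance. The marginal
#' distribution is Gaussian.
#'
#' @param model An `fc_ground_truth` object.
#' @param group,timepoint Condition selectors (determine which planted
#'   effects apply).
#' @param n_volumes Number of volumes to simulate (default 240).
#' @param tr_seconds Repetition time in seconds (default 3).
#' @param subject_id,session Metadata stored on the result; `session`
#'   defaults to `timepoint`.
#' @param seed Integer seed; output is bit-reproducible given it.
#' @return A [roi_ts] object of dimension `n_nodes` x `n_volumes`.
#' @export
#' @examples
#' gt <- make_ground_truth(n_nodes = 6, n_modules = 2, seed = 1)
#' b <- simulate_bold(gt, "OMT", "T0", n_volumes = 60, seed = 2)
#' dim(b)
simulate_bold <- function(model, group, timepoint, n_volumes = 240,
                          tr_seconds = 3, subject_id = NA_character_,
                          session = timepoint, seed = 1) {
  stopifnot(inherits(model, "fc_ground_truth"), n_volumes >= 20)
  sigma <- covariance_for(model, group, timepoint)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance is not positive-definite")
  phi <- model$ar_coefficient
  n <- model$n_nodes

  set.seed(as.integer(seed))
  l <- chol(sigma)                     # upper triangular, sigma = t(l) %*% l
  # innovations: volumes x nodes, each row ~ N(0, sigma)
  z <- matrix(stats::rnorm(n_volumes * n), n_volumes, n) %*% l
  if (phi > 0) {
    # scale innovations after the first so the stationary marginal is sigma
    z[-1, ] <- z[-1, ] * sqrt(1 - phi^2)
    z <- stats::filter(z, phi, method = "recursive")
    z <- matrix(as.numeric(z), n_volumes, n)
  }
  roi_ts(t(z), tr = tr_seconds, node_labels = model$node_labels,
         subject_id = subject_id, session = session)
}

#' Add physiological contamination to a BOLD series
#'
#' Superimposes cardiac and respiratory artifacts on every ROI: the first
#' and second harmonic of each physiological phase, with ROI-specific random
#' phase offsets and amplitudes. Phases advance at a constant rate sampled
#' at volume times (aliasing relative to the volume sampling is allowed and
#' expected, as in real BOLD). The exact phase traces are returned so a
#' subsequent RETROICOR-style regression can be verified against ground
#' truth.
#'
#' @param series A [roi_ts] object.
#' @param cardiac_hz,resp_hz Mean cardiac and respiratory rates in Hz
#'   (defaults 1.1 and 0.3, i.e. 66 beats and 18 breaths per minute). The
#'   instantaneous rates are slowly modulated (3% and 5% sinusoidal
#'   variation) to emulate heart-rate and breathing variability; this also
#'   keeps the aliased harmonic and interaction frequencies from
#'   coinciding exactly on the volume grid.
#' @param rate_sd Relative amplitude of the rate modulation
#'   `c(cardiac, resp)`; set to zero for strictly constant rates.
#' @param amplitudes Named numeric vector `c(cardiac = , resp = )` giving
#'   the first-harmonic amplitude per modality in signal units; the second
#'   harmonic gets half that amplitude. Must be non-negative.
#' @param seed Integer seed for the random phase offsets.
#' @return A list with elements `series` (contaminated [roi_ts]) and
#'   `physio` (a [physio_recording] with the injected phase traces).
#' @export
add_physio <- function(series, cardiac_hz = 1.1, resp_hz = 0.3,
                       rate_sd = c(0.03, 0.05),
                       amplitudes = c(cardiac = 0.5, resp = 0.4),
                       seed = 1) {
  stopifnot(inherits(series, "roi_ts"))
  a_c <- amplitudes[["cardiac"]]
  a_r <- amplitudes[["resp"]]
  if (a_c < 0 || a_r < 0) stop("amplitudes must be non-negative")

  v <- n_volumes(series)
  n <- n_nodes(series)
  times <- (seq_len(v) - 1L) * series$tr
  set.seed(as.integer(seed))
  phi0_c <- stats::runif(1, 0, 2 * pi)
  phi0_r <- stats::runif(1, 0, 2 * pi)
  # instantaneous rates with slow sinusoidal variability; phase is the
  # cumulative integral of the rate over volume times
  mod_ph <- stats::runif(2, 0, 2 * pi)
  f_c <- cardiac_hz * (1 + rate_sd[1] * sin(2 * pi * times / 180 + mod_ph[1]))
  f_r <- resp_hz * (1 + rate_sd[2] * sin(2 * pi * times / 120 + mod_ph[2]))
  ph_c <- phi0_c + 2 * pi * c(0, cumsum(f_c[-v] * series$tr))
  ph_r <- phi0_r + 2 * pi * c(0, cumsum(f_r[-v] * series$tr))

  out <- series
  if (a_c > 0 || a_r > 0) {
    # ROI-specific phase offsets per harmonic keep the artifact inside the
    # span of a sin/cos regressor pair while varying across regions
    off <- matrix(stats::runif(n * 4L, 0, 2 * pi), n, 4L)
    contam <- a_c * sin(outer(rep(1, n), ph_c) + off[, 1L]) +
      0.5 * a_c * sin(outer(rep(1, n), 2 * ph_c) + off[, 2L]) +
      a_r * sin(outer(rep(1, n), ph_r) + off[, 3L]) +
      0.5 * a_r * sin(outer(rep(1, n), 2 * ph_r) + off[, 4L])
    out$data <- series$data + contam
  }
  list(series = out, physio = physio_recording(ph_c, ph_r))
}

#' Simulate a six-parameter head-motion trace
#'
#' Produces slow sinusoidal drift on all six rigid-body parameters (three
#' translations in mm, three rotations in radians), plus optional single
#' volume spikes at a given rate. With `spike_rate = 0` the trace is smooth:
#' the per-volume parameter change is bounded by the drift amplitude times
#' the drift angular frequency.
#'
#' @param n_volumes Number of volumes.
#' @param spike_rate Per-volume probability of a motion spike, in `[0, 1]`.
#' @param drift_amplitude Maximum drift amplitude (mm for translations; the
#'   rotational amplitude is `drift_amplitude / 50`, i.e. matched arc length
#'   at a 50 mm radius).
#' @param seed Integer seed.
#' @return Numeric matrix `n_volumes` x 6 with columns `trans_x..z` (mm) and
#'   `rot_x..z` (radians).
#' @export
simulate_motion <- function(n_volumes, spike_rate = 0.02,
                            drift_amplitude = 0.1, seed = 1) {
  stopifnot(n_volumes >= 2, spike_rate >= 0, spike_rate <= 1)
  set.seed(as.integer(seed))
  t <- seq_len(n_volumes)
  out <- matrix(0, n_volumes, 6L)
  colnames(out) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
  periods <- c(64, 128)
  for (j in seq_len(6L)) {
    amp_max <- if (j <= 3L) drift_amplitude else drift_amplitude / 50
    a <- stats::runif(2, 0, amp_max)
    ph <- stats::runif(2, 0, 2 * pi)
    out[, j] <- a[1] * sin(2 * pi * t / periods[1] + ph[1]) +
      a[2] * sin(2 * pi * t / periods[2] + ph[2])
  }
  if (spike_rate > 0) {
    hit <- which(stats::runif(n_volumes) < spike_rate)
    for (i in hit) {
      j <- sample.int(6L, 1L)
      size <- stats::runif(1, 0.3, 1.5)
      if (j > 3L) size <- size / 50
      out[i, j] <- out[i, j] + sample(c(-1, 1), 1L) * size
    }
  }
  out
}

#' Render a toy 4D volume plus integer atlas from ROI series
#'
#' Lays ROIs out as contiguous voxel blocks (ROI `i` occupies row `i` of a
#' `n_nodes` x `voxels_per_roi` x 1 grid). Each voxel carries the ROI signal
#' plus independent Gaussian voxel noise, so that atlas parcellation with
#' zero noise round-trips the input exactly. Intended for exercising
#' [parcellate()]; not an anatomical simulation.
#'
#' @param series A [roi_ts] object.
#' @param voxels_per_roi Number of voxels per region (>= 1).
#' @param noise_sd Standard deviation of independent voxel noise.
#' @param seed Integer seed for the voxel noise.
#' @return A list with `volume` (4D array, x-y-z-time) and `labels` (3D
#'   integer array; labels `1..n_nodes`, 0 = background).
#' @export
render_toy_nifti <- function(series, voxels_per_roi = 3, noise_sd = 0,
                             seed = 1) {
  stopifnot(inherits(series, "roi_ts"), voxels_per_roi >= 1)
  n <- n_nodes(series)
  v <- n_volumes(series)
  set.seed(as.integer(seed))
  vol <- array(0, dim = c(n, voxels_per_roi, 1L, v))
  for (t in seq_len(v)) {
    base <- matrix(series$data[, t], n, voxels_per_roi)
    if (noise_sd > 0) {
      base <- base + matrix(stats::rnorm(n * voxels_per_roi, sd = noise_sd),
                            n, voxels_per_roi)
    }
    vol[, , 1L, t] <- base
  }
  labels <- array(0L, dim = c(n, voxels_per_roi, 1L))
  labels[, , 1L] <- matrix(seq_len(n), n, voxels_per_roi)
  list(volume = vol, labels = labels)
}

#' Default attrition pattern
#'
#' Mirrors the emulated trial: 2 placebo subjects unusable from baseline
#' on, one treated subject lost from the post-treatment session, two more
#' treated and one placebo lost at follow-up (leaving 12 + 12 complete
#' cases from 15 + 15 enrolled).
#'
#' @return Data frame with columns `group`, `from_session`, `n`.
#' @export
default_dropout <- function() {
  data.frame(group = c("P", "OMT", "OMT", "P"),
             from_session = c("T0", "T1", "T2", "T2"),
             n = c(2L, 1L, 2L, 1L),
             stringsAsFactors = FALSE)
}

#' Default demographic targets for cohort synthesis
#'
#' Group-wise means and SDs of age, education and body-mass index, the
#' male fraction, and the Poisson mean of the somatic-dysfunction count
#' used by [make_cohort()].
#'
#' @return Nested list keyed by group.
#' @export
default_demographics <- function() {
  list(
    OMT = list(age = c(28.0, 5.5), education = c(16.0, 1.5),
               bmi = c(20.9, 6.1), p_male = 8 / 15),
    P = list(age = c(25.4, 3.2), education = c(16.1, 0.4),
             bmi = c(21.0, 6.6), p_male = 4 / 15),
    dysfunction_lambda = 5
  )
}

#' Generate a two-group, three-session cohort design table
#'
#' Builds a demographics and availability table for a randomized two-arm
#' design (treatment `"OMT"` vs placebo `"P"`) measured at sessions T0, T1,
#' T2. Continuous demographics are standardized within group to match the
#' requested means and SDs exactly; session availability follows the
#' dropout specification, where a subject dropped "from" a session lacks
#' that session and all later ones. Treated subjects always carry at least
#' one somatic dysfunction; placebo subjects may carry zero.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param dropout_spec Data frame with columns `group`, `from_session`,
#'   `n`; the default mirrors the trial's attrition (2 placebo from T0,
#'   1 treated from T1, 2 treated and 1 placebo from T2).
#'   Pass a zero-row data frame for no dropout.
#' @param demographics_spec List with per-group `age`, `education`, `bmi`
#'   (each `c(mean, sd)`) and `p_male`, plus `dysfunction_lambda` (Poisson
#'   mean of the somatic-dysfunction count).
#' @param seed Integer seed.
#' @return Data frame with one row per subject: `subject_id`, `group`,
#'   `has_T0`, `has_T1`, `has_T2`, `age`, `sex`, `education`, `bmi`,
#'   `n_dysfunctions`.
#' @export
#' @examples
#' coh <- make_cohort(n_per_group = 15, seed = 1)
#' table(coh$group)
make_cohort <- function(n_per_group = 15, dropout_spec = default_dropout(),
                        demographics_spec = default_demographics(),
                        seed = 1) {
  stopifnot(n_per_group >= 2)
  set.seed(as.integer(seed))
  groups <- c("OMT", "P")
  rows <- list()
  for (g in groups) {
    spec <- demographics_spec[[g]]
    n <- n_per_group
    draw_exact <- function(ms) {
      x <- stats::rnorm(n)
      ms[1] + ms[2] * as.numeric(scale(x))
    }
    n_male <- round(spec$p_male * n)
    sex <- sample(c(rep("M", n_male), rep("F", n - n_male)))
    lam <- demographics_spec$dysfunction_lambda
    dys <- if (g == "OMT") 1L + stats::rpois(n, lam - 1) else
      stats::rpois(n, lam)
    rows[[g]] <- data.frame(
      subject_id = sprintf("%s%02d", ifelse(g == "OMT", "O", "P"),
                           seq_len(n)),
      group = g,
      has_T0 = TRUE, has_T1 = TRUE, has_T2 = TRUE,
      age = draw_exact(spec$age),
      sex = sex,
      education = draw_exact(spec$education),
      bmi = draw_exact(spec$bmi),
      n_dysfunctions = dys,
      stringsAsFactors = FALSE
    )
  }
  coh <- do.call(rbind, rows)
  rownames(coh) <- NULL

  sessions <- c("T0", "T1", "T2")
  if (NROW(dropout_spec)) {
    for (i in seq_len(nrow(dropout_spec))) {
      g <- dropout_spec$group[i]
      from <- dropout_spec$from_session[i]
      k <- dropout_spec$n[i]
      stopifnot(from %in% sessions)
      # drop the last still-complete subjects of the group, deterministically
      complete <- which(coh$group == g & coh$has_T0 & coh$has_T1 & coh$has_T2)
      if (length(complete) < k) {
        stop("dropout_spec removes more subjects than available in group ", g)
      }
      pick <- utils::tail(complete, k)
      cut <- match(from, sessions)
      for (s in seq(cut, 3L)) {
        coh[[paste0("has_", sessions[s])]][pick] <- FALSE
      }
    }
  }
  coh
}

#' Sessions available for each cohort row
#' @param cohort A cohort table from [make_cohort()].
#' @return Named list mapping subject_id to a character vector of sessions.
#' @export
available_sessions <- function(cohort) {
  sessions <- c("T0", "T1", "T2")
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    sessions[c(cohort$has_T0[i], cohort$has_T1[i], cohort$has_T2[i])]
  })
  names(out) <- cohort$subject_id
  out
}
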