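#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes of a series (acquired before the
#' scanner magnetization reaches steady state). Physiological and motion
#' traces aligned to the same volumes must be truncated consistently by the
#' caller; [truncate_physio()] and standard matrix subsetting do this.
#'
#' @param series A [roi_ts] object.
#' @param n_discard Number of leading volumes to drop (default 5).
#' @return A [roi_ts] with `n_discard` fewer volumes.
#' @export
discard_initial <- function(series, n_discard = 5) {
  stopifnot(inherits(series, "roi_ts"), n_discard >= 0)
  v <- n_volumes(series)
  if (n_discard >= v) {
    stop("n_discard (", n_discard, ") must be smaller than the number of ",
         "volumes (", v, ")")
  }
  if (n_discard == 0) return(series)
  out <- series
  out$data <- series$data[, -seq_len(n_discard), drop = FALSE]
  out
}

#' Truncate a physiological recording to match discarded volumes
#' @param physio A [physio_recording].
#' @param n_discard Number of leading volumes to drop.
#' @return A [physio_recording] aligned to the truncated series.
#' @export
truncate_physio <- function(physio, n_discard = 5) {
  stopifnot(inherits(physio, "physio_recording"))
  if (n_discard == 0) return(physio)
  keep <- -seq_len(n_discard)
  physio_recording(physio$cardiac_phase[keep], physio$respiratory_phase[keep])
}

#' Confound design matrix
#'
#' @param matrix Numeric matrix, volumes by regressors.
#' @param names Column labels.
#' @return An object of class `confound_design`.
#' @export
confound_design <- function(matrix, names = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (is.null(names)) names <- sprintf("reg%02d", seq_len(ncol(matrix)))
  stopifnot(length(names) == ncol(matrix), all(is.finite(matrix)))
  colnames(matrix) <- names
  structure(list(matrix = matrix, names = names), class = "confound_design")
}

#' RETROICOR physiological regressor set
#'
#' Builds the 12-column Fourier design for phase-locked cardiac and
#' respiratory artifact removal: sine and cosine of the first two cardiac
#' harmonics (4 columns), of the first two respiratory harmonics (4), and
#' of the two multiplicative interaction phases, cardiac + respiratory and
#' cardiac - respiratory (4).
#'
#' A rank-deficient design (e.g. from constant phases) is detected and
#' reported with a warning; [regress_confounds()] will drop the collinear
#' columns.
#'
#' @param physio A [physio_recording] aligned to the series volumes.
#' @return A [confound_design] with `V` rows and 12 columns.
#' @export
retroicor_design <- function(physio) {
  stopifnot(inherits(physio, "physio_recording"))
  c1 <- physio$cardiac_phase
  r1 <- physio$respiratory_phase
  x <- cbind(
    sin(c1), cos(c1), sin(2 * c1), cos(2 * c1),
    sin(r1), cos(r1), sin(2 * r1), cos(2 * r1),
    sin(c1 + r1), cos(c1 + r1), sin(c1 - r1), cos(c1 - r1)
  )
  nm <- c("card_sin1", "card_cos1", "card_sin2", "card_cos2",
          "resp_sin1", "resp_cos1", "resp_sin2", "resp_cos2",
          "int_sin_sum", "int_cos_sum", "int_sin_diff", "int_cos_diff")
  d <- confound_design(x, nm)
  rk <- qr(cbind(1, x))$rank
  if (rk < ncol(x) + 1L) {
    warning("RETROICOR design is rank-deficient (rank ", rk - 1L,
            " of 12); collinear columns will be dropped at regression")
  }
  d
}

#' Frame-wise displacement from six motion parameters
#'
#' Summarizes per-volume head motion as the sum of absolute backward
#' differences of the three translations plus the three rotations converted
#' to arc length at a spherical head radius:
#' `FWD(t) = sum |d trans_i| + radius * sum |d rot_i|`. The first volume's
#' FWD is 0 by convention.
#'
#' @param motion Numeric matrix `V` x 6: translations (mm) in columns 1-3,
#'   rotations (radians) in columns 4-6.
#' @param head_radius_mm Head radius used to convert rotations to mm
#'   (default 50, the common convention).
#' @return Numeric vector of length `V`, in mm.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6L, nrow(motion) >= 2L, all(is.finite(motion)))
  d <- abs(diff(motion))
  fwd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fwd)
}

#' Motion confound regressors (FWD and its derivative)
#'
#' @param fwd Frame-wise displacement trace from
#'   [framewise_displacement()].
#' @return A [confound_design] with columns `fwd` and `fwd_deriv`
#'   (backward difference, first element 0).
#' @export
fwd_design <- function(fwd) {
  stopifnot(is.numeric(fwd), length(fwd) >= 2L)
  confound_design(cbind(fwd = fwd, fwd_deriv = c(0, diff(fwd))))
}

#' Low-frequency physiological rate regressors
#'
#' Sliding-window estimates of the instantaneous cardiac and respiratory
#' rate (Hz), computed from the phase increment over a centered window
#' (default 9 volumes) and demeaned. These capture slow heart-rate and
#' breathing-rate fluctuations that leak into the BOLD signal at low
#' frequency; the published variants of this correction differ in their
#' response models, so only the windowed rates themselves are offered, as
#' an optional design, off by default in [preprocess_session()].
#'
#' @param physio A [physio_recording].
#' @param tr Repetition time in seconds.
#' @param window_vols Window length in volumes (default 9).
#' @return A [confound_design] with columns `cardiac_rate`, `resp_rate`.
#' @export
rate_design <- function(physio, tr, window_vols = 9) {
  stopifnot(inherits(physio, "physio_recording"), window_vols >= 2)
  v <- length(physio$cardiac_phase)
  h <- floor(window_vols / 2)
  windowed_rate <- function(phase) {
    lo <- pmax(seq_len(v) - h, 1L)
    hi <- pmin(seq_len(v) + h, v)
    r <- (phase[hi] - phase[lo]) / ((hi - lo) * tr * 2 * pi)
    r - mean(r)
  }
  confound_design(cbind(cardiac_rate = windowed_rate(physio$cardiac_phase),
                        resp_rate = windowed_rate(physio$respiratory_phase)))
}

#' Regress confounds out of a time series
#'
#' Stacks the supplied confound designs, adds an intercept, and replaces
#' each node's series by its ordinary-least-squares residual. Collinear
#' columns are dropped (with a warning) via pivoted QR so the projection is
#' always well defined; residuals are orthogonal to every retained
#' regressor.
#'
#' @param series A [roi_ts] object.
#' @param ... One or more [confound_design] objects (or bare matrices) with
#'   rows equal to the volume count.
#' @return A [roi_ts] of residuals.
#' @export
regress_confounds <- function(series, ...) {
  stopifnot(inherits(series, "roi_ts"))
  designs <- list(...)
  v <- n_volumes(series)
  mats <- lapply(designs, function(d) {
    m <- if (inherits(d, "confound_design")) d$matrix else as.matrix(d)
    if (nrow(m) != v) {
      stop("confound design has ", nrow(m), " rows but the series has ",
           v, " volumes")
    }
    m
  })
  x <- cbind(intercept = rep(1, v), do.call(cbind, mats))
  dq <- qr(x)
  if (dq$rank < ncol(x)) {
    dropped <- colnames(x)[dq$pivot[-seq_len(dq$rank)]]
    warning("dropping ", length(dropped), " collinear confound column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, dq$pivot[seq_len(dq$rank)], drop = FALSE]
    dq <- qr(x)
  }
  resid <- t(qr.resid(dq, t(series$data)))
  out <- series
  dimnames(resid) <- dimnames(series$data)
  out$data <- resid
  out
}

#' Temporal cleaning: demean, detrend, de-spike, band-pass
#'
#' Applies, in order: mean removal, linear detrending, spike clipping and
#' zero-phase band-pass filtering to every node series.
#'
#' De-spiking uses a robust z-score (median / MAD): samples with `|z|`
#' above `despike_z` are clipped to the threshold value, preserving sign.
#' The band-pass is a 4th-order Butterworth applied forward and backward
#' (zero phase, squared magnitude response).
#'
#' @param series A [roi_ts] object.
#' @param band_hz Length-2 pass band in Hz (default `c(0.01, 0.15)`, the
#'   conventional resting-state band).
#' @param despike_z Robust z threshold for spike clipping (default 4).
#' @return A cleaned [roi_ts]; each node series has mean approximately 0.
#' @export
temporal_clean <- function(series, band_hz = c(0.01, 0.15), despike_z = 4) {
  stopifnot(inherits(series, "roi_ts"), length(band_hz) == 2L)
  if (band_hz[2] <= band_hz[1]) {
    stop("upper band edge must exceed lower band edge")
  }
  nyquist <- 1 / (2 * series$tr)
  if (band_hz[1] <= 0 || band_hz[2] >= nyquist) {
    stop("band must lie strictly inside (0, ", signif(nyquist, 3),
         ") Hz for TR = ", series$tr, " s")
  }
  v <- n_volumes(series)
  tt <- seq_len(v)
  tt_c <- tt - mean(tt)
  denom <- sum(tt_c^2)
  bf <- signal::butter(4, band_hz / nyquist, type = "pass")

  out <- series
  out$data <- t(apply(series$data, 1L, function(x) {
    x <- x - mean(x)                        # demean
    x <- x - (sum(x * tt_c) / denom) * tt_c # linear detrend
    med <- stats::median(x)
    s <- stats::mad(x)
    if (s > 0) {                            # de-spike (robust z clip)
      z <- (x - med) / s
      hi <- z > despike_z
      lo <- z < -despike_z
      x[hi] <- med + despike_z * s
      x[lo] <- med - despike_z * s
    }
    signal::filtfilt(bf, x)                 # zero-phase band-pass
  }))
  dimnames(out$data) <- dimnames(series$data)
  out
}

#' Average a 4D volume within atlas regions
#'
#' For each positive integer label in the atlas, averages the voxel time
#' series within that region; output rows are ordered by ascending label.
#'
#' @param volume4d 4D numeric array (x, y, z, time).
#' @param label_volume 3D integer array of the same spatial shape;
#'   non-negative labels, 0 = background.
#' @param tr Repetition time in seconds for the resulting series.
#' @param expected_labels Optional integer vector; if supplied, every listed
#'   label must be present in `label_volume`, otherwise an error names the
#'   missing label.
#' @param node_labels Optional ROI names (per ascending label); defaults to
#'   `ROI<label>`.
#' @param subject_id,session Metadata stored on the result.
#' @return A [roi_ts] with one row per label.
#' @export
parcellate <- function(volume4d, label_volume, tr = 3,
                       expected_labels = NULL, node_labels = NULL,
                       subject_id = NA_character_, session = NA_character_) {
  stopifnot(length(dim(volume4d)) == 4L, length(dim(label_volume)) == 3L)
  if (!all(dim(volume4d)[1:3] == dim(label_volume))) {
    stop("spatial dimensions of the 4D volume and the label volume differ")
  }
  lv <- as.integer(label_volume)
  if (any(lv < 0)) stop("labels must be non-negative integers")
  present <- sort(unique(lv[lv > 0L]))
  if (!is.null(expected_labels)) {
    missing <- setdiff(as.integer(expected_labels), present)
    if (length(missing)) {
      stop("label(s) with zero voxels: ", paste(missing, collapse = ", "))
    }
    present <- sort(as.integer(expected_labels))
  }
  if (length(present) == 0L) stop("label volume contains no positive labels")
  v <- dim(volume4d)[4]
  n_vox <- prod(dim(label_volume))
  mat <- matrix(volume4d, n_vox, v)
  keep <- lv > 0L & lv %in% present
  sums <- rowsum(mat[keep, , drop = FALSE], group = lv[keep])
  counts <- as.vector(table(factor(lv[keep], levels = present)))
  data <- sums / counts
  if (is.null(node_labels)) node_labels <- sprintf("ROI%d", present)
  roi_ts(data, tr = tr, node_labels = node_labels,
         subject_id = subject_id, session = session)
}

#' Full per-session confound removal and temporal cleaning
#'
#' Convenience wrapper applying the fixed stage order: discard initial
#' volumes, RETROICOR + frame-wise-displacement regression, then demean /
#' detrend / de-spike / band-pass.
#'
#' @param series A [roi_ts] object.
#' @param physio Optional [physio_recording] aligned to the *original*
#'   volumes (truncated internally).
#' @param motion Optional `V` x 6 motion-parameter matrix aligned to the
#'   original volumes.
#' @param n_discard Leading volumes to drop (default 5).
#' @param band_hz,despike_z,head_radius_mm Passed to the respective stages.
#' @param rate_regressors Logical; additionally include the low-frequency
#'   sliding-window cardiac/respiratory rate regressors of [rate_design()]
#'   (off by default).
#' @return A cleaned [roi_ts].
#' @export
preprocess_session <- function(series, physio = NULL, motion = NULL,
                               n_discard = 5, band_hz = c(0.01, 0.15),
                               despike_z = 4, head_radius_mm = 50,
                               rate_regressors = FALSE) {
  out <- discard_initial(series, n_discard)
  designs <- list()
  if (!is.null(physio)) {
    trunc <- truncate_physio(physio, n_discard)
    designs <- c(designs, list(retroicor_design(trunc)))
    if (isTRUE(rate_regressors)) {
      designs <- c(designs, list(rate_design(trunc, tr = series$tr)))
    }
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (n_discard > 0) motion <- motion[-seq_len(n_discard), , drop = FALSE]
    designs <- c(designs,
                 list(fwd_design(framewise_displacement(motion,
                                                        head_radius_mm))))
  }
  if (length(designs)) {
    out <- do.call(regress_confounds, c(list(out), designs))
  }
  temporal_clean(out, band_hz = band_hz, despike_z = despike_z)
}
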