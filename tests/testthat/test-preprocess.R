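make_series <- function(n = 4, v = 120, tr = 3, seed = 1) {
  set.seed(seed)
  roi_ts(matrix(rnorm(n * v), n, v), tr = tr)
}

test_that("initial-volume discard truncates and guards its bounds", {
  s <- make_series(v = 240)
  expect_equal(ncol(discard_initial(s, 5)$data), 235L)
  expect_identical(discard_initial(s, 0), s)
  expect_error(discard_initial(s, 240), "smaller than")
  p <- physio_recording(seq_len(240), seq_len(240) / 2)
  expect_equal(length(truncate_physio(p, 5)$cardiac_phase), 235L)
})

test_that("RETROICOR design has 12 aligned Fourier columns", {
  ph <- physio_recording(cumsum(runif(80, 1, 2)), cumsum(runif(80, 0.3, 0.6)))
  d <- retroicor_design(ph)
  expect_equal(dim(d$matrix), c(80L, 12L))
  expect_equal(sum(grepl("^card", d$names)), 4L)
  expect_equal(sum(grepl("^resp", d$names)), 4L)
  expect_equal(sum(grepl("^int", d$names)), 4L)
  expect_warning(retroicor_design(physio_recording(rep(1, 50), rep(2, 50))),
                 "rank-deficient")
})

test_that("a pure-harmonic contaminant is removed to numerical zero", {
  set.seed(3)
  ph <- physio_recording(cumsum(runif(100, 1.5, 2.5)),
                         cumsum(runif(100, 0.4, 0.7)))
  x <- 3 * sin(ph$cardiac_phase) - 2 * cos(2 * ph$respiratory_phase)
  s <- roi_ts(rbind(x), tr = 3)
  res <- regress_confounds(s, retroicor_design(ph))
  expect_lt(var(res$data[1, ]) / var(x), 1e-10)
})

test_that("frame-wise displacement follows the translation + arc-length formula", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))
  m[6:10, 1] <- 1                       # 1 mm x step between volumes 5 and 6
  fwd <- framewise_displacement(m)
  expect_equal(fwd[6], 1)
  expect_equal(fwd[7], 0)
  m2 <- matrix(0, 5, 6)
  m2[3:5, 4] <- 0.02                    # 0.02 rad step at 50 mm radius
  expect_equal(framewise_displacement(m2, head_radius_mm = 50)[3], 1)
  expect_equal(framewise_displacement(m2)[1], 0)
})

test_that("confound regression is an orthogonal projection", {
  s <- make_series(n = 5, v = 90, seed = 2)
  # intercept only: demeaning
  demeaned <- regress_confounds(s)
  expect_equal(demeaned$data, s$data - rowMeans(s$data), tolerance = 1e-12)
  expect_equal(regress_confounds(demeaned)$data, demeaned$data,
               tolerance = 1e-12)
  # input inside the design span leaves ~zero residual
  set.seed(4)
  d <- confound_design(matrix(rnorm(90 * 3), 90, 3))
  inside <- roi_ts(t(d$matrix %*% c(1, -2, 0.5)), tr = 3)
  expect_lt(max(abs(regress_confounds(inside, d)$data)), 1e-10)
  # residuals orthogonal to every regressor
  res <- regress_confounds(s, d)
  ip <- crossprod(t(res$data), cbind(1, d$matrix))
  expect_lt(max(abs(ip)) / max(abs(s$data)), 1e-8)
  # collinear columns are dropped with a warning, not an error
  dd <- confound_design(cbind(d$matrix, d$matrix[, 1]))
  expect_warning(regress_confounds(s, dd), "collinear")
  expect_error(regress_confounds(s, d$matrix[1:10, ]), "rows")
})

test_that("band-pass keeps in-band sinusoids and suppresses drift", {
  v <- 300; tr <- 3
  t_s <- (seq_len(v) - 1) * tr
  amp_out <- function(f) {
    x <- sin(2 * pi * f * t_s)
    y <- temporal_clean(roi_ts(rbind(x), tr = tr))$data[1, ]
    # amplitude at f via the discrete Fourier component
    2 * abs(sum(y * exp(-2i * pi * f * t_s))) / v
  }
  expect_equal(amp_out(0.05), 1, tolerance = 0.05)   # passband
  expect_lt(amp_out(0.005), 0.2)                     # stopband
  const <- temporal_clean(roi_ts(rbind(rep(5, v)), tr = tr))
  expect_equal(max(abs(const$data)), 0, tolerance = 1e-9)
  expect_error(temporal_clean(make_series(), band_hz = c(0.15, 0.01)),
               "band")
  expect_error(temporal_clean(make_series(tr = 3), band_hz = c(0.01, 0.2)),
               "inside")
})

test_that("de-spiking clips robust-z outliers and only outliers", {
  set.seed(5)
  x <- rnorm(200)
  x[50] <- 25
  s <- roi_ts(rbind(x), tr = 3)
  # isolate the despike step by using an extremely wide band
  cleaned <- temporal_clean(s, despike_z = 4)$data[1, ]
  raw <- temporal_clean(s, despike_z = Inf)$data[1, ]
  expect_lt(max(abs(cleaned)), max(abs(raw)))
})

test_that("parcellation averages voxels by ascending label", {
  vol <- array(0, dim = c(2, 2, 1, 3))
  vol[1, , 1, ] <- 3.0                       # label 1: constant 3
  vol[2, 1, 1, ] <- c(1, 2, 3)               # label 2: two voxels
  vol[2, 2, 1, ] <- c(3, 4, 5)
  lab <- array(c(1L, 2L, 1L, 2L), dim = c(2, 2, 1))
  ts <- parcellate(vol, lab, tr = 2)
  expect_equal(nrow(ts$data), 2L)
  expect_equal(unname(ts$data[1, ]), rep(3, 3))
  expect_equal(unname(ts$data[2, ]), c(2, 3, 4))
  expect_error(parcellate(vol, lab, expected_labels = 1:3), "zero voxels")
  expect_error(parcellate(vol, array(1L, dim = c(3, 3, 1))), "dimensions")
})

test_that("cleaning a contaminated series restores the correlation structure", {
  gt <- make_ground_truth(n_nodes = 10, n_modules = 2, seed = 1)
  truth <- cov2cor(gt$base_covariance)
  wins <- 0L
  for (seed in 1:20) {
    b <- simulate_bold(gt, "OMT", "T0", n_volumes = 160, seed = seed)
    cont <- add_physio(b, amplitudes = c(cardiac = 1.5, resp = 1.2),
                       seed = seed)
    mot <- simulate_motion(160, seed = seed)
    clean <- preprocess_session(cont$series, physio = cont$physio,
                                motion = mot)
    d_cont <- norm(cor(t(cont$series$data)) - truth, "F")
    d_clean <- norm(cor(t(clean$data)) - truth, "F")
    wins <- wins + (d_clean < d_cont)
  }
  expect_gte(wins, 18L)
})

test_that("sliding-window rate regressors track the injected rates", {
  v <- 200; tr <- 3
  t_s <- (seq_len(v) - 1) * tr
  f_c <- 1.1 + 0.05 * sin(2 * pi * t_s / 300)
  ph_c <- 2 * pi * c(0, cumsum(f_c[-v] * tr))
  ph_r <- 2 * pi * 0.3 * t_s
  d <- rate_design(physio_recording(ph_c, ph_r), tr = tr)
  expect_equal(dim(d$matrix), c(200L, 2L))
  # demeaned estimate correlates strongly with the true rate modulation
  expect_gt(cor(d$matrix[, "cardiac_rate"], f_c - mean(f_c)), 0.95)
  # constant respiratory rate: regressor is numerically flat
  expect_lt(max(abs(d$matrix[, "resp_rate"])), 1e-10)
  s <- roi_ts(matrix(rnorm(3 * 100), 3, 100), tr = 3)
  cont <- add_physio(s, seed = 1)
  clean <- preprocess_session(cont$series, physio = cont$physio,
                              rate_regressors = TRUE)
  expect_equal(ncol(clean$data), 95L)
})
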