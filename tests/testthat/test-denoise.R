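# Confound removal: FD, outlier flagging, exclusion rule, nuisance
# regression, bandpass, masked smoothing.

make_session <- function(data4d, tr = 3, mp = NULL,
                         mask = array(TRUE, dim(data4d)[1:3])) {
  bold_session(data4d, mask, tr, "sX", "placebo", mp)
}

test_that("framewise displacement follows the composite-motion formula", {
  # constant parameters: zero displacement throughout
  mp <- matrix(0.3, 10, 6)
  expect_equal(framewise_displacement(mp), rep(0, 9))
  # one 0.6 mm translation step
  mp <- matrix(0, 5, 6); mp[3:5, 1] <- 0.6
  expect_equal(framewise_displacement(mp), c(0, 0.6, 0, 0))
  # a 0.01 rad rotation at 50 mm radius contributes 0.5 mm of arc
  mp <- matrix(0, 4, 6); mp[2:4, 5] <- 0.01
  expect_equal(framewise_displacement(mp), c(0.5, 0, 0))
  # head radius is configurable
  expect_equal(framewise_displacement(mp, head_radius_mm = 100),
               c(1.0, 0, 0))
  expect_error(framewise_displacement(matrix(0, 1, 6)), "2 volumes")
})

test_that("outlier detection applies the 0.5 mm / 3 SD rule", {
  set.seed(1)
  arr <- array(rnorm(4 * 4 * 3 * 6), c(4, 4, 3, 6))
  s <- make_session(arr)
  # quiet global signal, provided FD series: only the >0.5 volume flags
  det <- detect_outliers(s, fd_series = c(0.1, 0.6, 0.2, 0.1, 0.3))
  expect_equal(which(det$outlier_flags), 3L)  # FD(t) flags volume t
  # constant signal, zero motion: nothing flags
  s0 <- make_session(array(1, c(4, 4, 3, 6)), mp = matrix(0, 6, 6))
  expect_false(any(detect_outliers(s0)$outlier_flags))
  # synthetic spikes are recovered at the default thresholds
  tr <- small_truth()
  sess <- simulate_session(tr, small_spec(spike_prob = 0.1, noise_sd = 1),
                           seed = 99)
  det2 <- detect_outliers(sess)
  truth_spikes <- sess$truth$spike_volumes
  expect_gte(mean(truth_spikes %in% which(det2$outlier_flags)), 0.9)
})

test_that("subject exclusion uses strict inequalities in either session", {
  # passing sessions at the reported residual-motion levels
  ok <- subject_exclusion(list(rep(0.15, 100), rep(0.19, 100)))
  expect_false(ok$excluded)
  # 51% of volumes above threshold in one scan
  fd_bad <- c(rep(0.6, 51), rep(0.1, 49))
  expect_true(subject_exclusion(list(rep(0.1, 100), fd_bad))$excluded)
  # boundary: mean FD exactly 0.5 is retained
  expect_false(subject_exclusion(list(rep(0.5, 100)))$excluded)
  expect_true(subject_exclusion(list(rep(0.5 + 1e-9, 100)))$excluded)
})

test_that("confound matrix has the documented columns and rank repair", {
  set.seed(2)
  arr <- array(rnorm(4 * 4 * 3 * 20), c(4, 4, 3, 20))
  s <- make_session(arr)
  tis <- tissue_surrogates(s)
  # no flags, no motion table: intercept + 2 drifts + wm + csf
  X <- build_confound_matrix(s, NULL, tis)
  expect_equal(ncol(X), 5L)
  # 3 flagged volumes with a motion table: 5 + 12 + 3 = 20
  s2 <- make_session(arr, mp = matrix(rnorm(120, sd = 0.01), 20, 6))
  flags <- rep(FALSE, 20); flags[c(3, 9, 15)] <- TRUE
  X2 <- build_confound_matrix(s2, flags, tis)
  expect_equal(ncol(X2), 20L)
  expect_true(all(c("spike3", "spike9", "spike15") %in% colnames(X2)))
  # duplicated tissue signal: one of the five columns dropped and recorded
  X3 <- build_confound_matrix(s, NULL, list(wm = tis$wm, csf = tis$wm))
  expect_equal(ncol(X3), 4L)
  expect_equal(attr(X3, "dropped"), "csf")
  # scrubbing everything is an error
  expect_error(build_confound_matrix(s, rep(TRUE, 20), tis),
               "all volumes")
})

test_that("confound regression is an orthogonal projection", {
  set.seed(3)
  T <- 30
  arr <- array(rnorm(3 * 3 * 2 * T), c(3, 3, 2, T))
  s <- make_session(arr)
  X <- cbind(1, seq_len(T) / T, (seq_len(T) / T)^2)
  colnames(X) <- c("intercept", "drift1", "drift2")
  # data equal to a nuisance column vanish
  s_col <- s
  for (v in 1:T) s_col$data[, , , v] <- X[v, 2]
  r1 <- regress_confounds(s_col, X)
  expect_lt(max(abs(r1$data)), 1e-8)
  # planted quadratic drift of amplitude 10 is removed
  s_drift <- s
  drift <- 10 * (seq_len(T) / T)^2
  for (v in 1:T) s_drift$data[, , , v] <- s_drift$data[, , , v] + drift[v]
  r2 <- regress_confounds(s_drift, X)
  resid_fit <- lm(as.vector(r2$data[1, 1, 1, ]) ~ poly(seq_len(T), 2))
  expect_lt(max(abs(coef(resid_fit)[-1])), 1e-6)
  # data orthogonal to the design are only demeaned
  ortho <- qr.resid(qr(X), matrix(rnorm(T * 4), T, 4))
  s_orth <- make_session(array(t(ortho), c(2, 2, 1, T)))
  r3 <- regress_confounds(s_orth, X)
  expect_equal(r3$data, s_orth$data, tolerance = 1e-10)
  # residuals at scrubbed volumes are exactly zero
  flags <- rep(FALSE, T); flags[c(5, 12)] <- TRUE
  Xs <- build_confound_matrix(s, flags, NULL)
  r4 <- regress_confounds(s, Xs)
  expect_lt(max(abs(r4$data[, , , c(5, 12)])), 1e-10)
  # rank-deficient designs are refused with the offending column named
  Xbad <- cbind(X, drift1b = X[, 2])
  expect_error(regress_confounds(s, Xbad), "drift1b")
})

test_that("the cleaning chain is idempotent on its own output", {
  # regression (with band-limited regressors) + ideal bandpass: a second
  # pass is a no-op. Spike indicators are broadband by nature, so strict
  # idempotence holds on sessions without scrubbed volumes; smoothing is
  # excluded (two Gaussian passes compose to a wider kernel by design).
  tr <- small_truth()
  s <- simulate_session(tr, small_spec(spike_prob = 0, noise_sd = 0.5),
                        seed = 1)
  d1 <- denoise_session(s, fwhm_mm = 0)
  expect_false(any(d1$confounds$outlier_flags))
  d2 <- denoise_session(d1$session, fwhm_mm = 0, confounds = d1$confounds)
  expect_lt(max(abs(d2$session$data - d1$session$data)),
            1e-8 * max(abs(d1$session$data)))
  # with spikes, scrubbed volumes are exactly zero right after regression
  s2 <- simulate_session(tr, small_spec(spike_prob = 0.05, noise_sd = 1),
                         seed = 5)
  d3 <- denoise_session(s2, fwhm_mm = 0)
  flagged <- which(d3$confounds$outlier_flags)
  expect_gt(length(flagged), 0)
  r <- regress_confounds(s2, d3$confounds$nuisance_matrix)
  expect_lt(max(abs(r$data[, , , flagged])), 1e-9)
})

test_that("bandpass is an ideal zero-phase frequency mask", {
  T <- 1000; tr <- 3
  t_sec <- (seq_len(T) - 1) * tr
  # 0.05 Hz (on-bin) passes within 1%; 0.002 Hz is suppressed below 1%
  pass <- sin(2 * pi * 0.05 * t_sec)
  stop_ <- sin(2 * pi * 0.002 * t_sec)
  arr <- array(0, c(2, 1, 1, T))
  arr[1, 1, 1, ] <- pass
  arr[2, 1, 1, ] <- stop_
  out <- bandpass(make_session(arr, tr = tr))
  amp <- function(x) (max(x) - min(x)) / 2
  expect_equal(amp(out$data[1, 1, 1, ]), 1, tolerance = 0.01)
  expect_lt(amp(out$data[2, 1, 1, ]), 0.01)
  # constant series: zero after DC removal
  cst <- make_session(array(7, c(2, 1, 1, 50)), tr = tr)
  expect_lt(max(abs(bandpass(cst)$data)), 1e-10)
  # cutoffs above Nyquist are clamped with a warning (0.9 vs 0.167 Hz)
  s <- make_session(array(rnorm(100), c(2, 1, 1, 50)), tr = 3)
  expect_warning(bandpass(s, 0.008, 0.9), "Nyquist")
  expect_error(bandpass(s, 0.2, 0.3), "Nyquist")
})

test_that("masked Gaussian smoothing matches the discrete kernel oracle", {
  mask <- array(TRUE, c(11, 11, 9))
  arr <- array(0, c(11, 11, 9, 2))
  arr[6, 6, 5, ] <- 1
  s <- make_session(arr, mask = mask)
  sm <- smooth_session(s, fwhm_mm = 6, voxel_size_mm = c(3, 3, 3))
  # direct kernel-sum oracle at the impulse center
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  r <- ceiling(4 * sigma)
  k1 <- exp(-0.5 * ((-r):r / sigma)^2); k1 <- k1 / sum(k1)
  expect_equal(sm$data[6, 6, 5, 1], k1[r + 1]^3, tolerance = 1e-12)
  expect_equal(sm$data[, , , 1], sm$data[, , , 2], tolerance = 1e-12)
  # fwhm = 0 is the identity
  expect_identical(smooth_session(s, fwhm_mm = 0)$data, s$data)
  # constant field inside a full mask is preserved (mass conservation)
  cst <- make_session(array(3, c(8, 8, 6, 2)))
  smc <- smooth_session(cst, fwhm_mm = 6)
  expect_equal(smc$data, cst$data, tolerance = 1e-12)
  # voxels outside the mask are neither read nor written
  mask2 <- ellipsoid_mask(c(11, 11, 9))
  s2 <- make_session(arr + 100 * array(!mask2, c(11, 11, 9, 2)),
                     mask = mask2)
  sm2 <- smooth_session(s2, fwhm_mm = 6)
  expect_true(all(sm2$data[array(!mask2, c(11, 11, 9, 2))] == 0))
})

test_that("denoising improves edge recovery when spikes are present", {
  tr <- small_truth()
  sp <- small_spec(n_subjects = 1, spike_prob = 0.08, noise_sd = 1)
  z_err <- function(session) {
    tc <- network_timeseries(session, tr)
    z <- edge_matrix(tc)$z
    zt <- atanh(session$truth$edge_corr * (1 - 1e-12))
    mean(abs(z - zt)[upper.tri(z)])
  }
  errs <- vapply(1:6, function(seed) {
    s <- simulate_session(tr, sp, seed = seed)
    dn <- denoise_session(s)$session
    dn$truth <- s$truth
    c(raw = z_err(s), den = z_err(dn))
  }, numeric(2))
  expect_lt(mean(errs["den", ]), mean(errs["raw", ]))
})
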