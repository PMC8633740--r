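# Confound-removal stage: motion/global-signal outlier flagging, subject
# exclusion, nuisance regression (drift + motion + derivatives + tissue
# signals + spike regressors), zero-phase bandpass, masked Gaussian
# smoothing. Fixed order: outliers -> regression -> bandpass -> smoothing.

#' Framewise displacement from motion parameters
#'
#' Power-style composite motion: the sum of absolute backward differences of
#' the three translations plus the three rotations converted to arc length at
#' `head_radius_mm`. "Composite motion" has no universal formula; this is the
#' field standard and matches the 0.5 mm threshold scale.
#'
#' @param motion_params T x 6 matrix: translations x/y/z (mm) then rotations
#'   (radians).
#' @param head_radius_mm radius for the rotation-to-arc-length conversion.
#' @return numeric vector of length T-1, nonnegative, in mm.
#' @export
#' @examples
#' mp <- matrix(0, 5, 6); mp[3, 1] <- 0.6
#' framewise_displacement(mp)  # one 0.6 step in, one out
framewise_displacement <- function(motion_params, head_radius_mm = 50) {
  motion_params <- as.matrix(motion_params)
  if (nrow(motion_params) < 2L)
    stop("framewise displacement needs at least 2 volumes")
  stopifnot(ncol(motion_params) == 6L)
  d <- abs(diff(motion_params))
  as.numeric(rowSums(d[, 1:3, drop = FALSE]) +
             head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Flag motion/global-signal outlier volumes
#'
#' Volume t is flagged iff its framewise displacement exceeds `fd_thresh`
#' (conservative default 0.5 mm) or the z-scored within-mask global signal
#' change exceeds `gs_thresh` SD (default 3). The FD series is backward
#' looking, so a displacement between t-1 and t flags volume t; the first
#' volume can only be flagged by the global-signal criterion.
#'
#' @param session a [bold_session()].
#' @param fd_series optional precomputed [framewise_displacement()] vector;
#'   computed from `session$motion_params` when absent.
#' @param fd_thresh framewise-displacement threshold, mm.
#' @param gs_thresh global-signal z threshold, SD units.
#' @return list: `outlier_flags` (T logicals), `fd_series` (length T-1, or
#'   NULL without motion parameters), `global_z` (length T).
#' @export
detect_outliers <- function(session, fd_series = NULL, fd_thresh = 0.5,
                            gs_thresh = 3) {
  T <- n_volumes(session)
  if (is.null(fd_series) && !is.null(session$motion_params))
    fd_series <- framewise_displacement(session$motion_params)
  if (!is.null(fd_series) && length(fd_series) != T - 1L)
    stop("fd_series must have length T-1")
  gm <- colMeans(mask_matrix(session$data, session$mask))
  dg <- c(0, diff(gm))
  s <- sd(dg)
  global_z <- if (is.finite(s) && s > 0) (dg - mean(dg)) / s else rep(0, T)
  flags <- abs(global_z) > gs_thresh
  if (!is.null(fd_series)) flags <- flags | c(FALSE, fd_series > fd_thresh)
  list(outlier_flags = flags, fd_series = fd_series, global_z = global_z)
}

#' Subject-level motion exclusion rule
#'
#' A subject is excluded when, in either session, mean FD exceeds 0.5 mm or
#' more than 50% of volumes exceed 0.5 mm FD. Strict inequalities, following
#' the "> 0.5 mm" wording of the conservative scrubbing convention.
#'
#' @param fd_sessions list of FD vectors, one per session (both sessions of
#'   the subject).
#' @param fd_thresh mm threshold.
#' @param max_mean_fd mean-FD exclusion bound, mm.
#' @param max_frac fraction-of-bad-volumes exclusion bound.
#' @return list: `excluded` (logical) and `reason` (string or NA).
#' @export
subject_exclusion <- function(fd_sessions, fd_thresh = 0.5,
                              max_mean_fd = 0.5, max_frac = 0.5) {
  stopifnot(length(fd_sessions) >= 1L)
  for (i in seq_along(fd_sessions)) {
    fd <- fd_sessions[[i]]
    if (mean(fd) > max_mean_fd)
      return(list(excluded = TRUE,
                  reason = sprintf("session %d mean FD %.3f mm > %.2f", i,
                                   mean(fd), max_mean_fd)))
    if (mean(fd > fd_thresh) > max_frac)
      return(list(excluded = TRUE,
                  reason = sprintf("session %d: %.0f%% of volumes over %.2f mm",
                                   i, 100 * mean(fd > fd_thresh), fd_thresh)))
  }
  list(excluded = FALSE, reason = NA_character_)
}

#' Mean white-matter / CSF surrogate signals for synthetic sessions
#'
#' Synthetic grids carry no tissue segmentation. Sessions produced by the
#' study generator carry two designated signal-free subregions
#' (`$tissue_regions`, the stand-ins for white matter and CSF, chosen away
#' from every planted network just as anatomical WM/CSF lie outside gray
#' matter); their mean time series are returned. Sessions without
#' designated regions fall back to the lowest-x and highest-x deciles of
#' the mask.
#'
#' @param session a [bold_session()].
#' @return list with T-vectors `wm` and `csf`.
#' @export
tissue_surrogates <- function(session) {
  Y <- mask_matrix(session$data, session$mask)
  if (!is.null(session$tissue_regions)) {
    inmask <- which(as.logical(session$mask))
    wm_idx <- match(which(session$tissue_regions$wm), inmask)
    csf_idx <- match(which(session$tissue_regions$csf), inmask)
    return(list(wm = colMeans(Y[wm_idx, , drop = FALSE]),
                csf = colMeans(Y[csf_idx, , drop = FALSE])))
  }
  idx <- which(array(as.logical(session$mask), dim(session$mask)),
               arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  n <- nrow(idx)
  k <- max(1L, floor(n / 10))
  list(wm = colMeans(Y[ord[seq_len(k)], , drop = FALSE]),
       csf = colMeans(Y[ord[(n - k + 1):n], , drop = FALSE]))
}

#' Build the nuisance design matrix
#'
#' Columns: intercept; linear and quadratic drift; the 6 motion parameters
#' and their backward-difference first derivatives (when a motion table is
#' present); white-matter and CSF signals; one indicator column per flagged
#' volume (scrubbing). Near-collinear columns are dropped by QR rank
#' detection and recorded in attribute `dropped`.
#'
#' @param session a [bold_session()].
#' @param outlier_flags T logicals (from [detect_outliers()]); NULL for none.
#' @param tissue_signals list with T-vectors `wm`, `csf` (see
#'   [tissue_surrogates()]); NULL omits them.
#' @param drift_order polynomial drift order (default 2).
#' @return T x P numeric matrix with column names; attribute `dropped` lists
#'   removed near-collinear columns.
#' @export
build_confound_matrix <- function(session, outlier_flags = NULL,
                                  tissue_signals = NULL, drift_order = 2L) {
  T <- n_volumes(session)
  t_std <- seq_len(T) / T
  X <- cbind(intercept = rep(1, T))
  for (p in seq_len(drift_order))
    X <- cbind(X, setNames(data.frame(t_std^p), paste0("drift", p)))
  X <- as.matrix(X)
  if (!is.null(session$motion_params)) {
    mp <- as.matrix(session$motion_params)
    dmp <- rbind(0, diff(mp))
    colnames(mp) <- paste0("motion", 1:6)
    colnames(dmp) <- paste0("dmotion", 1:6)
    X <- cbind(X, mp, dmp)
  }
  if (!is.null(tissue_signals))
    X <- cbind(X, wm = tissue_signals$wm, csf = tissue_signals$csf)
  if (!is.null(outlier_flags) && any(outlier_flags)) {
    if (all(outlier_flags))
      stop("all volumes flagged as outliers: nothing left to analyze")
    flagged <- which(outlier_flags)
    S <- matrix(0, T, length(flagged))
    S[cbind(flagged, seq_along(flagged))] <- 1
    colnames(S) <- paste0("spike", flagged)
    X <- cbind(X, S)
  }
  # drop near-collinear columns (pivoted out by rank-revealing QR)
  qrX <- qr(X, tol = 1e-7)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    X <- X[, keep, drop = FALSE]
  }
  attr(X, "dropped") <- dropped
  X
}

#' Regress confounds out of a session
#'
#' Per-voxel ordinary least squares against the nuisance matrix; residuals
#' replace the data. The intercept column guarantees zero-mean residual
#' series, and spike-indicator columns force exactly-zero residuals at
#' flagged volumes.
#'
#' @param session a [bold_session()].
#' @param nuisance_matrix T x P full-rank matrix from
#'   [build_confound_matrix()].
#' @return the residual [bold_session()].
#' @export
regress_confounds <- function(session, nuisance_matrix) {
  X <- as.matrix(nuisance_matrix)
  T <- n_volumes(session)
  stopifnot(nrow(X) == T)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("nuisance matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- t(mask_matrix(session$data, session$mask))   # T x V
  res <- qr.resid(qrX, Y)
  out <- session
  out$data <- unmask_matrix(t(res), session$mask)
  out
}

#' Zero-phase frequency-mask bandpass filter
#'
#' Ideal (hard-mask) bandpass in the frequency domain, applied per voxel:
#' Fourier bins with frequency in `[low_hz, high_hz]` are kept, all others
#' (including DC) zeroed; the inverse transform is exactly zero phase. A high
#' cutoff above the Nyquist frequency `1/(2 TR)` is clamped to 0.99 Nyquist
#' with a warning (printed acquisition parameters occasionally quote cutoffs
#' above Nyquist, e.g. 0.9 where 0.09 Hz is meant).
#'
#' @param session a [bold_session()].
#' @param low_hz,high_hz passband edges, Hz (defaults 0.008 and 0.09).
#' @return the filtered [bold_session()].
#' @export
bandpass <- function(session, low_hz = 0.008, high_hz = 0.09) {
  T <- n_volumes(session)
  nyq <- 1 / (2 * session$tr_seconds)
  if (low_hz >= nyq) stop("low cutoff is at or above the Nyquist frequency")
  if (low_hz < 0 || high_hz <= low_hz) stop("need 0 <= low_hz < high_hz")
  if (high_hz > nyq) {
    warning(sprintf("high cutoff %.3g Hz exceeds Nyquist (%.3g Hz); clamped",
                    high_hz, nyq))
    high_hz <- 0.99 * nyq
  }
  Y <- t(mask_matrix(session$data, session$mask))       # T x V
  out <- session
  out$data <- unmask_matrix(
    t(bandpass_matrix(Y, session$tr_seconds, low_hz, high_hz)),
    session$mask)
  out
}

# hard frequency-mask filter on the columns of a T x V matrix
bandpass_matrix <- function(Y, tr_seconds, low_hz, high_hz) {
  T <- nrow(Y)
  freqs <- (seq_len(T) - 1) / (T * tr_seconds)
  freqs <- pmin(freqs, 1 / tr_seconds - freqs)          # two-sided
  keep <- freqs >= low_hz & freqs <= high_hz
  Yf <- stats::mvfft(Y)
  Yf[!keep, ] <- 0
  Re(stats::mvfft(Yf, inverse = TRUE)) / T
}

# normalized 1D Gaussian kernel, truncated at 4 sigma
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k / sum(k)
}

# separable 1D convolution of a 3D array along axis `ax`, zero padded
conv_axis <- function(vol, k, ax) {
  if (length(k) == 1L) return(vol)
  r <- (length(k) - 1L) / 2L
  dm <- dim(vol)
  out <- array(0, dm)
  for (off in (-r):r) {
    w <- k[off + r + 1L]
    src <- seq_len(dm[ax]) - off
    ok <- src >= 1L & src <= dm[ax]
    idx_to <- which(ok)
    idx_from <- src[ok]
    if (ax == 1L) out[idx_to, , ] <- out[idx_to, , ] + w * vol[idx_from, , ]
    else if (ax == 2L) out[, idx_to, ] <- out[, idx_to, ] + w * vol[, idx_from, ]
    else out[, , idx_to] <- out[, , idx_to] + w * vol[, , idx_from]
  }
  out
}

smooth_volume_masked <- function(vol, mask, sigma_vox) {
  m <- array(as.numeric(mask), dim(mask))
  num <- vol * m
  den <- m
  for (ax in 1:3) {
    k <- gauss_kernel(sigma_vox[ax])
    num <- conv_axis(num, k, ax)
    den <- conv_axis(den, k, ax)
  }
  out <- array(0, dim(vol))
  inside <- as.logical(mask) & den > 0
  out[inside] <- num[inside] / den[inside]
  out
}

#' Masked Gaussian spatial smoothing
#'
#' Per-volume Gaussian smoothing with sigma = `fwhm_mm / (2 sqrt(2 ln 2))`
#' per axis (in voxel units), restricted to the mask: values outside the mask
#' are neither read nor written (normalized masked convolution), so a
#' constant field inside the mask is preserved exactly.
#'
#' @param session a [bold_session()].
#' @param fwhm_mm full width at half maximum, mm (default 6).
#' @param voxel_size_mm voxel edge lengths, mm.
#' @return the smoothed [bold_session()].
#' @export
smooth_session <- function(session, fwhm_mm = 6, voxel_size_mm = c(3, 3, 3)) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(session)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  out <- session
  for (t in seq_len(n_volumes(session)))
    out$data[, , , t] <- smooth_volume_masked(session$data[, , , t],
                                              session$mask, sigma_vox)
  out
}

#' Full denoising pass over one session
#'
#' Fixed order: outlier detection, confound regression (drift, motion and
#' derivatives, tissue surrogates, spike regressors), bandpass, smoothing.
#' Steps can be switched off by setting their parameter to NULL/0.
#'
#' @param session a [bold_session()].
#' @param fd_thresh,gs_thresh outlier thresholds (mm, SD).
#' @param drift_order polynomial drift order.
#' @param low_hz,high_hz bandpass edges; `NULL` skips filtering.
#' @param fwhm_mm smoothing kernel; 0 skips smoothing.
#' @param voxel_size_mm voxel size for smoothing.
#' @param confounds optional precomputed confound set (the `confounds`
#'   element of an earlier call); when supplied, outlier detection and
#'   design construction are skipped and the given nuisance matrix is used
#'   as is.
#' @details When filtering is enabled, the continuous nuisance regressors
#'   (drift, motion, tissue) are band-limited with the same passband before
#'   the regression, so that the regression and the filter commute; with
#'   smoothing disabled the cleaning chain is then exactly idempotent.
#'   Spatial Gaussian smoothing, by construction, is not (two passes
#'   compose to a wider kernel).
#' @return list: `session` (denoised), `confounds` (flags, FD, global z,
#'   nuisance matrix).
#' @export
denoise_session <- function(session, fd_thresh = 0.5, gs_thresh = 3,
                            drift_order = 2L, low_hz = 0.008, high_hz = 0.09,
                            fwhm_mm = 6, voxel_size_mm = c(3, 3, 3),
                            confounds = NULL) {
  filtering <- !is.null(low_hz) && !is.null(high_hz)
  if (is.null(confounds)) {
    det <- detect_outliers(session, fd_thresh = fd_thresh,
                           gs_thresh = gs_thresh)
    tissue <- tissue_surrogates(session)
    X <- build_confound_matrix(session, det$outlier_flags, tissue,
                               drift_order)
    if (filtering) {
      # band-limit the continuous nuisance regressors so regression and
      # filtering commute (avoids reintroducing removed frequencies);
      # intercept and spike indicators are left unfiltered
      cont <- !grepl("^(intercept|spike)", colnames(X))
      if (any(cont))
        X[, cont] <- bandpass_matrix(X[, cont, drop = FALSE],
                                     session$tr_seconds, low_hz, high_hz)
      qrX <- qr(X, tol = 1e-7)
      if (qrX$rank < ncol(X)) {
        keep <- sort(qrX$pivot[seq_len(qrX$rank)])
        attr_drop <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
        X <- X[, keep, drop = FALSE]
        attr(X, "dropped") <- attr_drop
      }
    }
    confounds <- list(outlier_flags = det$outlier_flags,
                      fd_series = det$fd_series, global_z = det$global_z,
                      nuisance_matrix = X)
  }
  out <- regress_confounds(session, confounds$nuisance_matrix)
  if (filtering) out <- bandpass(out, low_hz, high_hz)
  if (fwhm_mm > 0) out <- smooth_session(out, fwhm_mm, voxel_size_mm)
  list(session = out, confounds = confounds)
}
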