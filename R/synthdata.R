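# Synthetic paired drug/placebo study generator. The generative model is the
# converse of dual regression: K planted spatial networks (compact Gaussian
# blobs), K-dimensional Gaussian network time courses with a prescribed
# between-network correlation, voxel signal = maps x time courses + white
# noise, plus occasional motion-spike volumes and drug-responsive ratings.
# Everything downstream is validated against the recorded ground truth.

#' Study specification for the synthetic generator
#'
#' Bundles every generator parameter. The defaults emulate the acquisition
#' and sample of a typical single-dose crossover stimulant study: 22
#' subjects, two sessions, TR 3 s, 124 volumes.
#'
#' @param n_subjects number of subjects (each contributes a placebo and a
#'   drug session).
#' @param tr_seconds repetition time, seconds.
#' @param n_volumes volumes per session.
#' @param n_networks number of planted networks K.
#' @param edge_corr_placebo K x K correlation matrix of network time courses
#'   in the placebo condition (default: weak 0.1 background coupling with one
#'   stronger 0.4 cortical-cortical edge between networks 2 and 3).
#' @param edge_delta_drug K x K additive change applied in the drug condition
#'   (default: a thalamus-like hub pattern, network 1 gaining 0.2 with
#'   networks 2 and 3 while the 2-3 edge loses 0.2; the paper-style
#'   between-network signature).
#' @param noise_sd white-noise standard deviation per voxel.
#' @param subject_sd SD of the subject-level random edge perturbation, shared
#'   across a subject's two sessions.
#' @param spike_prob per-volume probability of a motion-spike volume.
#' @param signal_band_hz frequency band of the network time courses
#'   (default 0.01-0.08 Hz, the canonical low-frequency resting-state
#'   range, inside the analysis passband); NULL for white courses.
#' @param grid_shape 3 integers, voxel grid.
#' @param seed master seed; every stream below derives from it.
#' @return object of class `study_spec`.
#' @export
study_spec <- function(n_subjects = 22L, tr_seconds = 3, n_volumes = 124L,
                       n_networks = 8L,
                       edge_corr_placebo = NULL, edge_delta_drug = NULL,
                       noise_sd = 1, subject_sd = 0.05, spike_prob = 0.03,
                       signal_band_hz = c(0.01, 0.08),
                       grid_shape = c(16L, 16L, 12L), seed = 1L) {
  K <- as.integer(n_networks)
  stopifnot(K >= 2L, n_subjects >= 1L, tr_seconds > 0, n_volumes >= 2L,
            noise_sd >= 0, subject_sd >= 0, spike_prob >= 0, spike_prob < 0.5)
  if (is.null(edge_corr_placebo)) {
    edge_corr_placebo <- matrix(0.1, K, K)
    diag(edge_corr_placebo) <- 1
    if (K >= 3) edge_corr_placebo[2, 3] <- edge_corr_placebo[3, 2] <- 0.4
  }
  if (is.null(edge_delta_drug)) {
    edge_delta_drug <- matrix(0, K, K)
    if (K >= 3) {
      edge_delta_drug[1, 2] <- edge_delta_drug[2, 1] <- 0.2
      edge_delta_drug[1, 3] <- edge_delta_drug[3, 1] <- 0.2
      edge_delta_drug[2, 3] <- edge_delta_drug[3, 2] <- -0.2
    }
  }
  validate_correlation(edge_corr_placebo, "edge_corr_placebo")
  validate_correlation(edge_corr_placebo + edge_delta_drug,
                       "edge_corr_placebo + edge_delta_drug")
  structure(list(
    n_subjects = as.integer(n_subjects), tr_seconds = tr_seconds,
    n_volumes = as.integer(n_volumes), n_networks = K,
    edge_corr_placebo = edge_corr_placebo, edge_delta_drug = edge_delta_drug,
    noise_sd = noise_sd, subject_sd = subject_sd, spike_prob = spike_prob,
    signal_band_hz = signal_band_hz,
    grid_shape = as.integer(grid_shape), seed = as.integer(seed)),
    class = "study_spec")
}

validate_correlation <- function(C, what) {
  if (!isSymmetric(unname(C), tol = 1e-8))
    stop(what, " must be symmetric")
  if (any(abs(diag(C) - 1) > 1e-8)) stop(what, " must have unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop(what, " is not positive semidefinite")
  invisible(TRUE)
}

# Repair a nearly-valid correlation matrix; attribute "projected" records
# whether a projection to the nearest correlation matrix was needed.
project_correlation <- function(C) {
  C <- (C + t(C)) / 2
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  projected <- FALSE
  if (min(ev) < 1e-10) {
    np <- tryCatch(Matrix::nearPD(C, corr = TRUE, keepDiag = TRUE),
                   error = function(e) NULL)
    if (is.null(np) || !np$converged)
      stop("correlation matrix could not be repaired (non-PSD)")
    C <- as.matrix(np$mat)
    projected <- TRUE
  }
  attr(C, "projected") <- projected
  C
}

#' Plant K compact network maps on a voxel grid
#'
#' Places K anisotropic Gaussian blobs (truncated at 5% of peak, zero outside
#' the mask) such that every pair of maps has in-mask spatial correlation
#' below `max_pair_cor`. Placement retries a bounded number of times; a mask
#' too small to separate K blobs raises an error.
#'
#' @param K number of networks (>= 2 for a study; 1 accepted for degenerate
#'   single-blob tests).
#' @param grid_shape 3 integers.
#' @param mask binary 3D array; defaults to [ellipsoid_mask()] on
#'   `grid_shape`.
#' @param seed integer seed (deterministic output).
#' @param max_pair_cor pairwise spatial correlation bound (default 0.3).
#' @param max_tries placement retries per blob before giving up.
#' @return object of class `ground_truth_networks`: list with `maps` (4D
#'   array x,y,z,K), `mask`, `grid_shape`, `network_labels`.
#' @export
generate_network_maps <- function(K, grid_shape = c(16L, 16L, 12L),
                                  mask = NULL, seed = 1L,
                                  max_pair_cor = 0.3, max_tries = 400L) {
  stopifnot(K >= 1L)
  if (is.null(mask)) mask <- ellipsoid_mask(grid_shape)
  stopifnot(all(dim(mask) == grid_shape))
  if (sum(mask) < 20 * K)
    stop("mask too small: need at least 20 voxels per network")
  mask <- array(as.logical(mask), dim(mask))
  idx <- which(mask, arr.ind = TRUE)
  maps <- array(0, dim = c(grid_shape, K))
  placed <- matrix(0, nrow = sum(mask), ncol = 0)
  with_seed(seed, {
    for (k in seq_len(K)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        ctr <- idx[sample.int(nrow(idx), 1L), ]
        sig <- runif(3, 1.1, 2.0)
        g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                         z = seq_len(grid_shape[3]))
        w <- exp(-0.5 * (((g$x - ctr[1]) / sig[1])^2 +
                         ((g$y - ctr[2]) / sig[2])^2 +
                         ((g$z - ctr[3]) / sig[3])^2))
        w[w < 0.05] <- 0                       # compact support
        vol <- array(w, dim = grid_shape)
        vol[!mask] <- 0
        v <- mask_vector(vol, mask)
        if (max(v) <= 0) next
        if (ncol(placed) > 0 &&
            any(abs(suppressWarnings(cor(v, placed))) >= max_pair_cor, na.rm = TRUE))
          next
        maps[, , , k] <- vol
        placed <- cbind(placed, v)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not place network ", k, " under the separation ",
             "constraint after ", max_tries, " tries; enlarge the mask or ",
             "reduce K")
    }
  })
  # designate two signal-free tissue-surrogate regions (the stand-ins for
  # white matter and CSF): voxels untouched by any planted map, split along
  # the x axis, ~10% of the mask each
  free <- which(mask & apply(maps, 1:3, max) <= 0)
  free_x <- arrayInd(free, grid_shape)[, 1]
  free <- free[order(free_x)]
  k10 <- max(1L, min(floor(length(free) / 2), round(0.1 * sum(mask))))
  wm <- array(FALSE, grid_shape); wm[free[seq_len(k10)]] <- TRUE
  csf <- array(FALSE, grid_shape)
  csf[free[(length(free) - k10 + 1):length(free)]] <- TRUE
  structure(list(maps = maps, mask = array(as.logical(mask), dim(mask)),
                 grid_shape = as.integer(grid_shape),
                 network_labels = sprintf("net%02d", seq_len(K)),
                 tissue_masks = list(wm = wm, csf = csf)),
            class = "ground_truth_networks")
}

#' @export
print.ground_truth_networks <- function(x, ...) {
  cat(sprintf("<ground_truth_networks> K = %d on grid %s (%d mask voxels)\n",
              dim(x$maps)[4], paste(x$grid_shape, collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

n_networks <- function(truth) dim(truth$maps)[4]

# in-mask voxel x K matrix of the truth maps
truth_matrix <- function(truth) {
  K <- n_networks(truth)
  vapply(seq_len(K), function(k) mask_vector(truth$maps[, , , k], truth$mask),
         numeric(sum(truth$mask)))
}

# T x K samples of a zero-mean unit-variance Gaussian with correlation C.
# Network fluctuations are band-limited (resting-state signal lives below
# ~0.1 Hz; that is the premise of the analysis bandpass): white draws are
# hard-filtered to `band_hz`, mixed to the target correlation, and column-
# standardized (filtering and mixing commute, so the correlation survives).
# band_hz = NULL gives white courses.
sample_timecourses <- function(T, C, tr_seconds = 3,
                               band_hz = c(0.01, 0.08)) {
  eta <- matrix(rnorm(T * ncol(C)), T, ncol(C))
  if (!is.null(band_hz) && T >= 8) {
    hi <- min(band_hz[2], 0.99 / (2 * tr_seconds))
    eta <- bandpass_matrix(eta, tr_seconds, band_hz[1], hi)
  }
  tc <- eta %*% chol(project_correlation(C))
  sweep(tc, 2, apply(tc, 2, sd), `/`)
}

#' Simulate one BOLD session from planted networks
#'
#' Draws `n_volumes` samples of a K-dimensional Gaussian with the requested
#' between-network correlation, projects them through the planted spatial
#' maps, adds white voxel noise, and inserts motion-spike volumes (a global
#' signal excursion plus a recorded head displacement above 0.5 mm) with
#' probability `spike_prob`. The generating time courses and the true spike
#' indices are recorded in the returned session (`$truth`).
#'
#' @param truth a [generate_network_maps()] result.
#' @param spec a [study_spec()].
#' @param edge_corr K x K correlation for this session (defaults to
#'   `spec$edge_corr_placebo`). If `edge_corr + subject_offsets` is not a
#'   valid correlation matrix it is projected to the nearest one and the
#'   projection recorded.
#' @param subject_offsets K x K symmetric zero-diagonal perturbation.
#' @param seed integer seed.
#' @param subject_id,condition labels carried on the session.
#' @return a [bold_session()] with an extra `truth` element: list
#'   `timecourses` (T x K), `spike_volumes` (integer indices),
#'   `edge_corr` (the realized, possibly projected, correlation matrix).
#' @export
simulate_session <- function(truth, spec, edge_corr = NULL,
                             subject_offsets = NULL, seed = 1L,
                             subject_id = "s01", condition = "placebo") {
  K <- n_networks(truth)
  if (is.null(edge_corr)) edge_corr <- spec$edge_corr_placebo
  if (is.null(subject_offsets)) subject_offsets <- matrix(0, K, K)
  stopifnot(all(dim(edge_corr) == c(K, K)),
            all(dim(subject_offsets) == c(K, K)))
  C <- project_correlation(edge_corr + subject_offsets)
  T <- spec$n_volumes
  X <- truth_matrix(truth)                      # V x K
  with_seed(seed, {
    tc <- sample_timecourses(T, C, spec$tr_seconds,
                             spec$signal_band_hz)   # T x K
    Y <- X %*% t(tc)                            # V x T
    if (spec$noise_sd > 0)
      Y <- Y + matrix(rnorm(length(Y), sd = spec$noise_sd), nrow(Y), ncol(Y))
    # motion parameters: small physiological jitter as a random walk
    mp <- apply(matrix(rnorm(T * 6, sd = rep(c(0.02, 0.0004), each = 3 * T)),
                       T, 6), 2, cumsum)
    spikes <- which(runif(T) < spec$spike_prob)
    if (length(spikes) > 0) {
      # global artifact: every voxel shifts by several noise SDs, which both
      # trips the global-signal detector and visibly corrupts raw edge
      # estimates (the realistic scale of a motion spike)
      gm_diff_sd <- sd(diff(colMeans(Y)))
      if (!is.finite(gm_diff_sd) || gm_diff_sd == 0) gm_diff_sd <- 1e-3
      amp <- max(4 * spec$noise_sd, 8 * gm_diff_sd) *
        sample(c(-1, 1), length(spikes), replace = TRUE)
      # common offset (trips the global-signal detector) plus a spatially
      # heterogeneous pattern of the same scale, including a component that
      # aliases into the planted networks: real motion artifacts are not
      # uniform and do corrupt network estimates, which is what scrubbing
      # is there to repair
      for (q in seq_along(spikes))
        Y[, spikes[q]] <- Y[, spikes[q]] +
          amp[q] * (1 + rnorm(nrow(Y)) + as.vector(X %*% rnorm(K)))
      # single-volume displacement excursion of 0.8 mm
      mp[spikes, 1] <- mp[spikes, 1] + 0.8
    }
  })
  session <- bold_session(unmask_matrix(Y, truth$mask), truth$mask,
                          spec$tr_seconds, subject_id, condition, mp)
  session$tissue_regions <- truth$tissue_masks
  session$truth <- list(timecourses = tc, spike_volumes = spikes,
                        edge_corr = C)
  session
}

#' Simulate a full paired drug/placebo study
#'
#' Per subject, one random symmetric edge perturbation (SD `subject_sd`) is
#' drawn once and shared across both sessions, creating the within-subject
#' correlation structure that the paired tests exploit; the drug session uses
#' `edge_corr_placebo + edge_delta_drug`. All seeds derive deterministically
#' from `spec$seed`.
#'
#' @param spec a [study_spec()].
#' @param truth optional pre-built [generate_network_maps()] result; by
#'   default K blobs are planted on the spec's grid.
#' @return list of class `synthetic_study`: `sessions` (list of
#'   2 x n_subjects [bold_session()]s, placebo and drug per subject), `truth`,
#'   `edge_truth` (per subject, per condition realized correlation matrices),
#'   and `spec`.
#' @export
simulate_paired_study <- function(spec, truth = NULL) {
  K <- spec$n_networks
  seeds <- derive_seeds(spec$seed, 1L + spec$n_subjects * 3L)
  if (is.null(truth))
    truth <- generate_network_maps(K, spec$grid_shape, seed = seeds[1])
  sessions <- list()
  edge_truth <- list()
  for (i in seq_len(spec$n_subjects)) {
    sid <- sprintf("s%02d", i)
    off <- with_seed(seeds[1 + (i - 1) * 3 + 1], {
      o <- matrix(0, K, K)
      o[upper.tri(o)] <- rnorm(K * (K - 1) / 2, sd = spec$subject_sd)
      o + t(o)
    })
    pl <- simulate_session(truth, spec, spec$edge_corr_placebo, off,
                           seed = seeds[1 + (i - 1) * 3 + 2],
                           subject_id = sid, condition = "placebo")
    dr <- simulate_session(truth, spec,
                           spec$edge_corr_placebo + spec$edge_delta_drug, off,
                           seed = seeds[1 + (i - 1) * 3 + 3],
                           subject_id = sid, condition = "drug")
    sessions[[paste0(sid, "_placebo")]] <- pl
    sessions[[paste0(sid, "_drug")]] <- dr
    edge_truth[[sid]] <- list(placebo = pl$truth$edge_corr,
                              drug = dr$truth$edge_corr)
  }
  structure(list(sessions = sessions, truth = truth, edge_truth = edge_truth,
                 spec = spec), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d subjects x 2 sessions, K = %d networks, grid %s\n",
    x$spec$n_subjects, x$spec$n_networks,
    paste(x$spec$grid_shape, collapse = "x")))
  invisible(x)
}

#' Ratings schedule for the subjective/cardiovascular generator
#'
#' @param timepoints_min minutes relative to dosing; the first must be
#'   negative (pre-dose baseline) and the rest strictly increasing. Default
#'   `c(-10, 15, 30, 75, 115, 200)`.
#' @param measures measure names.
#' @param drug_effect_size per-measure peak amplitude of the drug response
#'   (same units as the measure).
#' @param within_subject_sd Gaussian within-subject noise SD.
#' @param baseline per-measure pre-dose mean.
#' @return object of class `ratings_schedule`.
#' @export
ratings_schedule <- function(timepoints_min = c(-10, 15, 30, 75, 115, 200),
                             measures = c("arci_a", "heart_rate", "map"),
                             drug_effect_size = c(arci_a = 4, heart_rate = 15,
                                                  map = 8),
                             within_subject_sd = 1.5,
                             baseline = c(arci_a = 2, heart_rate = 65,
                                          map = 90)) {
  stopifnot(timepoints_min[1] < 0, all(diff(timepoints_min) > 0),
            sum(timepoints_min > 0) >= 2, within_subject_sd >= 0)
  drug_effect_size <- rep_len(drug_effect_size, length(measures))
  baseline <- rep_len(baseline, length(measures))
  names(drug_effect_size) <- names(baseline) <- measures
  structure(list(timepoints_min = timepoints_min, measures = measures,
                 drug_effect_size = drug_effect_size,
                 within_subject_sd = within_subject_sd, baseline = baseline),
            class = "ratings_schedule")
}

# Smooth rise-and-fall drug response, normalized so its maximum over the
# post-dose observed timepoints is exactly 1 (peak lands between the 2nd and
# 3rd post-dose timepoints).
drug_bump <- function(timepoints_min) {
  post <- timepoints_min[timepoints_min > 0]
  t_peak <- mean(post[2:3])
  width <- (max(post) - min(post)) / 2.5
  b <- exp(-0.5 * ((timepoints_min - t_peak) / width)^2)
  b[timepoints_min < 0] <- 0
  b / max(b[timepoints_min > 0])
}

#' Simulate drug-responsive rating time courses
#'
#' Placebo sessions fluctuate around the per-measure baseline; drug sessions
#' add a smooth rise-and-fall response peaking between the second and third
#' post-dose timepoints, with amplitude `drug_effect_size` scaled by a
#' per-subject sensitivity factor (mean 1, SD 0.25, floored at 0.2).
#'
#' @param schedule a [ratings_schedule()].
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return long-format `data.frame` with columns `subject`, `session`,
#'   `condition`, `time_min`, `measure`, `value`, plus attribute
#'   `sensitivity` (the per-subject factors).
#' @export
simulate_ratings <- function(schedule, n_subjects, seed = 1L) {
  tp <- schedule$timepoints_min
  bump <- drug_bump(tp)
  with_seed(seed, {
    sens <- pmax(rnorm(n_subjects, 1, 0.25), 0.2)
    rows <- list()
    for (i in seq_len(n_subjects)) {
      sid <- sprintf("s%02d", i)
      for (cond in c("placebo", "drug")) {
        for (m in schedule$measures) {
          mu <- schedule$baseline[[m]] +
            (cond == "drug") * schedule$drug_effect_size[[m]] * sens[i] * bump
          val <- mu + rnorm(length(tp), sd = schedule$within_subject_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = sid, session = if (cond == "placebo") 1L else 2L,
            condition = cond, time_min = tp, measure = m, value = val,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sensitivity") <- sens
  out
}

#' Write a synthetic study to disk
#'
#' Sessions go out as NIfTI-1 4D images (TR in the header) with motion text
#' files, the mask as 3D NIfTI, the planted maps as a 4D NIfTI, edge ground
#' truth as per-subject CSVs, and a sidecar JSON index.
#'
#' @param study a [simulate_paired_study()] result.
#' @param dir output directory (created if needed).
#' @param gz gzip the NIfTI images.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, gz = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$sessions))
    write_session(study$sessions[[nm]], file.path(dir, nm), gz = gz)
  ext <- if (gz) ".nii.gz" else ".nii"
  write_nifti(study$truth$maps, file.path(dir, paste0("truth_maps", ext)))
  for (sid in names(study$edge_truth)) {
    for (cond in c("placebo", "drug"))
      write.csv(study$edge_truth[[sid]][[cond]],
                file.path(dir, sprintf("edges_%s_%s.csv", sid, cond)),
                row.names = FALSE)
  }
  jsonlite::write_json(
    list(n_subjects = study$spec$n_subjects, n_networks = study$spec$n_networks,
         grid_shape = study$spec$grid_shape, seed = study$spec$seed,
         sessions = names(study$sessions),
         network_labels = study$truth$network_labels),
    file.path(dir, "study.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
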