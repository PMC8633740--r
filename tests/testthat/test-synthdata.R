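# Synthetic-study generator: planted maps, session simulation, paired
# studies, ratings.

test_that("planted network maps are compact, separated and deterministic", {
  tr <- generate_network_maps(5, c(12, 12, 10), seed = 7)
  X <- truth_mat(tr)
  # all 10 distinct-pair spatial correlations below the 0.3 bound
  pc <- cor(X)[upper.tri(diag(5))]
  expect_length(pc, 10L)
  expect_true(all(abs(pc) < 0.3))
  # zero outside mask, at least one strictly positive voxel each
  for (k in 1:5) {
    vol <- tr$maps[, , , k]
    expect_true(all(vol[!tr$mask] == 0))
    expect_gt(max(vol), 0)
  }
  # seeded determinism: bit-identical maps
  tr2 <- generate_network_maps(5, c(12, 12, 10), seed = 7)
  expect_identical(tr$maps, tr2$maps)
  # K = 1: single blob peaks at its center voxel
  one <- generate_network_maps(1, c(9, 9, 7), seed = 2)
  expect_equal(max(one$maps[, , , 1]), 1, tolerance = 1e-12)
})

test_that("impossible placements fail loudly", {
  tiny <- array(TRUE, c(3, 3, 3))
  expect_error(generate_network_maps(4, c(3, 3, 3), mask = tiny),
               "mask too small")
  # a mask barely large enough in voxels but too cramped for separation
  m <- array(FALSE, c(30, 2, 2))
  m[1:30, 1:2, 1:2] <- TRUE
  expect_error(generate_network_maps(6, c(30, 2, 2), mask = m,
                                     max_tries = 5),
               "separation")
})

test_that("noiseless sessions are an exact linear mixture of the maps", {
  s <- noiseless_session()
  tr <- small_truth()
  X <- truth_mat(tr)
  Y <- s$data
  Ym <- matrix(Y, prod(dim(Y)[1:3]), dim(Y)[4])[as.logical(tr$mask), ]
  # stage-1 regression of the true maps recovers the generating courses
  rec <- qr.coef(qr(cbind(1, X)), Ym)[-1, ]
  expect_lt(max(abs(t(rec) - s$truth$timecourses)), 1e-8)
})

test_that("independent networks give uncorrelated recovered courses", {
  # K = 2, identity edge correlation, long series: |r| small
  tr <- generate_network_maps(2, c(10, 10, 8), seed = 21)
  sp <- study_spec(n_subjects = 1, n_networks = 2, n_volumes = 1000,
                   noise_sd = 0, spike_prob = 0,
                   grid_shape = c(10, 10, 8), seed = 21,
                   edge_corr_placebo = diag(2),
                   edge_delta_drug = matrix(0, 2, 2))
  s <- simulate_session(tr, sp, edge_corr = diag(2), seed = 5)
  r <- cor(s$truth$timecourses)[1, 2]
  expect_lt(abs(r), 0.15)
})

test_that("spike volumes are logged at the binomial rate and move the head", {
  tr <- small_truth()
  sp <- small_spec(spike_prob = 0.1, noise_sd = 1)
  counts <- vapply(1:50, function(seed)
    length(simulate_session(tr, sp, seed = seed)$truth$spike_volumes),
    numeric(1))
  # binomial(124, 0.1): mean 12.4, sd 3.34; the mean of 50 draws should sit
  # well within 4 standard errors
  expect_lt(abs(mean(counts) - 12.4), 4 * 3.34 / sqrt(50))
  # logged spikes carry a recorded displacement above the scrubbing threshold
  s <- simulate_session(tr, sp, seed = 11)
  fd <- framewise_displacement(s$motion_params)
  expect_true(all(fd[s$truth$spike_volumes[
    s$truth$spike_volumes > 1] - 1] > 0.5))
})

test_that("session duration follows TR and volume count", {
  s <- simulate_session(small_truth(), small_spec(), seed = 1)
  expect_equal(session_duration(s), 124 * 3)  # 372 s
})

test_that("paired studies share subject effects and honour the null", {
  sp <- small_spec(n_subjects = 3, subject_sd = 0.1,
                   edge_delta_drug = matrix(0, 5, 5))
  study <- simulate_paired_study(sp)
  expect_length(study$sessions, 6L)
  # null drug effect: ground-truth edge matrices identical per subject
  for (sid in names(study$edge_truth))
    expect_equal(study$edge_truth[[sid]]$placebo,
                 study$edge_truth[[sid]]$drug, tolerance = 1e-12)
  # reproducibility: identical spec -> bit-identical bundle
  study2 <- simulate_paired_study(sp)
  expect_identical(study$sessions[[1]]$data, study2$sessions[[1]]$data)
  expect_identical(study$sessions[[6]]$data, study2$sessions[[6]]$data)
  # with a drug delta the two conditions differ as prescribed
  sp2 <- small_spec(n_subjects = 2, subject_sd = 0)
  study3 <- simulate_paired_study(sp2)
  d <- study3$edge_truth$s01$drug - study3$edge_truth$s01$placebo
  expect_equal(d[1, 2], sp2$edge_delta_drug[1, 2], tolerance = 0.05)
})

test_that("edge ground truth is recovered from long generating courses", {
  # sample Fisher z of the generating courses converges to atanh(edge_corr)
  K <- 4
  C <- matrix(0.2, K, K); diag(C) <- 1; C[1, 2] <- C[2, 1] <- 0.5
  tr <- generate_network_maps(K, c(10, 10, 8), seed = 31)
  sp <- study_spec(n_subjects = 1, n_networks = K, n_volumes = 2000,
                   noise_sd = 0, spike_prob = 0, grid_shape = c(10, 10, 8),
                   seed = 31, edge_corr_placebo = C,
                   edge_delta_drug = matrix(0, K, K))
  s <- simulate_session(tr, sp, edge_corr = C, seed = 9)
  z_hat <- atanh(cor(s$truth$timecourses))
  bias <- abs(z_hat - atanh(C))[upper.tri(C)]
  expect_lt(max(bias), 0.05)
})

test_that("invalid correlation inputs are repaired or rejected", {
  K <- 3
  C <- matrix(0.9, K, K); diag(C) <- 1
  off <- matrix(0, K, K); off[1, 2] <- off[2, 1] <- 0.5  # pushes past PSD
  tr <- generate_network_maps(K, c(10, 10, 8), seed = 41)
  sp <- study_spec(n_subjects = 1, n_networks = K,
                   grid_shape = c(10, 10, 8), seed = 41,
                   edge_corr_placebo = diag(K),
                   edge_delta_drug = matrix(0, K, K))
  s <- simulate_session(tr, sp, edge_corr = C, subject_offsets = off,
                        seed = 2)
  expect_true(attr(s$truth$edge_corr, "projected"))
  ev <- eigen(s$truth$edge_corr, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # asymmetric spec matrices are rejected up front
  bad <- diag(K); bad[1, 2] <- 0.3
  expect_error(study_spec(n_networks = K, edge_corr_placebo = bad),
               "symmetric")
})

test_that("ratings generator matches its stated construction", {
  sch <- ratings_schedule()
  expect_equal(sch$timepoints_min, c(-10, 15, 30, 75, 115, 200))
  # noiseless drug response: PCS equals amplitude x subject sensitivity
  sch0 <- ratings_schedule(within_subject_sd = 0)
  rt <- simulate_ratings(sch0, 5, seed = 4)
  sens <- attr(rt, "sensitivity")
  pcs <- peak_change_score(rt, "arci_a")
  expect_equal(pcs$pcs_drug, sch0$drug_effect_size[["arci_a"]] * sens,
               tolerance = 1e-12)
  expect_equal(pcs$pcs_placebo, rep(0, 5), tolerance = 1e-12)
  # null amplitude: mean drug-placebo PCS difference ~ 0 across seeds
  schnull <- ratings_schedule(drug_effect_size = c(0, 0, 0),
                              within_subject_sd = 1)
  deltas <- vapply(1:100, function(seed) {
    mean(peak_change_score(simulate_ratings(schnull, 6, seed = seed),
                           "arci_a")$delta)
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 2 * sd(deltas) / sqrt(100))
})

test_that("a study round-trips through the NIfTI writer", {
  dir <- withr::local_tempdir()
  sp <- small_spec(n_subjects = 1)
  study <- simulate_paired_study(sp)
  write_study(study, dir)
  expect_true(file.exists(file.path(dir, "study.json")))
  back <- read_session(file.path(dir, "s01_placebo"))
  orig <- study$sessions$s01_placebo
  expect_equal(back$data, orig$data, tolerance = 1e-5,
               ignore_attr = TRUE)  # float32 payload
  expect_equal(back$tr_seconds, orig$tr_seconds)
  expect_equal(back$subject_id, "s01")
  expect_equal(as.matrix(back$motion_params),
               as.matrix(orig$motion_params),
               tolerance = 1e-6, ignore_attr = TRUE)
})
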