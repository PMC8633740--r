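# Dual regression, TFCE, sign-flip permutation inference, Bonferroni gate.

test_that("dual regression round-trips noiseless sessions", {
  s <- noiseless_session()
  tr <- small_truth()
  dr <- dual_regression(s, tr)
  # stage-1 courses match the generators up to scale
  cc <- abs(diag(cor(t(dr$timecourses), s$truth$timecourses)))
  expect_equal(unname(cc), rep(1, 5), tolerance = 1e-6)
  # unit-variance contract
  expect_equal(unname(apply(dr$timecourses, 1, var)), rep(1, 5),
               tolerance = 1e-6)
  # stage-2 maps correlate 1 with the generating maps
  X <- truth_mat(tr)
  expect_equal(unname(diag(cor(dr$maps, X))), rep(1, 5), tolerance = 1e-6)
})

test_that("single all-ones map yields the global mean course", {
  s <- noiseless_session()
  mask <- s$mask
  ones <- structure(list(
    maps = array(rep(as.numeric(mask), 1), c(dim(mask), 1)),
    mask = mask, grid_shape = dim(mask), network_labels = "global"),
    class = "ground_truth_networks")
  tc <- network_timeseries(s, ones)
  gm <- colMeans(metaconn:::mask_matrix(s$data, mask))
  expect_equal(abs(cor(tc[1, ], gm)), 1, tolerance = 1e-10)
})

test_that("null regressors produce near-zero stage-2 maps", {
  # add a network whose true presence is zero: its map stays at noise floor
  tr <- small_truth()
  sp <- small_spec(noise_sd = 0.05)
  s <- simulate_session(tr, sp, seed = 13)
  extra <- generate_network_maps(1, c(12, 12, 10), mask = tr$mask, seed = 99)
  aug <- tr
  aug$maps <- array(c(tr$maps, extra$maps), c(12, 12, 10, 6))
  aug$network_labels <- c(tr$network_labels, "null")
  dr <- dual_regression(s, aug)
  planted_scale <- max(abs(dr$maps[, 1:5]))
  expect_lt(max(abs(dr$maps[, 6])), 0.1 * planted_scale)
})

test_that("collinear consensus maps are rejected with the pair named", {
  tr <- small_truth()
  s <- noiseless_session()
  dup <- tr
  dup$maps <- array(c(tr$maps, tr$maps[, , , 1] * (1 + 1e-9)),
                    c(12, 12, 10, 6))
  dup$network_labels <- c(tr$network_labels, "dup")
  expect_error(dual_regression(s, dup), "collinear")
})

test_that("paired differences give the one-sample t with df N-1", {
  tr <- small_truth()
  sp <- small_spec(n_subjects = 5, edge_delta_drug = matrix(0, 5, 5))
  study <- simulate_paired_study(sp)
  ids <- sprintf("s%02d", 1:5)
  dr <- lapply(study$sessions, dual_regression, consensus = study$truth)
  pd <- paired_differences(dr[paste0(ids, "_drug")],
                           dr[paste0(ids, "_placebo")], 2)
  expect_equal(pd$df, 4L)
  # identical conditions: all-zero t map
  pd0 <- paired_differences(dr[paste0(ids, "_drug")],
                            dr[paste0(ids, "_drug")], 2)
  expect_true(all(pd0$t_map == 0))
  # against R's own t.test at a handful of voxels
  for (v in c(1, 17, 101)) {
    tt <- t.test(pd$diff_maps[, v])
    expect_equal(pd$t_map[v], unname(tt$statistic), tolerance = 1e-10)
  }
  # mismatched subject sets are refused
  expect_error(paired_differences(dr[paste0(ids, "_drug")],
                                  rev(dr[paste0(ids, "_placebo")]), 1),
               "matched")
})

test_that("TFCE reproduces the hand-computed and brute-force values", {
  # explicit two-step threshold sum: [0, 2, 0] with dh = 1 -> center 5
  m <- array(0, c(3, 1, 1)); m[2, 1, 1] <- 2
  out <- tfce(m, tfce_params(dh = 1))
  expect_equal(out[2, 1, 1], 5)
  expect_equal(out[c(1, 3), 1, 1], c(0, 0))
  # all-zero map stays zero
  expect_equal(tfce(array(0, c(4, 4, 4))), array(0, c(4, 4, 4)))
  # random signed maps match the independent brute-force oracle
  for (i in 1:5) {
    set.seed(i)
    m <- array(rnorm(9 * 8 * 7), c(9, 8, 7))
    expect_lt(max(abs(tfce(m) - brute_tfce_signed(m))), 1e-10)
  }
  # connectivity variants agree with the oracle too
  set.seed(99)
  m <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  for (conn in c(6L, 18L, 26L)) {
    got <- tfce(m, tfce_params(connectivity = conn))
    want <- brute_tfce_signed(m, conn = conn)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("sign-flip inference ranks extremes correctly and enumerates", {
  mask <- array(TRUE, c(6, 6, 4))
  set.seed(8)
  # strong constant effect: observed max is the all-time maximum
  D <- matrix(rnorm(8 * 144, mean = 3), 8, 144)
  pi1 <- permutation_inference(D, mask, n_perm = 300, seed = 2)
  # 2^8 = 256 <= 300: full enumeration engaged
  expect_true(pi1$enumerated)
  # the identity assignment dominates: minimal attainable p = 1/2^N ... the
  # sign-symmetric mirror ties it, so p is 2/256 at the peak
  expect_lte(min(pi1$p_fwe_pos), 2 / 256)
  # Monte-Carlo path agrees with enumeration within 2/sqrt(n_perm)
  pi2 <- permutation_inference(D, mask, n_perm = 255, seed = 2)
  expect_false(pi2$enumerated)
  expect_lt(max(abs(pi1$p_fwe_pos - pi2$p_fwe_pos)), 2 / sqrt(255))
  # extreme-rank convention for the Monte-Carlo path: observed acts as the
  # identity permutation, so the minimum attainable p is 1/(n_perm + 1)
  D2 <- matrix(rnorm(20 * 144, mean = 3), 20, 144)
  pi3 <- permutation_inference(D2, mask, n_perm = 200, seed = 3)
  expect_equal(min(pi3$p_fwe_pos), 1 / 201)
  # permutation p-values are reproducible under the same seed
  pi4 <- permutation_inference(D2, mask, n_perm = 200, seed = 3)
  expect_identical(pi3$p_fwe_pos, pi4$p_fwe_pos)
})

test_that("planted within-network effects are detected, nulls are not", {
  tr <- small_truth()
  mask <- tr$mask
  X <- truth_mat(tr)
  n <- 10
  set.seed(123)
  # effect: a localized loading increase within network 2's blob
  blob <- X[, 2] > 0.5 * max(X[, 2])
  eff <- numeric(nrow(X)); eff[blob] <- 2
  D_eff <- t(replicate(n, eff + rnorm(nrow(X), sd = 1)))
  pi_eff <- permutation_inference(D_eff, mask, n_perm = 400, seed = 5)
  expect_lt(min(pi_eff$p_fwe_pos), 0.05 / 10)
  # and the detected voxels sit inside the blob
  hit <- which(pi_eff$p_fwe_pos < 0.05 / 10)
  expect_gt(mean(hit %in% which(blob)), 0.5)
})

test_that("the Bonferroni gate counts networks x directions", {
  mask <- array(TRUE, c(4, 4, 2))
  fake_contrast <- function(pmin_pos) {
    p <- rep(1, 32); p[5] <- pmin_pos
    structure(list(t_map = rep(0, 32), tfce_pos = rep(0, 32),
                   tfce_neg = rep(0, 32), p_fwe_pos = p,
                   p_fwe_neg = rep(1, 32), mask = mask, df = 9L,
                   n_perm = 100L, enumerated = FALSE),
              class = "voxel_contrast")
  }
  # 23 networks, 2 directions: per-test alpha 0.05/46, the ~0.001 gate
  contrasts <- setNames(lapply(rep(1, 23), fake_contrast),
                        sprintf("RSN%02d", 1:23))
  gate <- bonferroni_gate(contrasts)
  expect_equal(gate$n_tests, 46L)
  expect_equal(gate$per_test_alpha, 0.05 / 46, tolerance = 1e-12)
  expect_equal(nrow(gate$clusters), 0L)
  # one passing voxel in one network
  contrasts$RSN05 <- fake_contrast(1e-4)
  gate2 <- bonferroni_gate(contrasts)
  expect_equal(nrow(gate2$clusters), 1L)
  expect_equal(gate2$clusters$network, "RSN05")
  expect_equal(gate2$clusters$size, 1L)
  # a single test gets the full alpha
  gate3 <- bonferroni_gate(contrasts["RSN05"])
  expect_equal(gate3$per_test_alpha, 0.05 / 2)
})
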