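# Consensus network identification: model order, group ICA, cross-run
# matching, clique consensus, relaxed support, artifact heuristics.

test_that("Laplace evidence recovers planted PCA ranks", {
  set.seed(11)
  plant <- function(rank, d, n, noise_sd) {
    matrix(rnorm(d * rank), d, rank) %*% matrix(rnorm(rank * n), rank, n) +
      matrix(rnorm(d * n, sd = noise_sd), d, n)
  }
  expect_equal(estimate_model_order(plant(5, 60, 200, 0.01), 20), 5L)
  expect_equal(estimate_model_order(plant(8, 40, 300, 0.01), 20), 8L)
  expect_equal(estimate_model_order(plant(3, 30, 500, 0.05), 10), 3L)
  # pure isotropic noise: order stays at the floor almost always
  orders <- vapply(1:50, function(i) {
    set.seed(100 + i)
    estimate_model_order(matrix(rnorm(30 * 200), 30, 200), 10)
  }, integer(1))
  expect_gte(mean(orders <= 1), 0.95)
  # degenerate flat spectrum (equal singular values, rows pre-centered)
  M <- matrix(rnorm(30 * 200), 30, 200)
  M <- M - rowMeans(M)
  sv <- svd(M)
  flat <- sv$u %*% t(sv$v)
  expect_warning(ord <- estimate_model_order(flat, 10), "degenerate")
  expect_equal(ord, 0L)
})

test_that("group ICA recovers planted networks and is seed-stable", {
  tr <- small_truth()
  sp <- small_spec(noise_sd = 0.3)
  study <- simulate_paired_study(sp, truth = tr)
  pl <- study$sessions[grep("placebo", names(study$sessions))]
  run <- fit_group_ica(pl, 5, subject_order_seed = 1, ica_seed = 2)
  X <- truth_mat(tr)
  R <- abs(cor(run$components, X))
  # every truth map matched by some component at |r| > 0.9
  expect_true(all(apply(R, 2, max) > 0.9))
  # unit variance and nonnegative skewness within mask
  expect_equal(unname(apply(run$components, 2, var)), rep(1, 5),
               tolerance = 1e-6)
  expect_true(all(apply(run$components, 2, function(v) mean(v^3)) >= 0))
  # identical seeds give identical maps
  run2 <- fit_group_ica(pl, 5, subject_order_seed = 1, ica_seed = 2)
  expect_identical(run$components, run2$components)
  # different subject order: same components as a set (greedy |r| matching)
  run3 <- fit_group_ica(pl, 5, subject_order_seed = 9, ica_seed = 2)
  M <- abs(cor(run$components, run3$components))
  expect_true(all(apply(M, 1, max) > 0.9))
})

test_that("meta-gICA produces distinct seeded runs with sane orders", {
  tr <- small_truth()
  study <- simulate_paired_study(small_spec(noise_sd = 0.3), truth = tr)
  pl <- study$sessions[grep("placebo", names(study$sessions))]
  runs <- run_meta_gica(pl, n_runs = 4, master_seed = 5)
  expect_length(runs, 4L)
  # per-run model order within +-2 of the planted K = 5 at high SNR
  expect_true(all(abs(vapply(runs, `[[`, integer(1), "model_order") - 5) <= 2))
  expect_error(run_meta_gica(pl, n_runs = 1), "n_runs")
  runs2 <- run_meta_gica(pl, n_runs = 4, master_seed = 5)
  expect_identical(runs[[2]]$components, runs2[[2]]$components)
})

test_that("cross-run matching builds the documented graph", {
  mask <- array(TRUE, c(6, 6, 4))
  set.seed(3)
  base <- matrix(rnorm(144 * 2), 144, 2)
  # run 2 carries a sign-flipped copy of run 1's first component and an
  # orthogonal second component
  r1 <- make_fake_run(1, base, mask, noise = 0)
  r2_maps <- cbind(-base[, 1], rnorm(144))
  r2 <- make_fake_run(2, r2_maps, mask, noise = 0)
  g <- cross_correlate_runs(list(r1, r2), threshold = 0.7)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(abs(g$edges$r), 1, tolerance = 1e-12)
  # the matched pair spans the two runs
  expect_equal(sort(g$nodes$run[c(g$edges$from, g$edges$to)]), c(1L, 2L))
  # grid mismatch refused
  r3 <- make_fake_run(3, base, array(TRUE, c(4, 6, 6)), noise = 0)
  expect_error(cross_correlate_runs(list(r1, r3)), "mask")
})

test_that("full-support consensus averages planted cliques", {
  mask <- array(TRUE, c(8, 8, 4))
  set.seed(4)
  truth_maps <- matrix(rnorm(256 * 3), 256, 3)
  runs <- lapply(1:10, function(r)
    make_fake_run(r, truth_maps, mask, noise = 0.15, extra_noise_comps = 2))
  g <- cross_correlate_runs(runs, threshold = 0.7)
  cons <- extract_consensus(g, n_runs = 10)
  expect_equal(ncol(cons$maps), 3L)
  expect_equal(cons$support, rep(10L, 3))
  # members come from 10 distinct runs
  for (m in cons$members) expect_equal(sort(m$run), 1:10)
  # averaged map re-correlates above threshold with every member
  for (j in 1:3) {
    mem <- cons$members[[j]]
    for (q in seq_len(nrow(mem))) {
      comp <- runs[[mem$run[q]]]$components[, mem$comp[q]]
      expect_gt(abs(cor(cons$maps[, j], comp)), g$threshold)
    }
  }
  # and matches its truth map
  expect_true(all(apply(abs(cor(cons$maps, truth_maps)), 2, max) > 0.9))
})

test_that("relaxed support rescues weak networks without reuse", {
  mask <- array(TRUE, c(8, 8, 4))
  set.seed(5)
  strong <- matrix(rnorm(256 * 2), 256, 2)
  weak <- rnorm(256)
  # the weak network appears in only 4 of 10 runs
  runs <- lapply(1:10, function(r) {
    maps <- if (r <= 4) cbind(strong, weak) else strong
    make_fake_run(r, maps, mask, noise = 0.1, extra_noise_comps = 1)
  })
  g <- cross_correlate_runs(runs, threshold = 0.7)
  full <- extract_consensus(g, n_runs = 10)
  expect_equal(ncol(full$maps), 2L)          # weak one absent at support 10
  expect_true(all(apply(abs(cor(full$maps, strong)), 2, max) > 0.9))
  rel <- relaxed_consensus(g, min_support = 4, exclude = full$used)
  expect_equal(ncol(rel$maps), 1L)
  expect_equal(rel$support, 4L)
  expect_gt(abs(cor(rel$maps[, 1], weak)), 0.9)
  # components consumed by the full-support pass are never reused
  rel_nodes <- unlist(lapply(rel$members, function(m)
    mapply(function(r, c) which(g$nodes$run == r & g$nodes$comp == c),
           m$run, m$comp)))
  expect_length(intersect(full$used, rel_nodes), 0L)
  # combining keeps support bookkeeping
  both <- combine_consensus(full, rel)
  expect_equal(both$support, c(10L, 10L, 4L))
})

test_that("artifact heuristics flag rim components and honour overrides", {
  grid <- c(16, 16, 12)
  mask <- ellipsoid_mask(grid)
  # rim blob: weight concentrated on the boundary shell
  shell_map <- array(0, grid)
  bs <- metaconn:::mask_boundary_shell(mask)
  shell_map[bs] <- 1
  # interior blob planted at the mask center
  g <- expand.grid(x = 1:16, y = 1:16, z = 1:12)
  interior <- array(exp(-0.5 * ((g$x - 8.5)^2 + (g$y - 8.5)^2 +
                                (g$z - 6.5)^2) / 2^2), grid)
  interior[!mask] <- 0
  inmask <- as.logical(mask)
  cons <- structure(list(
    maps = cbind(scale(shell_map[inmask]), scale(interior[inmask])),
    support = c(10L, 10L), members = list(NULL, NULL),
    labels = c("RSN01", "RSN02"), artifact_flag = c(FALSE, FALSE),
    mask = mask, threshold = 0.7, used = integer(0)),
    class = "consensus_networks")
  out <- flag_artifact_components(cons)
  expect_true(out$artifact_flag[1])
  expect_false(out$artifact_flag[2])
  # manual override always wins
  out2 <- flag_artifact_components(cons, override = list(RSN02 = TRUE,
                                                         RSN01 = FALSE))
  expect_false(out2$artifact_flag[1])
  expect_true(out2$artifact_flag[2])
  expect_equal(n_clean_networks(out2), 1L)
})

test_that("consensus networks and match graphs round-trip to disk", {
  mask <- array(TRUE, c(6, 6, 4))
  set.seed(6)
  truth_maps <- matrix(rnorm(144 * 2), 144, 2)
  runs <- lapply(1:3, function(r) make_fake_run(r, truth_maps, mask, 0.05))
  g <- cross_correlate_runs(runs, threshold = 0.7)
  cons <- extract_consensus(g, n_runs = 3)
  dir <- withr::local_tempdir()
  write_consensus(cons, file.path(dir, "nets"))
  img <- read_nifti(file.path(dir, "nets.nii"))
  expect_equal(dim(img)[4], ncol(cons$maps))
  meta <- jsonlite::read_json(file.path(dir, "nets.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$support, cons$support)
  write_match_graph(g, file.path(dir, "graph.tsv"))
  tab <- read.delim(file.path(dir, "graph.tsv"))
  expect_equal(nrow(tab), nrow(g$edges))
})
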