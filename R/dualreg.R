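# Within-network analysis: dual regression of the consensus maps onto every
# session, paired drug-placebo voxelwise contrasts per network, TFCE,
# sign-flip permutation inference, Bonferroni gating across networks and
# directions.

#' TFCE parameters
#'
#' Extent exponent `E`, height exponent `H`, integration step `dh` and
#' neighbourhood connectivity. Defaults E = 0.5, H = 2, dh = max(stat)/100,
#' 26-connectivity: the field-standard settings of the TFCE method.
#'
#' @param E extent exponent (> 0).
#' @param H height exponent (> 0).
#' @param dh integration step; `NULL` (default) uses max(stat)/`nsteps`.
#' @param connectivity 6, 18 or 26.
#' @param nsteps number of integration steps when `dh` is NULL.
#' @return object of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, connectivity = 26L,
                        nsteps = 100L) {
  stopifnot(E > 0, H > 0, is.null(dh) || dh > 0,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(E = E, H = H, dh = dh, connectivity = as.integer(connectivity),
                 nsteps = as.integer(nsteps)), class = "tfce_params")
}

#' Dual regression of consensus networks onto one session
#'
#' Stage 1 (spatial regression): all K consensus maps plus an intercept are
#' regressed onto each volume, giving a K x T matrix of time courses, which
#' are then normalized to unit variance. Stage 2 (temporal regression): the K
#' normalized time courses plus an intercept are regressed onto each voxel's
#' series, giving K voxelwise fit-coefficient maps.
#'
#' @param session a denoised [bold_session()].
#' @param consensus a `consensus_networks` object (or a
#'   `ground_truth_networks` object, accepted for validation against planted
#'   maps).
#' @param normalize_stage1 normalize stage-1 time courses to unit variance
#'   (default TRUE; the alternative normalizes stage-2 maps instead).
#' @param max_condition collinearity guard: error when the condition number
#'   of the stage-1 design exceeds this.
#' @return object of class `subject_network_maps`: `timecourses` (K x T),
#'   `maps` (in-mask voxel x K), `subject_id`, `condition`, `mask`, `labels`.
#' @export
dual_regression <- function(session, consensus, normalize_stage1 = TRUE,
                            max_condition = 1e6) {
  X <- consensus_matrix(consensus)              # V x K (in-mask)
  K <- ncol(X)
  stopifnot(K >= 1L)
  if (!all(dim(consensus_mask(consensus)) == dim(session$mask)))
    stop("session and consensus are on different grids")
  Y <- mask_matrix(session$data, session$mask)  # V x T
  kap <- kappa(crossprod(X), exact = TRUE)
  if (!is.finite(kap) || kap > max_condition^2) {
    R <- abs(suppressWarnings(cor(X)))
    R[!is.finite(R)] <- 1
    diag(R) <- 0
    worst <- if (K > 1) which(R == max(R), arr.ind = TRUE)[1, ] else c(1, 1)
    stop(sprintf(
      "consensus maps are collinear (networks %d and %d, |r| = %.3f)",
      worst[1], worst[2], max(R)))
  }
  # spatial intercept, unless a map is itself constant over the mask (the
  # all-ones/global-signal case), where it would be collinear with it
  Xd <- cbind(1, X)
  if (qr(Xd)$rank < K + 1L) Xd <- X
  tc <- qr.coef(qr(Xd), Y)
  if (ncol(Xd) > K) tc <- tc[-1, , drop = FALSE]  # K x T stage-1 betas
  sds <- apply(tc, 1, sd)
  if (any(sds == 0)) stop("constant stage-1 time course (network ",
                          which(sds == 0)[1], ")")
  tcn <- if (normalize_stage1) tc / sds else tc
  Z <- cbind(1, t(tcn))                         # T x (K+1)
  maps <- t(qr.coef(qr(Z), t(Y))[-1, , drop = FALSE])  # V x K
  if (!normalize_stage1) maps <- sweep(maps, 2, apply(maps, 2, sd), `/`)
  structure(list(timecourses = tcn, maps = maps,
                 subject_id = session$subject_id,
                 condition = session$condition, mask = session$mask,
                 labels = consensus_labels(consensus)),
            class = "subject_network_maps")
}

# accept either consensus_networks or ground_truth_networks
consensus_matrix <- function(x) {
  if (inherits(x, "consensus_networks")) return(x$maps)
  if (inherits(x, "ground_truth_networks")) return(truth_matrix(x))
  stop("expected consensus_networks or ground_truth_networks")
}

consensus_mask <- function(x) x$mask

consensus_labels <- function(x) {
  if (inherits(x, "consensus_networks")) return(x$labels)
  x$network_labels
}

#' @export
print.subject_network_maps <- function(x, ...) {
  cat(sprintf("<subject_network_maps> subject %s (%s): %d networks, %d volumes\n",
              x$subject_id, x$condition, nrow(x$timecourses),
              ncol(x$timecourses)))
  invisible(x)
}

#' Paired voxelwise differences and t map for one network
#'
#' Subject-wise drug minus placebo difference of the stage-2 fit maps, and
#' the per-voxel one-sample t statistic on those differences (df = N - 1).
#' Zero-variance voxels get t = 0 (recorded in attribute `zero_variance`).
#'
#' @param maps_drug,maps_placebo lists of [dual_regression()] results,
#'   matched by subject (same order, same subjects).
#' @param network network index k.
#' @return list: `diff_maps` (N x V matrix), `t_map` (in-mask vector), `df`.
#' @export
paired_differences <- function(maps_drug, maps_placebo, network) {
  N <- length(maps_drug)
  stopifnot(N == length(maps_placebo), N >= 3L)
  ids_d <- unname(vapply(maps_drug, `[[`, character(1), "subject_id"))
  ids_p <- unname(vapply(maps_placebo, `[[`, character(1), "subject_id"))
  if (!identical(ids_d, ids_p))
    stop("drug and placebo lists are not matched by subject")
  D <- t(vapply(seq_len(N), function(i)
    maps_drug[[i]]$maps[, network] - maps_placebo[[i]]$maps[, network],
    numeric(nrow(maps_drug[[1]]$maps))))
  tt <- one_sample_t(D)
  list(diff_maps = D, t_map = tt$t, df = N - 1L)
}

# columnwise one-sample t; zero-variance columns -> 0
one_sample_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- colSums(sweep(D, 2, m)^2) / (n - 1)
  t <- ifelse(v > 0, m / sqrt(v / n), 0)
  list(t = t, zero_variance = which(v == 0))
}

#' Threshold-free cluster enhancement
#'
#' For each voxel, sums `e(h)^E * h^H * dh` over thresholds
#' `h = dh, 2dh, ... <= max(stat)`, where `e(h)` is the size of the voxel's
#' connected suprathreshold cluster at height h. The negative tail is handled
#' by applying the same transform to the negated map; the returned map is the
#' signed combination (positive branch minus the branch of the negated map).
#'
#' @param stat_map 3D array, or an in-mask vector together with `mask`.
#' @param params a [tfce_params()].
#' @param mask 3D mask required when `stat_map` is a vector.
#' @return enhancement map in the same format as the input.
#' @export
tfce <- function(stat_map, params = tfce_params(), mask = NULL) {
  vec_in <- is.null(dim(stat_map))
  if (vec_in) {
    stopifnot(!is.null(mask))
    stat_map <- unmask_vector(stat_map, mask)
  }
  dm <- dim(stat_map)
  stopifnot(length(dm) == 3L)
  dh <- if (is.null(params$dh)) -1 else params$dh
  pos <- .tfce_cpp(as.numeric(stat_map), as.integer(dm), params$E, params$H,
                   dh, params$connectivity, params$nsteps)
  neg <- .tfce_cpp(as.numeric(-stat_map), as.integer(dm), params$E, params$H,
                   dh, params$connectivity, params$nsteps)
  out <- array(pos - neg, dm)
  if (vec_in) mask_vector(out, mask) else out
}

# sign matrix for the permutation engines: row 1 is the identity, the rest
# random +/-1 rows; full enumeration when 2^N <= n_perm.
sign_matrix <- function(N, n_perm, seed) {
  if (2^N <= n_perm) {
    S <- as.matrix(expand.grid(rep(list(c(1L, -1L)), N)))
    # put the identity first
    idx <- which(rowSums(S == 1L) == N)
    S <- rbind(S[idx, , drop = FALSE], S[-idx, , drop = FALSE])
    attr(S, "enumerated") <- TRUE
    return(S)
  }
  S <- with_seed(seed,
    matrix(sample(c(1L, -1L), (n_perm + 1L) * N, replace = TRUE),
           n_perm + 1L, N))
  S[1, ] <- 1L
  attr(S, "enumerated") <- FALSE
  S
}

#' Sign-flip TFCE permutation inference for one network
#'
#' Paired-design exchangeability: the subject difference maps are sign
#' flipped, the one-sample t map and its TFCE recomputed per permutation, and
#' the image-wide maximum recorded. Familywise-corrected
#' `p_fwe(v) = (1 + #\{perm max >= observed tfce(v)\}) / (1 + n_perm)`; the
#' observed statistic is the identity permutation. All `2^N` sign patterns
#' are enumerated when `2^N <= n_perm`.
#'
#' @param diff_maps N x V matrix of subject difference images (in-mask), or a
#'   `paired_differences()` result.
#' @param mask 3D mask.
#' @param params a [tfce_params()].
#' @param n_perm number of permutations (default 5000).
#' @param seed permutation seed.
#' @return object of class `voxel_contrast`: `t_map`, `tfce_pos`, `tfce_neg`,
#'   `p_fwe_pos`, `p_fwe_neg` (in-mask vectors), `max_pos`/`max_neg` null
#'   distributions, `n_perm`, `enumerated`, `df`.
#' @export
permutation_inference <- function(diff_maps, mask, params = tfce_params(),
                                  n_perm = 5000L, seed = 1L) {
  if (is.list(diff_maps)) diff_maps <- diff_maps$diff_maps
  N <- nrow(diff_maps)
  stopifnot(N >= 3L, n_perm >= 100L)
  S <- sign_matrix(N, n_perm, seed)
  enumerated <- attr(S, "enumerated")
  # embed in-mask columns into the full grid (zeros outside stay zero under
  # sign flips and contribute no clusters)
  full <- matrix(0, N, length(mask))
  full[, as.logical(mask)] <- diff_maps
  res <- .tfce_perm_cpp(full, as.integer(dim(mask)), params$E, params$H,
                        params$connectivity, params$nsteps, S)
  inmask <- as.logical(mask)
  obs_pos <- res$tfce_pos[inmask]
  obs_neg <- res$tfce_neg[inmask]
  if (enumerated) {
    denom <- nrow(S)
    p_pos <- vapply(obs_pos, function(o) sum(res$max_pos >= o) / denom,
                    numeric(1))
    p_neg <- vapply(obs_neg, function(o) sum(res$max_neg >= o) / denom,
                    numeric(1))
  } else {
    denom <- n_perm + 1
    p_pos <- vapply(obs_pos, function(o)
      (1 + sum(res$max_pos[-1] >= o)) / denom, numeric(1))
    p_neg <- vapply(obs_neg, function(o)
      (1 + sum(res$max_neg[-1] >= o)) / denom, numeric(1))
  }
  structure(list(t_map = res$t[inmask], tfce_pos = obs_pos,
                 tfce_neg = obs_neg, p_fwe_pos = p_pos, p_fwe_neg = p_neg,
                 max_pos = res$max_pos, max_neg = res$max_neg,
                 n_perm = n_perm, enumerated = enumerated, df = N - 1L,
                 mask = mask),
            class = "voxel_contrast")
}

#' @export
print.voxel_contrast <- function(x, ...) {
  cat(sprintf(
    "<voxel_contrast> %d voxels, %s permutations, min p_fwe: +%.4g / -%.4g\n",
    length(x$t_map),
    if (x$enumerated) "fully enumerated" else as.character(x$n_perm),
    min(x$p_fwe_pos), min(x$p_fwe_neg)))
  invisible(x)
}

#' Bonferroni gate across networks and directions
#'
#' The familywise alpha is split over all evaluated GLMs: per-test alpha =
#' `familywise_alpha / (n_networks x 2 directions)` (e.g. 23 networks give
#' 0.05/46, approximately the 0.001 gate). Voxels passing the gate are
#' grouped into connected clusters.
#'
#' @param contrasts named list of [permutation_inference()] results, one per
#'   (non-artifact) network.
#' @param familywise_alpha total alpha (default 0.05).
#' @param connectivity cluster connectivity for grouping passing voxels.
#' @return list: `per_test_alpha`, `n_tests`, and `clusters`: data.frame
#'   (network, direction, cluster id, size, peak p) plus a list of voxel
#'   index sets in `cluster_voxels`.
#' @export
bonferroni_gate <- function(contrasts, familywise_alpha = 0.05,
                            connectivity = 26L) {
  n_tests <- length(contrasts) * 2L
  stopifnot(n_tests >= 1L)
  alpha <- familywise_alpha / n_tests
  rows <- list()
  voxsets <- list()
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    for (dir in c("pos", "neg")) {
      p <- if (dir == "pos") ct$p_fwe_pos else ct$p_fwe_neg
      pass <- p < alpha
      if (!any(pass)) next
      cl <- connected_clusters(pass, ct$mask, connectivity)
      for (ci in seq_along(cl)) {
        rows[[length(rows) + 1L]] <- data.frame(
          network = nm, direction = if (dir == "pos") "drug>placebo"
                        else "placebo>drug",
          cluster = ci, size = length(cl[[ci]]),
          peak_p = min(p[cl[[ci]]]), stringsAsFactors = FALSE)
        voxsets[[length(voxsets) + 1L]] <- cl[[ci]]
      }
    }
  }
  clusters <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(network = character(0), direction = character(0),
               cluster = integer(0), size = integer(0), peak_p = numeric(0))
  list(per_test_alpha = alpha, n_tests = n_tests, clusters = clusters,
       cluster_voxels = voxsets)
}

# connected clusters (lists of in-mask voxel indices) of a logical in-mask
# vector, via igraph on the suprathreshold lattice
connected_clusters <- function(pass_inmask, mask, connectivity = 26L) {
  inmask_idx <- which(as.logical(mask))
  vox <- inmask_idx[pass_inmask]
  if (length(vox) == 0) return(list())
  dm <- dim(mask)
  coords <- arrayInd(vox, dm)
  offs <- neighbour_offsets_r(connectivity)
  id_of <- new.env(hash = TRUE)
  for (i in seq_along(vox)) assign(as.character(vox[i]), i, envir = id_of)
  edges <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + dm[1] * (nb[ok, 2] - 1) + dm[1] * dm[2] * (nb[ok, 3] - 1)
    src <- which(ok)
    for (q in seq_along(lin)) {
      j <- mget(as.character(lin[q]), envir = id_of, ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && j > src[q]) edges <- c(edges, src[q], j)
    }
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(ci) {
    # return positions within the in-mask vector
    match(vox[comp == ci], inmask_idx)
  })
}

neighbour_offsets_r <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(g))
  keep <- nz > 0 & switch(as.character(connectivity),
                          "6" = nz <= 1, "18" = nz <= 2, "26" = nz <= 3)
  g[keep, , drop = FALSE]
}
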