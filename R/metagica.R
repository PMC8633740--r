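# Consensus resting-state network identification: repeated group ICA with
# randomized scan-concatenation order, Laplace-evidence model-order
# estimation, cross-run component matching by spatial correlation, clique
# averaging at full support, and a relaxed-support second pass (the
# "thalamus rule"). No ICA package is available in this environment, so the
# fixed-point (FastICA) algorithm with the logcosh contrast is implemented
# here; that keeps the whole meta-gICA under test in one place.

#' Laplace-evidence model order for probabilistic PCA
#'
#' Minka's Laplace approximation to the Bayesian evidence of the PCA model
#' order, evaluated on the eigenvalue spectrum of the row-space (time x time)
#' covariance; columns (voxels) are treated as samples. Returns the order
#' with maximal evidence among `1..max_order`.
#'
#' @param stacked_data time x voxel matrix (rows are the reduced/concatenated
#'   time dimension).
#' @param max_order largest order considered; capped at `nrow - 2`.
#' @return integer model order (0, with a warning, for a degenerate
#'   all-equal spectrum).
#' @export
estimate_model_order <- function(stacked_data, max_order = 20L) {
  X <- as.matrix(stacked_data)
  d <- nrow(X)
  n <- ncol(X)
  max_order <- min(as.integer(max_order), d - 2L)
  if (max_order < 1L) stop("need at least max_order + 2 rows")
  X <- X - rowMeans(X)
  lambda <- eigen(tcrossprod(X) / n, symmetric = TRUE,
                  only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  if (max(lambda) - min(lambda) < 1e-12 * max(lambda, 1e-300)) {
    warning("degenerate (flat) eigenvalue spectrum; model order undefined")
    return(0L)
  }
  ll <- vapply(seq_len(max_order), function(k)
    laplace_evidence(lambda, k, n), numeric(1))
  which.max(ll)
}

# Minka (2000) Laplace evidence for PCA rank k given spectrum lambda (length
# d) and n samples; mirrors the standard reference implementation.
laplace_evidence <- function(lambda, k, n) {
  d <- length(lambda)
  eps <- 1e-15
  if (lambda[k] < eps) return(-Inf)
  pu <- -k * log(2)
  i <- seq_len(k)
  pu <- pu + sum(lgamma((d - i + 1) / 2) - ((d - i + 1) / 2) * log(pi))
  pl <- -n / 2 * sum(log(lambda[seq_len(k)]))
  v <- max(eps, sum(lambda[(k + 1):d]) / (d - k))
  pv <- -n * (d - k) / 2 * log(v)
  m <- d * k - k * (k + 1) / 2
  pp <- (m + k) / 2 * log(2 * pi)
  spec_hat <- lambda
  spec_hat[(k + 1):d] <- v
  pa <- 0
  for (i in seq_len(k)) {
    j <- (i + 1):d
    pa <- pa + sum(log((lambda[i] - lambda[j]) *
                       (1 / spec_hat[j] - 1 / spec_hat[i])) + log(n))
  }
  pu + pl + pv + pp - pa / 2 - k * log(n) / 2
}

# Symmetric fixed-point ICA with logcosh contrast on whitened data
# (components x samples). Returns the orthogonal unmixing matrix W so that
# the sources are W %*% Xw.
fastica_symm <- function(Xw, seed, max_iter = 500L, tol = 1e-7,
                         restarts = 5L) {
  M <- nrow(Xw)
  n <- ncol(Xw)
  seeds <- derive_seeds(seed, restarts)
  for (r in seq_len(restarts)) {
    W <- with_seed(seeds[r], matrix(rnorm(M * M), M, M))
    W <- sym_decorrelate(W)
    for (it in seq_len(max_iter)) {
      WX <- W %*% Xw                       # M x n source estimates
      G <- tanh(WX)
      gprime <- 1 - G^2
      W1 <- (G %*% t(Xw)) / n - diag(rowMeans(gprime)) %*% W
      W1 <- sym_decorrelate(W1)
      delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
      W <- W1
      if (delta < tol) return(W)
    }
  }
  stop("fixed-point ICA failed to converge after ", restarts, " restarts")
}

sym_decorrelate <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

#' One group-ICA run
#'
#' Per-session temporal PCA reduction (to `ceiling(reduction_factor * M)`
#' dimensions), temporal concatenation in a seeded random session order,
#' group PCA to `M` whitened dimensions, then spatial fixed-point ICA with
#' the logcosh contrast. Component maps are z-scaled within the mask and
#' sign-oriented so their in-mask skewness is nonnegative.
#'
#' @param sessions list of denoised [bold_session()]s sharing grid and mask.
#' @param order model order M (number of components).
#' @param subject_order_seed seed for the random concatenation order.
#' @param ica_seed seed for the ICA initialization.
#' @param reduction_factor per-session PCA keeps
#'   `ceiling(reduction_factor * order)` dimensions (default 1.5).
#' @param run_id integer label carried on the result.
#' @return object of class `ica_run`: `components` (in-mask voxel x M matrix
#'   of z-scaled maps), `subject_order`, `model_order`, `run_id`, `mask`,
#'   `timecourse_power_high` (fraction of spectral power above 0.1 Hz per
#'   component, used by the artifact heuristic).
#' @export
fit_group_ica <- function(sessions, order, subject_order_seed = 1L,
                          ica_seed = 1L, reduction_factor = 1.5,
                          run_id = 1L) {
  stopifnot(length(sessions) >= 2L, order >= 2L)
  mask <- sessions[[1]]$mask
  for (s in sessions)
    if (!all(dim(s$mask) == dim(mask)) || !all(s$mask == mask))
      stop("all sessions must share one grid and mask")
  p <- ceiling(reduction_factor * order)
  ord <- with_seed(subject_order_seed, sample(seq_along(sessions)))
  reduced <- lapply(sessions[ord], function(s) {
    Y <- t(mask_matrix(s$data, mask))            # T x V
    Y <- Y - rowMeans(Y)
    pr <- min(p, nrow(Y) - 1L)
    e <- eigen(tcrossprod(Y), symmetric = TRUE)
    t(e$vectors[, seq_len(pr), drop = FALSE]) %*% Y   # pr x V
  })
  G <- do.call(rbind, reduced)                   # (n*p) x V
  if (order > nrow(G)) stop("model order exceeds the reduced dimension")
  G <- G - rowMeans(G)
  e <- eigen(tcrossprod(G) / ncol(G), symmetric = TRUE)
  U <- e$vectors[, seq_len(order), drop = FALSE]
  lam <- pmax(e$values[seq_len(order)], 1e-12)
  Xw <- diag(1 / sqrt(lam)) %*% t(U) %*% G / sqrt(ncol(G))  # M x V whitened
  Xw <- Xw * sqrt(ncol(G))                       # unit variance rows
  W <- fastica_symm(Xw, seed = ica_seed)
  S <- W %*% Xw                                  # M x V spatial sources
  # z-scale within mask, orient by skewness
  S <- t(apply(S, 1, function(v) {
    v <- (v - mean(v)) / sd(v)
    if (mean(v^3) < 0) -v else v
  }))
  # mixing time courses (for the artifact frequency heuristic): project the
  # concatenated reduced data onto the sources
  A <- G %*% t(S) %*% solve(tcrossprod(S))       # (n*p) x M
  tr <- sessions[[1]]$tr_seconds
  power_high <- apply(A, 2, function(a) {
    sp <- Mod(fft(a - mean(a)))^2
    f <- (seq_along(a) - 1) / (length(a) * tr)
    f <- pmin(f, 1 / tr - f)
    sum(sp[f > 0.1]) / max(sum(sp), 1e-300)
  })
  structure(list(components = t(S), subject_order = ord,
                 model_order = as.integer(order), run_id = as.integer(run_id),
                 seed = as.integer(ica_seed), mask = mask,
                 timecourse_power_high = power_high),
            class = "ica_run")
}

#' @export
print.ica_run <- function(x, ...) {
  cat(sprintf("<ica_run> run %d: %d components, %d sessions concatenated\n",
              x$run_id, x$model_order, length(x$subject_order)))
  invisible(x)
}

#' Repeated group ICA with randomized scan order
#'
#' Runs `n_runs` group ICAs whose session-concatenation orders and ICA
#' initializations derive deterministically from `master_seed`. The model
#' order of each run is re-estimated on that run's concatenated reduced data
#' by [estimate_model_order()] unless `order` is fixed.
#'
#' @param sessions list of denoised [bold_session()]s.
#' @param n_runs number of ICA repetitions (default 10).
#' @param master_seed master seed.
#' @param order fixed model order; NULL (default) re-estimates per run.
#' @param max_order cap for the model-order search.
#' @param reduction_factor see [fit_group_ica()].
#' @return list of [fit_group_ica()] results (class `meta_gica_runs`).
#' @export
run_meta_gica <- function(sessions, n_runs = 10L, master_seed = 1L,
                          order = NULL, max_order = 20L,
                          reduction_factor = 1.5) {
  stopifnot(n_runs >= 2L)
  seeds <- derive_seeds(master_seed, 2L * n_runs)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    M <- order
    if (is.null(M)) {
      # estimate on this run's concatenated per-session-reduced data
      mask <- sessions[[1]]$mask
      p <- ceiling(reduction_factor * max_order)
      ordset <- with_seed(seeds[2 * r - 1], sample(seq_along(sessions)))
      reduced <- lapply(sessions[ordset], function(s) {
        Y <- t(mask_matrix(s$data, mask))
        Y <- Y - rowMeans(Y)
        pr <- min(p, nrow(Y) - 1L)
        e <- eigen(tcrossprod(Y), symmetric = TRUE)
        t(e$vectors[, seq_len(pr), drop = FALSE]) %*% Y
      })
      M <- max(2L, estimate_model_order(do.call(rbind, reduced), max_order))
    }
    runs[[r]] <- fit_group_ica(sessions, M,
                               subject_order_seed = seeds[2 * r - 1],
                               ica_seed = seeds[2 * r],
                               reduction_factor = reduction_factor,
                               run_id = r)
  }
  structure(runs, class = "meta_gica_runs")
}

#' Cross-run component match graph
#'
#' Correlates every component map against every component of every other run
#' (in-mask Pearson correlation, absolute value — ICA sign is arbitrary) and
#' keeps pairs above `threshold`. No edge ever joins two components of the
#' same run.
#'
#' @param runs list of [fit_group_ica()] results.
#' @param threshold spatial correlation threshold (default 0.7).
#' @return object of class `component_match_graph`: `nodes` data.frame
#'   (`run`, `comp`), `edges` data.frame (`from`, `to`, `r` signed
#'   correlation), `threshold`, plus the component matrix and run index.
#' @export
cross_correlate_runs <- function(runs, threshold = 0.7) {
  mask <- runs[[1]]$mask
  for (r in runs)
    if (!all(dim(r$mask) == dim(mask)) || !all(r$mask == mask))
      stop("runs were fitted on different grids/masks")
  comp <- do.call(cbind, lapply(runs, `[[`, "components"))
  run_of <- rep(seq_along(runs), vapply(runs, function(r)
    ncol(r$components), integer(1)))
  comp_of <- unlist(lapply(runs, function(r) seq_len(ncol(r$components))))
  R <- cor(comp)
  n <- ncol(comp)
  pairs <- which(upper.tri(R) & abs(R) > threshold &
                 outer(run_of, run_of, `!=`), arr.ind = TRUE)
  edges <- data.frame(from = pairs[, 1], to = pairs[, 2],
                      r = R[pairs])
  structure(list(nodes = data.frame(run = run_of, comp = comp_of),
                 edges = edges, threshold = threshold, components = comp,
                 mask = mask, cor_matrix = R),
            class = "component_match_graph")
}

# igraph of a component_match_graph (weights |r|)
match_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  if (nrow(graph$edges) > 0)
    g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to),
                           weight = abs(graph$edges$r))
  g
}

# Internal clique harvest: maximal cliques of size >= min_support among
# `available` nodes, greedy by descending mean internal |r|, each component
# used once. Because the match graph has no within-run edges, any clique has
# at most one component per run.
harvest_cliques <- function(graph, min_support, available) {
  g <- match_igraph(graph)
  used <- rep(FALSE, nrow(graph$nodes))
  used[setdiff(seq_len(nrow(graph$nodes)), available)] <- TRUE
  out <- list()
  repeat {
    sub_nodes <- which(!used)
    if (length(sub_nodes) < min_support) break
    sg <- igraph::induced_subgraph(g, sub_nodes)
    cl <- igraph::max_cliques(sg, min = min_support)
    if (length(cl) == 0) break
    # mean internal |r| of each clique
    score <- vapply(cl, function(v) {
      ids <- sub_nodes[as.integer(v)]
      mean(abs(graph$cor_matrix[ids, ids][upper.tri(diag(length(ids)))]))
    }, numeric(1))
    best <- cl[[which.max(score)]]
    ids <- sub_nodes[as.integer(best)]
    out[[length(out) + 1L]] <- list(members = ids, mean_r = max(score))
    used[ids] <- TRUE
  }
  out
}

# average the member maps of one clique (sign-aligned to the member with the
# largest mean |r| to the others), re-z-scale
average_clique <- function(graph, members) {
  R <- graph$cor_matrix[members, members, drop = FALSE]
  ref <- members[which.max(rowMeans(abs(R)))]
  signs <- sign(graph$cor_matrix[ref, members])
  signs[signs == 0] <- 1
  m <- as.vector(graph$components[, members, drop = FALSE] %*% signs) /
    length(members)
  (m - mean(m)) / sd(m)
}

#' Extract full-support consensus networks
#'
#' Finds groups of `min_support` components, one per run, all mutually
#' correlated above the graph threshold (cliques of the match graph), greedy
#' by descending mean internal correlation with each component usable once.
#' Member maps are sign-aligned and averaged, then re-z-scaled.
#'
#' @param graph a [cross_correlate_runs()] result.
#' @param n_runs total number of ICA runs.
#' @param min_support required support (default `n_runs`: a component must
#'   appear in every run).
#' @return object of class `consensus_networks`: `maps` (in-mask voxel x n
#'   matrix), `support`, `members` (list of data.frames run/comp), `labels`,
#'   `artifact_flag` (all FALSE until [flag_artifact_components()]), `mask`,
#'   `threshold`, `used` (internal bookkeeping of consumed components).
#' @export
extract_consensus <- function(graph, n_runs, min_support = n_runs) {
  stopifnot(min_support >= 2L, min_support <= n_runs)
  cl <- harvest_cliques(graph, min_support, seq_len(nrow(graph$nodes)))
  build_consensus(graph, cl)
}

build_consensus <- function(graph, cliques) {
  n <- length(cliques)
  V <- nrow(graph$components)
  maps <- matrix(numeric(0), V, 0)
  members <- list()
  support <- integer(0)
  for (cc in cliques) {
    maps <- cbind(maps, average_clique(graph, cc$members))
    members[[length(members) + 1L]] <-
      graph$nodes[cc$members, , drop = FALSE]
    support <- c(support, length(cc$members))
  }
  used <- unlist(lapply(cliques, `[[`, "members"))
  structure(list(maps = maps, support = support, members = members,
                 labels = if (n > 0) sprintf("RSN%02d", seq_len(n))
                          else character(0),
                 artifact_flag = rep(FALSE, n), mask = graph$mask,
                 threshold = graph$threshold, used = used),
            class = "consensus_networks")
}

#' Relaxed-support consensus pass
#'
#' Re-runs clique averaging on the components not consumed by the
#' full-support pass, at a reduced support requirement (default 4: the rule
#' that rescues networks, like the thalamus, that only a minority of runs
#' recover). Returned networks carry their true support count.
#'
#' @param graph a [cross_correlate_runs()] result.
#' @param min_support reduced support requirement (>= 2).
#' @param exclude integer node ids already consumed (typically
#'   `consensus$used` from [extract_consensus()]).
#' @return a `consensus_networks` object with the additional networks.
#' @export
relaxed_consensus <- function(graph, min_support = 4L, exclude = integer(0)) {
  stopifnot(min_support >= 2L)
  avail <- setdiff(seq_len(nrow(graph$nodes)), exclude)
  cl <- harvest_cliques(graph, min_support, avail)
  out <- build_consensus(graph, cl)
  if (length(out$labels) > 0)
    out$labels <- sprintf("RSNr%02d", seq_along(out$labels))
  out
}

#' Merge two consensus sets
#'
#' Concatenates a full-support set with a relaxed-support set (labels and
#' support counts preserved).
#'
#' @param a,b `consensus_networks` objects on the same mask.
#' @return combined `consensus_networks`.
#' @export
combine_consensus <- function(a, b) {
  stopifnot(all(dim(a$mask) == dim(b$mask)))
  structure(list(maps = cbind(a$maps, b$maps),
                 support = c(a$support, b$support),
                 members = c(a$members, b$members),
                 labels = c(a$labels, b$labels),
                 artifact_flag = c(a$artifact_flag, b$artifact_flag),
                 mask = a$mask, threshold = a$threshold,
                 used = union(a$used, b$used)),
            class = "consensus_networks")
}

#' @export
print.consensus_networks <- function(x, ...) {
  cat(sprintf("<consensus_networks> %d networks (support %s)%s\n",
              ncol(x$maps), paste(x$support, collapse = ", "),
              if (any(x$artifact_flag))
                sprintf(", %d flagged artifact", sum(x$artifact_flag)) else ""))
  invisible(x)
}

#' Number of non-artifact networks
#' @param consensus a `consensus_networks` object.
#' @return integer count.
#' @export
n_clean_networks <- function(consensus) sum(!consensus$artifact_flag)

#' Heuristic artifact flagging of consensus networks
#'
#' Visual artifact identification cannot be automated faithfully; this
#' heuristic flags a network when more than half of its top-decile weight
#' voxels sit on the mask boundary shell (rim/edge components), or when the
#' mean high-frequency (> 0.1 Hz) time-course power fraction of its member
#' components exceeds `power_thresh`. A manual override list always wins.
#'
#' @param consensus a `consensus_networks` object.
#' @param runs optional list of `ica_run`s (enables the frequency heuristic
#'   via their mixing time courses).
#' @param boundary_frac fraction of top-decile voxels on the shell that
#'   triggers a flag (default 0.5).
#' @param power_thresh high-frequency power fraction that triggers a flag.
#' @param override named logical vector or list, `label = TRUE/FALSE`,
#'   forcing flags regardless of the heuristics.
#' @return the consensus object with `artifact_flag` filled in.
#' @export
flag_artifact_components <- function(consensus, runs = NULL,
                                     boundary_frac = 0.5,
                                     power_thresh = 0.5, override = NULL) {
  shell <- mask_vector(mask_boundary_shell(consensus$mask), consensus$mask)
  n <- ncol(consensus$maps)
  flags <- rep(FALSE, n)
  for (j in seq_len(n)) {
    v <- abs(consensus$maps[, j])
    top <- v >= quantile(v, 0.9)
    if (mean(shell[top]) > boundary_frac) flags[j] <- TRUE
    if (!is.null(runs)) {
      mem <- consensus$members[[j]]
      pw <- mapply(function(r, c) runs[[r]]$timecourse_power_high[c],
                   mem$run, mem$comp)
      if (mean(pw) > power_thresh) flags[j] <- TRUE
    }
  }
  if (!is.null(override)) {
    ov <- unlist(override)
    hit <- intersect(names(ov), consensus$labels)
    flags[match(hit, consensus$labels)] <- as.logical(ov[hit])
  }
  consensus$artifact_flag <- flags
  consensus
}

#' Write consensus networks to disk
#'
#' Maps go out as one 4D NIfTI (network index on the 4th dimension) with a
#' JSON sidecar (labels, support, members, artifact flags); the match graph
#' can be exported separately as an edge-list TSV with
#' [write_match_graph()].
#'
#' @param consensus a `consensus_networks` object.
#' @param stem output path stem.
#' @param gz gzip the image.
#' @return the image path, invisibly.
#' @export
write_consensus <- function(consensus, stem, gz = FALSE) {
  ext <- if (gz) ".nii.gz" else ".nii"
  arr <- unmask_matrix(consensus$maps, consensus$mask)
  write_nifti(arr, paste0(stem, ext))
  jsonlite::write_json(
    list(labels = consensus$labels, support = consensus$support,
         artifact_flag = consensus$artifact_flag,
         members = lapply(consensus$members, function(m)
           list(run = m$run, comp = m$comp)),
         threshold = consensus$threshold),
    paste0(stem, ".json"), digits = NA)
  invisible(paste0(stem, ext))
}

#' @rdname write_consensus
#' @param graph a [cross_correlate_runs()] result.
#' @param path TSV output path.
#' @export
write_match_graph <- function(graph, path) {
  e <- graph$edges
  out <- data.frame(run_i = graph$nodes$run[e$from],
                    comp_i = graph$nodes$comp[e$from],
                    run_j = graph$nodes$run[e$to],
                    comp_j = graph$nodes$comp[e$to],
                    r = e$r)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
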