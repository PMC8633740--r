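# Between-network connectivity: network time courses per session, Fisher-z
# edge matrices, paired edge-wise t tests, and network-level (NBS)
# permutation inference with the conventional thresholds (edge p < 0.01,
# component p < 0.05 familywise).

#' Network time courses for one session
#'
#' Returns the stage-1 dual-regression time courses of the consensus
#' networks (unit variance per course) — the natural weighted extraction
#' when networks come from ICA. A simple weighted-mean alternative
#' (`method = "weighted_mean"`) is provided.
#'
#' @param session a denoised [bold_session()].
#' @param consensus `consensus_networks` or `ground_truth_networks`.
#' @param method `"dual_regression"` (default) or `"weighted_mean"`.
#' @return K x T matrix of unit-variance time courses.
#' @export
network_timeseries <- function(session, consensus,
                               method = c("dual_regression",
                                          "weighted_mean")) {
  method <- match.arg(method)
  if (method == "dual_regression")
    return(dual_regression(session, consensus)$timecourses)
  X <- consensus_matrix(consensus)
  Y <- mask_matrix(session$data, session$mask)
  tc <- t(X) %*% Y / colSums(abs(X))           # K x T weighted means
  sds <- apply(tc, 1, sd)
  if (any(sds == 0)) stop("constant network time course (network ",
                          which(sds == 0)[1], ")")
  tc / sds
}

#' Fisher-z edge matrix from network time courses
#'
#' `z(i, j) = atanh(r(i, j))` with r the Pearson correlation between courses
#' i and j; correlations are clipped at `1 - 1e-12` in magnitude before the
#' transform. The diagonal is NA.
#'
#' @param timeseries K x T matrix (rows are networks).
#' @param subject_id,condition labels carried on the result.
#' @param labels optional network labels.
#' @return object of class `edge_matrix`: `z` (K x K, NA diagonal), labels.
#' @export
edge_matrix <- function(timeseries, subject_id = NA_character_,
                        condition = NA_character_, labels = NULL) {
  K <- nrow(timeseries)
  T <- ncol(timeseries)
  stopifnot(K >= 2L, T >= 3L)
  sds <- apply(timeseries, 1, sd)
  if (any(sds == 0))
    stop("constant time course for network ", which(sds == 0)[1])
  r <- cor(t(timeseries))
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z <- atanh(r)
  diag(z) <- NA_real_
  if (is.null(labels)) labels <- sprintf("net%02d", seq_len(K))
  dimnames(z) <- list(labels, labels)
  structure(list(z = z, subject_id = as.character(subject_id),
                 condition = as.character(condition), labels = labels),
            class = "edge_matrix")
}

#' @export
print.edge_matrix <- function(x, ...) {
  cat(sprintf("<edge_matrix> %d networks, subject %s (%s)\n",
              nrow(x$z), x$subject_id, x$condition))
  invisible(x)
}

# upper-triangle edge list helpers (i < j, column-major order as used by
# upper.tri)
edge_index <- function(K) {
  ut <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  ut[order(ut[, 2], ut[, 1]), , drop = FALSE]
}

edges_vector <- function(z) z[upper.tri(z)]

#' Paired edge-wise t test
#'
#' Per-edge paired t on the Fisher-z differences (drug minus placebo),
#' df = N - 1, with two-sided p values from the t distribution. These
#' uncorrected p values serve only as the NBS edge gate; inference is by
#' permutation ([network_level_inference()]).
#'
#' @param drug,placebo lists of [edge_matrix()] objects matched by subject.
#' @return list: `t_edges`, `p_edges` (K x K, NA diagonal), `z_diffs`
#'   (N x n_edges matrix), `df`, `labels`.
#' @export
paired_edge_test <- function(drug, placebo) {
  N <- length(drug)
  stopifnot(N == length(placebo), N >= 3L)
  ids_d <- unname(vapply(drug, `[[`, character(1), "subject_id"))
  ids_p <- unname(vapply(placebo, `[[`, character(1), "subject_id"))
  if (!identical(ids_d, ids_p))
    stop("drug and placebo edge matrices are not matched by subject")
  K <- nrow(drug[[1]]$z)
  D <- t(vapply(seq_len(N), function(i)
    edges_vector(drug[[i]]$z - placebo[[i]]$z), numeric(K * (K - 1) / 2)))
  tt <- one_sample_t(D)
  t_edges <- matrix(NA_real_, K, K)
  t_edges[upper.tri(t_edges)] <- tt$t
  t_edges[lower.tri(t_edges)] <- t(t_edges)[lower.tri(t_edges)]
  p_edges <- 2 * pt(abs(t_edges), df = N - 1, lower.tail = FALSE)
  labels <- drug[[1]]$labels
  dimnames(t_edges) <- dimnames(p_edges) <- list(labels, labels)
  list(t_edges = t_edges, p_edges = p_edges, z_diffs = D, df = N - 1L,
       labels = labels)
}

#' Network-level (NBS) permutation inference
#'
#' Per contrast direction: edges are gated at uncorrected p < `edge_p`
#' (paired t), connected components of the suprathreshold network graph are
#' formed, and each component is scored by its mass (sum of |t| over its
#' edges; extent available via `statistic = "extent"`). Whole-matrix sign
#' flips of the subject difference matrices rebuild the null distribution of
#' the maximal component mass;
#' `p_fwe = (1 + #\{perm max >= observed\}) / (1 + n_perm)`. Components with
#' `p_fwe < component_alpha` are kept.
#'
#' @param z_diffs N x n_edges matrix of per-subject Fisher-z differences
#'   (from [paired_edge_test()]), or the `paired_edge_test()` result itself.
#' @param K number of networks.
#' @param edge_p edge-inclusion threshold (default 0.01).
#' @param component_alpha component-level familywise alpha (default 0.05).
#' @param n_perm permutations (default 5000).
#' @param seed permutation seed.
#' @param labels network labels.
#' @param statistic component statistic, `"mass"` (default) or `"extent"`.
#' @return object of class `edge_contrast`: `t_edges`, `p_edges`,
#'   `components` (list with edges, networks, mass, direction, p_fwe),
#'   `thresholds`, `df`, `n_perm`.
#' @export
network_level_inference <- function(z_diffs, K = NULL, edge_p = 0.01,
                                    component_alpha = 0.05, n_perm = 5000L,
                                    seed = 1L, labels = NULL,
                                    statistic = c("mass", "extent")) {
  statistic <- match.arg(statistic)
  if (is.list(z_diffs)) {
    if (is.null(labels)) labels <- z_diffs$labels
    z_diffs <- z_diffs$z_diffs
  }
  N <- nrow(z_diffs)
  E <- ncol(z_diffs)
  if (is.null(K)) K <- as.integer((1 + sqrt(1 + 8 * E)) / 2)
  stopifnot(N >= 3L, K * (K - 1) / 2 == E, edge_p > 0, edge_p < 1,
            component_alpha > 0, component_alpha < 1)
  if (is.null(labels)) labels <- sprintf("net%02d", seq_len(K))
  ei <- edge_index(K)
  df <- N - 1L
  tcrit <- qt(1 - edge_p / 2, df)
  S <- sign_matrix(N, n_perm, seed)
  enumerated <- attr(S, "enumerated")
  res <- .nbs_perm_cpp(z_diffs, as.integer(ei[, 1] - 1L),
                       as.integer(ei[, 2] - 1L), as.integer(K), tcrit, S,
                       if (statistic == "mass") 0L else 1L)
  t_edges <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  t_edges[cbind(ei[, 1], ei[, 2])] <- res$t
  t_edges[cbind(ei[, 2], ei[, 1])] <- res$t
  p_edges <- 2 * pt(abs(t_edges), df, lower.tail = FALSE)
  components <- list()
  for (dir in c("pos", "neg")) {
    tvec <- if (dir == "pos") res$t else -res$t
    keep <- which(tvec > tcrit)
    if (length(keep) == 0) next
    g <- igraph::graph_from_edgelist(
      cbind(ei[keep, 1], ei[keep, 2]), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, K - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
    # familywise null over BOTH directions: per permutation, the largest
    # component mass in either direction (controls the whole-analysis FWER
    # at component_alpha without splitting alpha across directions)
    null_max <- pmax(res$max_pos, res$max_neg)
    for (ci in unique(memb[ei[keep, 1]])) {
      edges_in <- keep[memb[ei[keep, 1]] == ci & memb[ei[keep, 2]] == ci]
      mass <- sum(abs(res$t[edges_in]))
      stat_obs <- if (statistic == "mass") mass else length(edges_in)
      p_fwe <- if (enumerated) mean(null_max >= stat_obs) else
        (1 + sum(null_max[-1] >= stat_obs)) / (1 + n_perm)
      components[[length(components) + 1L]] <- list(
        edges = cbind(i = ei[edges_in, 1], j = ei[edges_in, 2]),
        networks = sort(unique(c(ei[edges_in, 1], ei[edges_in, 2]))),
        t = res$t[edges_in], mass = mass,
        direction = if (dir == "pos") "drug>placebo" else "placebo>drug",
        p_fwe = p_fwe)
    }
  }
  significant <- vapply(components, function(cc) cc$p_fwe < component_alpha,
                        logical(1))
  structure(list(t_edges = t_edges, p_edges = p_edges,
                 components = components, significant = significant,
                 thresholds = list(edge_p = edge_p,
                                   component_alpha = component_alpha),
                 labels = labels, df = df, n_perm = n_perm,
                 enumerated = enumerated),
            class = "edge_contrast")
}

#' @export
print.edge_contrast <- function(x, ...) {
  nsig <- sum(x$significant)
  cat(sprintf(
    "<edge_contrast> %d networks, %d suprathreshold component(s), %d significant (alpha %.2g)\n",
    nrow(x$t_edges), length(x$components), nsig,
    x$thresholds$component_alpha))
  invisible(x)
}

#' Significant network-pair table
#'
#' One row per edge of every significant component, sorted within direction
#' by |t| descending (decreases first, then increases), mirroring the
#' conventional reporting layout.
#'
#' @param result an [network_level_inference()] result.
#' @return data.frame with columns `pair`, `direction`, `t`, `p` (edge-level
#'   uncorrected p), `component_p_fwe`.
#' @export
report_pairs <- function(result) {
  rows <- list()
  for (ci in seq_along(result$components)) {
    cc <- result$components[[ci]]
    if (!result$significant[ci]) next
    for (q in seq_len(nrow(cc$edges))) {
      i <- cc$edges[q, 1]; j <- cc$edges[q, 2]
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(result$labels[i], "and", result$labels[j]),
        i = i, j = j, direction = cc$direction, t = cc$t[q],
        p = result$p_edges[i, j], component_p_fwe = cc$p_fwe,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(pair = character(0), i = integer(0), j = integer(0),
                      direction = character(0), t = numeric(0),
                      p = numeric(0), component_p_fwe = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("i", "j", "direction")]), ]
  ord <- order(out$direction != "placebo>drug", -abs(out$t))
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Write an edge matrix (or list of them) as CSV / long TSV
#'
#' @param em an [edge_matrix()] object.
#' @param path_csv K x K CSV path (header = labels); NULL skips.
#' @param path_tsv long-format TSV path (columns i, j, z); NULL skips.
#' @return invisibly, the paths written.
#' @export
write_edge_matrix <- function(em, path_csv = NULL, path_tsv = NULL) {
  if (!is.null(path_csv))
    write.csv(em$z, path_csv, row.names = TRUE)
  if (!is.null(path_tsv)) {
    ei <- edge_index(nrow(em$z))
    long <- data.frame(i = em$labels[ei[, 1]], j = em$labels[ei[, 2]],
                       z = em$z[ei])
    write.table(long, path_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(c(path_csv, path_tsv))
}
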