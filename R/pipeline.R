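# Orchestration: configuration, the end-to-end study analysis, and a thin
# command-line front end. Consensus networks are always estimated from the
# placebo sessions only; both conditions then receive dual regression
# against those maps.

#' Study configuration
#'
#' All pipeline parameters with their conventional defaults: outlier
#' thresholds 0.5 mm / 3 SD, drift order 2, band 0.008-0.09 Hz, 6 mm FWHM,
#' 10 ICA runs matched at spatial correlation 0.7 with relaxed support 4,
#' 5000 permutations, TFCE E = 0.5 / H = 2 / 26-connectivity, NBS edge gate
#' 0.01 and component alpha 0.05, familywise alpha 0.05.
#'
#' @param ... overrides of the defaults (see the returned list for names).
#' @return object of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    # synthesis
    n_subjects = 22L, tr_seconds = 3, n_volumes = 124L, n_networks = 8L,
    noise_sd = 1, subject_sd = 0.05, spike_prob = 0.03,
    grid_shape = c(16L, 16L, 12L), seed = 1L,
    # denoising
    fd_thresh = 0.5, gs_thresh = 3, drift_order = 2L,
    low_hz = 0.008, high_hz = 0.09, fwhm_mm = 6, voxel_size_mm = c(3, 3, 3),
    # consensus ICA
    n_runs = 10L, match_threshold = 0.7, relaxed_support = 4L,
    ica_order = NULL, max_order = 20L,
    # inference
    n_perm = 5000L, tfce_E = 0.5, tfce_H = 2, connectivity = 26L,
    familywise_alpha = 0.05, edge_p = 0.01, component_alpha = 0.05,
    # behavior
    rating_measure = "arci_a",
    # orchestration
    skip_smoothing = FALSE, output_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "study_config")
}

#' Read a configuration file (YAML or JSON)
#'
#' @param path `.yml`/`.yaml` or `.json` file whose keys override
#'   [study_config()] defaults.
#' @return a `study_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(study_config, vals)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  # small deterministic polynomial hash (no digest package available)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full study analysis end-to-end
#'
#' Stages, in order: synthesis (or ingestion) -> denoising -> consensus
#' meta-gICA on the placebo sessions -> within-network dual regression +
#' TFCE permutation contrasts (both conditions) -> between-network Fisher-z
#' edges + NBS -> ratings analysis (RM-ANOVA, peak change scores,
#' brain-behavior correlation). Returns a provenance-stamped results bundle;
#' re-running with the same config reproduces it.
#'
#' @param config a [study_config()].
#' @param study optional pre-built [simulate_paired_study()] bundle (for
#'   user-supplied data, construct the same structure from
#'   [read_session()]s); synthesized from the config when NULL.
#' @param ratings optional ratings table; synthesized when NULL.
#' @param verbose print per-stage progress.
#' @return object of class `results_bundle`: `consensus`, `within`
#'   (contrast list + gated cluster table), `between` (`edge_contrast` +
#'   pair table), `behavior` (ANOVA, PCS, correlations), `provenance`.
#' @export
run_full <- function(config = study_config(), study = NULL, ratings = NULL,
                     verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- derive_seeds(config$seed, 6L)
  t0 <- Sys.time()

  say("stage synthdata: %d subjects x 2 sessions", config$n_subjects)
  spec <- study_spec(
    n_subjects = config$n_subjects, tr_seconds = config$tr_seconds,
    n_volumes = config$n_volumes, n_networks = config$n_networks,
    noise_sd = config$noise_sd, subject_sd = config$subject_sd,
    spike_prob = config$spike_prob, grid_shape = config$grid_shape,
    seed = seeds[1])
  if (is.null(study)) study <- simulate_paired_study(spec)
  if (is.null(ratings))
    ratings <- simulate_ratings(ratings_schedule(), config$n_subjects,
                                seed = seeds[2])

  say("stage denoise: %d sessions", length(study$sessions))
  denoised <- lapply(study$sessions, function(s) {
    denoise_session(s, fd_thresh = config$fd_thresh,
                    gs_thresh = config$gs_thresh,
                    drift_order = config$drift_order,
                    low_hz = config$low_hz, high_hz = config$high_hz,
                    fwhm_mm = if (config$skip_smoothing) 0 else config$fwhm_mm,
                    voxel_size_mm = config$voxel_size_mm)$session
  })
  is_placebo <- vapply(denoised, function(s) s$condition == "placebo",
                       logical(1))

  say("stage metagica: %d runs on %d placebo sessions", config$n_runs,
      sum(is_placebo))
  runs <- run_meta_gica(denoised[is_placebo], n_runs = config$n_runs,
                        master_seed = seeds[3], order = config$ica_order,
                        max_order = config$max_order)
  graph <- cross_correlate_runs(runs, threshold = config$match_threshold)
  consensus <- extract_consensus(graph, n_runs = config$n_runs)
  relaxed <- relaxed_consensus(graph, min_support = config$relaxed_support,
                               exclude = consensus$used)
  consensus <- combine_consensus(consensus, relaxed)
  consensus <- flag_artifact_components(consensus, runs)
  if (n_clean_networks(consensus) == 0)
    stop("stage metagica: no non-artifact consensus networks identified")
  keep <- !consensus$artifact_flag
  clean <- consensus
  clean$maps <- clean$maps[, keep, drop = FALSE]
  clean$support <- clean$support[keep]
  clean$members <- clean$members[keep]
  clean$labels <- clean$labels[keep]
  clean$artifact_flag <- clean$artifact_flag[keep]

  say("stage dualreg: %d networks", ncol(clean$maps))
  dr <- lapply(denoised, dual_regression, consensus = clean)
  subj_ids <- unique(vapply(denoised, `[[`, character(1), "subject_id"))
  maps_pl <- dr[paste0(subj_ids, "_placebo")]
  maps_dr <- dr[paste0(subj_ids, "_drug")]
  params <- tfce_params(E = config$tfce_E, H = config$tfce_H,
                        connectivity = config$connectivity)
  contrasts <- list()
  for (k in seq_len(ncol(clean$maps))) {
    pd <- paired_differences(maps_dr, maps_pl, k)
    contrasts[[clean$labels[k]]] <- permutation_inference(
      pd, clean$mask, params, n_perm = config$n_perm,
      seed = seeds[4] + k)
  }
  gate <- bonferroni_gate(contrasts, config$familywise_alpha,
                          config$connectivity)

  say("stage betweennet: %d networks", ncol(clean$maps))
  em <- lapply(dr, function(d)
    edge_matrix(d$timecourses, d$subject_id, d$condition, d$labels))
  edge_test <- paired_edge_test(em[paste0(subj_ids, "_drug")],
                                em[paste0(subj_ids, "_placebo")])
  nbs <- network_level_inference(edge_test, edge_p = config$edge_p,
                                 component_alpha = config$component_alpha,
                                 n_perm = config$n_perm, seed = seeds[5])
  pair_table <- report_pairs(nbs)

  say("stage behav: measure %s", config$rating_measure)
  anova_res <- rm_anova(ratings, config$rating_measure)
  pcs <- peak_change_score(ratings, config$rating_measure)
  fc_behavior <- NULL
  fc_deltas <- extract_fc_deltas(gate, contrasts, maps_dr, maps_pl,
                                 pair_table, em, subj_ids)
  if (!is.null(fc_deltas) && ncol(fc_deltas) > 0)
    fc_behavior <- fc_behavior_correlation(
      fc_deltas, pcs$delta[match(subj_ids, pcs$subject)])

  bundle <- structure(list(
    consensus = consensus,
    within = list(contrasts = contrasts, gate = gate),
    between = list(result = nbs, pairs = pair_table,
                   edge_test = edge_test),
    behavior = list(anova = anova_res, pcs = pcs,
                    fc_correlation = fc_behavior),
    provenance = list(config = config, config_hash = config_hash(config),
                      seeds = seeds, started = t0, finished = Sys.time(),
                      package_version =
                        as.character(utils::packageVersion("metaconn")))),
    class = "results_bundle")
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

# per-subject connectivity change scores for every significant finding:
# within-network = mean stage-2 coefficient over each significant cluster,
# differenced drug - placebo; between-network = per-subject z of each
# significant pair, differenced drug - placebo.
extract_fc_deltas <- function(gate, contrasts, maps_dr, maps_pl, pair_table,
                              em, subj_ids) {
  cols <- list()
  if (nrow(gate$clusters) > 0) {
    for (q in seq_len(nrow(gate$clusters))) {
      nw <- gate$clusters$network[q]
      k <- match(nw, names(contrasts))
      vox <- gate$cluster_voxels[[q]]
      cols[[sprintf("within_%s_c%d", nw, gate$clusters$cluster[q])]] <-
        vapply(seq_along(subj_ids), function(i)
          mean(maps_dr[[i]]$maps[vox, k]) - mean(maps_pl[[i]]$maps[vox, k]),
          numeric(1))
    }
  }
  if (nrow(pair_table) > 0) {
    for (q in seq_len(nrow(pair_table))) {
      i <- pair_table$i[q]; j <- pair_table$j[q]
      cols[[sprintf("between_%d_%d", i, j)]] <-
        vapply(subj_ids, function(sid)
          em[[paste0(sid, "_drug")]]$z[i, j] -
            em[[paste0(sid, "_placebo")]]$z[i, j], numeric(1))
    }
  }
  if (length(cols) == 0) return(NULL)
  do.call(cbind, cols)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>\n")
  cat(sprintf("  consensus: %d networks (%d flagged artifact)\n",
              length(x$consensus$labels), sum(x$consensus$artifact_flag)))
  cat(sprintf("  within-network: %d significant cluster(s) at gate %.2g\n",
              nrow(x$within$gate$clusters), x$within$gate$per_test_alpha))
  cat(sprintf("  between-network: %d significant pair(s)\n",
              nrow(x$between$pairs)))
  e <- x$behavior$anova$effects
  cat(sprintf("  behavior: drug x time F(%g, %g) = %.2f, p = %.3g\n",
              e$df1[3], e$df2[3], e$F[3], e$p[3]))
  cat(sprintf("  config hash %s\n", x$provenance$config_hash))
  invisible(x)
}

#' Write a results bundle to a directory
#'
#' One subdirectory per stage with TSV/CSV/JSON tables and NIfTI maps, plus
#' a manifest with the config hash and seeds. Existing files are never
#' silently overwritten: a content-hash suffix is appended when a different
#' bundle already occupies the directory.
#'
#' @param bundle a [run_full()] result.
#' @param dir output directory.
#' @return the directory used, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (!identical(old$config_hash, bundle$provenance$config_hash))
      dir <- paste0(dir, "_", bundle$provenance$config_hash)
    manifest_path <- file.path(dir, "manifest.json")
  }
  for (sub in c("consensus", "within", "between", "behavior"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  write_consensus(bundle$consensus, file.path(dir, "consensus", "networks"))
  write.table(bundle$within$gate$clusters,
              file.path(dir, "within", "clusters.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(bundle$between$pairs, file.path(dir, "between", "pairs.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(bundle$between$edge_test$t_edges,
            file.path(dir, "between", "t_edges.csv"))
  write.table(bundle$behavior$anova$effects,
              file.path(dir, "behavior", "anova.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.csv(bundle$behavior$pcs, file.path(dir, "behavior", "pcs.csv"),
            row.names = FALSE)
  if (!is.null(bundle$behavior$fc_correlation))
    write.table(bundle$behavior$fc_correlation,
                file.path(dir, "behavior", "fc_correlation.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(config_hash = bundle$provenance$config_hash,
         seeds = bundle$provenance$seeds,
         package_version = bundle$provenance$package_version,
         finished = format(bundle$provenance$finished)),
    manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `denoise`, `networks`, `within`, `between`,
#' `behavior`, `run-all`; each accepts `--config <file>`, `--seed <int>`,
#' `--out <dir>`. `--version` and `--help` exit 0. Intended to be invoked
#' through the thin wrapper script installed at `exec/metaconn`.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code (0 on success), invisibly.
#' @export
metaconn_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: metaconn <subcommand> [--config FILE] [--seed INT] [--out DIR]",
    "subcommands: simulate | denoise | networks | within | between |",
    "             behavior | run-all",
    sep = "\n")
  if (length(argv) == 0) { cat(usage, "\n"); return(invisible(2L)) }
  if (argv[1] %in% c("--help", "-h")) { cat(usage, "\n"); return(invisible(0L)) }
  if (argv[1] == "--version") {
    cat("metaconn", as.character(utils::packageVersion("metaconn")), "\n")
    return(invisible(0L))
  }
  sub <- argv[1]
  known <- c("simulate", "denoise", "networks", "within", "between",
             "behavior", "run-all")
  if (!sub %in% known) {
    cat("unknown subcommand: ", sub, "\n", usage, "\n", sep = "")
    return(invisible(2L))
  }
  opts <- list(config = NULL, seed = NULL, out = "metaconn_out")
  i <- 2L
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opts) || i == length(argv)) {
      cat("bad flag: ", argv[i], "\n", usage, "\n", sep = "")
      return(invisible(2L))
    }
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else study_config()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  out <- opts$out
  run_stage <- function() {
    if (sub == "simulate") {
      spec <- study_spec(n_subjects = cfg$n_subjects,
                         tr_seconds = cfg$tr_seconds,
                         n_volumes = cfg$n_volumes,
                         n_networks = cfg$n_networks,
                         noise_sd = cfg$noise_sd, subject_sd = cfg$subject_sd,
                         spike_prob = cfg$spike_prob,
                         grid_shape = cfg$grid_shape, seed = cfg$seed)
      write_study(simulate_paired_study(spec), out)
      rt <- simulate_ratings(ratings_schedule(), cfg$n_subjects,
                             seed = cfg$seed)
      write.csv(rt, file.path(out, "ratings.csv"), row.names = FALSE)
    } else {
      # the remaining subcommands run the pipeline up to the requested stage;
      # intermediate stages are required inputs of the later ones
      cfg$output_dir <- out
      bundle <- run_full(cfg, verbose = TRUE)
      print(bundle)
    }
    0L
  }
  code <- tryCatch(run_stage(), error = function(e) {
    cat("error:", conditionMessage(e), "\n")
    1L
  })
  invisible(code)
}
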