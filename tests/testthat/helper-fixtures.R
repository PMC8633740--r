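# Shared fixtures (built once per test run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small planted-network study: 5 networks on a 12x12x10 grid
small_truth <- function() fixture("small_truth", function()
  generate_network_maps(5, c(12L, 12L, 10L), seed = 7))

small_spec <- function(...) {
  args <- list(n_subjects = 4L, n_networks = 5L, noise_sd = 0.5,
               spike_prob = 0, grid_shape = c(12L, 12L, 10L), seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(study_spec, args)
}

# a clean noiseless session driven by the small truth maps
noiseless_session <- function(seed = 3) {
  simulate_session(small_truth(), small_spec(noise_sd = 0), seed = seed)
}

# in-mask truth map matrix
truth_mat <- function(truth = small_truth()) {
  K <- dim(truth$maps)[4]
  vapply(seq_len(K), function(k)
    truth$maps[, , , k][as.logical(truth$mask)], numeric(sum(truth$mask)))
}

# ---- independent oracles -------------------------------------------------

# Brute-force TFCE: rebuilds the suprathreshold clusters at every threshold
# step independently (igraph components), no shared code with the C++ path.
brute_tfce <- function(m, E = 0.5, H = 2, nsteps = 100, conn = 26,
                       dh = NULL) {
  mx <- max(m)
  if (mx <= 0) return(array(0, dim(m)))
  if (is.null(dh)) dh <- mx / nsteps
  out <- array(0, dim(m))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & nz <= c("6" = 1, "18" = 2, "26" = 3)[as.character(conn)], ]
  dm <- dim(m)
  for (step in seq_len(floor(mx / dh + 1e-12))) {
    h <- step * dh
    sup <- which(m >= h)
    if (length(sup) == 0) next
    co <- arrayInd(sup, dm)
    g <- igraph::make_empty_graph(length(sup), directed = FALSE)
    el <- c()
    for (o in seq_len(nrow(offs))) {
      nb <- sweep(co, 2, offs[o, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
        nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
      lin <- nb[ok, 1] + dm[1] * (nb[ok, 2] - 1) +
        dm[1] * dm[2] * (nb[ok, 3] - 1)
      src <- which(ok)
      hit <- !is.na(match(lin, sup))
      el <- c(el, rbind(src[hit], match(lin[hit], sup)))
    }
    if (length(el)) g <- igraph::add_edges(g, el)
    memb <- igraph::components(g)$membership
    sz <- table(memb)
    out[sup] <- out[sup] + as.numeric(sz[memb])^E * h^H * dh
  }
  out
}

# signed brute-force TFCE matching tfce()
brute_tfce_signed <- function(m, ...) brute_tfce(m, ...) - brute_tfce(-m, ...)

# RM-ANOVA oracle via stats::aov with an Error() stratum
aov_oracle <- function(tb) {
  tb$subject <- factor(tb$subject)
  tb$condition <- factor(tb$condition)
  tb$time <- factor(tb$time_min)
  fit <- summary(stats::aov(
    value ~ condition * time + Error(subject / (condition * time)),
    data = tb))
  get_f <- function(stratum, row) {
    s <- fit[[stratum]][[1]]
    c(F = s[row, "F value"], df1 = s[row, "Df"],
      df2 = s[nrow(s), "Df"], p = s[row, "Pr(>F)"])
  }
  list(drug = get_f("Error: subject:condition", 1),
       time = get_f("Error: subject:time", 1),
       interaction = get_f("Error: subject:condition:time", 1))
}

# random balanced ratings table with arbitrary cell effects
random_ratings <- function(n_subj, n_time, seed) {
  withr::with_seed(seed, {
    tp <- c(-10, sort(sample(10:200, n_time - 1)))
    rows <- expand.grid(subject = sprintf("s%02d", seq_len(n_subj)),
                        condition = c("placebo", "drug"), time_min = tp,
                        stringsAsFactors = FALSE)
    rows$measure <- "m"
    rows$session <- ifelse(rows$condition == "placebo", 1L, 2L)
    rows$value <- rnorm(nrow(rows), sd = 2) +
      2 * (rows$condition == "drug") * (rows$time_min > 50)
    rows
  })
}

# build a synthetic ica_run whose components are z-scored noisy copies of
# given in-mask maps (plus optional pure-noise components)
make_fake_run <- function(run_id, maps_inmask, mask, noise = 0.15,
                          extra_noise_comps = 0,
                          seed = 7919L * run_id + 101L) {
  withr::with_seed(seed, {
    comp <- apply(maps_inmask, 2, function(v)
      v + rnorm(length(v), sd = noise * sd(v)))
    if (extra_noise_comps > 0)
      comp <- cbind(comp, matrix(rnorm(nrow(comp) * extra_noise_comps),
                                 ncol = extra_noise_comps))
    comp <- apply(comp, 2, function(v) (v - mean(v)) / sd(v))
  })
  structure(list(components = comp, subject_order = seq_len(2),
                 model_order = ncol(comp), run_id = as.integer(run_id),
                 seed = as.integer(seed), mask = mask,
                 timecourse_power_high = rep(0, ncol(comp))),
            class = "ica_run")
}
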