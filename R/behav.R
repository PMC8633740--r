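# Subjective/cardiovascular analysis: mean arterial pressure, two-factor
# fully-within-subject repeated-measures ANOVA, peak change scores, and
# Bonferroni-corrected Pearson correlations between connectivity change and
# subjective-response change.

#' Mean arterial pressure
#'
#' Standard clinical weighting of the cardiac cycle:
#' `MAP = (SBP + 2 DBP) / 3`.
#'
#' @param sbp systolic blood pressure, mmHg.
#' @param dbp diastolic blood pressure, mmHg (must be strictly below `sbp`).
#' @return MAP in mmHg (vectorized).
#' @export
#' @examples
#' mean_arterial_pressure(120, 80)  # 93.33
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(dbp <= 0) || any(sbp <= dbp))
    stop("need sbp > dbp > 0")
  (sbp + 2 * dbp) / 3
}

# check a long ratings table for a complete subject x condition x timepoint
# crossing for `measure`; returns the subset
check_ratings <- function(table, measure) {
  tb <- table[table$measure == measure, , drop = FALSE]
  if (nrow(tb) == 0) stop("no rows for measure ", measure)
  xt <- table(tb$subject, tb$condition, tb$time_min)
  if (any(xt != 1)) {
    bad <- which(xt != 1, arr.ind = TRUE)
    stop("ratings table is not a complete crossing for measure ", measure,
         " (e.g. subject ", rownames(xt)[bad[1, 1]], ", condition ",
         colnames(xt)[bad[1, 2]], ", t = ", dimnames(xt)[[3]][bad[1, 3]], ")")
  }
  tb
}

#' Two-factor fully within-subject repeated-measures ANOVA
#'
#' Drug (condition) and time are both within-subject factors; each effect is
#' tested against its own subject-by-effect interaction error term
#' (uncorrected df; a Greenhouse-Geisser epsilon is reported for optional
#' correction but not applied by default).
#'
#' @param table long ratings table (columns `subject`, `condition`,
#'   `time_min`, `measure`, `value`) with a complete balanced crossing.
#' @param measure measure name to analyze.
#' @param gg_correct apply the Greenhouse-Geisser correction to the reported
#'   df/p (default FALSE).
#' @return object of class `rm_anova`: data.frame `effects` with F, df1,
#'   df2, p per effect (`drug`, `time`, `drug:time`).
#' @export
rm_anova <- function(table, measure, gg_correct = FALSE) {
  tb <- check_ratings(table, measure)
  subj <- factor(tb$subject)
  drug <- factor(tb$condition)
  time <- factor(tb$time_min)
  y <- tb$value
  n <- nlevels(subj); a <- nlevels(drug); b <- nlevels(time)
  stopifnot(n >= 3L, a >= 2L, b >= 2L)
  cell_mean <- function(f) tapply(y, f, mean)
  gm <- mean(y)
  m_s <- cell_mean(subj); m_a <- cell_mean(drug); m_b <- cell_mean(time)
  m_sa <- tapply(y, list(subj, drug), mean)
  m_sb <- tapply(y, list(subj, time), mean)
  m_ab <- tapply(y, list(drug, time), mean)
  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, m_b, `+`) + gm)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, m_a, `+`) + gm)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, m_b, `+`) + gm)^2)
  # residual (subject x drug x time) error term for the interaction
  m_full <- y  # one observation per cell
  pred <- m_sa[cbind(subj, drug)] + m_sb[cbind(subj, time)] +
    m_ab[cbind(drug, time)] - m_s[subj] - m_a[drug] - m_b[time] + gm
  ss_sab <- sum((m_full - pred)^2)
  eff <- data.frame(
    effect = c("drug", "time", "drug:time"),
    ss = c(ss_a, ss_b, ss_ab),
    ss_err = c(ss_sa, ss_sb, ss_sab),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1)),
    stringsAsFactors = FALSE)
  eff$F <- (eff$ss / eff$df1) / (eff$ss_err / eff$df2)
  eff$epsilon <- c(1, gg_epsilon(m_sb), gg_epsilon_int(tb, subj, drug, time))
  if (gg_correct) {
    eff$df1 <- eff$df1 * eff$epsilon
    eff$df2 <- eff$df2 * eff$epsilon
  }
  eff$p <- pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  structure(list(effects = eff, measure = measure, n_subjects = n,
                 gg_correct = gg_correct), class = "rm_anova")
}

# Greenhouse-Geisser epsilon from a subject x level matrix of means
gg_epsilon <- function(m_sb) {
  S <- cov(m_sb)
  k <- ncol(S)
  mean_diag <- mean(diag(S))
  mean_all <- mean(S)
  num <- (k * (mean_diag - mean_all))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mean_all^2)
  if (den <= 0) return(1)
  min(1, max(num / den, 1 / (k - 1)))
}

gg_epsilon_int <- function(tb, subj, drug, time) {
  if (nlevels(drug) != 2L) return(1)
  # epsilon on the per-subject drug-difference profiles across time
  d <- tapply(tb$value, list(subj, time, drug), mean)
  gg_epsilon(d[, , 2] - d[, , 1])
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> measure %s, %d subjects%s\n", x$measure,
              x$n_subjects,
              if (x$gg_correct) " (Greenhouse-Geisser corrected)" else ""))
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-10s F(%.3g, %.3g) = %.3f, p = %.4g\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i]))
  invisible(x)
}

#' Peak change scores
#'
#' Per subject and session, `PCS = max over post-dose timepoints of
#' (value - session baseline)`; the baseline is the (single) pre-dose
#' timepoint of the same session. `delta = PCS_drug - PCS_placebo`.
#'
#' @param table long ratings table.
#' @param measure measure name.
#' @return data.frame with one row per subject: `subject`, `pcs_placebo`,
#'   `pcs_drug`, `delta`.
#' @export
peak_change_score <- function(table, measure) {
  tb <- check_ratings(table, measure)
  if (!any(tb$time_min < 0)) stop("no pre-dose baseline timepoint")
  subjects <- sort(unique(tb$subject))
  pcs <- function(sub, cond) {
    s <- tb[tb$subject == sub & tb$condition == cond, ]
    base <- s$value[s$time_min < 0]
    if (length(base) != 1L)
      stop("expected exactly one baseline for subject ", sub, " (", cond, ")")
    max(s$value[s$time_min > 0] - base)
  }
  out <- data.frame(
    subject = subjects,
    pcs_placebo = vapply(subjects, pcs, numeric(1), cond = "placebo"),
    pcs_drug = vapply(subjects, pcs, numeric(1), cond = "drug"))
  out$delta <- out$pcs_drug - out$pcs_placebo
  rownames(out) <- NULL
  out
}

#' Correlate connectivity change with subjective-response change
#'
#' Pearson correlations between each column of `fc_deltas` (per-subject
#' drug-minus-placebo connectivity change scores: mean stage-2 coefficient
#' over a significant cluster, or the Fisher z of a significant network
#' pair) and `pcs_deltas` (drug-minus-placebo peak-change-score difference),
#' with two-sided p values and a Bonferroni multiplier equal to the number
#' of connectivity measures tested.
#'
#' @param fc_deltas numeric matrix or data.frame, one column per
#'   connectivity measure, one row per subject.
#' @param pcs_deltas numeric vector, same subjects.
#' @return data.frame: `measure`, `r`, `p_raw`, `p_bonferroni`,
#'   `significant` (at 0.05 after correction). Zero-variance pairings give
#'   an NA correlation.
#' @export
fc_behavior_correlation <- function(fc_deltas, pcs_deltas) {
  fc <- as.matrix(fc_deltas)
  stopifnot(nrow(fc) == length(pcs_deltas), nrow(fc) >= 4L)
  m <- ncol(fc)
  nm <- colnames(fc) %||% sprintf("fc%02d", seq_len(m))
  out <- data.frame(measure = nm, r = NA_real_, p_raw = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    x <- fc[, j]
    if (sd(x) == 0 || sd(pcs_deltas) == 0) next
    ct <- stats::cor.test(x, pcs_deltas)
    out$r[j] <- unname(ct$estimate)
    out$p_raw[j] <- ct$p.value
  }
  out$p_bonferroni <- pmin(1, out$p_raw * m)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < 0.05
  out
}

#' Per-timepoint mean and SEM plot of ratings
#'
#' Base-graphics reproduction of the classic timecourse figure: mean with
#' SEM bars per timepoint, one line per condition.
#'
#' @param table long ratings table.
#' @param measure measure to plot.
#' @param file optional output path (`.svg` or `.png`); NULL draws on the
#'   active device.
#' @return invisibly, the summarized data.frame.
#' @export
plot_ratings <- function(table, measure, file = NULL) {
  tb <- check_ratings(table, measure)
  agg <- aggregate(value ~ condition + time_min, tb, function(v)
    c(mean = mean(v), sem = sd(v) / sqrt(length(v))))
  agg <- data.frame(condition = agg$condition, time_min = agg$time_min,
                    mean = agg$value[, "mean"], sem = agg$value[, "sem"])
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 6, height = 4)
    else grDevices::png(file, width = 720, height = 480)
    on.exit(grDevices::dev.off())
  }
  rng <- range(agg$mean - agg$sem, agg$mean + agg$sem)
  plot(NA, xlim = range(agg$time_min), ylim = rng,
       xlab = "time relative to dosing (min)", ylab = measure,
       main = paste("Mean ± SEM:", measure))
  conds <- unique(agg$condition)
  for (ci in seq_along(conds)) {
    a <- agg[agg$condition == conds[ci], ]
    a <- a[order(a$time_min), ]
    graphics::lines(a$time_min, a$mean, col = ci, type = "b",
                    pch = c(21, 22)[ci])
    graphics::arrows(a$time_min, a$mean - a$sem, a$time_min, a$mean + a$sem,
                     angle = 90, code = 3, length = 0.03, col = ci)
  }
  graphics::legend("topright", legend = conds, col = seq_along(conds),
                   pch = c(21, 22), bty = "n")
  invisible(agg)
}
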