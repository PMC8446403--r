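#' Odds ratio for a 2x2 table, with Haldane zero-cell correction
#'
#' Cell layout: `a` = patients with the event, `b` = patients without,
#' `c` = controls with the event, `d` = controls without, so the odds ratio
#' is the event odds in patients over the event odds in controls. When any
#' cell is zero the Woolf–Haldane correction adds 0.5 to *all four* cells
#' before forming the ratio, which keeps the odds ratio and its logit-based
#' confidence interval defined.
#'
#' @param a,b,c,d Nonnegative integer counts.
#' @return List with `or` and logical `corrected`.
#' @export
odds_ratio <- function(a, b, c, d) {
  check_counts(a, b, c, d)
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(or = (a * d) / (b * c), corrected = corrected)
}

check_counts <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  if (a + b == 0 || c + d == 0)
    stop("empty group margin in 2x2 table")
  invisible(NULL)
}

#' Woolf confidence interval for an odds ratio
#'
#' Logit-scale interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When the table
#' required the Haldane correction, the corrected cells are used in both the
#' odds ratio and the variance term.
#'
#' @inheritParams odds_ratio
#' @param level Confidence level (default 0.95).
#' @return List with `ci_low`, `ci_high`.
#' @export
or_confidence_interval <- function(a, b, c, d, level = 0.95) {
  check_counts(a, b, c, d)
  stopifnot(level >= 0, level < 1)
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  lor <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm((1 + level) / 2)
  list(ci_low = exp(lor - z * se), ci_high = exp(lor + z * se))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditions on both margins: with the margins fixed, the count in cell `a`
#' follows a hypergeometric distribution. The two-sided p-value is the sum
#' of the probabilities of all tables whose point probability does not
#' exceed that of the observed table (point-probability method, within a
#' relative tolerance of 1e-7 to absorb floating-point ties).
#'
#' @inheritParams odds_ratio
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  m <- a + b          # patient margin
  n <- c + d          # control margin
  k <- a + c          # event margin
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Full contingency comparison for one event
#'
#' Bundles the odds ratio, Woolf confidence interval, and two-sided Fisher
#' exact p-value for one 2x2 table.
#'
#' @inheritParams odds_ratio
#' @param level Confidence level for the interval.
#' @return List with `a`, `b`, `c`, `d`, `corrected`, `or`, `ci_low`,
#'   `ci_high`, `p_two_sided`.
#' @export
contingency_result <- function(a, b, c, d, level = 0.95) {
  or <- odds_ratio(a, b, c, d)
  ci <- or_confidence_interval(a, b, c, d, level)
  list(a = a, b = b, c = c, d = d, corrected = or$corrected, or = or$or,
       ci_low = ci$ci_low, ci_high = ci$ci_high,
       p_two_sided = fisher_exact(a, b, c, d))
}

#' Compare decline/improvement rates between groups
#'
#' Builds, for every measure and for each event type (declined, improved),
#' the 2x2 patients-versus-controls table and computes the odds ratio,
#' confidence interval, and Fisher exact p.
#'
#' @param change_scores Long data frame from [score_cohort()].
#' @param level Confidence level.
#' @return Data frame: one row per measure x event type with columns
#'   `measure_id`, `event`, `a`, `b`, `c`, `d`, `corrected`, `or`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
compare_rates <- function(change_scores, level = 0.95) {
  out <- list()
  for (m in unique(change_scores$measure_id)) {
    sub <- change_scores[change_scores$measure_id == m, , drop = FALSE]
    pat <- sub[sub$group == "patient", , drop = FALSE]
    ctl <- sub[sub$group == "control", , drop = FALSE]
    for (ev in c("declined", "improved")) {
      a <- sum(pat$category == ev); b <- nrow(pat) - a
      c <- sum(ctl$category == ev); d <- nrow(ctl) - c
      res <- contingency_result(a, b, c, d, level)
      out[[length(out) + 1L]] <- data.frame(
        measure_id = m, event = ev, a = a, b = b, c = c, d = d,
        corrected = res$corrected, or = res$or, ci_low = res$ci_low,
        ci_high = res$ci_high, p = res$p_two_sided,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' BCa bootstrap confidence interval for a difference in means
#'
#' Bias-corrected and accelerated (BCa) interval for `mean(x) - mean(y)`.
#' The bias correction z0 comes from the fraction of bootstrap statistics
#' below the observed difference; the acceleration comes from the jackknife
#' skewness of the statistic. If the jackknife distribution is degenerate
#' (zero variance) the function falls back to the plain percentile interval
#' with a warning.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `estimate`, `ci_low`, `ci_high`, `method` ("bca" or
#'   "percentile").
#' @export
bca_bootstrap_mean_diff <- function(x, y, n_boot = 10000, level = 0.95,
                                    seed = NULL) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(x) - mean(y)
  nx <- length(x); ny <- length(y)
  boots <- vapply(seq_len(n_boot), function(i)
    mean(x[sample.int(nx, nx, replace = TRUE)]) -
      mean(y[sample.int(ny, ny, replace = TRUE)]),
    numeric(1))
  alpha <- (1 - level) / 2
  # jackknife over the concatenated sample, leaving one observation out
  jack <- c(vapply(seq_len(nx), function(i) mean(x[-i]) - mean(y), numeric(1)),
            vapply(seq_len(ny), function(i) mean(x) - mean(y[-i]), numeric(1)))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)
  if (denom <= 0) {
    warning("degenerate jackknife distribution; ",
            "falling back to percentile interval")
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE,
                          type = 6)
    return(list(estimate = obs, ci_low = qs[1], ci_high = qs[2],
                method = "percentile"))
  }
  accel <- sum((jm - jack)^3) / (6 * denom^1.5)
  prop_below <- mean(boots < obs)
  prop_below <- min(max(prop_below, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
  z0 <- stats::qnorm(prop_below)
  adj <- function(alph) {
    za <- stats::qnorm(alph)
    stats::pnorm(z0 + (z0 + za) / (1 - accel * (z0 + za)))
  }
  qs <- stats::quantile(boots, c(adj(alpha), adj(1 - alpha)), names = FALSE,
                        type = 6)
  list(estimate = obs, ci_low = qs[1], ci_high = qs[2], method = "bca")
}

#' Group-by-time test for a two-timepoint continuous variable
#'
#' Two complementary views of the same question. (1) A change-score
#' regression of `delta = t2 - t1` on baseline, group, and group x baseline,
#' reporting standardized coefficients and p-values for the group and
#' interaction terms. (2) A repeated-measures (mixed) ANOVA with group as
#' the between-subject factor and time as the within-subject factor,
#' reporting the group x time interaction F and p.
#'
#' @param t1,t2 Numeric vectors of baseline and follow-up values.
#' @param group Character/factor vector of group labels (two levels).
#' @return List with `beta_group`, `p_group`, `beta_interaction`,
#'   `p_interaction` (from the delta regression) and `f_group_time`,
#'   `p_group_time` (from the repeated-measures ANOVA).
#' @export
group_time_glm <- function(t1, t2, group) {
  stopifnot(length(t1) == length(t2), length(t1) == length(group))
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (stats::sd(t1) == 0) stop("constant baseline predictor")
  delta <- t2 - t1
  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  g_num <- as.numeric(group) - 1
  dz <- zs(delta); t1z <- zs(t1); gz <- zs(g_num)
  fit <- stats::lm(dz ~ t1z + gz + t1z:gz)
  sm <- summary(fit)$coefficients
  # repeated-measures ANOVA, long format, subject as error stratum
  n <- length(t1)
  long <- data.frame(
    y = c(t1, t2),
    time = factor(rep(c("t1", "t2"), each = n)),
    grp = factor(rep(group, 2)),
    id = factor(rep(seq_len(n), 2)))
  aovfit <- stats::aov(y ~ grp * time + Error(id / time), data = long)
  tab <- summary(aovfit)[["Error: id:time"]][[1]]
  ix <- grep("grp:time", rownames(tab))
  list(beta_group = unname(sm["gz", "Estimate"]),
       p_group = unname(sm["gz", "Pr(>|t|)"]),
       beta_interaction = unname(sm["t1z:gz", "Estimate"]),
       p_interaction = unname(sm["t1z:gz", "Pr(>|t|)"]),
       f_group_time = unname(tab[ix, "F value"]),
       p_group_time = unname(tab[ix, "Pr(>F)"]))
}
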