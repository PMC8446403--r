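#' Fit a standardized regression-based (SRB) change model
#'
#' Regresses the control group's follow-up raw score on baseline score,
#' premorbid IQ, and age (ordinary least squares with intercept). The fitted
#' equation predicts every participant's expected follow-up score — thereby
#' absorbing practice effects, baseline level, and demographic trend — and
#' the control fit's standard error of estimate (SEE) scales observed minus
#' predicted into a z-score. SEE uses the residual degrees of freedom
#' `n - 4` (four fitted parameters including the intercept).
#'
#' @param controls Subject data frame restricted to (or containing) the
#'   control group; only rows with `group == "control"` are used.
#' @param measure_id Single measure identifier.
#' @return An `srb_model`: list with `measure_id`, `coefficients`
#'   (`intercept`, `baseline`, `premorbid_iq`, `age`), `see`, `n_controls`.
#' @export
fit_srb <- function(controls, measure_id) {
  stopifnot(length(measure_id) == 1L)
  df <- controls[controls$group == "control", , drop = FALSE]
  t1 <- df[[paste0(measure_id, "_t1")]]
  t2 <- df[[paste0(measure_id, "_t2")]]
  if (is.null(t1) || is.null(t2))
    stop("measure columns not found for: ", measure_id)
  n <- nrow(df)
  if (n < 6L)
    stop("too few controls (", n, ") to fit SRB model for ", measure_id)
  X <- cbind(1, t1, df$premorbid_iq, df$age)
  qrX <- qr(X)
  if (qrX$rank < 4L)
    stop("rank-deficient design for ", measure_id,
         " (constant baseline, IQ, or age column)")
  beta <- unname(qr.coef(qrX, t2))
  resid <- t2 - X %*% beta
  rss <- sum(resid^2)
  see <- sqrt(rss / (n - 4))
  if (see <= .Machine$double.eps^0.5 * max(1, stats::sd(t2)))
    stop("zero residual variance in SRB fit for ", measure_id,
         ": degenerate (noiseless) control data")
  structure(list(measure_id = measure_id,
                 coefficients = c(intercept = beta[1], baseline = beta[2],
                                  premorbid_iq = beta[3], age = beta[4]),
                 see = see, n_controls = n),
            class = "srb_model")
}

#' @export
print.srb_model <- function(x, ...) {
  cat(sprintf("SRB model [%s]: n=%d, SEE=%.4g\n", x$measure_id,
              x$n_controls, x$see))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit SRB models for a whole battery
#'
#' @param subjects Subject data frame (controls are selected internally).
#' @param measure_specs Measure-spec data frame.
#' @return Named list of `srb_model` objects, one per measure.
#' @export
fit_srb_battery <- function(subjects, measure_specs) {
  models <- lapply(measure_specs$measure_id, function(m)
    fit_srb(subjects, m))
  names(models) <- measure_specs$measure_id
  models
}

#' Score one subject's change on one measure
#'
#' @param model An `srb_model`.
#' @param t1,t2 The subject's baseline and follow-up raw scores.
#' @param premorbid_iq,age The subject's covariates.
#' @return List with `predicted_t2` (raw units) and `z`
#'   (`(t2 - predicted_t2) / see`, raw sign: positive means a higher raw
#'   score than predicted).
#' @export
score_subject <- function(model, t1, t2, premorbid_iq, age) {
  if (model$see <= 0) stop("SEE must be positive")
  b <- model$coefficients
  pred <- b[["intercept"]] + b[["baseline"]] * t1 +
    b[["premorbid_iq"]] * premorbid_iq + b[["age"]] * age
  list(predicted_t2 = pred, z = (t2 - pred) / model$see)
}

#' Harmonize a z-score's direction
#'
#' Flips the sign for lower-is-better measures (timed tests, error counts) so
#' that a positive harmonized z always means improvement and a negative one
#' always means decline, regardless of the raw scoring direction.
#'
#' @param z Raw SRB z-score(s).
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @return Harmonized z.
#' @export
harmonize_direction <- function(z, direction) {
  direction <- match.arg(direction, c("higher_is_better", "lower_is_better"))
  if (direction == "lower_is_better") -z else z
}

#' Classify a harmonized change score
#'
#' Clinically significant change corresponds to the extreme 5% at either end
#' of the standard normal distribution: `declined` if
#' `z_harmonized <= -threshold`, `improved` if `z_harmonized >= threshold`,
#' otherwise `stable`. Boundary values count as change (inclusive bounds).
#'
#' @param z_harmonized Harmonized z-score(s).
#' @param threshold Positive classification cutoff (default `1.64`, the
#'   standard normal 95th percentile to two decimals).
#' @return Character vector: `"declined"`, `"stable"`, or `"improved"`.
#' @export
classify_change <- function(z_harmonized, threshold = 1.64) {
  if (threshold <= 0) stop("threshold must be positive")
  out <- rep("stable", length(z_harmonized))
  out[z_harmonized <= -threshold] <- "declined"
  out[z_harmonized >= threshold] <- "improved"
  out
}

#' Score a whole cohort against control-fitted SRB models
#'
#' Applies every measure's SRB model to every subject (patients and controls
#' alike), harmonizes directions, classifies at `threshold`, and appends each
#' subject's global composite z (GCS-z): the arithmetic mean of the
#' harmonized z-scores across all measures, classified by the same rule and
#' reported as `measure_id = "overall"`.
#'
#' @param subjects Subject data frame.
#' @param models Named list from [fit_srb_battery()].
#' @param measure_specs Measure-spec data frame (for directions).
#' @param threshold Classification cutoff passed to [classify_change()].
#' @return Long data frame: `subject_id`, `group`, `measure_id`,
#'   `predicted_t2`, `z`, `z_harmonized`, `category` (the `"overall"` rows
#'   have `NA` for `predicted_t2` and `z`).
#' @export
score_cohort <- function(subjects, models, measure_specs,
                         threshold = 1.64) {
  rows <- lapply(measure_specs$measure_id, function(m) {
    mod <- models[[m]]
    if (is.null(mod)) stop("no SRB model for measure: ", m)
    dirn <- measure_specs$direction[measure_specs$measure_id == m]
    sc <- score_subject(mod, subjects[[paste0(m, "_t1")]],
                        subjects[[paste0(m, "_t2")]],
                        subjects$premorbid_iq, subjects$age)
    zh <- harmonize_direction(sc$z, dirn)
    data.frame(subject_id = subjects$subject_id, group = subjects$group,
               measure_id = m, predicted_t2 = sc$predicted_t2, z = sc$z,
               z_harmonized = zh,
               category = classify_change(zh, threshold),
               stringsAsFactors = FALSE)
  })
  per_measure <- do.call(rbind, rows)
  gcs <- global_composite(per_measure, threshold = threshold)
  rbind(per_measure, gcs)
}

#' Global composite change score (GCS-z)
#'
#' The mean of a subject's harmonized per-measure z-scores, classified with
#' the same threshold rule as the individual measures. Averaging shrinks
#' variance, so composite change rates are typically far below per-measure
#' rates.
#'
#' @param change_scores Long data frame from [score_cohort()] (per-measure
#'   rows only; any existing `"overall"` rows are ignored).
#' @param threshold Classification cutoff.
#' @return Data frame in the same layout with `measure_id = "overall"`.
#' @export
global_composite <- function(change_scores, threshold = 1.64) {
  cs <- change_scores[change_scores$measure_id != "overall", , drop = FALSE]
  if (nrow(cs) == 0L) stop("no per-measure change scores to average")
  agg <- stats::aggregate(z_harmonized ~ subject_id + group, data = cs,
                          FUN = mean)
  data.frame(subject_id = agg$subject_id, group = agg$group,
             measure_id = "overall", predicted_t2 = NA_real_, z = NA_real_,
             z_harmonized = agg$z_harmonized,
             category = classify_change(agg$z_harmonized, threshold),
             stringsAsFactors = FALSE)
}

#' Per-measure decline/improvement rate table
#'
#' Tallies, per measure and group, the number and percentage of subjects
#' classified as declined and improved, in the conventional
#' "percent (count)" presentation with percentages rounded to one decimal.
#'
#' @param change_scores Long data frame from [score_cohort()].
#' @return Data frame: `measure_id`, `group`, `n`, `n_declined`,
#'   `pct_declined`, `n_improved`, `pct_improved`, `declined_label`,
#'   `improved_label`.
#' @export
rate_table <- function(change_scores) {
  out <- list()
  for (m in unique(change_scores$measure_id)) {
    for (g in sort(unique(change_scores$group))) {
      sub <- change_scores[change_scores$measure_id == m &
                             change_scores$group == g, , drop = FALSE]
      n <- nrow(sub)
      nd <- sum(sub$category == "declined")
      ni <- sum(sub$category == "improved")
      pd <- round(100 * nd / n, 1)
      pi <- round(100 * ni / n, 1)
      out[[length(out) + 1L]] <- data.frame(
        measure_id = m, group = g, n = n,
        n_declined = nd, pct_declined = pd,
        n_improved = ni, pct_improved = pi,
        declined_label = sprintf("%.1f (%d)", pd, nd),
        improved_label = sprintf("%.1f (%d)", pi, ni),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
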