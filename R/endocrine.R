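#' Binding constants for the free-testosterone calculation
#'
#' Association constants for testosterone binding to SHBG and albumin, and a
#' default albumin concentration, as used in the standard calculated
#' free-testosterone equation. Defaults are the canonical published values:
#' `k_shbg = 1.0e9` L/mol, `k_albumin = 3.6e4` L/mol, albumin 43 g/L
#' (molar mass 66 500 g/mol).
#'
#' @param k_shbg,k_albumin Association constants in L/mol.
#' @param albumin_default Albumin concentration in g/L assumed when a sample
#'   lacks an albumin assay.
#' @param albumin_molar_mass Albumin molar mass in g/mol.
#' @return List of constants.
#' @export
binding_constants <- function(k_shbg = 1.0e9, k_albumin = 3.6e4,
                              albumin_default = 43,
                              albumin_molar_mass = 66500) {
  stopifnot(k_shbg > 0, k_albumin > 0, albumin_default > 0,
            albumin_molar_mass > 0)
  list(k_shbg = k_shbg, k_albumin = k_albumin,
       albumin_default = albumin_default,
       albumin_molar_mass = albumin_molar_mass)
}

#' Calculated free testosterone (mass-action equilibrium)
#'
#' Solves the mass-action binding equilibrium of testosterone with SHBG and
#' albumin for the free fraction. With `N = 1 + k_alb * [albumin]` (albumin
#' binding folded into a linear factor, the standard simplification given
#' albumin's weak affinity and large excess), free testosterone FT is the
#' positive root of
#' `k_shbg * N * FT^2 + (N + k_shbg * (SHBG - TT)) * FT - TT = 0`
#' with all concentrations in mol/L. The result is returned in nmol/L and
#' always satisfies `0 <= FT <= TT`. In healthy adult men the free fraction
#' is typically 1-4% of total testosterone.
#'
#' @param total_t Total testosterone, nmol/L (scalar or vector).
#' @param shbg SHBG, nmol/L.
#' @param constants See [binding_constants()].
#' @param albumin Albumin, g/L; defaults to `constants$albumin_default`.
#' @return Free testosterone, nmol/L.
#' @export
free_testosterone <- function(total_t, shbg,
                              constants = binding_constants(),
                              albumin = NULL) {
  if (any(total_t < 0) || any(shbg < 0))
    stop("concentrations must be nonnegative")
  if (is.null(albumin)) albumin <- constants$albumin_default
  if (any(albumin < 0)) stop("albumin must be nonnegative")
  tt <- total_t * 1e-9
  sh <- shbg * 1e-9
  alb_molar <- albumin / constants$albumin_molar_mass
  N <- 1 + constants$k_albumin * alb_molar
  a <- constants$k_shbg * N
  b <- N + constants$k_shbg * (sh - tt)
  ft <- (-b + sqrt(b^2 + 4 * a * tt)) / (2 * a)
  pmin(pmax(ft, 0), tt) * 1e9
}

#' Change scores (follow-up minus baseline)
#'
#' Computes per-subject change values `delta = t2 - t1` for every requested
#' two-timepoint variable, plus derived free testosterone at both timepoints
#' when the hormone panel is present.
#'
#' @param subjects Subject data frame with `<var>_t1`/`<var>_t2` columns.
#' @param variables Variables to difference; defaults to the hormone panel
#'   plus derived free testosterone.
#' @param constants Binding constants for the free-testosterone derivation.
#' @return Long data frame: `subject_id`, `group`, `variable`, `t1`, `t2`,
#'   `delta`. Variables whose columns are absent are skipped with a message.
#' @export
compute_deltas <- function(subjects,
                           variables = c(hormone_variables(),
                                         "free_testosterone"),
                           constants = binding_constants()) {
  df <- subjects
  if ("free_testosterone" %in% variables &&
      all(c("total_testosterone_t1", "shbg_t1",
            "total_testosterone_t2", "shbg_t2") %in% names(df))) {
    df$free_testosterone_t1 <- free_testosterone(
      df$total_testosterone_t1, df$shbg_t1, constants)
    df$free_testosterone_t2 <- free_testosterone(
      df$total_testosterone_t2, df$shbg_t2, constants)
  }
  out <- list()
  for (v in variables) {
    c1 <- paste0(v, "_t1"); c2 <- paste0(v, "_t2")
    if (!all(c(c1, c2) %in% names(df))) {
      message("skipping variable without both timepoints: ", v)
      next
    }
    ok <- !is.na(df[[c1]]) & !is.na(df[[c2]])
    if (any(!ok))
      message("skipping ", sum(!ok), " subject(s) with missing ", v)
    out[[length(out) + 1L]] <- data.frame(
      subject_id = df$subject_id[ok], group = df$group[ok], variable = v,
      t1 = df[[c1]][ok], t2 = df[[c2]][ok],
      delta = df[[c2]][ok] - df[[c1]][ok], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Group summary of change scores
#'
#' Per-variable group means and SDs at baseline and for the change score,
#' with the independent-samples t-test and BCa bootstrap interval for the
#' group difference in change scores.
#'
#' @param deltas Long data frame from [compute_deltas()].
#' @param n_boot,level,seed Bootstrap settings for the BCa interval.
#' @return Data frame, one row per variable.
#' @export
delta_summary <- function(deltas, n_boot = 2000, level = 0.95, seed = 1L) {
  out <- list()
  for (v in unique(deltas$variable)) {
    df <- deltas[deltas$variable == v, ]
    pat <- df[df$group == "patient", ]; ctl <- df[df$group == "control", ]
    tt <- stats::t.test(pat$delta, ctl$delta)
    ci <- bca_bootstrap_mean_diff(pat$delta, ctl$delta, n_boot = n_boot,
                                  level = level, seed = seed)
    out[[length(out) + 1L]] <- data.frame(
      variable = v,
      t1_mean_patient = mean(pat$t1), t1_sd_patient = stats::sd(pat$t1),
      t1_mean_control = mean(ctl$t1), t1_sd_control = stats::sd(ctl$t1),
      delta_mean_patient = mean(pat$delta),
      delta_sd_patient = stats::sd(pat$delta),
      delta_mean_control = mean(ctl$delta),
      delta_sd_control = stats::sd(ctl$delta),
      delta_p = tt$p.value, delta_ci_low = ci$ci_low,
      delta_ci_high = ci$ci_high, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simple predictor model of cognitive change
#'
#' Within-group simple linear regression of a cognitive change outcome
#' (harmonized z or a change score) on one predictor. When the within-group
#' slope is significant at `alpha`, a pooled model with group, predictor,
#' and group x predictor terms is fitted and the interaction p-value
#' reported, testing whether the association differs between groups.
#'
#' @param outcome Numeric outcome per subject.
#' @param predictor Numeric predictor per subject.
#' @param group Group label per subject; the model is fitted within
#'   `fit_group` and the interaction uses all subjects.
#' @param fit_group Group in which the simple regression is fitted.
#' @param alpha Threshold that triggers the interaction test.
#' @return List with `beta`, `p`, `n`, and `group_interaction_p` (`NA`
#'   unless triggered).
#' @export
predict_change <- function(outcome, predictor, group,
                           fit_group = "patient", alpha = 0.05) {
  stopifnot(length(outcome) == length(predictor),
            length(outcome) == length(group))
  sel <- group == fit_group & !is.na(outcome) & !is.na(predictor)
  if (sum(sel) < 10L)
    stop("fewer than 10 complete cases in group '", fit_group, "'")
  if (stats::sd(predictor[sel]) == 0) stop("constant predictor")
  fit <- stats::lm(outcome[sel] ~ predictor[sel])
  sm <- summary(fit)$coefficients
  beta <- unname(sm[2, "Estimate"]); p <- unname(sm[2, "Pr(>|t|)"])
  gi_p <- NA_real_
  if (is.finite(p) && p < alpha) {
    ok <- !is.na(outcome) & !is.na(predictor)
    g <- factor(group[ok])
    pool <- stats::lm(outcome[ok] ~ predictor[ok] * g)
    smp <- summary(pool)$coefficients
    ix <- grep(":", rownames(smp))
    gi_p <- unname(smp[ix, "Pr(>|t|)"])
  }
  list(beta = beta, p = p, n = sum(sel), group_interaction_p = gi_p)
}

#' Testosterone model adjusted for SHBG and CAG repeat length
#'
#' Multiple regression of a cognitive change outcome on testosterone
#' (baseline level or change score) adjusting for the matching SHBG value
#' and androgen-receptor CAG repeat length, reporting the testosterone
#' coefficient. A high design-matrix condition number triggers a
#' collinearity warning in the result.
#'
#' @param outcome Numeric outcome.
#' @param testosterone,shbg,cag Predictors (matching scale: both baseline or
#'   both change scores for testosterone/SHBG).
#' @param kappa_threshold Condition-number threshold for the collinearity
#'   flag.
#' @return List with `beta`, `p`, `n`, `collinear`.
#' @export
adjusted_testosterone_model <- function(outcome, testosterone, shbg, cag,
                                        kappa_threshold = 30) {
  ok <- stats::complete.cases(outcome, testosterone, shbg, cag)
  if (sum(ok) < 10L) stop("fewer than 10 complete cases")
  X <- scale(cbind(testosterone, shbg, cag)[ok, , drop = FALSE])
  kap <- kappa(cbind(1, X), exact = TRUE)
  collinear <- kap > kappa_threshold
  if (collinear)
    warning(sprintf("design condition number %.1f exceeds %.0f", kap,
                    kappa_threshold))
  fit <- stats::lm(outcome[ok] ~ testosterone[ok] + shbg[ok] + cag[ok])
  sm <- summary(fit)$coefficients
  list(beta = unname(sm[2, "Estimate"]), p = unname(sm[2, "Pr(>|t|)"]),
       n = sum(ok), collinear = collinear)
}

#' Risk-genotype effects on cognitive change
#'
#' Within patients, regresses each change outcome on each binary risk-allele
#' carrier flag. Genotypes with an empty carrier or non-carrier group are
#' skipped with a message (a one-level factor cannot be tested).
#'
#' @param subjects Subject data frame containing the genotype flag columns.
#' @param change_scores Long data frame from [score_cohort()].
#' @param outcomes Measure ids to model (default: the `"overall"` composite).
#' @param genotypes Flag columns to test.
#' @return Data frame: `outcome`, `genotype`, `beta`, `p`, `n`; zero rows if
#'   everything was skipped.
#' @export
genotype_effects <- function(subjects, change_scores,
                             outcomes = "overall",
                             genotypes = c("apoe_e4_carrier",
                                           "comt_val_carrier",
                                           "bdnf_val_val")) {
  pats <- subjects[subjects$group == "patient", , drop = FALSE]
  out <- list()
  for (gt in genotypes) {
    flag <- pats[[gt]]
    if (is.null(flag)) {
      message("genotype column absent, skipped: ", gt)
      next
    }
    if (length(unique(flag)) < 2L) {
      message("carrier group empty or universal, skipped: ", gt)
      next
    }
    for (oc in outcomes) {
      cs <- change_scores[change_scores$measure_id == oc &
                            change_scores$group == "patient", ]
      y <- cs$z_harmonized[match(pats$subject_id, cs$subject_id)]
      fit <- stats::lm(y ~ flag)
      sm <- summary(fit)$coefficients
      out[[length(out) + 1L]] <- data.frame(
        outcome = oc, genotype = gt, beta = unname(sm[2, "Estimate"]),
        p = unname(sm[2, "Pr(>|t|)"]), n = sum(!is.na(y)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(outcome = character(), genotype = character(),
                      beta = numeric(), p = numeric(), n = integer()))
  do.call(rbind, out)
}
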