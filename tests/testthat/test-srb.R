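# Helper: build a control-only frame with a known generative model on one
# measure so fits can be checked against truth.
make_controls <- function(n, b = c(2, 0.9, 0.1, 0), sigma = 1, seed = 1) {
  set.seed(seed)
  df <- data.frame(subject_id = sprintf("hc_%03d", seq_len(n)),
                   group = "control",
                   age = stats::runif(n, 20, 60),
                   premorbid_iq = stats::rnorm(n, 11, 2.5))
  t1 <- stats::rnorm(n, 30, 9)
  df$m_t1 <- t1
  df$m_t2 <- b[1] + b[2] * t1 + b[3] * df$premorbid_iq + b[4] * df$age +
    stats::rnorm(n, 0, sigma)
  df
}

test_that("noiseless controls are rejected as degenerate", {
  df <- make_controls(21, sigma = 0)
  expect_error(fit_srb(df, "m"), "zero residual variance")
})

test_that("rank-deficient designs are rejected", {
  df <- make_controls(21)
  df$age <- 50
  expect_error(fit_srb(df, "m"), "rank-deficient")
  expect_error(fit_srb(make_controls(5), "m"), "too few controls")
})

test_that("SRB fit recovers generative coefficients at n = 21", {
  # 500-replicate simulation: each fitted coefficient within 3 reported SEs
  # of truth in ~99.7% of cases; assert the aggregate miss rate stays small,
  # and that the SEE estimate tracks sigma.
  b <- c(2, 0.9, 0.2, -0.05); sigma <- 2
  miss <- 0L; sees <- numeric(500)
  for (r in 1:500) {
    df <- make_controls(21, b = b, sigma = sigma, seed = 1000 + r)
    fit <- fit_srb(df, "m")
    X <- cbind(1, df$m_t1, df$premorbid_iq, df$age)
    se <- fit$see * sqrt(diag(solve(crossprod(X))))
    miss <- miss + any(abs(fit$coefficients - b) > 3 * se)
    sees[r] <- fit$see
  }
  expect_lt(miss / 500, 0.05)
  expect_lt(abs(mean(sees) - sigma) / sigma, 0.30)
  # chi-square dispersion at 17 residual df puts ~92% of SEE draws within
  # 30% of sigma; require the bulk to land there
  expect_gt(mean(abs(sees / sigma - 1) < 0.30), 0.85)
})

test_that("scoring reproduces the OLS residual identities on the fit sample", {
  df <- make_controls(21, seed = 9)
  fit <- fit_srb(df, "m")
  sc <- score_subject(fit, df$m_t1, df$m_t2, df$premorbid_iq, df$age)
  expect_lt(abs(mean(sc$z)), 1e-9)
  # residual SD with n-1 dof is below the SEE (which uses n-4)
  expect_lte(stats::sd(sc$z * fit$see), fit$see + 1e-9)
  # unit-offset subject scores exactly z = 1
  one <- score_subject(fit, 30, 0, 11, 40)
  pred <- one$predicted_t2
  expect_equal(score_subject(fit, 30, pred, 11, 40)$z, 0)
  expect_equal(score_subject(fit, 30, pred + fit$see, 11, 40)$z, 1)
})

test_that("direction harmonization flips only lower-is-better measures", {
  expect_equal(harmonize_direction(-2, "higher_is_better"), -2)
  expect_equal(harmonize_direction(-2, "lower_is_better"), 2)
  # slower-than-predicted trail-making performance is decline
  z_raw <- 1.8
  zh <- harmonize_direction(z_raw, "lower_is_better")
  expect_equal(classify_change(zh), "declined")
})

test_that("classification is inclusive at the boundary and monotone", {
  expect_equal(classify_change(-1.64), "declined")
  expect_equal(classify_change(1.64), "improved")
  expect_equal(classify_change(1.639), "stable")
  expect_equal(classify_change(-1.639), "stable")
  z <- seq(-4, 4, by = 0.01)
  lv <- c(declined = 1, stable = 2, improved = 3)
  expect_true(all(diff(lv[classify_change(z)]) >= 0))
})

test_that("global composite is the mean of harmonized z and shrinks tails", {
  cs <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                   group = "patient",
                   measure_id = rep(c("m1", "m2"), 2),
                   predicted_t2 = 0, z = 0,
                   z_harmonized = c(1.64, -1.64, 2, 2),
                   category = "stable")
  g <- global_composite(cs)
  expect_equal(g$z_harmonized[g$subject_id == "a"], 0)
  expect_equal(g$category[g$subject_id == "a"], "stable")
  expect_equal(g$z_harmonized[g$subject_id == "b"], 2)
  expect_equal(g$category[g$subject_id == "b"], "improved")
  expect_error(global_composite(cs[0, ]), "no per-measure")

  # across a full synthetic cohort, composite change is rarer than
  # per-measure change (averaging shrinks variance)
  cfg <- cohort_config(n_patients = 60, n_controls = 40, seed = 3,
                       effect_multiplier = 0)
  sim <- generate_cohort(cfg)
  models <- fit_srb_battery(sim$subjects, cfg$measure_specs)
  ch <- score_cohort(sim$subjects, models, cfg$measure_specs)
  per <- ch[ch$measure_id != "overall", ]
  ovl <- ch[ch$measure_id == "overall", ]
  expect_lt(mean(ovl$category != "stable"), mean(per$category != "stable"))
})

test_that("rate table equals a direct tally and formats like '28.9 (11)'", {
  cfg <- tiny_config(seed = 21)
  sim <- generate_cohort(cfg)
  models <- fit_srb_battery(sim$subjects, cfg$measure_specs)
  ch <- score_cohort(sim$subjects, models, cfg$measure_specs)
  rt <- rate_table(ch)
  for (i in sample(nrow(rt), 10)) {
    sub <- ch[ch$measure_id == rt$measure_id[i] & ch$group == rt$group[i], ]
    expect_identical(rt$n_declined[i], sum(sub$category == "declined"))
    expect_identical(rt$n_improved[i], sum(sub$category == "improved"))
  }
  expect_equal(sprintf("%.1f (%d)", round(100 * 11 / 38, 1), 11L),
               "28.9 (11)")
  row0 <- rt[rt$n_declined == 0, ][1, ]
  if (!is.na(row0$measure_id))
    expect_match(row0$declined_label, "^0\\.0 \\(0\\)$")
})
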