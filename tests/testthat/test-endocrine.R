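test_that("free testosterone solves the binding equilibrium", {
  expect_equal(free_testosterone(0, 40), 0)
  # no binding proteins at all: everything is free
  expect_equal(free_testosterone(15, 0, albumin = 0), 15, tolerance = 1e-9)
  expect_error(free_testosterone(-1, 40), "nonnegative")

  # cohort-typical inputs: matches the fixed-point oracle and sits in the
  # physiological 1-4% free fraction
  ft <- free_testosterone(15.87, 38.18)
  expect_equal(ft, oracle_free_t(15.87, 38.18), tolerance = 1e-6)
  expect_gt(ft / 15.87, 0.01)
  expect_lt(ft / 15.87, 0.04)
})

test_that("free testosterone is monotone and bounded by total", {
  tt <- seq(2, 40, length.out = 12)
  sh <- seq(10, 90, length.out = 12)
  ft_tt <- free_testosterone(tt, 40)
  expect_true(all(diff(ft_tt) > 0))
  ft_sh <- free_testosterone(20, sh)
  expect_true(all(diff(ft_sh) < 0))
  grid <- expand.grid(tt = tt, sh = sh)
  ft <- free_testosterone(grid$tt, grid$sh)
  expect_true(all(ft <= grid$tt))
  expect_true(all(ft >= 0))
})

test_that("change scores difference follow-up minus baseline, antisymmetrically", {
  cfg <- tiny_config(seed = 14)
  sim <- generate_cohort(cfg)
  d <- compute_deltas(sim$subjects)
  expect_equal(d$delta, d$t2 - d$t1)
  expect_equal(38.18 + 9.11, 47.29)  # delta convention worked example
  # antisymmetry under timepoint swap
  swapped <- sim$subjects
  for (v in c("shbg", "total_testosterone")) {
    tmp <- swapped[[paste0(v, "_t1")]]
    swapped[[paste0(v, "_t1")]] <- swapped[[paste0(v, "_t2")]]
    swapped[[paste0(v, "_t2")]] <- tmp
  }
  d2 <- compute_deltas(swapped, variables = c("shbg", "total_testosterone"))
  d1 <- d[d$variable %in% c("shbg", "total_testosterone"), ]
  m <- match(paste(d2$subject_id, d2$variable),
             paste(d1$subject_id, d1$variable))
  expect_equal(d2$delta, -d1$delta[m])
  # group summaries equal a direct tally
  s <- delta_summary(d[d$variable == "shbg", ], n_boot = 200)
  pat <- d[d$variable == "shbg" & d$group == "patient", ]
  expect_equal(s$delta_mean_patient, mean(pat$delta))
  expect_equal(s$delta_sd_patient, stats::sd(pat$delta))
})

test_that("predictor models recover exact and designed relations", {
  set.seed(20)
  n <- 60
  group <- rep(c("patient", "control"), each = n / 2)
  x <- stats::rnorm(n)
  # exact linear relation: lm warns about the perfect fit, which is the point
  res <- suppressWarnings(predict_change(2 * x, x, group))
  expect_equal(res$beta, 2, tolerance = 1e-9)
  expect_lt(res$p, 1e-12)
  expect_error(predict_change(x, rep(1, n), group), "constant")
  expect_error(predict_change(x[1:12], x[1:12],
                              c(rep("patient", 4), rep("control", 8))),
               "complete cases")

  # negative baseline-testosterone -> memory-change slope: sign recovered
  hits <- 0L
  for (r in 1:100) {
    tt <- stats::rnorm(n, 16, 5)
    y <- -0.1 * tt + stats::rnorm(n, 0, 0.8)
    hits <- hits + (predict_change(y, tt, group)$beta < 0)
  }
  expect_gte(hits, 90)

  # calibration: independent predictor keeps type-I error near nominal
  pvals <- vapply(1:300, function(r) {
    y <- stats::rnorm(n)
    predict_change(y, stats::rnorm(n), group)$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("adjusted testosterone model partials out SHBG", {
  set.seed(33)
  n <- 80
  shbg <- stats::rnorm(n, 40, 15)
  tt <- stats::rnorm(n, 16, 5)
  cag <- round(stats::rnorm(n, 22, 3))
  y <- 0.05 * shbg + stats::rnorm(n, 0, 0.2)
  res <- adjusted_testosterone_model(y, tt, shbg, cag)
  expect_lt(abs(res$beta), 0.02)
  expect_false(res$collinear)
  expect_warning(
    adjusted_testosterone_model(y, shbg * 1.0000001, shbg, cag),
    "condition number")
  expect_error(adjusted_testosterone_model(y[1:5], tt[1:5], shbg[1:5],
                                           cag[1:5]),
               "complete cases")
})

test_that("genotype effect models skip degenerate flags and detect real ones", {
  cfg <- tiny_config(seed = 17)
  sim <- generate_cohort(cfg)
  models <- fit_srb_battery(sim$subjects, cfg$measure_specs)
  ch <- score_cohort(sim$subjects, models, cfg$measure_specs)

  allcar <- sim$subjects
  allcar$apoe_e4_carrier <- TRUE
  expect_message(
    res <- genotype_effects(allcar, ch, genotypes = "apoe_e4_carrier"),
    "skipped")
  expect_equal(nrow(res), 0L)

  # a designed carrier effect is detected with high power at large n
  set.seed(44)
  n <- 400
  df <- data.frame(subject_id = sprintf("p%03d", 1:n), group = "patient",
                   apoe_e4_carrier = stats::runif(n) < 0.4)
  cs <- data.frame(subject_id = df$subject_id, group = "patient",
                   measure_id = "overall", predicted_t2 = NA, z = NA,
                   z_harmonized = stats::rnorm(n) -
                     1.0 * df$apoe_e4_carrier,
                   category = "stable")
  res <- genotype_effects(df, cs, genotypes = "apoe_e4_carrier")
  expect_equal(nrow(res), 1L)
  expect_lt(res$beta, 0)
  expect_lt(res$p, 0.001)
})
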