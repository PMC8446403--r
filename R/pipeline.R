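#' Run the full analysis pipeline on a synthetic or supplied cohort
#'
#' Orchestrates the stages end to end: cohort simulation (or a supplied
#' subject table), SRB model fitting on controls and cohort-wide change
#' scoring, per-measure decline/improvement rates, exact-test group
#' comparison with odds ratios, connectome metric AUCs with group-by-time
#' tests, endocrine change scores and predictor models, and — when
#' `out_dir` is given — one CSV per result table plus a run manifest.
#' Identical `config` and seeds give identical outputs.
#'
#' @param config A `cohort_config` describing the cohort to simulate.
#' @param subjects Optional subject data frame; when supplied, simulation is
#'   skipped and `config` provides only the measure specs and settings.
#' @param connectomes Optional connectome list (as from
#'   [generate_connectomes()]); when `NULL` and `run_connectome` is `TRUE`,
#'   connectomes are simulated from `config`.
#' @param threshold Classification cutoff for [classify_change()].
#' @param exclude_metastatic If `TRUE`, the rate/odds-ratio stage is rerun
#'   on non-metastatic patients only (SRB models are not refitted: they
#'   depend only on controls) and reported as `or_table_sensitivity`.
#' @param run_connectome Set `FALSE` to skip the network stage.
#' @param grid,n_random Density grid and null-ensemble size for the network
#'   stage.
#' @param out_dir Optional output directory for [write_results()].
#' @return Named list of result tables: `change_scores`, `rate_table`,
#'   `or_table` (and `or_table_sensitivity`), `network_auc`,
#'   `network_tests`, `endocrine_deltas`, `predictor_models`.
#' @export
run_pipeline <- function(config = cohort_config(), subjects = NULL,
                         connectomes = NULL, threshold = 1.64,
                         exclude_metastatic = FALSE, run_connectome = TRUE,
                         grid = density_grid(), n_random = 20,
                         out_dir = NULL) {
  specs <- config$measure_specs
  if (is.null(subjects)) {
    sim <- generate_cohort(config)
    subjects <- sim$subjects
  }
  models <- fit_srb_battery(subjects, specs)
  changes <- score_cohort(subjects, models, specs, threshold = threshold)
  rates <- rate_table(changes)
  or_tab <- compare_rates(changes)
  tables <- list(change_scores = changes, rate_table = rates,
                 or_table = or_tab)
  if (exclude_metastatic) {
    keep <- subjects$subject_id[subjects$group == "control" |
                                  !isTRUE_vec(subjects$metastatic)]
    ch2 <- changes[changes$subject_id %in% keep, , drop = FALSE]
    tables$or_table_sensitivity <- compare_rates(ch2)
  }
  if (run_connectome) {
    if (is.null(connectomes))
      connectomes <- generate_connectomes(config, subjects)
    groups <- stats::setNames(subjects$group, subjects$subject_id)
    auc_df <- cohort_network_auc(connectomes, groups, grid = grid,
                                 n_random = n_random, seed = config$seed)
    net <- network_group_analysis(auc_df)
    tables$network_auc <- auc_df
    tables$network_tests <- net$nodes
    tables$network_global_tests <- net$global
    if (!is.null(net$deltas)) tables$network_deltas <- net$deltas
  }
  deltas <- compute_deltas(subjects)
  tables$endocrine_deltas <- deltas
  tables$endocrine_summary <- delta_summary(deltas, seed = config$seed)
  tables$predictor_models <- default_predictor_models(subjects, changes)
  if (!is.null(out_dir))
    write_results(tables, out_dir, seed = config$seed,
                  config = config[c("n_patients", "n_controls", "seed")])
  tables
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

# Baseline endocrine predictors of delayed-recall change plus risk-genotype
# models within patients: the package's default predictor screen.
default_predictor_models <- function(subjects, changes,
                                     outcome_measure = "hvltr_delayed") {
  cs <- changes[changes$measure_id == outcome_measure, ]
  y <- cs$z_harmonized[match(subjects$subject_id, cs$subject_id)]
  ft <- free_testosterone(subjects$total_testosterone_t1, subjects$shbg_t1)
  preds <- list(baseline_total_testosterone = subjects$total_testosterone_t1,
                baseline_free_testosterone = ft,
                delta_total_testosterone =
                  subjects$total_testosterone_t2 -
                  subjects$total_testosterone_t1,
                delta_estradiol = subjects$estradiol_t2 -
                  subjects$estradiol_t1,
                cag_repeat_length = subjects$ar_cag_repeat_length)
  empty <- data.frame(outcome = character(), predictor = character(),
                      beta = numeric(), p = numeric(), n = integer(),
                      group_interaction_p = numeric(),
                      stringsAsFactors = FALSE)
  if (sum(subjects$group == "patient") < 10L) {
    message("fewer than 10 patients: predictor models skipped")
    pm <- empty
  } else {
    rows <- lapply(names(preds), function(pn) {
      res <- predict_change(y, preds[[pn]], subjects$group,
                            fit_group = "patient")
      data.frame(outcome = outcome_measure, predictor = pn, beta = res$beta,
                 p = res$p, n = res$n,
                 group_interaction_p = res$group_interaction_p,
                 stringsAsFactors = FALSE)
    })
    pm <- do.call(rbind, rows)
  }
  gt <- genotype_effects(subjects, changes, outcomes = "overall")
  if (nrow(gt)) {
    gt <- data.frame(outcome = gt$outcome,
                     predictor = paste0("genotype_", gt$genotype),
                     beta = gt$beta, p = gt$p, n = gt$n,
                     group_interaction_p = NA_real_,
                     stringsAsFactors = FALSE)
    pm <- rbind(pm, gt)
  }
  pm
}
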