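#' Measure specifications
#'
#' A measure specification declares, for each cognitive outcome, the domain it
#' belongs to and its scoring direction. Direction matters because timed
#' outcomes (seconds to complete) and error counts improve when they go
#' *down*, while accuracy scores improve when they go *up*; all downstream
#' change classification is done on direction-harmonized z-scores where
#' positive always means improvement.
#'
#' @param measure_id Character vector of measure identifiers (used as column
#'   prefixes in the subject table: `<measure_id>_t1`, `<measure_id>_t2`).
#' @param domain Character vector of cognitive domains.
#' @param direction `"higher_is_better"` or `"lower_is_better"` per measure.
#' @return A data frame with columns `measure_id`, `domain`, `direction`.
#' @export
measure_specs <- function(measure_id, domain, direction) {
  stopifnot(length(measure_id) == length(domain),
            length(measure_id) == length(direction))
  if (anyDuplicated(measure_id))
    stop("duplicated measure_id in measure specs")
  bad <- setdiff(direction, c("higher_is_better", "lower_is_better"))
  if (length(bad))
    stop("unknown direction: ", paste(bad, collapse = ", "))
  data.frame(measure_id = as.character(measure_id),
             domain = as.character(domain),
             direction = as.character(direction),
             stringsAsFactors = FALSE)
}

#' Default neuropsychological test battery
#'
#' The 15-outcome battery used throughout the package: processing speed
#' (coding, trail-making A), attention/working memory (digit span), executive
#' functions (trail-making B, card-sorting perseverative errors), verbal
#' fluency (semantic and phonemic), verbal learning and memory (list-learning
#' immediate and delayed recall), visuospatial learning and memory (visual
#' reproduction I/II), and visuospatial ability (block design, figure
#' weights, matrix reasoning, visual puzzles). Trail-making times (seconds)
#' and perseverative errors are scored lower-is-better; all other outcomes
#' higher-is-better.
#'
#' @return A measure-spec data frame (see [measure_specs()]).
#' @export
default_measure_battery <- function() {
  measure_specs(
    measure_id = c("coding", "tmta",
                   "digit_span",
                   "tmtb", "wcst_pe",
                   "cowa_animals", "cowa_s",
                   "hvltr_immediate", "hvltr_delayed",
                   "vis_repro_1", "vis_repro_2",
                   "block_design", "figure_weights", "matrix_reasoning",
                   "visual_puzzles"),
    domain = c("processing_speed", "processing_speed",
               "attention_working_memory",
               "executive_functions", "executive_functions",
               "verbal_fluency", "verbal_fluency",
               "verbal_learning_memory", "verbal_learning_memory",
               "visuospatial_learning_memory", "visuospatial_learning_memory",
               "visuospatial_ability", "visuospatial_ability",
               "visuospatial_ability", "visuospatial_ability"),
    direction = c("higher_is_better", "lower_is_better",
                  "higher_is_better",
                  "lower_is_better", "lower_is_better",
                  "higher_is_better", "higher_is_better",
                  "higher_is_better", "higher_is_better",
                  "higher_is_better", "higher_is_better",
                  "higher_is_better", "higher_is_better", "higher_is_better",
                  "higher_is_better")
  )
}

# Hormone / hematology panel variables carried at both timepoints.
hormone_variables <- function() {
  c("total_testosterone", "estradiol", "lh", "fsh", "shbg",
    "hemoglobin", "erythrocytes", "neutrophils")
}

# PROM-style symptom variables carried at both timepoints.
symptom_variables <- function() {
  c("anxiety", "depression", "fatigue", "perceived_stress",
    "sleep_difficulties")
}
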