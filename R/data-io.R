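#' Read a wide-format subject table
#'
#' One row per subject; two-timepoint variables use the `_t1`/`_t2` column
#' suffix convention (`tmta_t1`, `tmta_t2`, ...). Required identifier
#' columns: `subject_id`, `group`, `age`, `premorbid_iq`. Optional:
#' `metastatic`, genotype flags (`apoe_e4_carrier`, `comt_val_carrier`,
#' `bdnf_val_val`, `ar_cag_repeat_length`), hormone and symptom columns.
#' Missing cells in declared measure columns are an error: the design assumes
#' complete two-timepoint data and does not impute.
#'
#' @param path Path to a delimited text file with a header row.
#' @param measure_specs Measure-spec data frame; every listed measure must be
#'   present at both timepoints.
#' @param sep Field separator (default comma).
#' @return A validated data frame of subjects, in file order.
#' @export
read_subject_table <- function(path, measure_specs, sep = ",") {
  if (!file.exists(path)) stop("subject table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_subject_table(df, measure_specs)
}

#' Validate a subject data frame
#'
#' Checks required columns, group labels, measure completeness, and basic
#' invariants (positive age, nonnegative hormone concentrations, positive CAG
#' repeat length where present).
#'
#' @param df Subject data frame.
#' @param measure_specs Measure-spec data frame.
#' @return The data frame, invisibly unchanged, with `group` as character.
#' @export
validate_subject_table <- function(df, measure_specs) {
  need <- c("subject_id", "group", "age", "premorbid_iq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("subject table missing column(s): ", paste(miss, collapse = ", "))
  df$group <- as.character(df$group)
  bad_grp <- setdiff(unique(df$group), c("patient", "control"))
  if (length(bad_grp))
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "),
         " (expected 'patient' or 'control')")
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id values in subject table")
  for (m in measure_specs$measure_id) {
    for (tp in c("t1", "t2")) {
      col <- paste0(m, "_", tp)
      if (!col %in% names(df))
        stop("subject table missing column: ", col)
      v <- df[[col]]
      if (!is.numeric(v)) {
        vn <- suppressWarnings(as.numeric(v))
        if (anyNA(vn) && !anyNA(v))
          stop("non-numeric value in column ", col, " (row ",
               which(is.na(vn))[1], ")")
        v <- vn
        df[[col]] <- v
      }
      if (anyNA(v))
        stop("missing value in column ", col, " (row ", which(is.na(v))[1],
             "); complete two-timepoint data required")
    }
  }
  if (any(df$age <= 0)) stop("age must be positive")
  for (h in intersect(paste0(rep(hormone_variables(), each = 2), "_",
                             c("t1", "t2")), names(df))) {
    if (any(df[[h]] < 0, na.rm = TRUE))
      stop("negative concentration in column ", h)
  }
  if ("ar_cag_repeat_length" %in% names(df) &&
      any(df$ar_cag_repeat_length <= 0, na.rm = TRUE))
    stop("ar_cag_repeat_length must be positive")
  df
}

#' Write a subject table
#'
#' @param df Subject data frame.
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a connectivity matrix
#'
#' Reads a square, symmetric, nonnegative weighted connectivity matrix from
#' whitespace- or comma-delimited text. Small numeric asymmetries (up to
#' `tol`) are symmetrized as `(M + t(M))/2`; larger asymmetry is an error.
#' The diagonal is forced to zero.
#'
#' @param path Path to the matrix file.
#' @param labels Ordered node labels; the matrix must be `length(labels)`
#'   square. Default: the 90-region anatomical parcellation labels
#'   (`aal90_labels()`).
#' @param subject_id,timepoint Metadata carried on the returned object.
#' @param tol Maximum tolerated absolute asymmetry (default `1e-6`).
#' @return A `connectome` object: list with `subject_id`, `timepoint`,
#'   `node_labels`, and the `weights` matrix.
#' @export
read_connectome <- function(path, labels = aal90_labels(),
                            subject_id = NA_character_,
                            timepoint = NA_character_, tol = 1e-6) {
  if (!file.exists(path)) stop("connectome file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  dimnames(m) <- NULL
  connectome(m, labels = labels, subject_id = subject_id,
             timepoint = timepoint, tol = tol)
}

#' Construct a connectome object from a matrix
#'
#' @param weights Square numeric matrix of nonnegative connection weights.
#' @inheritParams read_connectome
#' @return A `connectome` object.
#' @export
connectome <- function(weights, labels = aal90_labels(),
                       subject_id = NA_character_,
                       timepoint = NA_character_, tol = 1e-6) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("connectivity matrix must be square (got ",
         nrow(weights), "x", ncol(weights), ")")
  if (nrow(weights) != length(labels))
    stop("matrix size ", nrow(weights), " does not match ",
         length(labels), " node labels")
  if (any(weights < 0)) stop("negative connection weight")
  asym <- max(abs(weights - t(weights)))
  if (asym > tol)
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol))
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  structure(list(subject_id = subject_id, timepoint = timepoint,
                 node_labels = as.character(labels), weights = w),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("connectome: %s / %s, %d nodes, %d nonzero edges\n",
              x$subject_id, x$timepoint, n, nz))
  invisible(x)
}

#' Write a connectome matrix to delimited text
#'
#' @param conn A `connectome` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(conn, path) {
  utils::write.table(conn$weights, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Node labels for the 90-region anatomical parcellation
#'
#' Generic region labels `roi_001` ... `roi_090` standing in for a 90-region
#' cortical/subcortical atlas parcellation. Positions 77 and 78 are labelled
#' `thalamus_l` and `thalamus_r`, matching the convention that the left and
#' right thalamus occupy indices 77 and 78 in the common 90-region automated
#' anatomical labelling order.
#'
#' @return Character vector of 90 labels.
#' @export
aal90_labels <- function() {
  labs <- sprintf("roi_%03d", seq_len(90))
  labs[77] <- "thalamus_l"
  labs[78] <- "thalamus_r"
  labs
}

#' Write result tables with a run manifest
#'
#' Writes one CSV per table plus `manifest.json` recording the file list,
#' seed, and a hash of the configuration, so a pipeline run can be audited
#' and reruns compared.
#'
#' @param tables Named list of data frames (e.g. `change_scores`,
#'   `rate_table`, `or_table`, `network_auc`, `endocrine_deltas`,
#'   `predictor_models`).
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed recorded in the manifest.
#' @param config Arbitrary configuration list; hashed into the manifest.
#' @return The manifest, invisibly.
#' @export
write_results <- function(tables, out_dir, seed = NA_integer_,
                          config = list()) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables)))
    stop("tables must be named")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    tab <- tables[[nm]]
    tab <- tab[, sort(names(tab)), drop = FALSE]   # deterministic column order
    utils::write.table(tab, f, sep = ",", row.names = FALSE, quote = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(tables = files, seed = seed,
                   config_hash = config_hash(config),
                   n_tables = length(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Stable hash of a configuration list: canonical deparse -> sum of a simple
# polynomial rolling hash. Not cryptographic; only for change detection.
config_hash <- function(config) {
  s <- paste(deparse(config, control = "all"), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
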