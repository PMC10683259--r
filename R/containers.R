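#' Cohort table of mixed-type subject variables
#'
#' A `cohort_table` is a data frame of subjects (rows) by variables
#' (columns) carrying a variable-type map as metadata. The first column
#' must be `subject_id`. Risk variables, covariates and outcomes all live
#' in the same table; missing values are `NA` and form the missingness
#' mask.
#'
#' @param data data.frame with a `subject_id` column.
#' @param variable_types named character vector mapping every non-id
#'   column to `"continuous"` or `"categorical"`.
#' @return A `cohort_table` (data.frame subclass).
#' @export
cohort_table <- function(data, variable_types) {
  stopifnot(is.data.frame(data))
  if (!"subject_id" %in% names(data)) {
    stop_methrisk("cohort_table requires a 'subject_id' column",
                  "methrisk_invalid_input")
  }
  vars <- setdiff(names(data), "subject_id")
  missing_types <- setdiff(vars, names(variable_types))
  if (length(missing_types)) {
    stop_methrisk(paste0("no variable type declared for: ",
                         paste(missing_types, collapse = ", ")),
                  "methrisk_invalid_input")
  }
  bad <- !variable_types[vars] %in% c("continuous", "categorical")
  if (any(bad)) {
    stop_methrisk(paste0("unknown variable type for: ",
                         paste(vars[bad], collapse = ", ")),
                  "methrisk_invalid_input")
  }
  for (v in vars) {
    if (variable_types[[v]] == "categorical" && !is.factor(data[[v]])) {
      data[[v]] <- factor(data[[v]])
    }
    if (variable_types[[v]] == "continuous" && !is.numeric(data[[v]])) {
      stop_methrisk(paste0("continuous variable '", v, "' is not numeric"),
                    "methrisk_invalid_input")
    }
  }
  structure(data,
            variable_types = variable_types[vars],
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  vt <- attr(x, "variable_types")
  cat(sprintf("cohort_table: %d subjects, %d variables (%d continuous, %d categorical)\n",
              nrow(x), length(vt), sum(vt == "continuous"),
              sum(vt == "categorical")))
  NextMethod()
}

#' Variable types of a cohort table
#' @param x a `cohort_table`.
#' @return Named character vector of types.
#' @export
variable_types <- function(x) attr(x, "variable_types")

#' Variable specifications of a cohort table
#'
#' @param x a `cohort_table`.
#' @param variables optional subset of variable names.
#' @return List of specs: `name`, `kind`, and `levels` for categoricals.
#' @export
variable_specs <- function(x, variables = NULL) {
  vt <- variable_types(x)
  variables <- variables %||% names(vt)
  lapply(variables, function(v) {
    spec <- list(name = v, kind = vt[[v]])
    if (vt[[v]] == "categorical") spec$levels <- levels(x[[v]])
    spec
  })
}

#' Write / read a cohort table as TSV with a type sidecar
#'
#' The table is written as tab-separated text; variable kinds and factor
#' levels go to a sidecar JSON (`<path>.types.json`) so that a round-trip
#' preserves the mixed-data metadata.
#'
#' @param x a `cohort_table`.
#' @param path output TSV path.
#' @return `path`, invisibly (writer); a `cohort_table` (reader).
#' @export
write_cohort_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  sidecar <- list(
    variable_types = as.list(variable_types(x)),
    levels = lapply(Filter(function(s) s$kind == "categorical",
                           variable_specs(x)),
                    function(s) s$levels)
  )
  names(sidecar$levels) <-
    names(Filter(function(t) t == "categorical", variable_types(x)))
  write_json_file(sidecar, paste0(path, ".types.json"))
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  sidecar_path <- paste0(path, ".types.json")
  if (!file.exists(sidecar_path)) {
    stop_methrisk(paste0("missing variable-type sidecar: ", sidecar_path),
                  "methrisk_missing_sidecar")
  }
  sidecar <- read_json_file(sidecar_path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  vt <- unlist(sidecar$variable_types)
  for (v in names(vt)) {
    if (vt[[v]] == "categorical") {
      df[[v]] <- factor(df[[v]], levels = unlist(sidecar$levels[[v]]))
    }
  }
  cohort_table(df, vt)
}

#' Methylation matrix with CpG coordinates and sample metadata
#'
#' Container for a subjects-by-CpGs beta-value matrix (values in the open
#' interval (0,1)), a CpG coordinate table using 0-based half-open
#' intervals, and per-sample metadata (sex, age, estimated cell-type
#' proportions, processing batch).
#'
#' @param beta numeric matrix, subjects x CpGs, with dimnames.
#' @param coords data.frame with columns `cpg`, `chrom`, `start`, `end`.
#' @param samples data.frame with a `subject_id` column; one row per
#'   matrix row.
#' @return A `methylation_matrix` object.
#' @export
methylation_matrix <- function(beta, coords, samples) {
  stopifnot(is.matrix(beta), !is.null(colnames(beta)))
  if (nrow(beta) > 0 && is.null(rownames(beta))) {
    stop_methrisk("beta matrix must carry subject ids as rownames",
                  "methrisk_invalid_input")
  }
  stopifnot(all(c("cpg", "chrom", "start", "end") %in% names(coords)))
  if (!identical(sort(coords$cpg), sort(colnames(beta)))) {
    stop_methrisk("coords do not cover exactly the beta-matrix CpGs",
                  "methrisk_invalid_input")
  }
  if (!identical(as.character(samples$subject_id),
                 as.character(rownames(beta) %||% character(0)))) {
    stop_methrisk("sample metadata rows must match beta-matrix rows",
                  "methrisk_invalid_input")
  }
  coords <- coords[match(colnames(beta), coords$cpg), , drop = FALSE]
  rownames(coords) <- NULL
  structure(list(beta = beta, coords = coords, samples = samples),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d subjects x %d CpGs, beta in [%.4g, %.4g]\n",
              nrow(x$beta), ncol(x$beta), min(x$beta), max(x$beta)))
  invisible(x)
}

#' Write / read a methylation matrix as TSV files
#'
#' Writes `<prefix>_beta.tsv` (subjects x CpGs), `<prefix>_coords.tsv`
#' (cpg, chrom, 0-based start, end) and `<prefix>_samples.tsv`.
#'
#' @param x a `methylation_matrix`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly (writer); a `methylation_matrix` (reader).
#' @export
write_methylation_matrix <- function(x, prefix) {
  beta_df <- data.frame(subject_id = rownames(x$beta), x$beta,
                        check.names = FALSE)
  utils::write.table(beta_df, paste0(prefix, "_beta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$coords, paste0(prefix, "_coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, paste0(prefix, "_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_methylation_matrix
#' @export
read_methylation_matrix <- function(prefix) {
  beta_df <- utils::read.table(paste0(prefix, "_beta.tsv"), sep = "\t",
                               header = TRUE, check.names = FALSE,
                               colClasses = c(subject_id = "character"))
  beta <- as.matrix(beta_df[, -1, drop = FALSE])
  rownames(beta) <- beta_df$subject_id
  coords <- utils::read.table(paste0(prefix, "_coords.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  samples <- utils::read.table(paste0(prefix, "_samples.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE,
                               colClasses = c(subject_id = "character"))
  methylation_matrix(beta, coords, samples)
}
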