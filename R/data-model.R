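#' @useDynLib ecindex, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

GROUP_LEVELS <- c("case", "control")
CONTROL_SOURCE_LEVELS <- c("noncancer1", "noncancer2", "noncancer3")
STAGE_LEVELS <- c("0", "I", "II", "III", "IV")
SEX_LEVELS <- c("male", "female")

#' Validate a sample metadata table
#'
#' Sample metadata describes one serum sample per row: its case/control
#' label, and the optional clinical annotations used by the subgroup
#' analyses (tumour stage for cases, control cohort of origin for
#' controls, age, sex).
#'
#' @param samples A data.frame with at least columns `sample_id` and
#'   `group` (`"case"` or `"control"`). Optional columns:
#'   `control_source` (`"noncancer1"`, `"noncancer2"`, `"noncancer3"`;
#'   controls only), `stage` (`"0"`, `"I"`, `"II"`, `"III"`, `"IV"`;
#'   cases only), `age` (years), `sex` (`"male"`/`"female"`). Other
#'   columns are preserved untouched.
#' @return The validated data.frame (missing optional columns added as
#'   `NA`), invisibly classed as before.
#' @export
validate_sample_meta <- function(samples) {
  if (!is.data.frame(samples)) {
    stop("sample metadata must be a data.frame", call. = FALSE)
  }
  required <- c("sample_id", "group")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0L) {
    stop("sample metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  samples$group <- as.character(samples$group)
  bad <- setdiff(unique(samples$group), GROUP_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; expected 'case' or 'control'", call. = FALSE)
  }
  for (col in c("control_source", "stage", "sex")) {
    if (is.null(samples[[col]])) samples[[col]] <- NA_character_
    samples[[col]] <- as.character(samples[[col]])
    samples[[col]][!is.na(samples[[col]]) & samples[[col]] == ""] <- NA_character_
  }
  if (is.null(samples$age)) samples$age <- NA_real_
  samples$age <- as.numeric(samples$age)

  bad_src <- setdiff(stats::na.omit(unique(samples$control_source)),
                     CONTROL_SOURCE_LEVELS)
  if (length(bad_src) > 0L) {
    stop("unknown control_source label(s): ",
         paste(bad_src, collapse = ", "), call. = FALSE)
  }
  bad_stage <- setdiff(stats::na.omit(unique(samples$stage)), STAGE_LEVELS)
  if (length(bad_stage) > 0L) {
    stop("unknown stage label(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- setdiff(stats::na.omit(unique(samples$sex)), SEX_LEVELS)
  if (length(bad_sex) > 0L) {
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  # control_source only for controls, stage only for cases
  offending <- samples$sample_id[samples$group == "case" &
                                   !is.na(samples$control_source)]
  if (length(offending) > 0L) {
    stop("control_source set for case sample(s): ",
         paste(offending, collapse = ", "), call. = FALSE)
  }
  offending <- samples$sample_id[samples$group == "control" &
                                   !is.na(samples$stage)]
  if (length(offending) > 0L) {
    stop("stage set for control sample(s): ",
         paste(offending, collapse = ", "), call. = FALSE)
  }
  samples
}

#' Construct a raw expression study
#'
#' Bundles a sample-by-miRNA raw fluorescence matrix with its per-array
#' background values and sample metadata. This is the entry container of
#' the pipeline, prior to positive-call selection and normalization.
#'
#' @param signal Numeric N x M matrix (samples x miRNAs) of raw,
#'   nonnegative fluorescence signals. Column names are miRNA IDs, row
#'   names sample IDs (supplied or taken from `samples`).
#' @param background Numeric vector of length N: the per-array background
#'   signal subtracted from positive calls.
#' @param samples Sample metadata data.frame (see
#'   [validate_sample_meta()]); row order must match `signal`.
#' @return An object of class `raw_expression_study` with elements
#'   `signal`, `background`, `samples`, `mirna_ids`, `sample_ids`.
#' @export
raw_expression_study <- function(signal, background, samples) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  samples <- validate_sample_meta(samples)
  n <- nrow(signal)
  if (nrow(samples) != n) {
    stop("signal has ", n, " rows but metadata describes ",
         nrow(samples), " samples", call. = FALSE)
  }
  if (is.null(colnames(signal))) {
    stop("signal matrix must have miRNA IDs as column names", call. = FALSE)
  }
  if (anyDuplicated(colnames(signal))) {
    dup <- unique(colnames(signal)[duplicated(colnames(signal))])
    stop("duplicate miRNA ID(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(rownames(signal))) {
    rownames(signal) <- samples$sample_id
  } else if (!identical(rownames(signal), samples$sample_id)) {
    stop("signal row names do not match metadata sample_id order",
         call. = FALSE)
  }
  if (any(!is.finite(signal))) {
    stop("signal contains non-finite values", call. = FALSE)
  }
  if (any(signal < 0)) {
    stop("signal contains negative values", call. = FALSE)
  }
  background <- as.numeric(background)
  if (length(background) != n) {
    stop("background must have one value per sample (", n, ")",
         call. = FALSE)
  }
  if (any(!is.finite(background)) || any(background < 0)) {
    stop("background values must be finite and >= 0; offending sample(s): ",
         paste(samples$sample_id[!is.finite(background) | background < 0],
               collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(signal = signal, background = background, samples = samples,
         mirna_ids = colnames(signal), sample_ids = samples$sample_id),
    class = "raw_expression_study"
  )
}

#' @export
print.raw_expression_study <- function(x, ...) {
  cat("raw_expression_study:", nrow(x$signal), "samples x",
      ncol(x$signal), "miRNAs\n")
  tab <- table(x$samples$group)
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a normalized expression matrix
#'
#' Log2-scale expression with an explicit missing marker (`NA`) for
#' negative calls (probes not exceeding the array background). Linear
#' scale values are carried alongside; the missing pattern is identical
#' on both scales.
#'
#' @param linear N x M matrix of linear-scale values (NA where missing,
#'   strictly positive where present).
#' @param values Optional matching log2 matrix; computed as
#'   `log2(pmax(linear, pseudo_floor))` when omitted.
#' @param pseudo_floor Positive floor applied before the log transform.
#' @return An object of class `normalized_matrix` with elements `values`
#'   (log2), `linear` (linear scale), `mirna_ids`, `sample_ids`.
#' @export
normalized_matrix <- function(linear, values = NULL, pseudo_floor = 0.1) {
  linear <- as.matrix(linear)
  storage.mode(linear) <- "double"
  if (is.null(colnames(linear)) || is.null(rownames(linear))) {
    stop("linear matrix needs sample row names and miRNA column names",
         call. = FALSE)
  }
  present <- !is.na(linear)
  if (any(linear[present] <= 0)) {
    stop("linear values must be > 0 wherever present", call. = FALSE)
  }
  if (is.null(values)) {
    values <- log2(pmax(linear, pseudo_floor))
  } else {
    values <- as.matrix(values)
    if (!identical(is.na(values), is.na(linear))) {
      stop("missing pattern differs between log2 and linear matrices",
           call. = FALSE)
    }
  }
  dimnames(values) <- dimnames(linear)
  structure(
    list(values = values, linear = linear,
         mirna_ids = colnames(linear), sample_ids = rownames(linear)),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$values), "samples x",
      ncol(x$values), "miRNAs;",
      sprintf("%.1f%% negative calls\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Construct a linear discriminant model
#'
#' An ordered set of miRNA IDs, one coefficient per miRNA, and an
#' intercept. The score of a profile x is `sum(coefficients * x) +
#' intercept`; a sample is called a case if and only if the score is
#' strictly greater than `decision_threshold` (ties are called control).
#'
#' @param mirna_ids Character vector of 1 to 8 feature names.
#' @param coefficients Numeric vector, same length as `mirna_ids`.
#' @param intercept Single numeric intercept.
#' @param decision_threshold Score cut point, default 0.
#' @return An object of class `discriminant_model`.
#' @export
discriminant_model <- function(mirna_ids, coefficients, intercept,
                               decision_threshold = 0) {
  mirna_ids <- as.character(mirna_ids)
  coefficients <- as.numeric(coefficients)
  if (length(mirna_ids) < 1L) {
    stop("a discriminant model needs at least one miRNA", call. = FALSE)
  }
  if (anyDuplicated(mirna_ids)) {
    stop("duplicate miRNA IDs in model", call. = FALSE)
  }
  if (length(coefficients) != length(mirna_ids)) {
    stop("length(coefficients) must equal length(mirna_ids)", call. = FALSE)
  }
  if (any(!is.finite(coefficients)) || !is.finite(intercept)) {
    stop("model coefficients and intercept must be finite", call. = FALSE)
  }
  structure(
    list(mirna_ids = mirna_ids, coefficients = coefficients,
         intercept = as.numeric(intercept)[1L],
         decision_threshold = as.numeric(decision_threshold)[1L]),
    class = "discriminant_model"
  )
}

#' Render a discriminant model as a printable formula string
#'
#' @param model A [discriminant_model()].
#' @param digits Significant digits for the coefficients.
#' @return A single string such as
#'   `"(0.961037)*miR-8073+(-0.962054)*miR-6794-5p-9.799262"`.
#' @export
format_model <- function(model, digits = 6) {
  stopifnot(inherits(model, "discriminant_model"))
  terms <- sprintf("(%s)*%s",
                   formatC(model$coefficients, digits = digits,
                           format = "g"),
                   model$mirna_ids)
  icpt <- formatC(model$intercept, digits = digits + 1, format = "g")
  if (model$intercept >= 0) icpt <- paste0("+", icpt)
  paste0(paste(terms, collapse = "+"), icpt)
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("discriminant_model with", length(x$mirna_ids), "miRNA(s):\n ",
      format_model(x), "\n  case iff score >", x$decision_threshold, "\n")
  invisible(x)
}

#' Bundle a normalized matrix with metadata and the robust-miRNA set
#'
#' @param normalized A [normalized_matrix()].
#' @param samples Sample metadata (see [validate_sample_meta()]), in the
#'   same order as the matrix rows.
#' @param selected_mirnas Character vector of miRNA IDs retained by the
#'   robust filter; must be a subset of the matrix columns.
#' @return An object of class `study_bundle`.
#' @export
study_bundle <- function(normalized, samples, selected_mirnas) {
  stopifnot(inherits(normalized, "normalized_matrix"))
  samples <- validate_sample_meta(samples)
  if (!identical(samples$sample_id, normalized$sample_ids)) {
    stop("metadata sample order does not match the normalized matrix",
         call. = FALSE)
  }
  extra <- setdiff(selected_mirnas, normalized$mirna_ids)
  if (length(extra) > 0L) {
    stop("selected_mirnas not present in the matrix: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  structure(
    list(normalized = normalized, samples = samples,
         selected_mirnas = as.character(selected_mirnas)),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  print(x$normalized)
  cat("  robust miRNAs:", length(x$selected_mirnas), "of",
      length(x$normalized$mirna_ids), "\n")
  invisible(x)
}
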