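#' Normalization configuration
#'
#' Settings for internal-control ratio normalization. Each array is
#' rescaled so that the arithmetic mean of its internal-control miRNA
#' signals equals a common reference level: either the grand mean of the
#' per-array control means (`"grand_mean"`, the within-study default) or
#' a frozen `fixed_reference` value, which is what makes scoring a
#' single prospective array well-defined.
#'
#' @param internal_controls miRNA IDs of the stable internal-control
#'   probes. The defaults are the three controls of the serum miRNA
#'   array platform.
#' @param reference_level `"grand_mean"` or `"fixed_value"`.
#' @param fixed_reference Positive reference level; required iff
#'   `reference_level = "fixed_value"`.
#' @param log_base Base of the log transform (fixed at 2).
#' @param pseudo_floor Positive floor applied to linear values before
#'   the log transform, and used to impute negative calls at scoring
#'   time.
#' @return A list of class `normalization_config`.
#' @export
normalization_config <- function(internal_controls = c("miR-149-3p",
                                                       "miR-2861",
                                                       "miR-4463"),
                                 reference_level = c("grand_mean",
                                                     "fixed_value"),
                                 fixed_reference = NULL,
                                 log_base = 2,
                                 pseudo_floor = 0.1) {
  reference_level <- match.arg(reference_level)
  if (length(internal_controls) < 1L) {
    stop("internal_controls must be nonempty", call. = FALSE)
  }
  if (log_base != 2) stop("only log base 2 is supported", call. = FALSE)
  if (!is.numeric(pseudo_floor) || pseudo_floor <= 0) {
    stop("pseudo_floor must be > 0", call. = FALSE)
  }
  if (reference_level == "fixed_value") {
    if (is.null(fixed_reference) || !is.numeric(fixed_reference) ||
        fixed_reference <= 0) {
      stop("fixed_reference (> 0) is required when reference_level = ",
           "'fixed_value'", call. = FALSE)
    }
  } else if (!is.null(fixed_reference)) {
    stop("fixed_reference only applies when reference_level = ",
         "'fixed_value'", call. = FALSE)
  }
  structure(list(internal_controls = as.character(internal_controls),
                 reference_level = reference_level,
                 fixed_reference = fixed_reference,
                 log_base = 2, pseudo_floor = pseudo_floor),
            class = "normalization_config")
}

#' Robust-miRNA filter configuration
#'
#' A miRNA is retained when its linear normalized signal strictly
#' exceeds `signal_threshold` in strictly more than
#' `sample_fraction` of the samples of every group (`"all_groups"`,
#' default) or of at least one group (`"any_group"`).
#'
#' @param signal_threshold Linear-scale threshold (default 64).
#' @param sample_fraction Required fraction of samples per group, in
#'   (0, 1] (default 0.5).
#' @param group_rule `"all_groups"` or `"any_group"`.
#' @return A list of class `robust_filter_config`.
#' @export
robust_filter_config <- function(signal_threshold = 64,
                                 sample_fraction = 0.5,
                                 group_rule = c("all_groups",
                                                "any_group")) {
  group_rule <- match.arg(group_rule)
  if (!is.numeric(signal_threshold) || signal_threshold <= 0) {
    stop("signal_threshold must be > 0", call. = FALSE)
  }
  if (!is.numeric(sample_fraction) || sample_fraction <= 0 ||
      sample_fraction > 1) {
    stop("sample_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(list(signal_threshold = signal_threshold,
                 sample_fraction = sample_fraction,
                 group_rule = group_rule),
            class = "robust_filter_config")
}

#' Positive-call selection and background subtraction
#'
#' Probes whose raw signal strictly exceeds the array background are
#' positive calls; the background is subtracted from them. All other
#' cells become missing (negative calls). The result is a linear-stage,
#' still unnormalized [normalized_matrix()].
#'
#' @param study A [raw_expression_study()].
#' @param pseudo_floor Floor used for the accompanying log2 values.
#' @return A [normalized_matrix()] with `NA` at negative calls.
#' @export
positive_call_subtract <- function(study, pseudo_floor = 0.1) {
  stopifnot(inherits(study, "raw_expression_study"))
  bad <- which(is.na(study$background))
  if (length(bad) > 0L) {
    stop("background missing for sample(s): ",
         paste(study$sample_ids[bad], collapse = ", "), call. = FALSE)
  }
  linear <- sweep(study$signal, 1L, study$background, `-`)
  linear[study$signal <= study$background] <- NA_real_
  normalized_matrix(linear, pseudo_floor = pseudo_floor)
}

per_array_control_means <- function(m, cfg) {
  absent <- setdiff(cfg$internal_controls, m$mirna_ids)
  if (length(absent) > 0L) {
    stop("internal control(s) absent from the matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ctrl <- m$linear[, cfg$internal_controls, drop = FALSE]
  c_i <- rowMeans(ctrl, na.rm = TRUE)
  dead <- which(!is.finite(c_i))
  if (length(dead) > 0L) {
    stop("all internal controls are negative calls on array(s): ",
         paste(m$sample_ids[dead], collapse = ", "), call. = FALSE)
  }
  c_i
}

#' Internal-control ratio normalization
#'
#' Rescales each array by `f_i = R / c_i`, where `c_i` is the arithmetic
#' mean of that array's internal-control linear signals and `R` is the
#' reference level (grand mean of the `c_i`, or the frozen
#' `fixed_reference`). After scaling, every array's internal-control
#' mean equals `R`. Log2 values are `log2(pmax(linear, pseudo_floor))`.
#'
#' @param m A linear-stage [normalized_matrix()] from
#'   [positive_call_subtract()].
#' @param cfg A [normalization_config()].
#' @return A [normalized_matrix()] with attributes `reference` (the R
#'   used) and `scale_factors` (per-array `f_i`).
#' @export
normalize_internal_controls <- function(m, cfg = normalization_config()) {
  stopifnot(inherits(m, "normalized_matrix"),
            inherits(cfg, "normalization_config"))
  c_i <- per_array_control_means(m, cfg)
  R <- if (cfg$reference_level == "grand_mean") mean(c_i) else
    cfg$fixed_reference
  f_i <- R / c_i
  linear <- m$linear * f_i
  out <- normalized_matrix(linear, pseudo_floor = cfg$pseudo_floor)
  attr(out, "reference") <- R
  attr(out, "scale_factors") <- stats::setNames(f_i, m$sample_ids)
  out
}

#' Robust-miRNA filter
#'
#' Retains the miRNAs whose linear normalized signal strictly exceeds
#' the threshold in strictly more than the required fraction of samples
#' in each group (both inequalities strict; missing cells count as not
#' exceeding). Output order follows the input miRNA order.
#'
#' @param m A [normalized_matrix()].
#' @param groups Character/factor vector of group labels, one per
#'   sample.
#' @param cfg A [robust_filter_config()].
#' @return Character vector of retained miRNA IDs.
#' @export
robust_filter <- function(m, groups, cfg = robust_filter_config()) {
  stopifnot(inherits(m, "normalized_matrix"),
            inherits(cfg, "robust_filter_config"))
  groups <- as.character(groups)
  if (length(groups) != nrow(m$linear)) {
    stop("groups must have one label per sample", call. = FALSE)
  }
  levs <- unique(groups)
  if (length(levs) < 2L) {
    stop("robust_filter needs at least 2 groups", call. = FALSE)
  }
  exceeds <- !is.na(m$linear) & m$linear > cfg$signal_threshold
  frac <- vapply(levs, function(g) {
    rows <- groups == g
    if (!any(rows)) stop("group '", g, "' has no samples", call. = FALSE)
    colMeans(exceeds[rows, , drop = FALSE])
  }, numeric(ncol(exceeds)))
  pass <- frac > cfg$sample_fraction          # strict "more than"
  keep <- if (cfg$group_rule == "all_groups") {
    rowSums(pass) == length(levs)
  } else {
    rowSums(pass) >= 1L
  }
  m$mirna_ids[keep]
}

#' Run the full preprocessing stage
#'
#' Positive-call selection, background subtraction, internal-control
#' normalization and the robust-miRNA filter, bundled with the sample
#' metadata.
#'
#' @param study A [raw_expression_study()].
#' @param norm_cfg A [normalization_config()].
#' @param filter_cfg A [robust_filter_config()].
#' @return A [study_bundle()].
#' @export
preprocess_study <- function(study,
                             norm_cfg = normalization_config(),
                             filter_cfg = robust_filter_config()) {
  stage1 <- positive_call_subtract(study,
                                   pseudo_floor = norm_cfg$pseudo_floor)
  normed <- normalize_internal_controls(stage1, norm_cfg)
  selected <- robust_filter(normed, study$samples$group, filter_cfg)
  bundle <- study_bundle(normed, study$samples, selected)
  attr(bundle, "reference") <- attr(normed, "reference")
  bundle
}

#' Extract a model-ready log2 feature matrix
#'
#' Pulls the requested miRNA columns out of a normalized matrix and
#' imputes negative calls at the pseudo-floor (on the linear scale,
#' before log2). This is the deterministic low-expression handling used
#' when scoring a profile whose model miRNAs were not all positive
#' calls.
#'
#' @param m A [normalized_matrix()] or [study_bundle()].
#' @param mirna_ids Columns to extract (default: a bundle's
#'   `selected_mirnas`, or all columns).
#' @param pseudo_floor Imputation floor on the linear scale.
#' @return Numeric samples-x-features matrix of log2 values, no missing
#'   entries.
#' @export
feature_matrix <- function(m, mirna_ids = NULL, pseudo_floor = 0.1) {
  if (inherits(m, "study_bundle")) {
    if (is.null(mirna_ids)) mirna_ids <- m$selected_mirnas
    m <- m$normalized
  }
  stopifnot(inherits(m, "normalized_matrix"))
  if (is.null(mirna_ids)) mirna_ids <- m$mirna_ids
  absent <- setdiff(mirna_ids, m$mirna_ids)
  if (length(absent) > 0L) {
    stop("miRNA(s) absent from the matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  X <- m$values[, mirna_ids, drop = FALSE]
  X[is.na(X)] <- log2(pseudo_floor)
  X
}
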