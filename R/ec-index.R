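#' The published 6-miRNA EC index
#'
#' The frozen serum miRNA discriminant for esophageal squamous cell
#' carcinoma: six miRNAs with fixed coefficients and intercept. The
#' score of a profile is
#' `(0.961037)*miR-8073 + (-0.962054)*miR-6794-5p + (1.31647)*miR-3196 +
#'  (-1.0132)*miR-6820-5p + (0.657628)*miR-744-5p +
#'  (-0.406723)*miR-6799-5p - 9.799262`,
#' and a sample is called positive (cancer) iff the score is strictly
#' greater than 0. Inputs are internal-control-normalized log2 signal
#' values (see [normalize_internal_controls()]); the normalization
#' scale convention is the package's, as the coefficient scale of the
#' original assay is not recoverable from the printed formula alone.
#'
#' @return A [discriminant_model()] with the published constants.
#' @export
ec_index_model <- function() {
  discriminant_model(
    mirna_ids = c("miR-8073", "miR-6794-5p", "miR-3196", "miR-6820-5p",
                  "miR-744-5p", "miR-6799-5p"),
    coefficients = c(0.961037, -0.962054, 1.31647, -1.0132, 0.657628,
                     -0.406723),
    intercept = -9.799262,
    decision_threshold = 0
  )
}

#' Score profiles with the published EC index
#'
#' @param profile A named numeric vector (one sample) or a
#'   samples-x-miRNAs matrix/data.frame providing normalized log2
#'   values for all six index miRNAs. Negative calls must have been
#'   imputed upstream (see [feature_matrix()]).
#' @return A data.frame with columns `score` and `call`
#'   (`"positive"`/`"negative"`); a score of exactly 0 is negative.
#' @export
ec_score <- function(profile) {
  model <- ec_index_model()
  s <- score_samples(model, profile)
  data.frame(score = s,
             call = ifelse(s > model$decision_threshold,
                           "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Screening predictive values at a given disease prevalence
#'
#' Closed-form Bayes arithmetic for applying a test with known
#' sensitivity and specificity to a screening population:
#' `PPV = sens * p / (sens * p + (1 - spec) * (1 - p))` is the
#' post-test probability of disease after a positive result, and
#' `1 - NPV = (1 - sens) * p / ((1 - sens) * p + spec * (1 - p))`
#' the residual risk after a negative result.
#'
#' @param prevalence Disease prevalence, strictly inside (0, 1).
#' @param sensitivity,specificity Test operating characteristics, in
#'   (0, 1]; a perfect test (both 1) gives PPV 1 and 1 - NPV 0.
#' @return A list of class `screening_metrics` with `ppv`, `npv`,
#'   `one_minus_npv`, and the inputs.
#' @export
screening_metrics <- function(prevalence, sensitivity, specificity) {
  vals <- c(prevalence = prevalence, sensitivity = sensitivity,
            specificity = specificity)
  bad <- names(vals)[!is.finite(vals) | vals <= 0 | vals > 1]
  if (!is.finite(prevalence) || prevalence >= 1) bad <- union(bad, "prevalence")
  if (length(bad) > 0L) {
    stop("prevalence must lie in (0, 1) and sensitivity/specificity in ",
         "(0, 1]; offending: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- prevalence
  ppv <- sensitivity * p /
    (sensitivity * p + (1 - specificity) * (1 - p))
  one_minus_npv <- (1 - sensitivity) * p /
    ((1 - sensitivity) * p + specificity * (1 - p))
  structure(list(ppv = ppv, npv = 1 - one_minus_npv,
                 one_minus_npv = one_minus_npv,
                 prevalence = p, sensitivity = sensitivity,
                 specificity = specificity),
            class = "screening_metrics")
}

#' @export
print.screening_metrics <- function(x, ...) {
  pct <- function(v) paste0(formatC(100 * v, digits = 2, format = "g"),
                            "%")
  cat("screening at prevalence", pct(x$prevalence),
      "(sens", x$sensitivity, ", spec", x$specificity, "):\n")
  cat("  positive result -> disease probability", pct(x$ppv), "(PPV)\n")
  cat("  negative result -> residual risk", pct(x$one_minus_npv),
      "(1 - NPV)\n")
  invisible(x)
}
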