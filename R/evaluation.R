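#' ROC curve points
#'
#' Sweeps the decision threshold over the unique score values in
#' descending order and reports (false positive rate, true positive
#' rate) at each step. The endpoints (0,0) and (1,1) are always
#' included; tied scores move diagonally in a single step.
#'
#' @param scores Numeric discriminant scores (higher = more case-like).
#' @param y Labels (see [fit_fisher_lda()]).
#' @return A data.frame with columns `threshold` (`Inf` for the (0,0)
#'   corner), `fpr`, `tpr`.
#' @export
roc_points <- function(scores, y) {
  y_case <- as_case_indicator(y)
  if (length(scores) != length(y_case)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  n1 <- sum(y_case); n0 <- sum(!y_case)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y_case), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !y_case), numeric(1))
  data.frame(threshold = c(Inf, thr),
             fpr = c(0, fp / n0),
             tpr = c(0, tp / n1))
}

#' Area under the ROC curve with a DeLong 95% confidence interval
#'
#' The AUC is the Mann-Whitney U statistic scaled to \[0, 1\], with
#' tied case/control score pairs counted 1/2. The confidence interval
#' uses DeLong's structural-components variance estimate on the normal
#' scale, truncated to \[0, 1\]. For degenerate score sets (zero
#' variance, e.g. perfect separation) the interval collapses onto the
#' point estimate.
#'
#' @inheritParams roc_points
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `auc`, `lower`, `upper`, `se`.
#' @export
auc_ci <- function(scores, y, conf_level = 0.95) {
  y_case <- as_case_indicator(y)
  n1 <- sum(y_case); n0 <- sum(!y_case)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  s1 <- scores[y_case]; s0 <- scores[!y_case]
  a <- as.numeric(auc_cpp(as.numeric(scores), as.integer(y_case)))
  # DeLong structural components
  psi <- function(x, yv) mean((x > yv) + 0.5 * (x == yv))
  v10 <- vapply(s1, function(x) psi(x, s0), numeric(1))
  v01 <- vapply(s0, function(x) mean((s1 > x) + 0.5 * (s1 == x)),
                numeric(1))
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  se <- sqrt(max(var_auc, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = a,
       lower = max(0, a - z * se),
       upper = min(1, a + z * se),
       se = se)
}

#' @rdname auc_ci
#' @return `auc()` returns the point estimate only.
#' @export
auc <- function(scores, y) {
  y_case <- as_case_indicator(y)
  if (!any(y_case) || all(y_case)) {
    stop("both classes must be present", call. = FALSE)
  }
  as.numeric(auc_cpp(as.numeric(scores), as.integer(y_case)))
}

wilson_interval <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

clopper_pearson_interval <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}

#' Sensitivity, specificity and accuracy with confidence intervals
#'
#' @param calls Predicted labels (`"case"`/`"control"`, logical, or
#'   0/1).
#' @param y True labels.
#' @param ci_method `"wilson"` (default) or `"clopper_pearson"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A data.frame with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate`, `lower`, `upper`.
#' @export
binary_metrics <- function(calls, y,
                           ci_method = c("wilson", "clopper_pearson"),
                           conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  pred_case <- as_case_indicator(calls)
  y_case <- as_case_indicator(y)
  if (length(pred_case) != length(y_case)) {
    stop("calls and labels differ in length", call. = FALSE)
  }
  if (!any(y_case) || all(y_case)) {
    stop("both classes must be present", call. = FALSE)
  }
  ci_fun <- switch(ci_method, wilson = wilson_interval,
                   clopper_pearson = clopper_pearson_interval)
  tp <- sum(pred_case & y_case)
  tn <- sum(!pred_case & !y_case)
  counts <- rbind(
    sensitivity = c(tp, sum(y_case)),
    specificity = c(tn, sum(!y_case)),
    accuracy = c(tp + tn, length(y_case))
  )
  out <- lapply(rownames(counts), function(m) {
    x <- counts[m, 1L]; n <- counts[m, 2L]
    ci <- ci_fun(x, n, conf_level)
    data.frame(metric = m, numerator = x, denominator = n,
               estimate = x / n, lower = ci[1L], upper = ci[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Subgroup diagnostic metrics by stage or control cohort
#'
#' Sensitivity is computed within each tumour-stage stratum (cases
#' only); specificity within each control-source stratum (controls
#' only). Predictions derive from `score > threshold` with the model's
#' fixed threshold; strata with no samples are omitted with a message.
#'
#' @param scores Numeric discriminant scores, one per sample.
#' @param y True labels.
#' @param meta Sample metadata (see [validate_sample_meta()]), same
#'   order as `scores`.
#' @param strata `"stage"`, `"control_source"`, or both.
#' @param threshold Decision threshold (default 0); calls are
#'   case iff score strictly greater.
#' @param ci_method CI method for the per-stratum proportion.
#' @return A data.frame with columns `stratum_type`, `stratum`, `n`,
#'   `metric`, `numerator`, `estimate`, `lower`, `upper`.
#' @export
subgroup_report <- function(scores, y, meta,
                            strata = c("stage", "control_source"),
                            threshold = 0,
                            ci_method = c("wilson",
                                          "clopper_pearson")) {
  strata <- match.arg(strata, several.ok = TRUE)
  ci_method <- match.arg(ci_method)
  meta <- validate_sample_meta(meta)
  y_case <- as_case_indicator(y)
  if (length(scores) != nrow(meta) || length(y_case) != nrow(meta)) {
    stop("scores, labels and metadata must align", call. = FALSE)
  }
  ci_fun <- switch(ci_method, wilson = wilson_interval,
                   clopper_pearson = clopper_pearson_interval)
  pos <- scores > threshold
  rows <- list()
  if ("stage" %in% strata) {
    for (st in STAGE_LEVELS) {
      sel <- y_case & !is.na(meta$stage) & meta$stage == st
      n <- sum(sel)
      if (n == 0L) {
        message("stage ", st, ": no cases; stratum omitted")
        next
      }
      x <- sum(pos[sel])
      ci <- ci_fun(x, n)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum_type = "stage", stratum = st, n = n,
        metric = "sensitivity", numerator = x, estimate = x / n,
        lower = ci[1L], upper = ci[2L], stringsAsFactors = FALSE)
    }
  }
  if ("control_source" %in% strata) {
    for (src in CONTROL_SOURCE_LEVELS) {
      sel <- !y_case & !is.na(meta$control_source) &
        meta$control_source == src
      n <- sum(sel)
      if (n == 0L) {
        message("control source ", src, ": no controls; stratum omitted")
        next
      }
      x <- sum(!pos[sel])
      ci <- ci_fun(x, n)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum_type = "control_source", stratum = src, n = n,
        metric = "specificity", numerator = x, estimate = x / n,
        lower = ci[1L], upper = ci[2L], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Full diagnostic evaluation of scored samples
#'
#' Overall sensitivity/specificity/accuracy (calls from
#' `score > threshold`), AUC with DeLong CI, and the stage /
#' control-source subgroup breakdown.
#'
#' @inheritParams subgroup_report
#' @param meta Optional sample metadata for the subgroup section.
#' @return An object of class `evaluation_report`: list with
#'   `n_case`, `n_control`, `metrics` (from [binary_metrics()]),
#'   `auc` (from [auc_ci()]), `roc` (from [roc_points()]) and
#'   `per_stratum` (when `meta` is given).
#' @export
evaluate_scores <- function(scores, y, meta = NULL, threshold = 0,
                            ci_method = c("wilson",
                                          "clopper_pearson")) {
  ci_method <- match.arg(ci_method)
  y_case <- as_case_indicator(y)
  calls <- ifelse(scores > threshold, "case", "control")
  rep <- list(
    n_case = sum(y_case),
    n_control = sum(!y_case),
    metrics = binary_metrics(calls, y, ci_method = ci_method),
    auc = auc_ci(scores, y),
    roc = roc_points(scores, y),
    per_stratum = if (!is.null(meta)) {
      subgroup_report(scores, y, meta, threshold = threshold,
                      ci_method = ci_method)
    }
  )
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation:", x$n_case, "cases,", x$n_control, "controls\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %s  [%d/%d]\n", m$metric[i],
                ci_str(m$estimate[i], m$lower[i], m$upper[i]),
                m$numerator[i], m$denominator[i]))
  }
  cat(sprintf("  %-12s %s\n", "auc",
              ci_str(x$auc$auc, x$auc$lower, x$auc$upper)))
  if (!is.null(x$per_stratum)) {
    cat("  subgroups:\n")
    s <- x$per_stratum
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %s %-12s %s = %s (n=%d)\n", s$stratum_type[i],
                  s$stratum[i], s$metric[i],
                  ci_str(s$estimate[i], s$lower[i], s$upper[i]),
                  s$n[i]))
    }
  }
  invisible(x)
}
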