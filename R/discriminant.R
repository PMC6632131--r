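#' Fisher LDA fitting configuration
#'
#' @param prior `"equal"` (default; the training cohorts were designed
#'   1:1) or `"empirical"`, which shifts the intercept by
#'   `log(n_case / n_control)`.
#' @param ridge Nonnegative stabilizer added to the diagonal of the
#'   pooled within-class scatter before solving (default `1e-8`).
#' @param covariance Only `"pooled"` is supported.
#' @return A list of class `lda_config`.
#' @export
lda_config <- function(prior = c("equal", "empirical"), ridge = 1e-8,
                       covariance = "pooled") {
  prior <- match.arg(prior)
  if (!identical(covariance, "pooled")) {
    stop("only the pooled within-class covariance is supported",
         call. = FALSE)
  }
  if (!is.numeric(ridge) || length(ridge) != 1L || ridge < 0) {
    stop("ridge must be a single nonnegative number", call. = FALSE)
  }
  structure(list(prior = prior, ridge = ridge, covariance = "pooled"),
            class = "lda_config")
}

# coerce labels to a logical case indicator
as_case_indicator <- function(y) {
  if (is.logical(y)) return(y)
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), GROUP_LEVELS)
    if (length(bad) > 0L) {
      stop("labels must be 'case'/'control'; got: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    return(y == "case")
  }
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) {
      stop("numeric labels must be 0 (control) or 1 (case)", call. = FALSE)
    }
    return(y == 1)
  }
  stop("unsupported label type", call. = FALSE)
}

check_feature_matrix <- function(X, y_case, min_per_class = 2L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("X must not contain missing values", call. = FALSE)
  if (length(y_case) != nrow(X)) {
    stop("length(y) must equal nrow(X)", call. = FALSE)
  }
  n1 <- sum(y_case); n0 <- sum(!y_case)
  if (n1 < min_per_class || n0 < min_per_class) {
    stop("each class needs at least ", min_per_class, " samples (case=",
         n1, ", control=", n0, ")", call. = FALSE)
  }
  X
}

#' Fit a two-class Fisher linear discriminant
#'
#' Computes the Fisher direction `w = Sw^-1 (m_case - m_control)`,
#' where `Sw` is the pooled within-class scatter matrix (sum of the two
#' classes' centered cross-products), ridge-stabilized on its diagonal.
#' The intercept places the decision boundary at the midpoint of the
#' class means, `b = -w . (m_case + m_control) / 2`, shifted by
#' `log(n_case / n_control)` under empirical priors. A sample is called
#' a case iff `w . x + b > 0`; the Fisher direction is identified only
#' up to a positive scalar, and this un-normalized convention is the
#' package's fixed choice.
#'
#' @param X Numeric samples-x-features matrix of log2 normalized
#'   signals; no missing values.
#' @param y Labels: logical case indicator, `"case"`/`"control"`
#'   strings/factor, or 0/1.
#' @param cfg An [lda_config()].
#' @return A [discriminant_model()] whose `mirna_ids` are `colnames(X)`.
#' @export
fit_fisher_lda <- function(X, y, cfg = lda_config()) {
  stopifnot(inherits(cfg, "lda_config"))
  y_case <- as_case_indicator(y)
  X <- check_feature_matrix(X, y_case)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  }
  m1 <- colMeans(X[y_case, , drop = FALSE])
  m0 <- colMeans(X[!y_case, , drop = FALSE])
  center <- function(M, mu) sweep(M, 2L, mu, `-`)
  S1 <- crossprod(center(X[y_case, , drop = FALSE], m1))
  S0 <- crossprod(center(X[!y_case, , drop = FALSE], m0))
  Sw <- S1 + S0
  diag(Sw) <- diag(Sw) + cfg$ridge
  w <- tryCatch(
    solve(Sw, m1 - m0),
    error = function(e) {
      stop("pooled within-class scatter is singular; increase ridge ",
           "(currently ", cfg$ridge, "): ", conditionMessage(e),
           call. = FALSE)
    }
  )
  b <- -sum(w * (m1 + m0)) / 2
  if (cfg$prior == "empirical") {
    b <- b + log(sum(y_case) / sum(!y_case))
  }
  discriminant_model(colnames(X), as.numeric(w), b)
}

#' Score samples with a discriminant model
#'
#' @param model A [discriminant_model()].
#' @param x A named numeric vector (one profile) or a samples-x-features
#'   numeric matrix/data.frame whose columns cover `model$mirna_ids`.
#' @return Numeric vector of scores `w . x + intercept`.
#' @export
score_samples <- function(model, x) {
  stopifnot(inherits(model, "discriminant_model"))
  if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    stop("profile must name its miRNAs", call. = FALSE)
  }
  absent <- setdiff(model$mirna_ids, colnames(x))
  if (length(absent) > 0L) {
    stop("profile is missing model miRNA(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  drop(x[, model$mirna_ids, drop = FALSE] %*% model$coefficients) +
    model$intercept
}

#' Classify samples with a discriminant model
#'
#' A sample is called `"case"` iff its score strictly exceeds the
#' model's decision threshold; a score exactly at the threshold is
#' called `"control"`.
#'
#' @inheritParams score_samples
#' @return Character vector of `"case"`/`"control"` calls.
#' @export
classify_samples <- function(model, x) {
  s <- score_samples(model, x)
  ifelse(s > model$decision_threshold, "case", "control")
}

#' Leave-one-out cross-validated accuracy of a Fisher LDA
#'
#' For each sample, the discriminant is refit on the remaining N-1
#' samples and the held-out sample is predicted from its score.
#' Accuracy is the fraction of correct predictions. Deterministic.
#'
#' @param X Numeric samples-x-features matrix, no missing values.
#' @param y Labels (see [fit_fisher_lda()]).
#' @param features Optional character vector or column indices selecting
#'   a feature subset of `X`.
#' @param cfg An [lda_config()].
#' @return A list with `accuracy`, `predictions` (character calls),
#'   and `scores` (held-out discriminant scores).
#' @export
loocv_accuracy <- function(X, y, features = NULL, cfg = lda_config()) {
  stopifnot(inherits(cfg, "lda_config"))
  y_case <- as_case_indicator(y)
  X <- as.matrix(X)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  X <- check_feature_matrix(X, y_case)
  if (nrow(X) < 4L) stop("LOOCV needs at least 4 samples", call. = FALSE)
  # each fold must retain >= 1 sample per class; with >= 2 per class the
  # deleted fold cannot empty a class
  scores <- lda_loocv_cpp(X, as.integer(y_case), cfg$ridge,
                          cfg$prior == "empirical")
  preds <- ifelse(scores > 0, "case", "control")
  truth <- ifelse(y_case, "case", "control")
  list(accuracy = mean(preds == truth),
       predictions = preds,
       scores = as.numeric(scores))
}
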