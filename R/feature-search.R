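#' Beam-search configuration
#'
#' @param beam_width Number of feature combinations retained per subset
#'   size (default 20).
#' @param max_features Largest model size explored (default 8).
#' @param tie_break Total ranking rule; only
#'   `"auc_then_lexicographic"` is defined: LOOCV accuracy, then
#'   training AUC, then the lexicographically smallest sorted
#'   feature-ID tuple.
#' @param rng_seed Reserved for optional stochastic extensions; the
#'   search itself is deterministic and ignores it.
#' @return A list of class `search_config`.
#' @export
search_config <- function(beam_width = 20, max_features = 8,
                          tie_break = "auc_then_lexicographic",
                          rng_seed = NULL) {
  if (!identical(tie_break, "auc_then_lexicographic")) {
    stop("unsupported tie_break: ", tie_break, call. = FALSE)
  }
  beam_width <- as.integer(beam_width)
  max_features <- as.integer(max_features)
  if (beam_width < 1L) stop("beam_width must be >= 1", call. = FALSE)
  if (max_features < 1L) stop("max_features must be >= 1", call. = FALSE)
  structure(list(beam_width = beam_width, max_features = max_features,
                 tie_break = tie_break, rng_seed = rng_seed),
            class = "search_config")
}

set_key <- function(features) {
  paste(sort(features, method = "radix"), collapse = "|")
}

#' Greedy beam search over miRNA subsets scored by LOOCV accuracy
#'
#' Round 1 scores every candidate miRNA alone by leave-one-out
#' cross-validated Fisher-LDA accuracy and keeps the top `beam_width`.
#' Each subsequent round extends every kept subset by each remaining
#' candidate, collapses duplicate feature sets, re-ranks by LOOCV
#' accuracy (ties: higher training AUC, then lexicographically smallest
#' sorted feature tuple) and again keeps the top `beam_width`, up to
#' `max_features` miRNAs. Per-subset LOOCV results are memoized by
#' feature-set key, so no subset is evaluated twice.
#'
#' @param X Numeric samples-x-miRNAs log2 matrix, no missing values.
#' @param y Labels (see [fit_fisher_lda()]).
#' @param candidate_mirnas Columns of `X` to search over (default all).
#' @param cfg A [search_config()].
#' @param lda_cfg An [lda_config()].
#' @return An object of class `search_result`: list with
#'   `per_size_top` (per size, a ranked data.frame of candidates),
#'   `per_size_best` (rank-1 candidate per size, each with its refit
#'   [discriminant_model()]), `selected` (filled by
#'   [select_final_model()]), and the configs.
#' @export
beam_search <- function(X, y, candidate_mirnas = colnames(X),
                        cfg = search_config(), lda_cfg = lda_config()) {
  stopifnot(inherits(cfg, "search_config"),
            inherits(lda_cfg, "lda_config"))
  y_case <- as_case_indicator(y)
  X <- check_feature_matrix(X, y_case)
  if (is.null(colnames(X))) {
    stop("X must have miRNA IDs as column names", call. = FALSE)
  }
  candidate_mirnas <- as.character(candidate_mirnas)
  absent <- setdiff(candidate_mirnas, colnames(X))
  if (length(absent) > 0L) {
    stop("candidate miRNA(s) absent from X: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (length(candidate_mirnas) < 1L) {
    stop("need at least one candidate miRNA", call. = FALSE)
  }
  yi <- as.integer(y_case)
  col_of <- stats::setNames(seq_len(ncol(X)), colnames(X))
  memo <- new.env(parent = emptyenv())

  # evaluate, deduplicate, rank and trim one round's candidate sets
  rank_and_trim <- function(sets) {
    keys <- vapply(sets, set_key, character(1))
    first <- !duplicated(keys)            # identical sets, identical models
    sets <- sets[first]
    keys <- keys[first]
    todo_keys <- setdiff(keys, ls(memo, sorted = FALSE))
    if (length(todo_keys) > 0L) {
      todo <- keys %in% todo_keys
      idx <- lapply(sets[todo],
                    function(fs) as.integer(col_of[fs]) - 1L)
      res <- beam_eval_cpp(X, yi, idx, lda_cfg$ridge,
                           lda_cfg$prior == "empirical")
      kt <- keys[todo]
      for (p in seq_along(kt)) {
        assign(kt[p], c(res[p, 1L], res[p, 2L]), envir = memo)
      }
    }
    vals <- vapply(keys, get, numeric(2), envir = memo)
    df <- data.frame(key = keys,
                     loocv_accuracy = vals[1L, ],
                     training_auc = vals[2L, ],
                     stringsAsFactors = FALSE)
    df$features <- I(sets)
    ord <- order(-df$loocv_accuracy, -df$training_auc, df$key,
                 method = "radix")
    df <- df[ord, , drop = FALSE]
    utils::head(df, cfg$beam_width)
  }

  per_size_top <- list()
  sets <- lapply(candidate_mirnas, function(m) m)
  beam <- rank_and_trim(sets)
  per_size_top[["1"]] <- beam

  s <- 1L
  while (s < cfg$max_features) {
    if (s >= length(candidate_mirnas)) {
      message("beam search stopped at size ", s,
              ": only ", length(candidate_mirnas),
              " candidate miRNA(s) available")
      break
    }
    ext <- vector("list", nrow(beam))
    for (r in seq_len(nrow(beam))) {
      fs <- beam$features[[r]]
      remaining <- setdiff(candidate_mirnas, fs)
      ext[[r]] <- lapply(remaining, function(m) c(fs, m))
    }
    beam <- rank_and_trim(unlist(ext, recursive = FALSE))
    s <- s + 1L
    per_size_top[[as.character(s)]] <- beam
  }

  per_size_best <- lapply(per_size_top, function(df) {
    fs <- df$features[[1L]]
    model <- fit_fisher_lda(X[, fs, drop = FALSE], y_case, lda_cfg)
    list(features = fs,
         loocv_accuracy = df$loocv_accuracy[1L],
         training_auc = df$training_auc[1L],
         model = model)
  })

  structure(
    list(per_size_top = per_size_top,
         per_size_best = per_size_best,
         selected = NULL,
         config = cfg, lda_config = lda_cfg,
         candidate_mirnas = candidate_mirnas,
         X = X, y = ifelse(y_case, "case", "control")),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  sizes <- names(x$per_size_best)
  acc <- vapply(x$per_size_best, `[[`, numeric(1), "loocv_accuracy")
  cat("beam search over", length(x$candidate_mirnas),
      "candidate miRNAs (beam width", x$config$beam_width, ")\n")
  cat("  best LOOCV accuracy by size:\n")
  for (s in sizes) {
    cat(sprintf("    %s miRNA(s): %.4f  [%s]\n", s, acc[[s]],
                paste(sort(x$per_size_best[[s]]$features),
                      collapse = ", ")))
  }
  if (!is.null(x$selected)) {
    cat("  selected size:", length(x$selected$features), "\n")
  }
  invisible(x)
}

#' Pick the final model: high accuracy with few miRNAs
#'
#' Among the per-size best candidates, returns the smallest size whose
#' LOOCV accuracy is within `epsilon` of the maximum over all sizes.
#'
#' @param result A `search_result` from [beam_search()].
#' @param epsilon Accuracy slack tolerated in exchange for a smaller
#'   model (default 0.005).
#' @return The chosen candidate (list with `features`,
#'   `loocv_accuracy`, `training_auc`, `model`, `size`). The same
#'   candidate is also stored in `result$selected` when the returned
#'   result object is reassigned.
#' @export
select_final_model <- function(result, epsilon = 0.005) {
  stopifnot(inherits(result, "search_result"))
  if (length(result$per_size_best) == 0L) {
    stop("empty search result", call. = FALSE)
  }
  acc <- vapply(result$per_size_best, `[[`, numeric(1),
                "loocv_accuracy")
  target <- max(acc) - epsilon
  sizes <- as.integer(names(acc))
  chosen <- min(sizes[acc >= target])
  cand <- result$per_size_best[[as.character(chosen)]]
  cand$size <- chosen
  cand
}

ci_str <- function(est, lo, hi) {
  sprintf("%.2f (%.2f-%.2f)", est, lo, hi)
}

#' Per-size summary table of the beam search
#'
#' One row per model size: the best model's formula and its
#' sensitivity, specificity, accuracy (from the LOOCV per-sample
#' predictions, with 95% CIs) and AUC of the LOOCV scores (DeLong 95%
#' CI).
#'
#' @param result A `search_result` from [beam_search()].
#' @param ci_method CI method for the proportions, `"wilson"` (default)
#'   or `"clopper_pearson"`.
#' @return A data.frame with columns `n_mirnas`, `model`,
#'   `sensitivity`, `specificity`, `accuracy`, `auc` (formatted
#'   `"est (lo-hi)"` strings) plus numeric `*_est`, `*_lo`, `*_hi`
#'   columns for each metric.
#' @export
report_table <- function(result, ci_method = c("wilson",
                                               "clopper_pearson")) {
  stopifnot(inherits(result, "search_result"))
  ci_method <- match.arg(ci_method)
  rows <- lapply(names(result$per_size_best), function(s) {
    cand <- result$per_size_best[[s]]
    cv <- loocv_accuracy(result$X, result$y, cand$features,
                         result$lda_config)
    bm <- binary_metrics(cv$predictions, result$y,
                         ci_method = ci_method)
    au <- auc_ci(cv$scores, result$y)
    get <- function(metric) {
      r <- bm[bm$metric == metric, ]
      c(r$estimate, r$lower, r$upper)
    }
    se <- get("sensitivity"); sp <- get("specificity")
    ac <- get("accuracy")
    data.frame(
      n_mirnas = as.integer(s),
      model = format_model(cand$model),
      sensitivity = ci_str(se[1], se[2], se[3]),
      specificity = ci_str(sp[1], sp[2], sp[3]),
      accuracy = ci_str(ac[1], ac[2], ac[3]),
      auc = ci_str(au$auc, au$lower, au$upper),
      sensitivity_est = se[1], sensitivity_lo = se[2],
      sensitivity_hi = se[3],
      specificity_est = sp[1], specificity_lo = sp[2],
      specificity_hi = sp[3],
      accuracy_est = ac[1], accuracy_lo = ac[2], accuracy_hi = ac[3],
      auc_est = au$auc, auc_lo = au$lower, auc_hi = au$upper,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
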