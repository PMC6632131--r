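# Independent oracles used to cross-check the package implementations.
# These deliberately recompute every quantity with different code paths
# (explicit loops, brute-force enumeration) from the functions they test.

# two Gaussian classes, k features, class separation delta on each
make_gaussian <- function(n1 = 10, n0 = 10, k = 2, delta = 2,
                          seed = 1, sd = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n1 * k, mean = delta, sd = sd), n1, k),
    matrix(rnorm(n0 * k, mean = 0, sd = sd), n0, k)
  )
  colnames(X) <- paste0("m", seq_len(k))
  list(X = X, y = c(rep("case", n1), rep("control", n0)))
}

# Fisher direction by explicit per-sample outer products and qr.solve
oracle_lda <- function(X, y, ridge = 1e-8, empirical = FALSE) {
  case <- y == "case"
  m1 <- colMeans(X[case, , drop = FALSE])
  m0 <- colMeans(X[!case, , drop = FALSE])
  k <- ncol(X)
  Sw <- matrix(0, k, k)
  for (i in seq_len(nrow(X))) {
    mu <- if (case[i]) m1 else m0
    d <- X[i, ] - mu
    Sw <- Sw + outer(d, d)
  }
  Sw <- Sw + diag(ridge, k)
  w <- qr.solve(Sw, m1 - m0)
  b <- -sum(w * (m1 + m0)) / 2
  if (empirical) b <- b + log(sum(case) / sum(!case))
  list(w = as.numeric(w), b = b)
}

# naive per-fold LOOCV refit using the oracle fit
oracle_loocv <- function(X, y, ridge = 1e-8, empirical = FALSE) {
  n <- nrow(X)
  preds <- character(n)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    fit <- oracle_lda(X[-i, , drop = FALSE], y[-i], ridge, empirical)
    scores[i] <- sum(fit$w * X[i, ]) + fit$b
    preds[i] <- if (scores[i] > 0) "case" else "control"
  }
  list(accuracy = mean(preds == y), predictions = preds,
       scores = scores)
}

# all case-control pairs Mann-Whitney AUC
oracle_auc <- function(scores, y) {
  s1 <- scores[y == "case"]
  s0 <- scores[y == "control"]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s1) * length(s0))
}

# per-cell brute-force robust filter
oracle_robust_filter <- function(linear, groups, threshold = 64,
                                 fraction = 0.5,
                                 rule = "all_groups") {
  keep <- character(0)
  for (j in seq_len(ncol(linear))) {
    ok_per_group <- vapply(unique(groups), function(g) {
      rows <- which(groups == g)
      cnt <- 0
      for (i in rows) {
        v <- linear[i, j]
        if (!is.na(v) && v > threshold) cnt <- cnt + 1
      }
      cnt / length(rows) > fraction
    }, logical(1))
    ok <- if (rule == "all_groups") all(ok_per_group) else
      any(ok_per_group)
    if (ok) keep <- c(keep, colnames(linear)[j])
  }
  keep
}

# exhaustive best subset per size, same ranking rule as the search
oracle_exhaustive <- function(X, y, candidates, max_size,
                              lda_cfg = lda_config()) {
  best <- list()
  for (s in seq_len(max_size)) {
    combos <- utils::combn(candidates, s, simplify = FALSE)
    acc <- vapply(combos, function(fs) {
      loocv_accuracy(X, y, fs, lda_cfg)$accuracy
    }, numeric(1))
    aucv <- vapply(combos, function(fs) {
      fit <- fit_fisher_lda(X[, fs, drop = FALSE], y, lda_cfg)
      auc(score_samples(fit, X), y)
    }, numeric(1))
    key <- vapply(combos, function(fs) paste(sort(fs), collapse = "|"),
                  character(1))
    ord <- order(-acc, -aucv, key)
    best[[as.character(s)]] <- list(features = combos[[ord[1L]]],
                                    loocv_accuracy = acc[ord[1L]])
  }
  best
}

# separately coded classical greedy forward selection (beam width 1)
oracle_greedy <- function(X, y, candidates, max_size,
                          lda_cfg = lda_config()) {
  chosen <- character(0)
  out <- list()
  for (s in seq_len(max_size)) {
    remaining <- setdiff(candidates, chosen)
    if (length(remaining) == 0L) break
    cand_sets <- lapply(remaining, function(m) c(chosen, m))
    acc <- vapply(cand_sets, function(fs) {
      loocv_accuracy(X, y, fs, lda_cfg)$accuracy
    }, numeric(1))
    aucv <- vapply(cand_sets, function(fs) {
      fit <- fit_fisher_lda(X[, fs, drop = FALSE], y, lda_cfg)
      auc(score_samples(fit, X), y)
    }, numeric(1))
    key <- vapply(cand_sets, function(fs)
      paste(sort(fs), collapse = "|"), character(1))
    ord <- order(-acc, -aucv, key)
    chosen <- cand_sets[[ord[1L]]]
    out[[as.character(s)]] <- list(features = chosen,
                                   loocv_accuracy = acc[ord[1L]])
  }
  out
}

# small cohort settings used across tests to keep runtimes short
small_sim <- function(seed = 1, ...) {
  args <- list(n_case = 15, n_control = 15, n_mirna = 40,
               n_differential = 3, effect_size = 3, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  simulate_cohort(do.call(simulation_config, args))
}
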