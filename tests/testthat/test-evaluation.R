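test_that("ROC sweep hits the canonical corner cases", {
  y <- c("case", "case", "control", "control")
  r <- roc_points(c(3, 2, 1, 0), y)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_true(any(r$fpr == 0 & r$tpr == 1))     # passes the top-left
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))

  # all scores identical: a single diagonal step
  r2 <- roc_points(rep(1, 4), y)
  expect_equal(r2$fpr, c(0, 1))
  expect_equal(r2$tpr, c(0, 1))

  expect_error(roc_points(1:3, rep("case", 3)), "both classes")
})

test_that("a worked 6-sample ROC matches exhaustive confusion tables", {
  scores <- c(0.9, 0.7, 0.7, 0.4, 0.2, 0.1)
  y <- c("case", "control", "case", "case", "control", "control")
  r <- roc_points(scores, y)
  # hand enumeration at thresholds Inf, .9, .7, .4, .2, .1:
  # TP: 0,1,2,3,3,3  FP: 0,0,1,1,2,3  (ties at .7 move diagonally)
  expect_equal(r$tpr, c(0, 1, 2, 3, 3, 3) / 3)
  expect_equal(r$fpr, c(0, 0, 1, 1, 2, 3) / 3)
})

test_that("AUC equals the all-pairs Mann-Whitney count with half ties", {
  y <- c(rep("case", 4), rep("control", 6))
  s <- c(5, 4, 4, 1, 4, 3, 2, 2, 1, 0)          # deliberate ties
  expect_equal(auc(s, y), oracle_auc(s, y), tolerance = 1e-12)

  for (seed in 1:10) {
    set.seed(seed)
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    yy <- c(rep("case", n1), rep("control", n0))
    ss <- sample(0:5, n1 + n0, replace = TRUE) + rnorm(n1 + n0, 0, 0.1)
    expect_equal(auc(ss, yy), oracle_auc(ss, yy), tolerance = 1e-12)
  }

  expect_equal(auc(c(10, 9, 2, 1), c("case", "case", "control",
                                     "control")), 1.0)
  expect_equal(auc(rep(1, 8), rep(c("case", "control"), 4)), 0.5)
})

test_that("trapezoidal ROC area equals the rank AUC on tie-free data", {
  set.seed(31)
  y <- c(rep("case", 12), rep("control", 15))
  s <- rnorm(27)
  r <- roc_points(s, y)
  trap <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) +
                               utils::tail(r$tpr, -1)) / 2)
  expect_equal(trap, auc(s, y), tolerance = 1e-12)
})

test_that("DeLong interval agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(17)
  y <- c(rep("case", 30), rep("control", 40))
  s <- rnorm(70) + ifelse(y == "case", 1, 0)
  mine <- auc_ci(s, y)
  ref <- suppressMessages(
    pROC::ci.auc(pROC::roc(response = y, predictor = s,
                           levels = c("control", "case"),
                           direction = "<"), method = "delong"))
  expect_equal(mine$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(mine$lower, as.numeric(ref[1]), tolerance = 1e-9)
  expect_equal(mine$upper, as.numeric(ref[3]), tolerance = 1e-9)
})

test_that("proportion intervals match the reference implementations", {
  # Wilson: prop.test without continuity correction
  for (case in list(c(90, 100), c(96, 100), c(3, 10), c(50, 50))) {
    x <- case[1]; n <- case[2]
    mine <- ecindex:::wilson_interval(x, n)
    if (x < n) {
      ref <- stats::prop.test(x, n, correct = FALSE)$conf.int
      expect_equal(mine[1], ref[1], tolerance = 1e-10)
      expect_equal(mine[2], ref[2], tolerance = 1e-10)
    } else {
      expect_equal(mine[2], 1)
    }
    # Clopper-Pearson: binom.test
    cp <- ecindex:::clopper_pearson_interval(x, n)
    refb <- stats::binom.test(x, n)$conf.int
    expect_equal(cp[1], refb[1], tolerance = 1e-10)
    expect_equal(cp[2], refb[2], tolerance = 1e-10)
  }
})

test_that("binary metrics count the confusion table correctly", {
  y <- c(rep("case", 100), rep("control", 50))
  calls <- y
  calls[1:4] <- "control"              # 4 missed cases -> sens 0.96
  calls[101:102] <- "case"             # 2 false positives
  bm <- binary_metrics(calls, y)
  expect_equal(bm$estimate[bm$metric == "sensitivity"], 0.96)
  expect_equal(bm$estimate[bm$metric == "specificity"], 48 / 50)
  expect_equal(bm$estimate[bm$metric == "accuracy"], 144 / 150)
  expect_true(all(bm$lower <= bm$estimate & bm$estimate <= bm$upper))

  perfect <- binary_metrics(y, y)
  expect_true(all(perfect$estimate == 1))
  expect_true(all(perfect$upper == 1))
})

test_that("subgroups partition the cohort and pool back exactly", {
  sim <- small_sim(seed = 19, n_case = 40, n_control = 40,
                   effect_size = 2)
  meta <- sim$study$samples
  set.seed(19)
  scores <- rnorm(80) + ifelse(meta$group == "case", 2, 0)
  y <- meta$group

  rep <- subgroup_report(scores, y, meta)
  stages <- rep[rep$stratum_type == "stage", ]
  srcs <- rep[rep$stratum_type == "control_source", ]
  expect_equal(sum(stages$n), 40)
  expect_equal(sum(srcs$n), 40)

  # pooled stratum sensitivities reproduce the overall sensitivity
  overall_sens <- mean(scores[y == "case"] > 0)
  expect_equal(sum(stages$numerator) / sum(stages$n), overall_sens)
  overall_spec <- mean(scores[y == "control"] <= 0)
  expect_equal(sum(srcs$numerator) / sum(srcs$n), overall_spec)

  # a stratum where every case is called positive has sensitivity 1
  hi <- scores; hi[y == "case"] <- 10
  rep2 <- subgroup_report(hi, y, meta)
  expect_true(all(rep2[rep2$metric == "sensitivity", "estimate"] == 1))
})

test_that("stage-graded planted effects give stage-graded sensitivity", {
  cfg <- simulation_config(n_case = 150, n_control = 60, n_mirna = 30,
                           n_differential = 2, effect_size = 2.5,
                           effect_by_stage = c("0" = 0.1, "I" = 0.5,
                                               "II" = 1, "III" = 1.5,
                                               "IV" = 2),
                           stage_distribution = c("0" = 0.2, "I" = 0.2,
                                                  "II" = 0.2,
                                                  "III" = 0.2,
                                                  "IV" = 0.2),
                           seed = 23)
  sim <- simulate_cohort(cfg)
  bundle <- preprocess_study(sim$study)
  X <- feature_matrix(bundle$normalized,
                      sim$truth$differential_mirna_ids)
  fit <- fit_fisher_lda(X, bundle$samples$group)
  scores <- score_samples(fit, X)
  rep <- subgroup_report(scores, bundle$samples$group, bundle$samples,
                         strata = "stage")
  sens <- rep$estimate[match(c("0", "I", "IV"), rep$stratum)]
  # monotone planted effect: earliest stage weakest, latest strongest
  expect_lt(sens[1], sens[3])
  expect_lte(sens[1], sens[2])
})

test_that("evaluate_scores assembles a coherent report", {
  sim <- small_sim(seed = 29, n_case = 25, n_control = 25)
  meta <- sim$study$samples
  set.seed(29)
  scores <- rnorm(50) + ifelse(meta$group == "case", 3, 0)
  rep <- evaluate_scores(scores, meta$group, meta)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(rep$n_case, 25)
  expect_equal(rep$auc$auc, auc(scores, meta$group))
  expect_true(all(c("stage", "control_source") %in%
                    rep$per_stratum$stratum_type))
  expect_output(print(rep), "sensitivity")
})
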