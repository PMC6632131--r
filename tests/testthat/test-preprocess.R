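toy_study <- function(signal, background) {
  n <- nrow(signal)
  md <- data.frame(sample_id = rownames(signal),
                   group = rep(c("case", "control"), length.out = n))
  raw_expression_study(signal, background, md)
}

test_that("positive-call selection subtracts background and flags negatives", {
  sig <- matrix(c(100, 20, 30.5,
                  64, 30, 500), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("mA", "mB", "mC")))
  st <- toy_study(sig, c(30, 30))
  m <- positive_call_subtract(st)

  # cell-by-cell hand evaluation of the rule
  expect_equal(m$linear["s1", "mA"], 70)
  expect_true(is.na(m$linear["s1", "mB"]))     # 20 <= 30
  expect_equal(m$linear["s1", "mC"], 0.5)
  expect_equal(m$linear["s2", "mA"], 34)
  expect_true(is.na(m$linear["s2", "mB"]))     # equality is a negative call
  expect_equal(m$linear["s2", "mC"], 470)
  expect_identical(is.na(m$values), is.na(m$linear))
})

test_that("positive-call output is never negative (property)", {
  for (seed in 1:10) {
    set.seed(seed)
    sig <- matrix(rexp(60, 1 / 50), 6, 10,
                  dimnames = list(paste0("s", 1:6), paste0("m", 1:10)))
    st <- toy_study(sig, runif(6, 0, 80))
    m <- positive_call_subtract(st)
    expect_true(all(m$linear[!is.na(m$linear)] > 0))
  }
})

ctrl_ids <- c("miR-149-3p", "miR-2861", "miR-4463")

# a 3-array matrix whose internal-control means are exactly 200/400/800
control_mean_fixture <- function() {
  lin <- matrix(c(100, 200, 300,  50,
                  200, 400, 600, 500,
                  400, 800, 1200, 5000),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("a1", "a2", "a3"),
                                c(ctrl_ids, "mX")))
  normalized_matrix(lin)
}

test_that("internal-control normalization hits the reference exactly", {
  m <- control_mean_fixture()
  out <- normalize_internal_controls(m, normalization_config())
  R <- attr(out, "reference")
  expect_equal(R, mean(c(200, 400, 800)))        # 466.67 grand mean
  expect_equal(unname(attr(out, "scale_factors")),
               R / c(200, 400, 800))
  # after scaling every array's control mean equals R
  expect_equal(unname(rowMeans(out$linear[, ctrl_ids])), rep(R, 3))
  # non-control signals scale by the same per-array factor
  expect_equal(unname(out$linear[, "mX"]),
               c(50, 500, 5000) * R / c(200, 400, 800))
  expect_equal(out$values, log2(pmax(out$linear, 0.1)))
})

test_that("single-array grand-mean normalization is the identity", {
  lin <- matrix(c(100, 200, 300, 77), 1,
                dimnames = list("a1", c(ctrl_ids, "mX")))
  m <- normalized_matrix(lin)
  out <- normalize_internal_controls(m)
  expect_equal(out$linear, m$linear)
})

test_that("halving rule: control mean 1000 against reference 500", {
  lin <- matrix(c(900, 1000, 1100, 640), 1,
                dimnames = list("a1", c(ctrl_ids, "mX")))
  cfg <- normalization_config(reference_level = "fixed_value",
                              fixed_reference = 500)
  out <- normalize_internal_controls(normalized_matrix(lin), cfg)
  expect_equal(unname(out$linear[1, ]), c(900, 1000, 1100, 640) / 2)
})

test_that("normalization errors are specific", {
  lin <- matrix(c(100, 200), 1,
                dimnames = list("a1", c("miR-149-3p", "mX")))
  expect_error(normalize_internal_controls(normalized_matrix(lin)),
               "absent from the matrix")
  lin2 <- matrix(c(NA, NA, NA, 100,
                   100, 200, 300, 100), 2, byrow = TRUE,
                 dimnames = list(c("a1", "a2"), c(ctrl_ids, "mX")))
  expect_error(normalize_internal_controls(normalized_matrix(lin2)),
               "negative calls on array")
  expect_error(normalization_config(reference_level = "fixed_value"),
               "fixed_reference")
})

test_that("fixed-reference normalization cancels per-array rescaling", {
  sim <- small_sim(seed = 11)
  st <- sim$study
  cfg <- normalization_config(reference_level = "fixed_value",
                              fixed_reference = 2000)
  base <- normalize_internal_controls(positive_call_subtract(st), cfg)

  for (k in c(0.25, 3, 17)) {
    st2 <- st
    st2$signal[4, ] <- st2$signal[4, ] * k
    st2$background[4] <- st2$background[4] * k
    out <- normalize_internal_controls(positive_call_subtract(st2), cfg)
    expect_equal(out$linear, base$linear, tolerance = 1e-10)
    expect_equal(out$values, base$values, tolerance = 1e-10)
  }
})

test_that("robust filter applies strict thresholds per group", {
  groups <- c("case", "case", "control", "control")
  lin <- cbind(
    allhigh = c(100, 100, 100, 100),
    half = c(100, 10, 100, 100),     # exactly 50% of cases exceed
    onegroup = c(100, 100, 10, 10),
    missing = c(NA, NA, 100, 100)
  )
  rownames(lin) <- paste0("s", 1:4)
  m <- normalized_matrix(lin)
  cfg <- robust_filter_config()
  expect_identical(robust_filter(m, groups, cfg), "allhigh")
  # exactly-at-threshold signals do not count as exceeding
  lin2 <- lin; lin2[, "allhigh"] <- 64
  expect_identical(robust_filter(normalized_matrix(lin2), groups, cfg),
                   character(0))
  # the weaker any-group reading keeps group-specific miRNAs
  # ("half" qualifies through the control group, where all samples pass)
  any_cfg <- robust_filter_config(group_rule = "any_group")
  expect_identical(robust_filter(m, groups, any_cfg),
                   c("allhigh", "half", "onegroup", "missing"))
  expect_error(robust_filter(m, rep("case", 4), cfg), "at least 2 groups")
})

test_that("robust filter equals the brute-force per-cell oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 12
    lin <- matrix(2^runif(n * 20, 0, 12), n, 20,
                  dimnames = list(paste0("s", 1:n), paste0("m", 1:20)))
    lin[sample(length(lin), 25)] <- NA
    groups <- rep(c("case", "control"), each = n / 2)
    m <- normalized_matrix(lin)
    expect_identical(
      robust_filter(m, groups, robust_filter_config()),
      oracle_robust_filter(lin, groups)
    )
  }
})

test_that("robust filter is monotone in threshold and fraction", {
  set.seed(5)
  lin <- matrix(2^runif(300, 0, 12), 10, 30,
                dimnames = list(paste0("s", 1:10), paste0("m", 1:30)))
  m <- normalized_matrix(lin)
  groups <- rep(c("case", "control"), each = 5)
  prev <- NULL
  for (thr in c(4, 16, 64, 256)) {
    sel <- robust_filter(m, groups, robust_filter_config(thr, 0.5))
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
  prev <- NULL
  for (fr in c(0.2, 0.5, 0.8)) {
    sel <- robust_filter(m, groups, robust_filter_config(64, fr))
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
})

test_that("feature matrix imputes negative calls at the pseudo-floor", {
  lin <- matrix(c(100, NA, 200, 400), 2,
                dimnames = list(c("s1", "s2"), c("mA", "mB")))
  m <- normalized_matrix(lin)
  X <- feature_matrix(m, pseudo_floor = 0.1)
  expect_equal(X["s2", "mA"], log2(0.1))
  expect_equal(X["s1", "mA"], log2(100))
  expect_error(feature_matrix(m, "mZ"), "absent")
})
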