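# run code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic cohort simulation configuration
#'
#' Defines a case-control serum miRNA microarray cohort with the
#' statistical structure the pipeline assumes: log-normal fluorescence
#' signals with Gaussian log2-scale biological noise, a per-array
#' multiplicative scaling artifact, three near-constant internal
#' control miRNAs, a planted set of differentially expressed miRNAs
#' (alternating up/down in cases, optionally stage-modulated), additive
#' array background, and occasional sub-detection dropouts.
#'
#' @param n_case,n_control Samples per group (default 100 each).
#' @param n_mirna Total miRNAs on the array, including the three
#'   internal controls (default 500).
#' @param n_differential Number of planted differential miRNAs
#'   (default 6).
#' @param effect_size Log2-scale mean shift of planted miRNAs in cases
#'   (default 4); signs alternate across the planted set.
#' @param baseline_log2_mean_range Range of the per-miRNA baseline
#'   log2 means (default `c(6, 14)`). Planted miRNAs draw their
#'   baselines from the upper detectable band of this range so that
#'   they remain positive calls above the robust-filter threshold in
#'   both groups, mirroring the fact that index candidates are by
#'   construction robustly detected miRNAs.
#' @param biological_sd Per-cell log2 noise SD (default 1).
#' @param array_scale_sd SD of the per-array log-normal scale factor
#'   `exp(N(0, array_scale_sd))` (default 0.25).
#' @param background_mean,background_sd Per-array additive background
#'   level, linear scale (defaults 30 and 5).
#' @param internal_control_log2_levels Fixed log2 levels of the three
#'   internal controls (default `c(10, 11, 12)`).
#' @param internal_control_sd Log2 noise SD of the internal controls
#'   (default 0.05).
#' @param detection_dropout Probability that a probe's signal falls
#'   below the array background and becomes a negative call
#'   (default 0.02).
#' @param stage_distribution Named weights over stages
#'   `0, I, II, III, IV` for the case group; the default follows the
#'   stage mix of a surgical esophageal-cancer cohort dominated by
#'   stage I disease.
#' @param effect_by_stage Named multipliers applied to `effect_size`
#'   per stage, emulating weaker circulating signal in earlier-stage
#'   disease (default `c(0.6, 0.8, 1, 1, 1.2)`). Set to `NULL` for a
#'   stage-independent effect.
#' @param seed Integer seed governing all draws through one RNG stream.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_case = 100, n_control = 100,
                              n_mirna = 500, n_differential = 6,
                              effect_size = 4,
                              baseline_log2_mean_range = c(6, 14),
                              biological_sd = 1,
                              array_scale_sd = 0.25,
                              background_mean = 30,
                              background_sd = 5,
                              internal_control_log2_levels = c(10, 11, 12),
                              internal_control_sd = 0.05,
                              detection_dropout = 0.02,
                              stage_distribution = c("0" = 0.081,
                                                     "I" = 0.491,
                                                     "II" = 0.184,
                                                     "III" = 0.208,
                                                     "IV" = 0.035),
                              effect_by_stage = c("0" = 0.6, "I" = 0.8,
                                                  "II" = 1, "III" = 1,
                                                  "IV" = 1.2),
                              seed = 1) {
  cfg <- list(n_case = as.integer(n_case),
              n_control = as.integer(n_control),
              n_mirna = as.integer(n_mirna),
              n_differential = as.integer(n_differential),
              effect_size = effect_size,
              baseline_log2_mean_range = baseline_log2_mean_range,
              biological_sd = biological_sd,
              array_scale_sd = array_scale_sd,
              background_mean = background_mean,
              background_sd = background_sd,
              internal_control_log2_levels = internal_control_log2_levels,
              internal_control_sd = internal_control_sd,
              detection_dropout = detection_dropout,
              stage_distribution = stage_distribution,
              effect_by_stage = effect_by_stage,
              seed = as.integer(seed))
  n_controls_probes <- 3L
  if (cfg$n_mirna < cfg$n_differential + n_controls_probes) {
    stop("n_mirna must be at least n_differential + 3 (internal ",
         "controls)", call. = FALSE)
  }
  if (cfg$n_differential < 0L) {
    stop("n_differential must be >= 0", call. = FALSE)
  }
  sds <- c(biological_sd = biological_sd,
           array_scale_sd = array_scale_sd,
           background_sd = background_sd,
           internal_control_sd = internal_control_sd)
  if (any(sds <= 0)) {
    stop("all SDs must be > 0: ",
         paste(names(sds)[sds <= 0], collapse = ", "), call. = FALSE)
  }
  if (detection_dropout < 0 || detection_dropout >= 1) {
    stop("detection_dropout must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(stage_distribution)) {
    if (!all(names(stage_distribution) %in% STAGE_LEVELS) ||
        any(stage_distribution < 0) || sum(stage_distribution) <= 0) {
      stop("stage_distribution must be nonnegative weights over ",
           paste(STAGE_LEVELS, collapse = ", "), call. = FALSE)
    }
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a case-control serum miRNA cohort
#'
#' Draws a [raw_expression_study()] under the generative model of
#' [simulation_config()]: per miRNA m and sample i,
#' `log2 signal = baseline_m + effect_m * stage_multiplier_i * I(case)
#' + N(0, biological_sd)`; the linear signal is multiplied by the
#' array's scale factor `exp(N(0, array_scale_sd))`; internal controls
#' sit at their fixed log2 levels (before the array factor) with small
#' noise; the per-array background is drawn on the linear scale; a
#' `detection_dropout` fraction of probes is pushed below background
#' (negative calls). All draws flow through one RNG stream seeded by
#' `cfg$seed`, so equal seeds give identical cohorts.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `study` (the [raw_expression_study()]) and
#'   `truth` (class `simulation_truth`): `differential_mirna_ids`,
#'   signed `effects`, per-array `scale_factors`, per-sample `stage`,
#'   planted `baselines`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    ic_ids <- c("miR-149-3p", "miR-2861", "miR-4463")
    n_free <- cfg$n_mirna - length(ic_ids)
    free_ids <- sprintf("miR-sim-%04d", seq_len(n_free))
    mirna_ids <- c(ic_ids, free_ids)

    n <- cfg$n_case + cfg$n_control
    is_case <- c(rep(TRUE, cfg$n_case), rep(FALSE, cfg$n_control))
    sample_ids <- c(sprintf("case-%03d", seq_len(cfg$n_case)),
                    sprintf("ctrl-%03d", seq_len(cfg$n_control)))

    rng <- cfg$baseline_log2_mean_range
    baselines <- stats::setNames(
      stats::runif(n_free, rng[1L], rng[2L]), free_ids)

    diff_ids <- character(0)
    effects <- stats::setNames(numeric(n_free), free_ids)
    if (cfg$n_differential > 0L) {
      diff_ids <- sample(free_ids, cfg$n_differential)
      # planted markers live in the robustly detected high band
      hi <- c(rng[2L] - 2, rng[2L] - 0.5)
      baselines[diff_ids] <- stats::runif(cfg$n_differential,
                                          hi[1L], hi[2L])
      signs <- rep_len(c(1, -1), cfg$n_differential)
      effects[diff_ids] <- signs * cfg$effect_size
    }

    stage <- rep(NA_character_, n)
    mult <- rep(0, n)
    if (!is.null(cfg$stage_distribution)) {
      probs <- cfg$stage_distribution / sum(cfg$stage_distribution)
      stage[is_case] <- sample(names(probs), cfg$n_case, replace = TRUE,
                               prob = probs)
    } else {
      stage[is_case] <- "II"
    }
    if (!is.null(cfg$effect_by_stage)) {
      mult[is_case] <- cfg$effect_by_stage[stage[is_case]]
    } else {
      mult[is_case] <- 1
    }

    log2sig <- matrix(stats::rnorm(n * n_free,
                                   mean = rep(baselines, each = n),
                                   sd = cfg$biological_sd),
                      nrow = n, ncol = n_free,
                      dimnames = list(sample_ids, free_ids))
    if (cfg$n_differential > 0L) {
      for (m in diff_ids) {
        log2sig[, m] <- log2sig[, m] + effects[m] * mult
      }
    }
    ic <- matrix(stats::rnorm(n * 3L,
                              mean = rep(cfg$internal_control_log2_levels,
                                         each = n),
                              sd = cfg$internal_control_sd),
                 nrow = n, ncol = 3L,
                 dimnames = list(sample_ids, ic_ids))
    linear <- 2^cbind(ic, log2sig)[, mirna_ids, drop = FALSE]

    scale_factors <- exp(stats::rnorm(n, 0, cfg$array_scale_sd))
    linear <- linear * scale_factors
    background <- pmax(stats::rnorm(n, cfg$background_mean,
                                    cfg$background_sd), 1)

    if (cfg$detection_dropout > 0) {
      # sub-detection events concentrate near the detection limit:
      # only weakly detected probes (linear signal < 4x the robust
      # threshold of 64) can fall below background
      free_cols <- match(free_ids, mirna_ids)
      weak <- linear[, free_cols, drop = FALSE] < 256
      drop_mask <- weak & matrix(stats::runif(n * n_free) <
                                   cfg$detection_dropout, n, n_free)
      sub <- matrix(stats::runif(n * n_free) * background, n, n_free)
      linear[, free_cols][drop_mask] <- sub[drop_mask]
    }

    source_pool <- sample(CONTROL_SOURCE_LEVELS, cfg$n_control,
                          replace = TRUE, prob = c(0.57, 0.22, 0.21))
    samples <- data.frame(
      sample_id = sample_ids,
      group = ifelse(is_case, "case", "control"),
      control_source = ifelse(is_case, NA_character_, source_pool),
      stage = stage,
      age = round(ifelse(is_case, stats::rnorm(n, 66, 8),
                         stats::rnorm(n, 60, 12))),
      sex = ifelse(stats::runif(n) < ifelse(is_case, 0.83, 0.44),
                   "male", "female"),
      stringsAsFactors = FALSE
    )
    study <- raw_expression_study(linear, background, samples)
    truth <- structure(
      list(differential_mirna_ids = diff_ids,
           effects = effects[diff_ids],
           scale_factors = stats::setNames(scale_factors, sample_ids),
           stage = stats::setNames(stage, sample_ids),
           baselines = baselines),
      class = "simulation_truth")
    list(study = study, truth = truth)
  })
}

#' Write a simulated cohort as on-disk fixtures
#'
#' Emits the wide TSV expression table, the sidecar metadata TSV
#' (including backgrounds), and a `truth.json` listing the planted
#' differential miRNAs and their effects. The written pair round-trips
#' through [read_expression_table()].
#'
#' @param study A [raw_expression_study()].
#' @param truth The matching `simulation_truth`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (`expr.tsv`, `meta.tsv`,
#'   `truth.json`).
#' @export
write_fixture <- function(study, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr_path <- file.path(dir, "expr.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  truth_path <- file.path(dir, "truth.json")
  write_expression_table(study, expr_path, meta_path)
  jsonlite::write_json(
    list(differential_mirna_ids = truth$differential_mirna_ids,
         effects = as.list(truth$effects),
         scale_factors = as.list(truth$scale_factors)),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(expr_path, meta_path, truth_path))
}
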