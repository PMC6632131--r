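test_that("metadata invariants are enforced", {
  md <- data.frame(sample_id = c("a", "b"), group = c("case", "control"))
  expect_silent(validate_sample_meta(md))

  expect_error(validate_sample_meta(
    data.frame(sample_id = c("a", "a"), group = c("case", "case"))),
    "duplicate sample_id")
  expect_error(validate_sample_meta(
    data.frame(sample_id = "a", group = "tumour")), "unknown group")
  expect_error(validate_sample_meta(
    data.frame(sample_id = "a", group = "case",
               control_source = "noncancer1")),
    "control_source set for case")
  expect_error(validate_sample_meta(
    data.frame(sample_id = "a", group = "control", stage = "II")),
    "stage set for control")
})

test_that("raw study construction validates signals and alignment", {
  md <- data.frame(sample_id = c("s1", "s2"),
                   group = c("case", "control"))
  sig <- matrix(c(1, 2, 3, 4), 2, 2,
                dimnames = list(c("s1", "s2"), c("mA", "mB")))
  st <- raw_expression_study(sig, c(1, 1), md)
  expect_s3_class(st, "raw_expression_study")
  expect_identical(st$mirna_ids, c("mA", "mB"))

  expect_error(raw_expression_study(sig * -1, c(1, 1), md), "negative")
  sig_dup <- sig; colnames(sig_dup) <- c("mA", "mA")
  expect_error(raw_expression_study(sig_dup, c(1, 1), md),
               "duplicate miRNA")
  expect_error(raw_expression_study(sig, c(1, NA), md), "finite")
  expect_error(raw_expression_study(sig, 1, md), "one value per sample")
})

test_that("the shipped 3-sample example fixture parses as documented", {
  expr <- system.file("extdata", "example_expr.tsv", package = "ecindex")
  meta <- system.file("extdata", "example_meta.tsv", package = "ecindex")
  st <- read_expression_table(expr, meta = meta)
  expect_equal(dim(st$signal), c(3L, 4L))
  expect_identical(st$sample_ids, c("S1", "S2", "S3"))
  expect_equal(st$signal["S2", "miR-sim-0001"], 260)
  expect_equal(st$background, c(30, 28, 32))
  expect_identical(st$samples$stage, c("I", "III", NA))

  # S3's miR-sim-0001 signal (25) sits below its background (32)
  m <- positive_call_subtract(st)
  expect_true(is.na(m$linear["S3", "miR-sim-0001"]))
  expect_equal(m$linear["S1", "miR-sim-0001"], 90)
})

test_that("wide TSV fixtures round-trip losslessly", {
  sim <- small_sim(seed = 7)
  dir <- withr::local_tempdir()
  write_fixture(sim$study, sim$truth, dir)

  back <- read_expression_table(file.path(dir, "expr.tsv"),
                                meta = file.path(dir, "meta.tsv"))
  expect_equal(back$signal, sim$study$signal, tolerance = 1e-12)
  expect_identical(back$sample_ids, sim$study$sample_ids)
  expect_identical(back$mirna_ids, sim$study$mirna_ids)
  expect_identical(back$samples$group, sim$study$samples$group)
  expect_identical(back$samples$stage, sim$study$samples$stage)
  expect_equal(back$background, sim$study$background, tolerance = 1e-12)

  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_length(truth$differential_mirna_ids, 3L)
})

test_that("reader aligns shuffled metadata and rejects malformed tables", {
  sim <- small_sim(seed = 8)
  dir <- withr::local_tempdir()
  write_fixture(sim$study, sim$truth, dir)

  # shuffle the metadata rows; sample order must follow the matrix
  md <- read.table(file.path(dir, "meta.tsv"), header = TRUE, sep = "\t",
                   na.strings = c("NA", ""))
  md <- md[rev(seq_len(nrow(md))), ]
  write.table(md, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  back <- read_expression_table(file.path(dir, "expr.tsv"),
                                meta = file.path(dir, "meta.tsv"))
  expect_identical(back$sample_ids, sim$study$sample_ids)
  expect_equal(back$signal, sim$study$signal, tolerance = 1e-12)

  # duplicated miRNA row
  expr <- readLines(file.path(dir, "expr.tsv"))
  writeLines(c(expr, expr[2L]), file.path(dir, "expr.tsv"))
  expect_error(read_expression_table(file.path(dir, "expr.tsv"),
                                     meta = file.path(dir, "meta.tsv")),
               "duplicate miRNA row")

  # non-numeric signal cell
  expr[3L] <- sub("\t[0-9.]+$", "\tnot_a_number", expr[3L])
  writeLines(expr[1:10], file.path(dir, "expr2.tsv"))
  expect_error(read_expression_table(file.path(dir, "expr2.tsv"),
                                     meta = file.path(dir, "meta.tsv")),
               "non-numeric signal")

  # missing background column
  md$background <- NULL
  write.table(md, file.path(dir, "meta3.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  dir2 <- withr::local_tempdir()
  write_fixture(sim$study, sim$truth, dir2)
  expect_error(read_expression_table(file.path(dir2, "expr.tsv"),
                                     meta = file.path(dir, "meta3.tsv")),
               "background missing")
})

test_that("GEO series-matrix text maps samples and metadata", {
  sim <- small_sim(seed = 9, n_case = 3, n_control = 3, n_mirna = 8,
                   n_differential = 1)
  st <- sim$study
  n <- length(st$sample_ids)
  quoted <- function(x) paste0('"', x, '"')
  grp <- ifelse(st$samples$group == "case",
                "diagnosis: ESCC", "diagnosis: non-cancer control")
  lines <- c(
    "!Series_title\t\"synthetic serum miRNA cohort\"",
    paste(c("!Sample_geo_accession",
            quoted(st$sample_ids)), collapse = "\t"),
    paste(c("!Sample_characteristics_ch1", quoted(grp)),
          collapse = "\t"),
    paste(c("!Sample_characteristics_ch1",
            quoted(paste0("sex: ", st$samples$sex))), collapse = "\t"),
    "!series_matrix_table_begin",
    paste(c("ID_REF", quoted(st$sample_ids)), collapse = "\t"),
    vapply(seq_along(st$mirna_ids), function(j) {
      paste(c(quoted(st$mirna_ids[j]),
              format(st$signal[, j], digits = 10)), collapse = "\t")
    }, character(1)),
    "!series_matrix_table_end"
  )
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines, path)

  geo <- read_expression_table(path, format = "geo_series_matrix")
  expect_identical(geo$sample_ids, st$sample_ids)
  expect_identical(geo$samples$group, st$samples$group)
  expect_identical(geo$samples$sex, st$samples$sex)
  expect_equal(unname(geo$signal), unname(st$signal), tolerance = 1e-6)
  # no background in the headers -> treated as background-handled
  expect_identical(geo$background, rep(0, n))
})

test_that("model JSON round-trips bit-exactly and rejects bad files", {
  path <- withr::local_tempfile(fileext = ".json")

  m <- ec_index_model()
  write_model(m, path)
  expect_identical(read_model(path), m)

  # the largest published candidate model (8 miRNAs) round-trips too
  m8 <- discriminant_model(
    c("miR-8073", "miR-6794-5p", "miR-3196", "miR-6820-5p",
      "miR-744-5p", "miR-4433a-3p", "miR-4734", "miR-7641"),
    c(1.02319, -1.08749, 1.63503, -1.02075, 0.559982, 0.613777,
      -0.277379, 0.0347834),
    -17.08907)
  write_model(m8, path)
  expect_identical(read_model(path), m8)

  # awkward floats survive exactly
  set.seed(3)
  mr <- discriminant_model(letters[1:4], rnorm(4) / 3, pi / 7)
  write_model(mr, path)
  expect_identical(read_model(path), mr)

  expect_error(discriminant_model(character(0), numeric(0), 0),
               "at least one miRNA")
  jsonlite::write_json(list(format = "something-else", version = 1),
                       path, auto_unbox = TRUE)
  expect_error(read_model(path), "format")
  jsonlite::write_json(list(format = "ecindex-model", version = 99,
                            mirna_ids = "a", coefficients = "1",
                            intercept = "0", decision_threshold = "0"),
                       path, auto_unbox = TRUE)
  expect_error(read_model(path), "version")
})
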