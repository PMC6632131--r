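MODEL_FORMAT <- "ecindex-model"
MODEL_VERSION <- 1L

# 17 significant digits round-trip IEEE doubles exactly through text
num_to_chr <- function(x) formatC(x, digits = 17, format = "g")

#' Read an expression table into a raw expression study
#'
#' Two on-disk dialects are supported. `wide_tsv` is the repository
#' convention for scanner exports: a tab-separated table whose first
#' column holds miRNA IDs and whose remaining columns hold one sample
#' each; empty cells are missing. Sample metadata (including the
#' per-array `background` column) comes from a sidecar TSV.
#' `geo_series_matrix` is a best-effort reader for GEO series-matrix
#' text (`!Sample_*` header lines plus the `!series_matrix_table_begin`
#' block); a sidecar metadata file, when given, overrides fields parsed
#' from the headers.
#'
#' @param path Path to the expression table.
#' @param format `"wide_tsv"` (default) or `"geo_series_matrix"`.
#' @param meta Path to the sidecar metadata TSV with columns
#'   `sample_id`, `group`, and optionally `control_source`, `stage`,
#'   `age`, `sex`, `background`. Required for `wide_tsv`.
#' @return A [raw_expression_study()].
#' @export
read_expression_table <- function(path,
                                  format = c("wide_tsv",
                                             "geo_series_matrix"),
                                  meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         wide_tsv = read_wide_tsv(path, meta),
         geo_series_matrix = read_geo_series_matrix(path, meta))
}

read_meta_tsv <- function(meta) {
  if (is.null(meta)) {
    stop("wide_tsv input requires a sidecar metadata file (meta=)",
         call. = FALSE)
  }
  if (!file.exists(meta)) stop("file not found: ", meta, call. = FALSE)
  md <- utils::read.table(meta, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  md
}

read_wide_tsv <- function(path, meta) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) {
    stop("expression table must have an ID column plus >=1 sample column",
         call. = FALSE)
  }
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate miRNA row ID(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  sig <- tab[, -1L, drop = FALSE]
  for (j in seq_along(sig)) {
    col <- sig[[j]]
    if (!is.numeric(col)) {
      bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
      stop("non-numeric signal in column '", names(sig)[j], "'",
           if (length(bad) > 0L)
             paste0(", row '", ids[bad[1L]], "'"),
           call. = FALSE)
    }
  }
  signal <- t(as.matrix(sig))          # samples x miRNAs
  colnames(signal) <- ids
  md <- read_meta_tsv(meta)
  if (is.null(md$sample_id)) {
    stop("metadata file lacks a sample_id column", call. = FALSE)
  }
  md$sample_id <- as.character(md$sample_id)
  missing_samples <- setdiff(rownames(signal), md$sample_id)
  if (length(missing_samples) > 0L) {
    stop("metadata missing for sample(s): ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  md <- md[match(rownames(signal), md$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  if (is.null(md$background) || any(is.na(md$background))) {
    bad <- if (is.null(md$background)) md$sample_id else
      md$sample_id[is.na(md$background)]
    stop("background missing for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  background <- as.numeric(md$background)
  md$background <- NULL
  raw_expression_study(signal, background, md)
}

parse_geo_characteristics <- function(char_lines) {
  # each line: one field per sample, entries like "key: value"
  out <- list()
  for (ln in char_lines) {
    entries <- ln
    keys <- tolower(sub(":.*$", "", entries))
    vals <- trimws(sub("^[^:]*:", "", entries))
    key <- names(sort(table(keys), decreasing = TRUE))[1L]
    out[[key]] <- vals
  }
  out
}

read_geo_series_matrix <- function(path, meta) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop("no series-matrix table block found in ", path, call. = FALSE)
  }
  tab_lines <- lines[(begin + 1L):(end - 1L)]
  tab <- utils::read.table(text = tab_lines, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "", "null"), quote = "\"")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate probe ID(s) in series matrix", call. = FALSE)
  }
  signal <- t(as.matrix(tab[, -1L, drop = FALSE]))
  colnames(signal) <- ids

  header <- lines[seq_len(begin - 1L)]
  get_fields <- function(tag) {
    hits <- grep(paste0("^!", tag, "\t"), header, value = TRUE)
    lapply(hits, function(h) {
      gsub("^\"|\"$", "", strsplit(h, "\t")[[1L]][-1L])
    })
  }
  geo_acc <- get_fields("Sample_geo_accession")
  if (length(geo_acc) > 0L) rownames(signal) <- geo_acc[[1L]]
  chars <- parse_geo_characteristics(get_fields("Sample_characteristics_ch1"))

  n <- nrow(signal)
  md <- data.frame(sample_id = rownames(signal),
                   stringsAsFactors = FALSE)
  grp_key <- intersect(c("group", "disease state", "disease", "diagnosis"),
                       names(chars))
  if (length(grp_key) > 0L) {
    raw_grp <- tolower(chars[[grp_key[1L]]])
    md$group <- ifelse(grepl("control|non-?cancer|healthy|benign", raw_grp),
                       "control",
                       ifelse(grepl("escc|cancer|carcinoma|case|tumou?r",
                                    raw_grp), "case", NA))
  }
  if ("stage" %in% names(chars)) md$stage <- chars[["stage"]]
  if ("age" %in% names(chars)) {
    md$age <- suppressWarnings(as.numeric(chars[["age"]]))
  }
  if ("sex" %in% names(chars)) {
    s <- tolower(chars[["sex"]])
    md$sex <- ifelse(grepl("^f", s), "female",
                     ifelse(grepl("^m", s), "male", NA))
  }
  if ("background" %in% names(chars)) {
    md$background <- suppressWarnings(as.numeric(chars[["background"]]))
  }
  if (!is.null(meta)) {
    side <- read_meta_tsv(meta)
    side$sample_id <- as.character(side$sample_id)
    idx <- match(md$sample_id, side$sample_id)
    if (any(is.na(idx))) {
      stop("sidecar metadata missing for sample(s): ",
           paste(md$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    for (col in setdiff(names(side), "sample_id")) {
      md[[col]] <- side[[col]][idx]
    }
  }
  if (is.null(md$group) || any(is.na(md$group))) {
    stop("case/control labels could not be determined from the GEO ",
         "headers; supply a sidecar metadata file", call. = FALSE)
  }
  if (is.null(md$background)) {
    # series matrices rarely carry the raw array background; treat the
    # table as already background-handled
    md$background <- 0
  }
  background <- as.numeric(md$background)
  md$background <- NULL
  raw_expression_study(signal, background, md)
}

#' Write a raw expression study as the wide TSV dialect
#'
#' Emits the expression matrix (miRNA rows, sample columns) and the
#' sidecar metadata TSV (including the `background` column) that
#' [read_expression_table()] consumes.
#'
#' @param study A [raw_expression_study()].
#' @param expr_path,meta_path Output file paths.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_expression_table <- function(study, expr_path, meta_path) {
  stopifnot(inherits(study, "raw_expression_study"))
  tab <- data.frame(mirna_id = study$mirna_ids,
                    t(study$signal), check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab) <- c("mirna_id", study$sample_ids)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  md <- study$samples
  md$background <- study$background
  keep <- c("sample_id", "group", "control_source", "stage", "age", "sex",
            "background")
  md <- md[, c(keep, setdiff(names(md), keep)), drop = FALSE]
  utils::write.table(md, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(expr_path, meta_path))
}

#' Save a discriminant model as versioned JSON
#'
#' Coefficients are serialized at 17 significant digits so that
#' `read_model(write_model(m))` reproduces the model bit-exactly.
#'
#' @param model A [discriminant_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "discriminant_model"))
  if (length(model$mirna_ids) == 0L) {
    stop("refusing to write a model with no miRNAs", call. = FALSE)
  }
  obj <- list(
    format = MODEL_FORMAT,
    version = MODEL_VERSION,
    mirna_ids = model$mirna_ids,
    coefficients = num_to_chr(model$coefficients),
    intercept = num_to_chr(model$intercept),
    decision_threshold = num_to_chr(model$decision_threshold)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()` returns the [discriminant_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, MODEL_FORMAT)) {
    stop("not a discriminant model file (format field is ",
         deparse(obj$format), ")", call. = FALSE)
  }
  if (!identical(as.integer(obj$version), MODEL_VERSION)) {
    stop("unsupported model file version: ", obj$version, call. = FALSE)
  }
  required <- c("mirna_ids", "coefficients", "intercept",
                "decision_threshold")
  missing_f <- setdiff(required, names(obj))
  if (length(missing_f) > 0L) {
    stop("model file missing field(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  discriminant_model(
    mirna_ids = obj$mirna_ids,
    coefficients = as.numeric(obj$coefficients),
    intercept = as.numeric(obj$intercept),
    decision_threshold = as.numeric(obj$decision_threshold)
  )
}
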