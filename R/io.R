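#' Read a labelled numeric matrix from CSV
#'
#' Reads a UTF-8 CSV whose first column holds row labels and whose header
#' row holds column labels, validating shape and labels when expectations
#' are supplied. Any cell that fails numeric coercion is reported with its
#' row and column.
#'
#' @param path Path to the CSV file.
#' @param expected_rows,expected_cols Optional character vectors of required
#'   labels (order-insensitive).
#' @return A numeric matrix with dimnames.
#' @export
load_matrix_csv <- function(path, expected_rows = NULL, expected_cols = NULL) {
  if (!file.exists(path)) {
    nim_stop("nimcdm_config_error", sprintf("input file not found: %s", path))
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (ncol(df) < 2L) {
    nim_stop("nimcdm_schema_error",
             sprintf("%s: need a label column plus at least one data column", path))
  }
  labels <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(labels, colnames(body)))
  for (j in seq_len(ncol(body))) {
    col <- body[[j]]
    val <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & col != "" & is.na(val))
    if (length(bad)) {
      nim_stop("nimcdm_schema_error",
               sprintf("%s: non-numeric cell at row '%s', column '%s'",
                       path, labels[bad[1L]], colnames(body)[j]))
    }
    m[, j] <- val
  }
  if (!is.null(expected_cols) && !setequal(colnames(m), expected_cols)) {
    nim_stop("nimcdm_schema_error",
             sprintf("%s: column labels %s do not match the expected %s", path,
                     paste(colnames(m), collapse = ","),
                     paste(expected_cols, collapse = ",")))
  }
  if (!is.null(expected_rows) && !setequal(rownames(m), expected_rows)) {
    nim_stop("nimcdm_schema_error",
             sprintf("%s: row labels do not match the expected set", path))
  }
  m
}

#' Write a labelled numeric matrix to CSV
#'
#' Inverse of [load_matrix_csv()]: row labels in the first column (named
#' `id`), `NA` cells written as empty fields, '.' decimal separator.
#'
#' @param m Numeric matrix (dimnames used as labels; defaults generated).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  if (is.null(rownames(m))) rownames(m) <- paste0("R", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("C", seq_len(ncol(m)))
  df <- data.frame(id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a set of expert matrices to numbered CSV files
#'
#' @param surveys List of matrices (e.g. [gen_influence_survey()] or
#'   [gen_performance_scores()] output).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; files are `<prefix>_001.csv`, ...
#' @return The file paths, invisibly.
#' @export
write_survey_csv <- function(surveys, dir, prefix = "expert") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(surveys), function(h) {
    p <- file.path(dir, sprintf("%s_%03d.csv", prefix, h))
    write_matrix_csv(surveys[[h]], p)
    p
  }, character(1))
  invisible(paths)
}

extdata <- function(file) {
  system.file("extdata", file, package = "nimcdm", mustWork = TRUE)
}

#' Bundled three-hospital case study: published evaluation data
#'
#' The package ships the published evaluation data for three tertiary
#' hospitals in China's Pearl River Delta (labelled SYUH, GZMH, ZCWH),
#' assessed against an eight-criterion, two-dimension framework for
#' curbing nosocomial-infection risk: dimension D1 "guiding favorable
#' behavior" (criteria C11-C14) and D2 "reducing the source of infection"
#' (C21-C24).
#'
#' `case_study_loadings()` returns the published rotated factor loadings
#' (items x 2 dimensions, non-salient cells 0); `case_study_weights()` the
#' published criterion influence weights (data frame: criterion, dimension,
#' weight; weights sum to 1 within each dimension);
#' `case_study_normalized_scores()` the published vector-normalized
#' decision matrix (hospitals x criteria).
#'
#' @return See details; matrices or a data frame.
#' @name case_study
NULL

#' @rdname case_study
#' @export
case_study_loadings <- function() {
  m <- load_matrix_csv(extdata("hospital_case_loadings.csv"))
  m[is.na(m)] <- 0
  m
}

#' @rdname case_study
#' @export
case_study_weights <- function() {
  df <- utils::read.csv(extdata("hospital_case_weights.csv"),
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df
}

#' @rdname case_study
#' @export
case_study_normalized_scores <- function() {
  load_matrix_csv(extdata("hospital_case_scores.csv"))
}

#' Run the bundled case-study evaluation
#'
#' Per-dimension TOPSIS on the bundled three-hospital data: for each
#' dimension, the published criterion weights are applied to the published
#' normalized decision matrix, ideals taken with every criterion treated as
#' a benefit attribute, and relative proximities computed.
#'
#' @return Named list of `topsis_result`, one per dimension (`D1`, `D2`).
#' @examples
#' res <- case_study_evaluation()
#' round(res$D1$proximity, 3)
#' res$D2$ranking
#' @export
case_study_evaluation <- function() {
  w <- case_study_weights()
  N <- case_study_normalized_scores()
  dims <- split(w$criterion, w$dimension)
  dims <- dims[order(names(dims))]
  out <- lapply(names(dims), function(d) {
    cols <- w$criterion[w$dimension == d]
    wd <- stats::setNames(w$weight[w$dimension == d], cols)
    topsis(N[, cols, drop = FALSE], wd / sum(wd), normalized = TRUE)
  })
  names(out) <- names(dims)
  out
}
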