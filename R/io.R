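delim_for <- function(format) switch(format, tsv = "\t", csv = ",")

#' Read a samples-by-features matrix from delimited text
#'
#' Expects a header row of feature names and a first column of sample
#' identifiers.  Duplicate ids and malformed numeric cells are rejected
#' with row/column context; missing cells are rejected unless
#' `impute = TRUE`, in which case they are replaced by the column mean
#' (reported via a message).
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param omics_path Optional two-column table (feature id, omics type in
#'   expression/mutation/copy_number) attached as the `omics_type`
#'   attribute.
#' @param impute Impute missing cells by column mean instead of erroring.
#' @return A validated feature matrix (see [as_feature_matrix()]).
#' @export
read_feature_matrix <- function(path, format = c("tsv", "csv"),
                                omics_path = NULL, impute = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- readr::read_delim(path, delim = delim_for(format),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 2) stop_validation("expected a sample-id column plus feature columns in %s", path)
  feat <- names(raw)[-1]
  if (anyDuplicated(feat)) {
    stop_validation("duplicated feature column name(s) in %s: %s", path,
                    paste(unique(feat[duplicated(feat)]), collapse = ", "))
  }
  samples <- as.character(raw[[1]])
  vals <- matrix(NA_real_, nrow(raw), length(feat),
                 dimnames = list(samples, feat))
  for (j in seq_along(feat)) {
    cell <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell) & cell != "" & toupper(cell) != "NA")
    if (length(bad)) {
      stop_validation("non-numeric cell in %s: row %d (sample '%s'), column '%s' = '%s'",
                      path, bad[1], samples[bad[1]], feat[j], cell[bad[1]])
    }
    vals[, j] <- num
  }
  if (anyNA(vals)) {
    if (!impute) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop_validation("missing value in %s at sample '%s', feature '%s' (set impute = TRUE to use column means)",
                      path, samples[bad[1]], feat[bad[2]])
    }
    n_imp <- sum(is.na(vals))
    for (j in which(colSums(is.na(vals)) > 0)) {
      vals[is.na(vals[, j]), j] <- mean(vals[, j], na.rm = TRUE)
    }
    message(sprintf("imputed %d missing cell(s) by column mean", n_imp))
  }
  x <- as_feature_matrix(vals)
  if (!is.null(omics_path)) {
    om <- readr::read_delim(omics_path, delim = delim_for(format),
                            col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    types <- stats::setNames(as.character(om[[2]]), as.character(om[[1]]))
    attr(x, "omics_type") <- types[colnames(x)]
  }
  x
}

#' Read a per-sample response table
#'
#' Two-column delimited text: sample id, numeric response value (e.g.
#' activity area).
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return Named numeric vector of responses.
#' @export
read_response <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  raw <- readr::read_delim(path, delim = delim_for(format),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (ncol(raw) < 2) stop_validation("expected two columns (sample id, value) in %s", path)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop_validation("duplicated sample id(s) in %s: %s", path,
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(vals))
  if (length(bad)) {
    stop_validation("non-numeric response in %s at line %d (sample '%s'): '%s'",
                    path, bad[1] + 1L, ids[bad[1]], as.character(raw[[2]])[bad[1]])
  }
  stats::setNames(vals, ids)
}

#' Align a feature matrix and response by sample id
#'
#' Intersection by id, never by row order; dropped samples are reported.
#'
#' @param x Feature matrix with sample ids as rownames.
#' @param y Named response vector.
#' @return List with the aligned `x` and `y`.
#' @export
align_samples <- function(x, y) {
  x <- as_feature_matrix(x)
  if (is.null(names(y))) stop_validation("response must carry sample ids")
  common <- intersect(rownames(x), names(y))
  if (length(common) == 0) stop_validation("no overlapping samples between features and response")
  dropped <- (nrow(x) - length(common)) + (length(y) - length(common))
  if (dropped > 0) {
    warning(sprintf("dropped %d sample(s) without both features and response; keeping %d",
                    dropped, length(common)), call. = FALSE)
  }
  om <- attr(x, "omics_type", exact = TRUE)
  xa <- x[common, , drop = FALSE]
  if (!is.null(om)) attr(xa, "omics_type") <- om
  list(x = xa, y = y[common])
}

fmt17 <- function(v) sprintf("%.17g", v)

#' Write a feature matrix as delimited text
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces them exactly.
#'
#' @param x Feature matrix.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  x <- as_feature_matrix(x)
  d <- delim_for(format)
  lines <- c(
    paste(c("sample_id", colnames(x)), collapse = d),
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], fmt17(x[i, ])), collapse = d)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a response vector as delimited text
#'
#' @param y Named numeric vector.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param label Column header for the value column.
#' @return `path`, invisibly.
#' @export
write_response <- function(y, path, format = c("tsv", "csv"),
                           label = "response") {
  format <- match.arg(format)
  d <- delim_for(format)
  writeLines(c(paste(c("sample_id", label), collapse = d),
               paste(names(y), fmt17(y), sep = d)), path)
  invisible(path)
}

#' Write a full results bundle for a fitted ISIRS pipeline
#'
#' Emits into `output_dir`: `selected_features.tsv` (feature, omics type,
#' screening score, OLS coefficient, t, p, significance flag),
#' `iterations.tsv` (per-iteration trace), `cv_predictions.tsv` (when a
#' [cross_validate()] report is given), and `summary.json`, a
#' machine-readable summary carrying the metrics, seed, resolved
#' configuration and a configuration hash so a run can be reproduced
#' exactly.
#'
#' @param fit An [isirs()] fit.
#' @param output_dir Directory (created if needed).
#' @param cv_report Optional `cv_report`.
#' @param redundancy Optional [redundancy_report()] tibble.
#' @param config Optional named list echoed into the summary.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(fit, output_dir, cv_report = NULL,
                          redundancy = NULL, config = NULL) {
  if (!inherits(fit, "isirs")) stop_validation("fit must be an isirs() result")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) stop_validation("cannot create output dir: %s", output_dir)
  files <- c()

  sel <- tidy(fit)
  sel <- sel[sel$term != "(Intercept)", , drop = FALSE]
  om_types <- fit$omics_type
  sel$omics_type <- if (is.null(om_types)) NA_character_ else unname(om_types[sel$term])
  sel <- sel[, c("term", "omics_type", "omega", "screen_rank", "estimate",
                 "std.error", "statistic", "p.value", "significant")]
  readr::write_tsv(sel, file.path(output_dir, "selected_features.tsv"))
  files["selected_features"] <- file.path(output_dir, "selected_features.tsv")

  readr::write_tsv(tidy(fit$trace), file.path(output_dir, "iterations.tsv"))
  files["iterations"] <- file.path(output_dir, "iterations.tsv")

  if (!is.null(cv_report)) {
    readr::write_tsv(tidy(cv_report), file.path(output_dir, "cv_predictions.tsv"))
    files["cv_predictions"] <- file.path(output_dir, "cv_predictions.tsv")
  }

  cfg <- config %||% list()
  summary <- list(
    package = "isirs",
    d = fit$d,
    n_selected = length(fit$trace$final_set),
    selected = names(fit$trace$final_set),
    stop_reason = fit$trace$stop_reason,
    n_iter = fit$trace$n_iter,
    r_squared = fit$model$r_squared,
    pcc = if (is.null(cv_report)) NULL else cv_report$pcc,
    mse = if (is.null(cv_report)) NULL else cv_report$mse,
    cv_seed = if (is.null(cv_report)) NULL else cv_report$seed,
    mrs_pcc = if (is.null(redundancy)) NULL else redundancy$mrs_pcc,
    mrs_mi = if (is.null(redundancy)) NULL else redundancy$mrs_mi,
    config = cfg,
    config_hash = rlang::hash(cfg)
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files["summary"] <- file.path(output_dir, "summary.json")
  invisible(files)
}

#' Read back a results summary
#'
#' @param path Path to a `summary.json` written by [write_results()].
#' @return Named list of the stored summary.
#' @export
read_run_summary <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
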