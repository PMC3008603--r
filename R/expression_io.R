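#' Construct an expression matrix
#'
#' A probes x samples intensity matrix with a declared scale. Linear-scale
#' values must be non-negative; log2-scale values may be any real. Missing
#' cells are an ingest error, never silently repaired.
#'
#' @param values numeric matrix with probe ids as rownames and sample ids as
#'   colnames.
#' @param scale `"linear"` or `"log2"`.
#' @return an `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry probe ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale intensities must be non-negative")
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix: ", nrow(x$values), " probes x ", ncol(x$values),
      " samples (", x$scale, " scale)\n", sep = "")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

probe_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Convert an expression matrix to the canonical log2 scale
#'
#' Linear intensities are floored at 1 before taking log2 so that background
#' level probes map to non-negative log values; log2 input is returned
#' unchanged.
#'
#' @param x an `ExpressionMatrix`.
#' @return an `ExpressionMatrix` on log2 scale.
#' @export
as_log2 <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale == "log2") return(x)
  expression_matrix(log2(pmax(x$values, 1)), scale = "log2")
}

#' Convert an expression matrix to linear scale
#' @param x an `ExpressionMatrix`.
#' @return an `ExpressionMatrix` on linear scale.
#' @export
as_linear <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale == "linear") return(x)
  expression_matrix(2^x$values, scale = "linear")
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and probe ids in the first column.
#' With `scale_hint = "auto"` the scale is inferred: a maximum value above
#' `auto_threshold` implies linear intensities (log2 microarray values
#' rarely exceed ~16).
#'
#' @param path file path.
#' @param scale_hint `"linear"`, `"log2"` or `"auto"`.
#' @param auto_threshold maximum value above which auto-detection declares
#'   the matrix linear.
#' @return an `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(path, scale_hint = c("auto", "linear", "log2"),
                                   auto_threshold = 30) {
  scale_hint <- match.arg(scale_hint)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("expression file needs a probe id column and >= 1 sample")
  ids <- df[[1L]]
  num <- df[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(num), ncol(num),
                 dimnames = list(ids, colnames(num)))
  for (j in seq_len(ncol(num))) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    if (anyNA(v))
      stop(sprintf("non-numeric or missing cell at row %d, column '%s'",
                   which(is.na(v))[1], colnames(num)[j]))
    vals[, j] <- v
  }
  scale <- if (scale_hint == "auto") {
    if (max(vals) > auto_threshold) "linear" else "log2"
  } else scale_hint
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix to tab-delimited text
#'
#' @param x an `ExpressionMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(probe_id = probe_ids(x), x$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.clinical_required <- c("sample_id", "time_months", "event")
.clinical_columns <- c("sample_id", "age_years", "gender", "grade", "stage",
                       "time_months", "event", "endpoint",
                       "adj_chemo", "adj_radio")

#' Construct a clinical table
#'
#' Per-sample clinical covariates plus a right-censored survival endpoint.
#' `gender`, `grade`, `stage` and the adjuvant-therapy flags may be
#' `"unknown"` (or NA, normalised to `"unknown"`); such samples can be
#' classified but cannot enter the multivariate training screen.
#'
#' @param df data frame with columns `sample_id`, `time_months`, `event`,
#'   and optionally `age_years`, `gender`, `grade`, `stage`, `endpoint`,
#'   `adj_chemo`, `adj_radio`.
#' @return a `ClinicalTable` (validated data frame).
#' @export
clinical_table <- function(df) {
  missing_cols <- setdiff(.clinical_required, names(df))
  if (length(missing_cols))
    stop("clinical table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$time_months <- as.numeric(df$time_months)
  if (any(!is.finite(df$time_months)) || any(df$time_months < 0))
    stop("time_months must be finite and non-negative")
  ev <- suppressWarnings(as.integer(df$event))
  if (anyNA(ev) || !all(ev %in% c(0L, 1L)))
    stop("event must be 0 or 1")
  df$event <- ev
  for (col in setdiff(.clinical_columns, names(df))) df[[col]] <- "unknown"
  df$age_years <- suppressWarnings(as.numeric(df$age_years))
  for (col in c("gender", "grade", "stage", "endpoint", "adj_chemo", "adj_radio")) {
    v <- as.character(df[[col]])
    v[is.na(v) | v == ""] <- "unknown"
    df[[col]] <- v
  }
  bad_gender <- setdiff(unique(df$gender), c("male", "female", "unknown"))
  if (length(bad_gender)) stop("unrecognised gender value(s): ",
                               paste(bad_gender, collapse = ", "))
  st <- df$stage[df$stage != "unknown"]
  if (length(st) && !all(st %in% c("1", "2", "3", "4")))
    stop("stage must be 1-4 or unknown")
  df <- df[, .clinical_columns]
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Read a tab-delimited clinical table
#' @param path file path.
#' @return a `ClinicalTable`.
#' @export
read_clinical_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  clinical_table(df)
}

#' Write a clinical table to tab-delimited text
#' @param x a `ClinicalTable`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(x, path) {
  stopifnot(inherits(x, "ClinicalTable"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a reference probe list (one probe id per line)
#'
#' The reference set is a list of probes with low cross-tissue variance
#' (nominally 100) used to median-centre each chip.
#'
#' @param path file path.
#' @return a character vector of class `ReferenceProbeSet`.
#' @export
read_reference_probes <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(trimws(ids))]
  reference_probe_set(trimws(ids))
}

#' Construct a reference probe set
#' @param probe_ids character vector of unique probe ids.
#' @return a `ReferenceProbeSet`.
#' @export
reference_probe_set <- function(probe_ids) {
  probe_ids <- as.character(probe_ids)
  if (!length(probe_ids)) stop("reference probe set is empty")
  if (anyDuplicated(probe_ids))
    stop("duplicate reference probe id(s): ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  structure(probe_ids, class = "ReferenceProbeSet")
}

#' Write a reference probe list
#' @param x a `ReferenceProbeSet` or character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_probes <- function(x, path) {
  writeLines(as.character(x), path)
  invisible(path)
}

.model_schema_version <- "1.0"

#' Save a trained signature model as versioned JSON
#'
#' The serialised document carries the signature probe ids, principal
#' component loadings and centers, metagene Cox coefficients, classification
#' threshold, training index quantiles, calibrated replicate standard
#' deviation and the preprocessing state, under a schema version tag.
#' Loading a saved model reproduces predictions bit-stably.
#'
#' @param model a trained `SignatureModel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "SignatureModel"))
  if (!isTRUE(model$trained)) stop("refusing to save an untrained model")
  doc <- list(
    schema_version = .model_schema_version,
    probe_ids = model$probe_ids,
    pc_loadings = model$pc_loadings,        # k x p matrix
    pc_center = model$pc_center,
    metagene_betas = model$metagene_betas,
    threshold = model$threshold,
    training_index_quantiles = model$training_index_quantiles,
    training_indices = model$training_indices,
    replicate_sd = model$replicate_sd,
    retained_probe_ids = model$retained_probe_ids,
    reference_probe_ids = model$reference_probe_ids,
    filter_threshold = model$filter_threshold)
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a signature model saved by [save_model()]
#'
#' @param path file path of the JSON document.
#' @return a `SignatureModel`.
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE)),
                  error = function(e) stop("cannot parse model file (truncated or corrupt): ",
                                           conditionMessage(e)))
  if (is.null(doc$schema_version) || !identical(doc$schema_version, .model_schema_version))
    stop("model schema version mismatch: found '", doc$schema_version,
         "', expected '", .model_schema_version, "'")
  required <- c("probe_ids", "pc_loadings", "pc_center", "metagene_betas",
                "threshold")
  miss <- required[vapply(required, function(f) is.null(doc[[f]]), logical(1))]
  if (length(miss))
    stop("model file incomplete; missing field(s): ", paste(miss, collapse = ", "))
  loadings <- doc$pc_loadings
  if (!is.matrix(loadings)) loadings <- matrix(loadings, nrow = 1L)
  m <- structure(list(
    probe_ids = as.character(doc$probe_ids),
    pc_loadings = loadings,
    pc_center = as.numeric(doc$pc_center),
    metagene_betas = as.numeric(doc$metagene_betas),
    threshold = as.numeric(doc$threshold),
    training_index_quantiles = as.numeric(doc$training_index_quantiles),
    training_indices = as.numeric(doc$training_indices),
    replicate_sd = if (is.null(doc$replicate_sd)) NA_real_ else as.numeric(doc$replicate_sd),
    retained_probe_ids = as.character(doc$retained_probe_ids),
    reference_probe_ids = as.character(doc$reference_probe_ids),
    filter_threshold = if (is.null(doc$filter_threshold)) NA_real_ else as.numeric(doc$filter_threshold),
    trained = TRUE), class = "SignatureModel")
  colnames(m$pc_loadings) <- m$probe_ids
  names(m$pc_center) <- m$probe_ids
  m
}
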