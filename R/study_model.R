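#' Construct a study table
#'
#' A study table holds the experimental design of a paired-preservation study:
#' one record per sample, with its source material (the blocking factor, e.g.
#' "feces 1" or "soil 2"), its preservation treatment (e.g. "dried" or
#' "frozen"), and any number of scalar success metrics (DNA yield, read
#' counts, Shannon diversity, ...). Metric values may be missing (\code{NA});
#' analyses drop samples with missing values for the tested metric.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param material character vector of source-material labels (non-empty).
#' @param treatment character vector of treatment labels (non-empty).
#' @param metrics optional data frame (or named list) of numeric metric
#'   columns, one row/value per sample.
#' @return An object of class \code{study_table}: a data frame with columns
#'   \code{sample_id}, \code{material}, \code{treatment} and one column per
#'   metric, with attribute \code{"metrics"} listing the metric names in
#'   registration order.
#' @seealso [read_metadata()], [simulate_metric_table()]
#' @export
study_table <- function(sample_id, material, treatment, metrics = NULL) {
  sample_id <- as.character(sample_id)
  material  <- as.character(material)
  treatment <- as.character(treatment)
  n <- length(sample_id)
  if (length(material) != n || length(treatment) != n)
    stop("sample_id, material and treatment must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (n > 0 && (any(is.na(material)) || any(!nzchar(material))))
    stop("every record needs a non-empty material label")
  if (n > 0 && (any(is.na(treatment)) || any(!nzchar(treatment))))
    stop("every record needs a non-empty treatment label")
  df <- data.frame(sample_id = sample_id, material = material,
                   treatment = treatment, stringsAsFactors = FALSE)
  metric_names <- character(0)
  if (!is.null(metrics) && length(metrics)) {
    metrics <- as.data.frame(metrics, optional = TRUE)
    if (n == 0 && nrow(metrics) == 0) {
      metric_names <- names(metrics)
      for (nm in metric_names) df[[nm]] <- numeric(0)
    } else {
      if (nrow(metrics) != n)
        stop("metrics must have one row per sample")
      for (nm in names(metrics)) {
        v <- suppressWarnings(as.numeric(metrics[[nm]]))
        if (any(is.infinite(v)))
          stop("metric '", nm, "' contains non-finite values")
        df[[nm]] <- v
      }
      metric_names <- names(metrics)
    }
  }
  structure(df, metrics = metric_names,
            class = c("study_table", "data.frame"))
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("study_table: %d samples, %d materials, %d treatments, %d metrics\n",
              nrow(x), length(unique(x$material)),
              length(unique(x$treatment)), length(study_metrics(x))))
  if (length(study_metrics(x)))
    cat("metrics:", paste(study_metrics(x), collapse = ", "), "\n")
  NextMethod()
  invisible(x)
}

#' Metric names registered in a study table
#' @param study a \code{study_table}.
#' @return Character vector of metric column names, in file/registration order.
#' @export
study_metrics <- function(study) attr(study, "metrics", exact = TRUE)

#' Read sample metadata from a TSV file
#'
#' Reads a tab-delimited metadata table with a header row. The file must
#' contain a \code{sample_id} column plus the material and treatment columns
#' named by the caller; every remaining column is ingested as a scalar metric,
#' with non-numeric cells becoming missing values.
#'
#' @param path path to a tab-delimited UTF-8 text file.
#' @param material_col,treatment_col names of the columns holding the material
#'   and treatment labels.
#' @return A [study_table()].
#' @export
read_metadata <- function(path, material_col = "material",
                          treatment_col = "treatment") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  for (col in c("sample_id", material_col, treatment_col))
    if (!col %in% names(df))
      stop("metadata file is missing required column '", col, "'")
  metric_cols <- setdiff(names(df), c("sample_id", material_col, treatment_col))
  metrics <- NULL
  if (length(metric_cols)) {
    metrics <- df[metric_cols]
    for (nm in metric_cols)
      metrics[[nm]] <- suppressWarnings(as.numeric(metrics[[nm]]))
  }
  study_table(df$sample_id, df[[material_col]], df[[treatment_col]], metrics)
}

#' Write a study table to TSV
#' @param study a \code{study_table}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_metadata <- function(study, path) {
  utils::write.table(as.data.frame(study), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a feature table
#'
#' A feature table is a nonnegative features-by-samples matrix (the classic
#' OTU-table orientation) of either raw counts or proportions. Proportion
#' tables must have every sample column summing to one.
#'
#' @param values numeric matrix, features as rows, samples as columns, with
#'   dimnames giving feature and sample ids.
#' @param kind \code{"counts"} or \code{"proportions"}.
#' @return An object of class \code{feature_table} wrapping the matrix.
#' @seealso [read_feature_table()], [to_proportions()]
#' @export
feature_table <- function(values, kind = c("counts", "proportions")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature table values must be numeric")
  if (any(!is.finite(values))) stop("feature table values must be finite")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at feature row %d, sample column %d",
                 idx[1], idx[2]))
  }
  if (is.null(rownames(values)))
    rownames(values) <- paste0("feature_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (kind == "proportions") {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-9))
      stop("proportion table columns must sum to 1 (worst deviation ",
           format(max(abs(cs - 1))), ")")
  }
  structure(list(values = values, kind = kind), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table (%s): %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Feature and sample identifiers of a feature table
#' @param t a \code{feature_table}.
#' @return Character vector of ids.
#' @export
feature_ids <- function(t) rownames(t$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(t) colnames(t$values)

#' Read a feature table from TSV
#'
#' First column holds feature ids; remaining columns are samples with a
#' numeric body. The kind is inferred: proportions if and only if every
#' sample column sums to 1 within 1e-6, otherwise counts.
#'
#' @param path path to a tab-delimited text file.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("feature table needs an id column and >=1 sample column")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("feature table body must be numeric")
  if (any(m < 0, na.rm = TRUE)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at row %d ('%s'), column '%s'",
                 idx[1], ids[idx[1]], colnames(m)[idx[2]]))
  }
  rownames(m) <- ids
  kind <- if (ncol(m) > 0 && all(abs(colSums(m) - 1) <= 1e-6))
    "proportions" else "counts"
  feature_table(m, kind)
}

#' Write a feature table to TSV
#' @param t a \code{feature_table}.
#' @param path output file path.
#' @param id_col name for the feature-id column header.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(t, path, id_col = "feature_id") {
  df <- data.frame(rownames(t$values), t$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize a feature table to proportions
#'
#' Divides each sample column by its sum so that columns sum to one.
#' Idempotent on proportion tables.
#'
#' @param t a \code{feature_table}; every column must have a positive sum.
#' @return A \code{feature_table} of kind \code{"proportions"}.
#' @export
to_proportions <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  cs <- colSums(t$values)
  if (any(cs <= 0))
    stop("cannot normalize all-zero sample(s): ",
         paste(colnames(t$values)[cs <= 0], collapse = ", "))
  feature_table(sweep(t$values, 2, cs, "/"), "proportions")
}

#' Subset a study table by material and/or treatment
#'
#' @param x a \code{study_table}.
#' @param materials character vector of material labels to keep, or NULL for all.
#' @param treatments character vector of treatment labels to keep, or NULL for all.
#' @param ... ignored.
#' @return A \code{study_table} with the matching records, order preserved.
#' @export
subset.study_table <- function(x, materials = NULL, treatments = NULL, ...) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(materials)) {
    unknown <- setdiff(materials, unique(x$material))
    if (length(unknown))
      stop("unknown material(s) ", paste(unknown, collapse = ", "),
           "; available: ", paste(unique(x$material), collapse = ", "))
    keep <- keep & x$material %in% materials
  }
  if (!is.null(treatments)) {
    unknown <- setdiff(treatments, unique(x$treatment))
    if (length(unknown))
      stop("unknown treatment(s) ", paste(unknown, collapse = ", "),
           "; available: ", paste(unique(x$treatment), collapse = ", "))
    keep <- keep & x$treatment %in% treatments
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, metrics = study_metrics(x),
            class = c("study_table", "data.frame"))
}

#' Subset a feature table by sample ids
#'
#' @param x a \code{feature_table}.
#' @param samples character vector of sample ids to keep (order as given),
#'   or NULL for all.
#' @param ... ignored.
#' @return A \code{feature_table} with the selected columns.
#' @export
subset.feature_table <- function(x, samples = NULL, ...) {
  if (is.null(samples)) return(x)
  unknown <- setdiff(samples, colnames(x$values))
  if (length(unknown))
    stop("unknown sample(s) ", paste(unknown, collapse = ", "),
         "; available: ", paste(colnames(x$values), collapse = ", "))
  feature_table(x$values[, samples, drop = FALSE], x$kind)
}

#' MAG quality records
#'
#' Builds a data frame of metagenome-assembled-genome (MAG) quality records
#' with completeness and contamination estimates as percentages.
#'
#' @param mag_id character vector of MAG identifiers.
#' @param group character vector of group labels (e.g. "dried feces").
#' @param completeness numeric, percent in [0, 100].
#' @param contamination numeric, percent >= 0.
#' @return A data frame of class \code{mag_records}.
#' @export
mag_records <- function(mag_id, group, completeness, contamination) {
  if (any(completeness < 0 | completeness > 100, na.rm = TRUE))
    stop("completeness must lie in [0, 100]")
  if (any(contamination < 0, na.rm = TRUE))
    stop("contamination must be >= 0")
  structure(data.frame(mag_id = as.character(mag_id),
                       group = as.character(group),
                       completeness = as.numeric(completeness),
                       contamination = as.numeric(contamination),
                       stringsAsFactors = FALSE),
            class = c("mag_records", "data.frame"))
}

#' Filter MAGs by quality thresholds
#'
#' Retains MAGs of at least the requested quality: completeness at or above
#' \code{min_completeness} and contamination at or below
#' \code{max_contamination} (both boundaries inclusive). The defaults select
#' medium-or-better quality MAGs (completeness >= 50\%, contamination <= 10\%).
#'
#' @param mags a \code{mag_records} data frame.
#' @param min_completeness minimum completeness, percent in [0, 100].
#' @param max_contamination maximum contamination, percent >= 0.
#' @return The retained records, input order preserved.
#' @export
filter_mags <- function(mags, min_completeness = 50, max_contamination = 10) {
  if (min_completeness < 0 || min_completeness > 100)
    stop("min_completeness must lie in [0, 100]")
  if (max_contamination < 0) stop("max_contamination must be >= 0")
  keep <- mags$completeness >= min_completeness &
    mags$contamination <= max_contamination
  out <- mags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
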