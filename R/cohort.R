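# Cohort container and CSV I/O.

#' Construct a cohort object
#'
#' A cohort is a data.frame of raw integer feature values (one row per
#' patient, columns named per the schema) plus an optional label factor.
#'
#' @param data data.frame with the 91 feature columns (and optionally a
#'   `TreatmentType` column, integer codes 1-4 or class names).
#' @param labels Optional factor/character vector of class labels; if `NULL`
#'   and `data` has a `TreatmentType` column, labels are taken from it.
#' @param schema An `hs_schema` registry.
#' @param validate Validate all records? Default TRUE.
#' @param provenance Free-form list recording how the cohort was produced.
#' @return An object of class `hs_cohort`.
#' @export
as_cohort <- function(data, labels = NULL, schema = load_schema(),
                      validate = TRUE, provenance = list()) {
  data <- as.data.frame(data)
  if (is.null(labels) && "TreatmentType" %in% names(data))
    labels <- data$TreatmentType
  feats <- setdiff(schema$feature_order, names(data))
  if (length(feats))
    hs_error("hierscore_missing_feature",
             paste0("cohort columns missing: ", paste(feats, collapse = ", ")),
             features = feats)
  data <- data[, schema$feature_order, drop = FALSE]
  if (!is.null(labels)) {
    if (is.numeric(labels)) {
      bad <- !(labels %in% schema$label_codes)
      if (any(bad))
        hs_error("hierscore_parse_error",
                 paste0("unknown TreatmentType codes: ",
                        paste(unique(labels[bad]), collapse = ", ")))
      labels <- names(schema$label_codes)[match(labels, schema$label_codes)]
    }
    bad <- !(as.character(labels) %in% schema$classes)
    if (any(bad))
      hs_error("hierscore_parse_error",
               paste0("unknown class labels: ",
                      paste(unique(labels[bad]), collapse = ", ")))
    labels <- factor(as.character(labels), levels = schema$classes)
    stopifnot(length(labels) == nrow(data))
  }
  obj <- structure(list(data = data, labels = labels,
                        provenance = provenance),
                   class = "hs_cohort")
  if (validate) {
    for (i in seq_len(nrow(data))) {
      res <- tryCatch(validate_record(data[i, , drop = FALSE], schema),
                      hierscore_error = function(e) e)
      if (inherits(res, "hierscore_error"))
        stop(sprintf("record %d: %s", i, conditionMessage(res)),
             call. = FALSE)
    }
  }
  obj
}

#' @rdname as_cohort
#' @param x An object.
#' @export
is_cohort <- function(x) inherits(x, "hs_cohort")

# raw feature data.frame from cohort-or-data.frame
cohort_data <- function(x) {
  if (is_cohort(x)) x$data else as.data.frame(x)
}

#' Cohort labels
#' @param cohort An `hs_cohort`.
#' @return Factor of class labels, or `NULL` for unlabelled cohorts.
#' @export
cohort_labels <- function(cohort) {
  stopifnot(is_cohort(cohort))
  cohort$labels
}

#' @export
print.hs_cohort <- function(x, ...) {
  cat("<hs_cohort> ", nrow(x$data), " records, ",
      if (is.null(x$labels)) "unlabelled" else "labelled", "\n", sep = "")
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' @export
length.hs_cohort <- function(x) nrow(x$data)

#' Subset a cohort by record index
#' @param x An `hs_cohort`.
#' @param i Integer/logical index of records to keep.
#' @param ... Unused.
#' @export
`[.hs_cohort` <- function(x, i, ...) {
  structure(list(data = x$data[i, , drop = FALSE],
                 labels = if (is.null(x$labels)) NULL else x$labels[i],
                 provenance = x$provenance),
            class = "hs_cohort")
}

#' Read a cohort from CSV
#'
#' The file must have a header naming all 91 features; an optional
#' `TreatmentType` column carries the class label as integer codes
#' 1 = depression, 2 = panic, 3 = social phobia, 4 = specific phobia.
#'
#' @param path Path to a comma-separated UTF-8 file.
#' @param schema An `hs_schema` registry.
#' @param validate Validate all records? Default TRUE.
#' @return An `hs_cohort`.
#' @export
read_cohort_csv <- function(path, schema = load_schema(), validate = TRUE) {
  if (!file.exists(path))
    hs_error("hierscore_parse_error", paste0("file not found: ", path))
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e)
      hs_error("hierscore_parse_error",
               paste0("cannot parse ", path, ": ", conditionMessage(e))))
  as_cohort(df, schema = schema, validate = validate,
            provenance = list(source = path))
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: writing then reading reproduces values
#' exactly (all cells are integers).
#'
#' @param cohort An `hs_cohort`.
#' @param path Output path.
#' @param schema An `hs_schema` registry.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, schema = load_schema()) {
  stopifnot(is_cohort(cohort))
  df <- cohort$data
  if (!is.null(cohort$labels))
    df$TreatmentType <- unname(schema$label_codes[as.character(cohort$labels)])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
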