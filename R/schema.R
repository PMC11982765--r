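# Instrument schema: the 91-feature questionnaire + demographic battery used
# throughout the package, as machine-readable metadata.

#' Treatment classes
#'
#' The four treatment decisions the classifier discriminates between, in the
#' fixed order used by every probability vector, confusion matrix and output
#' layer in this package.
#'
#' @return Character vector of length 4.
#' @export
hs_classes <- function() {
  c("depression", "panic", "social_phobia", "specific_phobia")
}

# integer codes used in the TreatmentType CSV column
.hs_label_codes <- c(depression = 1L, panic = 2L, social_phobia = 3L,
                     specific_phobia = 4L)

.hs_schema_version <- "1.0"

# Fear Questionnaire structure (standard Marks-Mathews key):
#   item 1  = main target phobia avoidance ("fq_main", direct to output layer)
#   items 2-16 = three 5-item avoidance subscales
#   item 17 = "any other avoided situation", direct to output layer
#   item 18 = global phobia severity ("fq_global", direct)
#   items 19-23 = anxiety-depression subscale ("fq")
#   item 24 = "any other feelings", direct
.fq_ago <- paste0("Fq", c(5, 6, 8, 12, 15))   # agoraphobia
.fq_bi  <- paste0("Fq", c(2, 4, 10, 13, 16))  # blood-injury
.fq_soc <- paste0("Fq", c(3, 7, 9, 11, 14))   # social phobia
.fq_anxdep <- paste0("Fq", 19:23)

# SIAS items conventionally reverse-scored
.sias_reverse_default <- paste0("Sias", c(5, 9, 11))

#' Load the instrument schema registry
#'
#' Builds the static registry describing all 91 input features: their
#' instruments, allowed integer values, reverse-scoring flags, one-hot dummy
#' groups, the pseudosum-score wiring used by [build_model()], and the
#' traditional sum-score definitions with severity bands.
#'
#' @param sias_reverse_items Character vector of SIAS item names that are
#'   reverse-scored. Defaults to the standard key (items 5, 9 and 11).
#' @return An object of class `hs_schema`.
#' @export
load_schema <- function(sias_reverse_items = .sias_reverse_default) {
  stopifnot(all(sias_reverse_items %in% paste0("Sias", 1:20)))

  spec <- function(name, instrument, allowed, kind = "ordinal",
                   reverse = FALSE, group = NA_character_) {
    data.frame(name = name, instrument = instrument, kind = kind,
               reverse = reverse, onehot_group = group,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  allowed <- list()
  add <- function(name, instrument, vals, kind = "ordinal",
                  reverse = FALSE, group = NA_character_) {
    rows[[length(rows) + 1L]] <<- spec(name, instrument, vals, kind, reverse, group)
    allowed[[name]] <<- as.integer(vals)
  }

  add("Education", "demographic", 0:6)
  add("AlcoholIntake", "demographic", 0:5)
  add("UseOfDrugs", "demographic", 0:1, kind = "binary")
  add("CurrentMedication", "demographic", 0:3)
  for (i in 1:9) add(paste0("Phq", i), "PHQ9", 0:3)
  add("PhqTen", "PHQ9", 0:3)
  for (i in 1:7) add(paste0("Gad", i), "GAD7", 0:3)
  add("HasPhobia", "demographic", 0:1, kind = "binary")
  for (i in 1:24) add(paste0("Fq", i), "FQ", c(0L, 2L, 4L, 6L, 8L))
  for (i in 1:20) {
    nm <- paste0("Sias", i)
    add(nm, "SIAS", 0:4, reverse = nm %in% sias_reverse_items)
  }
  for (i in 1:7) add(paste0("Pdss", i), "PDSS", 0:4)
  for (nm in c("MansaTen", "MansaTwentyFour", "MansaTwentyFive"))
    add(nm, "MANSA", 1:7)
  for (i in 0:3) add(paste0("DAD", i), "demographic", 0:1,
                     kind = "onehot_member", group = "DAD")
  for (i in 1:7) add(paste0("INC_", i), "demographic", 0:1,
                     kind = "onehot_member", group = "INC")
  for (i in 1:4) add(paste0("APP_", i), "demographic", 0:1,
                     kind = "onehot_member", group = "APP")

  features <- do.call(rbind, rows)
  features$idx <- seq_len(nrow(features))
  stopifnot(nrow(features) == 91L)

  score_nodes <- list(
    phq  = c(paste0("Phq", 1:9), "PhqTen"),
    gad  = paste0("Gad", 1:7),
    sias = paste0("Sias", 1:20),
    pdss = paste0("Pdss", 1:7),
    fq     = .fq_anxdep,
    fq_ago = .fq_ago,
    fq_bi  = .fq_bi,
    fq_soc = .fq_soc
  )
  second_level <- list(fq_total = c("fq_ago", "fq_bi", "fq_soc"))
  # direct (bypass) inputs to the output layer; names are the output-node
  # labels used in figures, values are the underlying feature columns
  direct <- c(fq_main = "Fq1", fq_global = "Fq18", Fq17 = "Fq17",
              Fq24 = "Fq24",
              MansaTen = "MansaTen", MansaTwentyFour = "MansaTwentyFour",
              MansaTwentyFive = "MansaTwentyFive",
              Education = "Education", AlcoholIntake = "AlcoholIntake",
              UseOfDrugs = "UseOfDrugs",
              CurrentMedication = "CurrentMedication",
              HasPhobia = "HasPhobia",
              stats::setNames(paste0("DAD", 0:3), paste0("DAD", 0:3)),
              stats::setNames(paste0("INC_", 1:7), paste0("INC_", 1:7)),
              stats::setNames(paste0("APP_", 1:4), paste0("APP_", 1:4)))
  output_nodes <- c("phq", "gad", "sias", "pdss", "fq", "fq_total",
                    names(direct))

  bands <- function(lo, hi, labels) {
    data.frame(lo = lo, hi = hi, label = labels, stringsAsFactors = FALSE)
  }
  sum_defs <- list(
    PHQ9 = list(items = paste0("Phq", 1:9), reverse = FALSE,
                range = c(0L, 27L),
                bands = bands(c(0, 5, 10, 15, 20), c(4, 9, 14, 19, 27),
                              paste0(c("minimal", "mild", "moderate",
                                       "moderately severe", "severe"),
                                     " depression"))),
    GAD7 = list(items = paste0("Gad", 1:7), reverse = FALSE,
                range = c(0L, 21L),
                bands = bands(c(0, 5, 10, 15), c(4, 9, 14, 21),
                              paste0(c("minimal", "mild", "moderate",
                                       "severe"), " anxiety"))),
    SIAS = list(items = paste0("Sias", 1:20), reverse = TRUE,
                range = c(0L, 80L),
                bands = bands(c(0, 34, 43), c(33, 42, 80),
                              c("below social phobia threshold",
                                "probable social anxiety disorder",
                                "probable social phobia"))),
    PDSS = list(items = paste0("Pdss", 1:7), reverse = FALSE,
                range = c(0L, 28L),
                bands = bands(c(0, 2, 6, 10, 14, 17), c(1, 5, 9, 13, 16, 28),
                              c("normal", "borderline ill", "slightly ill",
                                "moderately ill", "markedly ill",
                                "severely ill"))),
    FQ = list(items = c(.fq_ago, .fq_bi, .fq_soc), reverse = FALSE,
              range = c(0L, 120L),
              bands = bands(c(0, 40, 80), c(39, 79, 120),
                            c("low phobic avoidance",
                              "moderate phobic avoidance",
                              "high phobic avoidance"))),
    FQ_ANXDEP = list(items = .fq_anxdep, reverse = FALSE,
                     range = c(0L, 40L),
                     bands = bands(c(0, 14, 27), c(13, 26, 40),
                                   c("low distress", "moderate distress",
                                     "high distress")))
  )

  onehot_groups <- split(features$name[!is.na(features$onehot_group)],
                         features$onehot_group[!is.na(features$onehot_group)])

  structure(list(
    version = .hs_schema_version,
    features = features,
    allowed = allowed,
    feature_order = features$name,
    classes = hs_classes(),
    label_codes = .hs_label_codes,
    score_nodes = score_nodes,
    second_level = second_level,
    direct = direct,
    output_nodes = output_nodes,
    onehot_groups = onehot_groups,
    sum_defs = sum_defs
  ), class = "hs_schema")
}

#' @export
print.hs_schema <- function(x, ...) {
  cat("<hs_schema> v", x$version, ": ", nrow(x$features),
      " input features, ", length(x$score_nodes),
      " pseudosum nodes, ", length(x$output_nodes),
      " output-layer inputs, ", length(x$classes), " classes\n", sep = "")
  invisible(x)
}

#' Export the schema as a plain list for JSON serialization
#'
#' @param schema An `hs_schema` registry.
#' @return A list convertible with [jsonlite::toJSON()].
#' @export
schema_export <- function(schema) {
  stopifnot(inherits(schema, "hs_schema"))
  list(
    version = schema$version,
    classes = schema$classes,
    features = lapply(seq_len(nrow(schema$features)), function(i) {
      f <- schema$features[i, ]
      list(name = f$name, instrument = f$instrument, kind = f$kind,
           reverse_scored = f$reverse,
           onehot_group = if (is.na(f$onehot_group)) NULL else f$onehot_group,
           allowed_values = schema$allowed[[f$name]])
    }),
    score_nodes = schema$score_nodes,
    second_level = schema$second_level,
    direct_inputs = as.list(schema$direct),
    output_nodes = schema$output_nodes
  )
}

# classed error helper so callers can distinguish failure modes
hs_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "hierscore_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Validate a patient record against the schema
#'
#' A record is a named list (or one-row data.frame) mapping every one of the
#' 91 feature names to an integer value. Validation enforces completeness,
#' per-feature allowed values, and exactly one active dummy per one-hot
#' group. Nothing is normalized or modified.
#'
#' @param record Named list or one-row data.frame of raw integer values.
#' @param schema An `hs_schema` registry.
#' @return The record, as a named integer vector in schema order.
#' @export
validate_record <- function(record, schema) {
  stopifnot(inherits(schema, "hs_schema"))
  if (is.data.frame(record)) record <- as.list(record[1, , drop = FALSE])
  vals <- record[schema$feature_order]
  missing <- schema$feature_order[vapply(vals, is.null, logical(1)) |
                                    vapply(vals, function(v) length(v) != 1 || is.na(v), logical(1))]
  if (length(missing))
    hs_error("hierscore_missing_feature",
             paste0("missing or NA features: ",
                    paste(missing, collapse = ", ")),
             features = missing)
  v <- vapply(vals, as.numeric, numeric(1))
  if (any(v != round(v)))
    hs_error("hierscore_out_of_range", "non-integer feature values")
  v <- stats::setNames(as.integer(v), schema$feature_order)
  for (nm in schema$feature_order) {
    if (!(v[[nm]] %in% schema$allowed[[nm]]))
      hs_error("hierscore_out_of_range",
               sprintf("feature %s: value %d not in allowed set {%s}",
                       nm, v[[nm]],
                       paste(schema$allowed[[nm]], collapse = ",")),
               feature = nm, value = v[[nm]])
  }
  for (g in names(schema$onehot_groups)) {
    active <- sum(v[schema$onehot_groups[[g]]])
    if (active != 1L)
      hs_error("hierscore_onehot_violation",
               sprintf("one-hot group %s has %d active dummies (expected 1)",
                       g, active),
               group = g)
  }
  v
}

#' Encode a validated record to the normalized feature vector
#'
#' Each ordinal feature is min-max scaled to \[0, 1\] over its schema-declared
#' range (not over observed data, so train- and predict-time scaling are
#' identical by construction). Reverse-scored SIAS items are flipped before
#' scaling; one-hot dummies pass through as 0/1; MANSA items on 1..7 map to
#' (v - 1)/6.
#'
#' @param record Named integer vector/list with all 91 features.
#' @param schema An `hs_schema` registry.
#' @param validate Validate first? Default TRUE.
#' @return Named numeric vector of length 91 in schema order, entries in \[0,1\].
#' @export
encode_record <- function(record, schema, validate = TRUE) {
  v <- if (validate) validate_record(record, schema) else
    stats::setNames(as.integer(record[schema$feature_order]),
                    schema$feature_order)
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    nm <- schema$feature_order[[i]]
    a <- schema$allowed[[nm]]
    x <- v[[i]]
    if (schema$features$reverse[[i]]) x <- max(a) + min(a) - x
    out[[i]] <- (x - min(a)) / (max(a) - min(a))
  }
  stats::setNames(out, schema$feature_order)
}

#' Encode a cohort to the normalized feature matrix
#'
#' @param cohort An `hs_cohort` (see [as_cohort()]) or data.frame of raw
#'   integer features.
#' @param schema An `hs_schema` registry.
#' @param validate Validate every record first? Default TRUE.
#' @return Numeric matrix (n x 91), rows in cohort order, columns in schema
#'   order, all entries in \[0, 1\].
#' @export
encode_cohort <- function(cohort, schema, validate = TRUE) {
  df <- cohort_data(cohort)
  if (validate) {
    for (i in seq_len(nrow(df))) {
      res <- tryCatch(validate_record(df[i, , drop = FALSE], schema),
                      hierscore_error = function(e) e)
      if (inherits(res, "hierscore_error"))
        stop(sprintf("record %d: %s", i, conditionMessage(res)), call. = FALSE)
    }
  }
  X <- as.matrix(df[, schema$feature_order, drop = FALSE])
  storage.mode(X) <- "double"
  rev_idx <- which(schema$features$reverse)
  for (j in seq_len(ncol(X))) {
    a <- schema$allowed[[schema$feature_order[[j]]]]
    if (j %in% rev_idx) X[, j] <- max(a) + min(a) - X[, j]
    X[, j] <- (X[, j] - min(a)) / (max(a) - min(a))
  }
  X
}

#' Traditional instrument sum-score with severity label
#'
#' Computes the conventional unweighted item sum for an instrument and the
#' severity band it falls into. PHQ-9 sums its nine symptom items (the tenth,
#' functional-impairment item is not part of the traditional 0-27 score);
#' SIAS reverse-scored items are flipped before summing, per the standard
#' scoring key. `FQ` is the Total Phobia score (sum of the agoraphobia,
#' blood-injury and social subscales); `FQ_ANXDEP` the anxiety-depression
#' subscale.
#'
#' @param record Named integer vector/list with all 91 features.
#' @param instrument_id One of `"PHQ9"`, `"GAD7"`, `"SIAS"`, `"PDSS"`,
#'   `"FQ"`, `"FQ_ANXDEP"`.
#' @param schema An `hs_schema` registry.
#' @return List with `score` (integer) and `severity` (character label).
#' @export
sum_score <- function(record, instrument_id, schema = load_schema()) {
  def <- schema$sum_defs[[instrument_id]]
  if (is.null(def))
    hs_error("hierscore_unknown_instrument",
             paste0("unknown instrument: ", instrument_id))
  v <- validate_record(record, schema)
  items <- v[def$items]
  if (def$reverse) {
    for (nm in def$items) {
      i <- match(nm, schema$feature_order)
      if (schema$features$reverse[[i]]) {
        a <- schema$allowed[[nm]]
        items[[nm]] <- max(a) + min(a) - items[[nm]]
      }
    }
  }
  s <- sum(items)
  b <- def$bands
  lab <- b$label[s >= b$lo & s <= b$hi]
  list(score = as.integer(s), severity = lab)
}
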