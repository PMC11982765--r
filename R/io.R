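# Model serialization: versioned JSON with full-precision weights.

#' Save a model to a JSON file
#'
#' The document records the schema version and feature order alongside all
#' weights at full floating-point precision, so that
#' `load_model(save_model(m))` reproduces every weight bit-exactly.
#'
#' @param model An `hs_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hs_model"))
  doc <- list(
    format = "hierscore-model",
    schema_version = model$schema_version,
    feature_order = model$feature_order,
    classes = model$classes,
    score_nodes = model$score_nodes,
    second_level = model$second_level,
    output_nodes = model$output_nodes,
    direct = as.list(model$direct),
    score_weights = lapply(model$score_weights, unname),
    second_weights = lapply(model$second_weights, unname),
    W = unname(apply(model$W, 1, identity, simplify = FALSE)),
    b = unname(as.numeric(model$b)),
    dropout_rate = model$dropout_rate,
    nonneg_score_weights = model$nonneg_score_weights,
    loss_history = model$loss_history
  )
  # digits = I(17) serializes doubles with 17 significant digits, enough to
  # reproduce every IEEE double bit-exactly on reload
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a model from a JSON file
#'
#' @param path Path written by [save_model()].
#' @param schema An `hs_schema` registry the model must be compatible with
#'   (same version and feature order).
#' @return An `hs_model`.
#' @export
load_model <- function(path, schema = load_schema()) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    hs_error("hierscore_corrupt_file",
                             paste0("cannot read model file: ",
                                    conditionMessage(e))))
  if (!identical(doc$format, "hierscore-model") || is.null(doc$W))
    hs_error("hierscore_corrupt_file", "not a hierscore model file")
  if (!identical(doc$schema_version, schema$version) ||
      !identical(as.character(doc$feature_order), schema$feature_order))
    hs_error("hierscore_version_mismatch",
             "model schema version or feature order does not match")
  sw <- lapply(names(schema$score_nodes), function(g)
    stats::setNames(as.numeric(doc$score_weights[[g]]),
                    schema$score_nodes[[g]]))
  names(sw) <- names(schema$score_nodes)
  vw <- lapply(names(schema$second_level), function(s)
    stats::setNames(as.numeric(doc$second_weights[[s]]),
                    schema$second_level[[s]]))
  names(vw) <- names(schema$second_level)
  W <- if (is.matrix(doc$W)) doc$W else
    do.call(rbind, lapply(doc$W, as.numeric))
  dimnames(W) <- list(schema$classes, schema$output_nodes)
  structure(list(
    schema_version = doc$schema_version,
    feature_order = schema$feature_order,
    classes = schema$classes,
    score_nodes = schema$score_nodes,
    second_level = schema$second_level,
    output_nodes = schema$output_nodes,
    direct = schema$direct,
    score_weights = sw,
    second_weights = vw,
    W = W,
    b = stats::setNames(as.numeric(doc$b), schema$classes),
    dropout_rate = as.numeric(doc$dropout_rate),
    nonneg_score_weights = isTRUE(doc$nonneg_score_weights),
    loss_history = as.numeric(doc$loss_history)
  ), class = "hs_model")
}
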