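# Weight-based global and local explanations. The weights reported here are
# the very weights the forward pass uses (the model is transparent); no
# surrogate model is involved.

#' Top signed output-layer weights for a class
#'
#' @param model A trained `hs_model`.
#' @param class One of the four class names.
#' @param k How many positive and how many negative weights to return
#'   (clipped to what exists; zero weights are omitted).
#' @return List with data.frames `positive` and `negative` (columns
#'   `feature`, `weight`), each sorted by |weight| descending.
#' @export
global_class_weights <- function(model, class, k = 6) {
  stopifnot(inherits(model, "hs_model"))
  if (!class %in% model$classes)
    hs_error("hierscore_unknown_class", paste0("unknown class: ", class))
  w <- model$W[class, ]
  pos <- sort(w[w > 0], decreasing = TRUE)
  neg <- sort(w[w < 0])
  pos <- pos[seq_len(min(k, length(pos)))]
  neg <- neg[seq_len(min(k, length(neg)))]
  list(positive = data.frame(feature = names(pos), weight = unname(pos),
                             row.names = NULL),
       negative = data.frame(feature = names(neg), weight = unname(neg),
                             row.names = NULL))
}

#' Standardized score-layer coefficients
#'
#' Multiplies each score-layer weight by the standard deviation (population
#' convention, divide by n) of the corresponding encoded feature over the
#' training cohort, giving a scale-free importance measure per item. For the
#' second-level node(s) the "features" are the subscale pseudoscores, whose
#' SDs are computed from the cohort's dropout-free pseudoscores.
#'
#' @param model A trained `hs_model`.
#' @param training_cohort The `hs_cohort` the model was trained on.
#' @param schema An `hs_schema` registry.
#' @return Named list (one element per score node) of data.frames with
#'   columns `item`, `weight`, `sd`, `standardized`, sorted by
#'   |standardized| descending.
#' @export
standardized_coefficients <- function(model, training_cohort,
                                      schema = load_schema()) {
  stopifnot(inherits(model, "hs_model"))
  X <- encode_cohort(training_cohort, schema, validate = FALSE)
  if (nrow(X) == 0)
    hs_error("hierscore_empty_cohort", "empty cohort")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  out <- list()
  for (g in names(model$score_weights)) {
    w <- model$score_weights[[g]]
    sds <- vapply(names(w), function(nm)
      pop_sd(X[, match(nm, model$feature_order)]), numeric(1))
    d <- data.frame(item = names(w), weight = unname(w), sd = unname(sds),
                    standardized = unname(w * sds), row.names = NULL)
    out[[g]] <- d[order(-abs(d$standardized)), ]
    rownames(out[[g]]) <- NULL
  }
  if (length(model$second_weights)) {
    S1 <- hm_forward(model, X)$S1
    for (s in names(model$second_weights)) {
      w <- model$second_weights[[s]]
      sds <- vapply(names(w), function(nm) pop_sd(S1[, nm]), numeric(1))
      d <- data.frame(item = names(w), weight = unname(w), sd = unname(sds),
                      standardized = unname(w * sds), row.names = NULL)
      out[[s]] <- d[order(-abs(d$standardized)), ]
      rownames(out[[s]]) <- NULL
    }
  }
  out
}

#' Local (per-patient) contributions to a class logit
#'
#' Decomposes the class logit into per-input contributions
#' `W[class, s] * X_s`, where `X_s` are the dropout-free pseudosum scores
#' and direct features the softmax layer sees. The contributions plus the
#' class bias reconstruct the logit exactly. With `node`, the decomposition
#' is instead of one pseudosum score into its item contributions
#' `w_item * x_item`.
#'
#' @param model A trained `hs_model`.
#' @param record Named integer vector/list with all 91 raw features.
#' @param class One of the four class names.
#' @param node Optional score-node name (e.g. `"phq"`) for a question-level
#'   decomposition of that pseudosum score.
#' @param schema An `hs_schema` registry.
#' @return List of class `hs_local_explanation`: `class`, `contributions`
#'   (data.frame feature/value/weight/contribution, |contribution|
#'   descending), `positive`, `negative`, `bias`, `logit`.
#' @export
local_contributions <- function(model, record, class, node = NULL,
                                schema = load_schema()) {
  stopifnot(inherits(model, "hs_model"))
  if (!class %in% model$classes)
    hs_error("hierscore_unknown_class", paste0("unknown class: ", class))
  x <- encode_record(record, schema)
  X <- matrix(x, nrow = 1)
  fw <- hm_forward(model, X)
  if (is.null(node)) {
    z <- fw$Z[1, ]
    wts <- model$W[class, ]
    contrib <- wts * z
    bias <- unname(model$b[[class]])
    logit <- unname(fw$logits[1, class])
    vals <- z
  } else {
    if (!node %in% names(model$score_weights))
      hs_error("hierscore_unknown_class", paste0("unknown score node: ", node))
    wts <- model$score_weights[[node]]
    vals <- x[names(wts)]
    contrib <- wts * vals
    bias <- 0
    logit <- unname(fw$S1[1, node])  # ReLU may clip the raw sum at 0
  }
  d <- data.frame(feature = names(contrib), value = unname(vals),
                  weight = unname(wts), contribution = unname(contrib),
                  row.names = NULL)
  d <- d[order(-abs(d$contribution)), ]
  rownames(d) <- NULL
  structure(list(class = class, node = node, contributions = d,
                 positive = d[d$contribution > 0, ],
                 negative = d[d$contribution < 0, ],
                 bias = bias, logit = logit),
            class = "hs_local_explanation")
}

#' @export
print.hs_local_explanation <- function(x, ...) {
  cat("<hs_local_explanation> class ", x$class,
      if (!is.null(x$node)) paste0(", node ", x$node) else "",
      "; logit ", format(x$logit, digits = 4), " (bias ",
      format(x$bias, digits = 4), ")\n", sep = "")
  print(utils::head(x$contributions, 12))
  invisible(x)
}

# minimal number of leading |weight|-ranked features whose cumulative
# absolute weight reaches `threshold` of the total
coverage_count <- function(weights, threshold = 0.8) {
  a <- sort(abs(weights), decreasing = TRUE)
  tot <- sum(a)
  if (tot == 0) return(1L)
  which(cumsum(a) >= threshold * tot - 1e-12)[1]
}

#' Multi-run training stability analysis
#'
#' Retrains the model from several seeds and aggregates, per class, (a) how
#' often each output-layer feature is the top positive weight (strict
#' argmax, ties toward the lowest index) and (b) how many features are
#' needed to cover 80% of the cumulative absolute output-layer weight.
#'
#' @param cohort A labelled `hs_cohort`.
#' @param config An `hs_train_config` used for every run (its seed is
#'   replaced per run).
#' @param n_runs Number of training runs (>= 2); ignored if `seeds` given.
#' @param seeds Integer vector of run seeds (default `seq_len(n_runs)`).
#' @param coverage_threshold Cumulative-|weight| threshold (default 0.8).
#' @param schema An `hs_schema` registry.
#' @return List of class `hs_stability`: `n_runs`, `top_feature_freq`
#'   (per-class named frequency tables summing to 1), `coverage_counts`
#'   (runs x classes matrix), `top_features` (runs x classes character
#'   matrix).
#' @export
stability_analysis <- function(cohort, config = train_config(),
                               n_runs = 30, seeds = NULL,
                               coverage_threshold = 0.8,
                               schema = load_schema()) {
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  stopifnot(length(seeds) >= 2)
  classes <- schema$classes
  top <- matrix(NA_character_, length(seeds), length(classes),
                dimnames = list(NULL, classes))
  cov <- matrix(NA_integer_, length(seeds), length(classes),
                dimnames = list(NULL, classes))
  for (i in seq_along(seeds)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[[i]])
    m <- build_model(schema, seed = cfg$seed,
                     dropout_rate = cfg$dropout_rate,
                     nonneg_score_weights = cfg$nonneg_score_weights)
    m <- train_model(m, cohort, cfg, schema)
    for (cl in classes) {
      w <- m$W[cl, ]
      top[i, cl] <- names(w)[which.max(w)]
      cov[i, cl] <- coverage_count(w, coverage_threshold)
    }
  }
  freq <- lapply(classes, function(cl) {
    t <- table(top[, cl]) / length(seeds)
    sort(t, decreasing = TRUE)
  })
  names(freq) <- classes
  structure(list(n_runs = length(seeds), seeds = seeds,
                 top_feature_freq = freq, coverage_counts = cov,
                 top_features = top,
                 coverage_threshold = coverage_threshold),
            class = "hs_stability")
}

#' @export
print.hs_stability <- function(x, ...) {
  cat("<hs_stability> ", x$n_runs, " runs; features for ",
      100 * x$coverage_threshold, "% cumulative |weight| (median per class):\n",
      sep = "")
  print(apply(x$coverage_counts, 2, stats::median))
  for (cl in names(x$top_feature_freq)) {
    cat(cl, ": top positive feature ", sep = "")
    f <- x$top_feature_freq[[cl]]
    cat(paste0(names(f), " (", round(100 * as.numeric(f)), "%)",
               collapse = ", "), "\n")
  }
  invisible(x)
}
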