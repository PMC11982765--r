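# Hierarchical pseudosum-score classifier: architecture, forward pass and
# mini-batch training with manual gradients.
#
# Architecture: instrument items -> pseudosum nodes (non-negative weighted
# sum + ReLU); the three Fear Questionnaire avoidance subscales feed a
# second-level fq_total node; pseudoscores and direct (bypass) features feed
# a 4-class softmax output layer. Bernoulli dropout masks are applied to the
# input of every weight layer, with inverted scaling (activations divided by
# the keep probability) so the dropout-free limit equals the point forward
# pass.

#' Training configuration
#'
#' Defaults follow the reference training regime: 2000 epochs, batch size 32, Adam at its
#' default hyperparameters, L1 regularization factor 0.001 and dropout rate
#' 0.05.
#'
#' @param epochs Number of passes over the training data (>= 1).
#' @param batch_size Mini-batch size.
#' @param reg_type `"L1"` or `"L2"`.
#' @param reg_factor Non-negative regularization factor (applied to all
#'   weights, never biases).
#' @param dropout_rate Bernoulli drop probability in \[0, 1), applied to the
#'   input of every weight layer during training (and by [mcd_predict()] at
#'   inference).
#' @param nonneg_score_weights Project score-layer weights to be >= 0 after
#'   every optimizer step? Default TRUE (preserves the sum-score analogy).
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters (defaults
#'   1e-3, 0.9, 0.999, 1e-8).
#' @param seed Integer seed driving initialization order, batch shuffling and
#'   dropout masks.
#' @return A list of class `hs_train_config`.
#' @export
train_config <- function(epochs = 2000, batch_size = 32, reg_type = c("L1", "L2"),
                         reg_factor = 0.001, dropout_rate = 0.05,
                         nonneg_score_weights = TRUE,
                         learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, seed = 1) {
  reg_type <- match.arg(reg_type)
  stopifnot(epochs >= 1, batch_size >= 1, reg_factor >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 reg_type = reg_type, reg_factor = reg_factor,
                 dropout_rate = dropout_rate,
                 nonneg_score_weights = isTRUE(nonneg_score_weights),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "hs_train_config")
}

# static wiring table derived from the schema
hm_wiring <- function(schema) {
  first <- names(schema$score_nodes)
  item_idx <- lapply(schema$score_nodes,
                     function(items) match(items, schema$feature_order))
  second <- names(schema$second_level)
  out_first <- intersect(schema$output_nodes, first)
  direct_idx <- match(schema$direct, schema$feature_order)
  names(direct_idx) <- names(schema$direct)
  list(first = first, item_idx = item_idx, second = second,
       second_subs = schema$second_level, out_first = out_first,
       direct_idx = direct_idx, output_nodes = schema$output_nodes)
}

#' Build an untrained hierarchical model
#'
#' Weights are initialized from a small symmetric uniform distribution
#' U(-0.05, 0.05) (seeded); biases start at zero. The output-layer input
#' width (number of pseudoscores plus direct features) is recorded and
#' asserted against the schema wiring.
#'
#' @param schema An `hs_schema` registry.
#' @param seed Integer seed for the weight initialization.
#' @param dropout_rate Dropout rate stored on the model (used by training
#'   and by Monte Carlo dropout inference). Default 0.05.
#' @param nonneg_score_weights Constrain score-layer weights to be
#'   non-negative? Default TRUE.
#' @return An object of class `hs_model`.
#' @export
build_model <- function(schema = load_schema(), seed = 1, dropout_rate = 0.05,
                        nonneg_score_weights = TRUE) {
  stopifnot(inherits(schema, "hs_schema"),
            dropout_rate >= 0, dropout_rate < 1)
  w <- hm_wiring(schema)
  K <- length(w$output_nodes)
  stopifnot(K == length(w$out_first) + length(w$second) +
              length(w$direct_idx))
  with_seed(seed, {
    init <- function(n, names) stats::setNames(stats::runif(n, -0.05, 0.05), names)
    # under the non-negativity constraint the score layers start in the
    # feasible region (uniform on [0, 0.05]) so no weight is clipped dead
    # at initialization
    init_score <- if (nonneg_score_weights)
      function(n, names) stats::setNames(stats::runif(n, 0, 0.05), names)
    else init
    score_weights <- lapply(schema$score_nodes, function(items)
      init_score(length(items), items))
    second_weights <- lapply(schema$second_level, function(subs)
      init_score(length(subs), subs))
    W <- matrix(stats::runif(4L * K, -0.05, 0.05), 4L, K,
                dimnames = list(schema$classes, w$output_nodes))
    structure(list(
      schema_version = schema$version,
      feature_order = schema$feature_order,
      classes = schema$classes,
      score_nodes = schema$score_nodes,
      second_level = schema$second_level,
      output_nodes = schema$output_nodes,
      direct = schema$direct,
      score_weights = score_weights,
      second_weights = second_weights,
      W = W,
      b = stats::setNames(numeric(4L), schema$classes),
      dropout_rate = dropout_rate,
      nonneg_score_weights = isTRUE(nonneg_score_weights),
      loss_history = numeric(0)
    ), class = "hs_model")
  })
}

#' @export
print.hs_model <- function(x, ...) {
  np <- sum(lengths(x$score_weights)) + sum(lengths(x$second_weights)) +
    length(x$W) + length(x$b)
  cat("<hs_model> ", length(x$score_nodes), " pseudosum nodes + ",
      length(x$second_level), " second-level node(s), output width ",
      ncol(x$W), ", ", np, " parameters, dropout ", x$dropout_rate,
      if (x$nonneg_score_weights) ", non-negative score weights" else "",
      if (length(x$loss_history)) sprintf(", trained %d epochs",
                                          length(x$loss_history)) else
        ", untrained",
      "\n", sep = "")
  invisible(x)
}

# draw an inverted-scaling dropout mask matrix (n x k), or NULL when p = 0
hm_mask <- function(n, k, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(n * k, 1L, 1 - p) / (1 - p), n, k)
}

# forward pass over an encoded feature matrix X (n x 91, schema order).
# masks: NULL (deterministic) or list(m1, m2, m3) of inverted-scaling masks.
# Returns list(P, logits, Z, S1, A1, A2, Xm, Um).
hm_forward <- function(model, X, masks = NULL) {
  w <- hm_wiring_cached(model)
  n <- nrow(X)
  Xm <- if (is.null(masks)) X else X * masks$m1
  A1 <- matrix(0, n, length(w$first), dimnames = list(NULL, w$first))
  for (g in w$first)
    A1[, g] <- Xm[, w$item_idx[[g]], drop = FALSE] %*%
      model$score_weights[[g]]
  S1 <- pmax(A1, 0)
  A2 <- NULL; S2 <- NULL; Um <- NULL
  if (length(w$second)) {
    A2 <- matrix(0, n, length(w$second), dimnames = list(NULL, w$second))
    Um <- list()
    for (s in w$second) {
      U <- S1[, w$second_subs[[s]], drop = FALSE]
      Um[[s]] <- if (is.null(masks)) U else U * masks$m2[[s]]
      A2[, s] <- Um[[s]] %*% model$second_weights[[s]]
    }
    S2 <- pmax(A2, 0)
  }
  Z <- matrix(0, n, length(w$output_nodes),
              dimnames = list(NULL, w$output_nodes))
  Z[, w$out_first] <- S1[, w$out_first]
  if (length(w$second)) Z[, w$second] <- S2[, w$second]
  Z[, names(w$direct_idx)] <- X[, w$direct_idx]
  Zm <- if (is.null(masks)) Z else Z * masks$m3
  logits <- Zm %*% t(model$W) + rep(1, n) %*% t(model$b)
  colnames(logits) <- model$classes
  m <- apply(logits, 1, max)
  E <- exp(logits - m)
  P <- E / rowSums(E)
  list(P = P, logits = logits, Z = Z, Zm = Zm, S1 = S1, A1 = A1, A2 = A2,
       Xm = Xm, Um = Um)
}

# wiring is pure schema structure; rebuild it from the model fields
hm_wiring_cached <- function(model) {
  first <- names(model$score_nodes)
  item_idx <- lapply(model$score_nodes,
                     function(items) match(items, model$feature_order))
  second <- names(model$second_level)
  out_first <- intersect(model$output_nodes, first)
  direct_idx <- match(model$direct, model$feature_order)
  names(direct_idx) <- names(model$direct)
  list(first = first, item_idx = item_idx, second = second,
       second_subs = model$second_level, out_first = out_first,
       direct_idx = direct_idx, output_nodes = model$output_nodes)
}

#' Deterministic class probabilities for a feature matrix
#'
#' @param model An `hs_model`.
#' @param X Encoded feature matrix (n x 91), as from [encode_cohort()].
#' @return n x 4 matrix of class probabilities (rows sum to 1).
#' @export
forward_matrix <- function(model, X) {
  stopifnot(inherits(model, "hs_model"))
  if (ncol(X) != length(model$feature_order))
    hs_error("hierscore_dimension_mismatch",
             sprintf("expected %d feature columns, got %d",
                     length(model$feature_order), ncol(X)))
  hm_forward(model, X)$P
}

#' Deterministic class probabilities for one encoded record
#'
#' The point prediction: a single forward pass with dropout inactive.
#'
#' @param model An `hs_model`.
#' @param x Encoded feature vector of length 91 (see [encode_record()]).
#' @return Named numeric vector of 4 class probabilities summing to 1.
#' @export
forward_point <- function(model, x) {
  p <- forward_matrix(model, matrix(x, nrow = 1))
  stats::setNames(as.numeric(p), model$classes)
}

#' Output-layer input vector (pseudoscores and direct features)
#'
#' Evaluates the dropout-free pseudosum scores and assembles the vector the
#' softmax layer sees, in `model$output_nodes` order. This is the `X_s` of
#' the per-class logit decomposition used by the explainability functions.
#'
#' @param model An `hs_model`.
#' @param X Encoded feature matrix (n x 91).
#' @return n x K matrix, K = output-layer input width.
#' @export
output_inputs <- function(model, X) {
  stopifnot(inherits(model, "hs_model"))
  hm_forward(model, X)$Z
}

# penalty value and gradient factory
hm_penalty <- function(reg_type, reg_factor) {
  if (reg_type == "L1")
    list(value = function(w) reg_factor * sum(abs(w)),
         grad = function(w) reg_factor * sign(w))
  else
    list(value = function(w) reg_factor * sum(w^2),
         grad = function(w) 2 * reg_factor * w)
}

#' Train the hierarchical model
#'
#' Minimizes categorical cross-entropy plus an L1 or L2 penalty on all
#' weights (not biases) by mini-batch Adam, with Bernoulli dropout masks on
#' the input of every weight layer. If the model constrains score weights,
#' they are projected to be non-negative after every optimizer step. Batch
#' order is reshuffled every epoch from the run seed; the last partial batch
#' is kept.
#'
#' @param model An `hs_model` (from [build_model()]).
#' @param cohort A labelled `hs_cohort` (or list with `X` encoded matrix and
#'   `y` factor).
#' @param config An `hs_train_config`.
#' @param schema An `hs_schema` registry (for encoding the cohort).
#' @return The trained `hs_model`; `$loss_history` holds the mean per-epoch
#'   training loss (cross-entropy + penalty).
#' @export
train_model <- function(model, cohort, config = train_config(),
                        schema = load_schema()) {
  stopifnot(inherits(model, "hs_model"), inherits(config, "hs_train_config"))
  if (is_cohort(cohort)) {
    y <- cohort_labels(cohort)
    if (is.null(y))
      hs_error("hierscore_unlabelled_cohort", "training needs labels")
    X <- encode_cohort(cohort, schema, validate = FALSE)
  } else {
    X <- cohort$X; y <- cohort$y
  }
  n <- nrow(X)
  if (n == 0) hs_error("hierscore_empty_cohort", "empty training cohort")
  if (length(unique(as.integer(y))) < 2)
    hs_error("hierscore_single_class_cohort",
             "training cohort contains a single class")
  model$dropout_rate <- config$dropout_rate
  p <- config$dropout_rate
  w <- hm_wiring_cached(model)
  yi <- as.integer(factor(y, levels = model$classes))
  Y <- matrix(0, n, 4L); Y[cbind(seq_len(n), yi)] <- 1
  pen <- hm_penalty(config$reg_type, config$reg_factor)

  # parameter and Adam state registries
  params <- c(stats::setNames(model$score_weights,
                              paste0("w.", names(model$score_weights))),
              stats::setNames(model$second_weights,
                              paste0("v.", names(model$second_weights))),
              list(W = model$W, b = model$b))
  mstate <- lapply(params, function(x) x * 0)
  vstate <- mstate
  tstep <- 0L
  lr <- config$learning_rate; b1 <- config$beta1; b2 <- config$beta2
  eps <- config$epsilon
  loss_hist <- numeric(config$epochs)

  sync <- function() {
    for (g in names(model$score_weights))
      model$score_weights[[g]] <<- params[[paste0("w.", g)]]
    for (s in names(model$second_weights))
      model$second_weights[[s]] <<- params[[paste0("v.", s)]]
    model$W <<- params$W
    model$b <<- params$b
  }

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      epoch_loss <- 0
      for (st in starts) {
        idx <- ord[st:min(st + config$batch_size - 1L, n)]
        nb <- length(idx)
        Xb <- X[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        masks <- if (p > 0) list(
          m1 = hm_mask(nb, ncol(Xb), p),
          m2 = stats::setNames(lapply(w$second, function(s)
            hm_mask(nb, length(w$second_subs[[s]]), p)), w$second),
          m3 = hm_mask(nb, length(w$output_nodes), p)) else NULL
        sync()
        fw <- hm_forward(model, Xb, masks)
        ce <- -sum(log(pmax(fw$P[cbind(seq_len(nb), yi[idx])], 1e-300))) / nb
        reg <- sum(vapply(grep("^(w|v)\\.|^W$", names(params)),
                          function(i) pen$value(params[[i]]), numeric(1)))
        epoch_loss <- epoch_loss + (ce + reg) * nb

        # backward
        dlog <- (fw$P - Yb) / nb                        # n x 4
        gW <- t(dlog) %*% fw$Zm + pen$grad(params$W)
        gb <- colSums(dlog)
        dZm <- dlog %*% model$W                         # n x K
        dZ <- if (is.null(masks)) dZm else dZm * masks$m3
        dS1 <- matrix(0, nb, length(w$first),
                      dimnames = list(NULL, w$first))
        dS1[, w$out_first] <- dZ[, w$out_first]
        grads <- list(W = gW, b = gb)
        for (s in w$second) {
          ds2 <- dZ[, s]
          da2 <- ds2 * (fw$A2[, s] > 0)
          grads[[paste0("v.", s)]] <-
            as.numeric(t(fw$Um[[s]]) %*% da2) +
            pen$grad(params[[paste0("v.", s)]])
          dUm <- outer(da2, model$second_weights[[s]])
          dU <- if (is.null(masks)) dUm else dUm * masks$m2[[s]]
          dS1[, w$second_subs[[s]]] <- dS1[, w$second_subs[[s]]] + dU
        }
        for (g in w$first) {
          da1 <- dS1[, g] * (fw$A1[, g] > 0)
          grads[[paste0("w.", g)]] <-
            as.numeric(t(fw$Xm[, w$item_idx[[g]], drop = FALSE]) %*% da1) +
            pen$grad(params[[paste0("w.", g)]])
        }

        # Adam update
        tstep <- tstep + 1L
        for (nm in names(grads)) {
          gr <- grads[[nm]]
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr^2
          mhat <- mstate[[nm]] / (1 - b1^tstep)
          vhat <- vstate[[nm]] / (1 - b2^tstep)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
        if (config$nonneg_score_weights) {
          for (nm in grep("^(w|v)\\.", names(params), value = TRUE))
            params[[nm]] <- pmax(params[[nm]], 0)
        }
      }
      loss_hist[[epoch]] <- epoch_loss / n
    }
  })
  sync()
  model$nonneg_score_weights <- config$nonneg_score_weights
  model$loss_history <- loss_hist
  model$train_config <- unclass(config)
  model
}

#' Predict classes or probabilities for a cohort
#'
#' @param object An `hs_model`.
#' @param cohort An `hs_cohort` or raw feature data.frame.
#' @param type `"prob"` for the n x 4 probability matrix, `"class"` for the
#'   argmax class factor (ties broken toward the lowest class index).
#' @param schema An `hs_schema` registry.
#' @param ... Unused.
#' @return Matrix or factor, depending on `type`.
#' @export
predict.hs_model <- function(object, cohort, type = c("prob", "class"),
                             schema = load_schema(), ...) {
  type <- match.arg(type)
  X <- encode_cohort(cohort, schema, validate = FALSE)
  P <- forward_matrix(object, X)
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}
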