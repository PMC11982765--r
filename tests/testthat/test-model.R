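test_that("model construction is seeded and wired to the schema", {
  schema <- fixture_schema()
  a <- build_model(schema, seed = 3)
  b <- build_model(schema, seed = 3)
  expect_identical(a$W, b$W)
  expect_identical(a$score_weights, b$score_weights)
  c <- build_model(schema, seed = 4)
  expect_false(identical(a$W, c$W))
  # output width: 6 pseudoscores (phq gad sias pdss fq fq_total) + 27 direct
  expect_equal(ncol(a$W), 33L)
  expect_equal(length(a$output_nodes),
               length(intersect(a$output_nodes, names(a$score_nodes))) +
                 length(a$second_level) + length(a$direct))
  # 4 output nodes regardless of the number of instruments
  expect_equal(nrow(a$W), 4L)
  # constrained build starts inside the feasible region
  expect_true(all(unlist(a$score_weights) >= 0))
})

test_that("the forward pass matches closed-form softmax arithmetic", {
  schema <- fixture_schema()
  m <- zero_model(schema)
  x <- encode_record(zero_record(schema), schema)
  # all-zero model: uniform probabilities
  expect_equal(unname(forward_point(m, x)), rep(0.25, 4))
  # toy: phq score 0.5*1.0, classes weighted +1/-1 on it
  m$score_weights$phq[["Phq1"]] <- 0.5
  m$W["depression", "phq"] <- 1
  m$W["panic", "phq"] <- -1
  r <- zero_record(schema); r$Phq1 <- 3L  # encodes to 1.0
  p <- forward_point(m, encode_record(r, schema))
  e <- exp(c(0.5, -0.5, 0, 0))
  expect_equal(unname(p), e / sum(e), tolerance = 1e-12)
  # ReLU clips a negative pseudosum at zero (unconstrained weights)
  m2 <- build_model(schema, seed = 1, nonneg_score_weights = FALSE)
  for (g in names(m2$score_weights)) m2$score_weights[[g]][] <- 0
  m2$second_weights$fq_total[] <- 0
  m2$score_weights$phq[["Phq1"]] <- -1
  Z <- output_inputs(m2, matrix(encode_record(r, schema), nrow = 1))
  expect_equal(unname(Z[1, "phq"]), 0)
})

test_that("probabilities form a simplex point for arbitrary inputs and weights", {
  schema <- fixture_schema()
  set.seed(8)
  m <- build_model(schema, seed = 8)
  for (g in names(m$score_weights))
    m$score_weights[[g]][] <- runif(length(m$score_weights[[g]]), 0, 2)
  m$W[] <- rnorm(length(m$W), sd = 2)
  m$b[] <- rnorm(4)
  X <- matrix(runif(200 * 91), 200, 91)
  P <- forward_matrix(m, X)
  expect_true(all(P >= 0))
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
})

test_that("constrained pseudoscores are monotone in item severity", {
  schema <- fixture_schema()
  tr <- fixture_trained()
  m <- tr$model
  set.seed(3)
  X <- encode_cohort(tr$cohort, schema, validate = FALSE)
  for (rep in 1:20) {
    i <- sample(nrow(X), 1)
    g <- sample(names(m$score_nodes), 1)
    item <- sample(m$score_nodes[[g]], 1)
    j <- match(item, m$feature_order)
    x1 <- X[i, ]; x2 <- x1
    x2[[j]] <- min(1, x1[[j]] + 0.25)
    Z1 <- output_inputs(m, matrix(x1, nrow = 1))
    Z2 <- output_inputs(m, matrix(x2, nrow = 1))
    col <- if (g %in% colnames(Z1)) g else "fq_total"
    expect_gte(Z2[1, col], Z1[1, col])
  }
})

test_that("training reduces the loss and fits separable data", {
  tr <- fixture_trained()
  lh <- tr$model$loss_history
  expect_gt(mean(head(lh, 10)), mean(tail(lh, 10)))
  ba <- balanced_accuracy(cohort_labels(tr$cohort),
                          predict(tr$model, tr$cohort, "class"))
  expect_gte(ba, 0.9)
})

test_that("an overwhelming penalty collapses the weights to the prior", {
  schema <- fixture_schema()
  coh <- fixture_cohort(n = 120, effect = 0.6, seed = 15)
  m <- train_model(build_model(schema, seed = 1), coh,
                   train_config(epochs = 40, reg_factor = 1000, seed = 1),
                   schema)
  expect_lt(max(abs(m$W)), 1e-3)
  expect_lt(max(abs(unlist(m$score_weights))), 1e-3)
  P <- predict(m, coh, "prob", schema)
  # predictions are (near) constant across records: the bias softmax
  expect_lt(max(apply(P, 2, stats::sd)), 0.01)
})

test_that("training rejects degenerate cohorts", {
  schema <- fixture_schema()
  coh <- fixture_cohort(n = 60, effect = 0.4, seed = 9)
  m <- build_model(schema, seed = 1)
  single <- coh[cohort_labels(coh) == "depression"]
  expect_error(train_model(m, single, train_config(epochs = 1), schema),
               class = "hierscore_single_class_cohort")
  un <- as_cohort(coh$data, schema = schema, validate = FALSE)
  expect_error(train_model(m, un, train_config(epochs = 1), schema),
               class = "hierscore_unlabelled_cohort")
})

test_that("model serialization round-trips bit-exactly", {
  schema <- fixture_schema()
  tr <- fixture_trained()
  m <- tr$model
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path, schema)
  expect_identical(m$W, m2$W)
  expect_identical(m$score_weights, m2$score_weights)
  expect_identical(m$second_weights, m2$second_weights)
  expect_identical(unname(as.numeric(m$b)), unname(as.numeric(m2$b)))
  set.seed(4)
  X <- matrix(runif(100 * 91), 100, 91)
  expect_identical(forward_matrix(m, X), forward_matrix(m2, X))
  # tampered feature order is a version mismatch
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$feature_order <- rev(doc$feature_order)
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path2, auto_unbox = TRUE, digits = I(17))
  expect_error(load_model(path2, schema),
               class = "hierscore_version_mismatch")
  # junk is a corrupt file, not a crash
  path3 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"something": 1}', path3)
  expect_error(load_model(path3, schema), class = "hierscore_corrupt_file")
})

test_that("cross-validation stratifies folds and selects the best factor", {
  schema <- fixture_schema()
  coh <- fixture_cohort(n = 150, effect = 0.6, seed = 33)
  cfg <- train_config(epochs = 25, seed = 1)
  res <- cross_validate_regularization(coh, factors = c(1e-4, 1e-3),
                                       reg_types = "L1", k_folds = 5,
                                       config = cfg, seed = 11,
                                       schema = schema)
  # fold sizes differ by at most one per class
  y <- cohort_labels(coh)
  for (cl in levels(y)) {
    sizes <- table(res$fold_assignment[y == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # selected factor equals the argmax of independently recomputed means
  means <- tapply(res$folds$balanced_accuracy, res$folds$factor, mean)
  expect_equal(unname(res$selected[["L1"]]),
               as.numeric(names(means)[which.max(means)]))
  # a one-point grid selects that point
  res1 <- cross_validate_regularization(coh, factors = 1e-3,
                                        reg_types = "L1", k_folds = 4,
                                        config = cfg, seed = 1,
                                        schema = schema)
  expect_equal(unname(res1$selected[["L1"]]), 1e-3)
  # classes smaller than the fold count are refused
  tiny <- coh[c(which(y == "depression")[1:3], which(y == "panic")[1:8],
                which(y == "social_phobia")[1:8],
                which(y == "specific_phobia")[1:3])]
  expect_error(cross_validate_regularization(tiny, 1e-3, "L1", 5, cfg, 1,
                                             schema),
               class = "hierscore_fold_too_small")
})
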