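# the reference test-set confusion matrix (published clinical evaluation,
# n = 267), used as a worked example
reference_confusion <- function() {
  as_confusion(matrix(c(72, 8, 9, 0,
                        10, 69, 8, 3,
                        13, 5, 45, 1,
                        0, 2, 1, 21), 4, 4, byrow = TRUE))
}

test_that("confusion matrices tally truth against prediction", {
  labs <- c("depression", "depression", "panic", "panic", "social_phobia",
            "specific_phobia")
  preds <- c("depression", "panic", "panic", "panic", "depression",
             "specific_phobia")
  cm <- confusion(labs, preds)
  expect_equal(unname(cm["depression", ]), c(1L, 1L, 0L, 0L))
  expect_equal(unname(cm["panic", ]), c(0L, 2L, 0L, 0L))
  expect_equal(unname(cm["social_phobia", ]), c(1L, 0L, 0L, 0L))
  expect_equal(unname(cm["specific_phobia", ]), c(0L, 0L, 0L, 1L))
  expect_equal(sum(cm), 6L)
  # empty input: all-zero matrix; mismatches raise classed errors
  expect_true(all(confusion(character(0), character(0)) == 0L))
  expect_error(confusion("depression", c("panic", "panic")),
               class = "hierscore_length_mismatch")
  expect_error(confusion("depression", "mania"),
               class = "hierscore_unknown_class")
})

test_that("metrics from the printed reference confusion match exact arithmetic", {
  mt <- metrics_from_confusion(reference_confusion())
  pc <- mt$per_class
  expect_equal(pc$precision, c(72 / 95, 69 / 84, 45 / 63, 21 / 25))
  expect_equal(pc$recall, c(72 / 89, 69 / 90, 45 / 64, 21 / 24))
  expect_equal(pc$specificity, c(155 / 178, 162 / 177, 185 / 203, 239 / 243))
  expect_equal(pc$f1, 2 * pc$precision * pc$recall /
                 (pc$precision + pc$recall))
  expect_equal(pc$balanced_accuracy, (pc$recall + pc$specificity) / 2)
  expect_equal(mt$balanced_accuracy, mean(pc$recall))
  expect_equal(mt$weighted_f1,
               sum(c(89, 90, 64, 24) / 267 * pc$f1))
})

test_that("metric edge cases: perfect, two-class and undefined cells", {
  perfect <- metrics_from_confusion(diag(c(5L, 3L, 2L, 4L)))
  expect_true(all(perfect$per_class$precision == 1))
  expect_true(all(perfect$per_class$recall == 1))
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$weighted_f1, 1)
  # two active classes confused half the time
  two <- metrics_from_confusion(matrix(c(1, 1, 0, 0,
                                         1, 1, 0, 0,
                                         0, 0, 0, 0,
                                         0, 0, 0, 0), 4, 4, byrow = TRUE))
  expect_equal(two$per_class$precision[1:2], c(0.5, 0.5))
  expect_equal(two$per_class$recall[1:2], c(0.5, 0.5))
  # empty rows/columns flag undefined metrics rather than silently zeroing
  expect_true(any(grepl("^recall:", two$undefined)))
  expect_true(any(grepl("^precision:", two$undefined)))
  expect_true(all(is.na(two$per_class$recall[3:4])))
  expect_error(metrics_from_confusion(matrix(0L, 4, 4)),
               class = "hierscore_empty_cohort")
})

test_that("metrics agree with a brute-force per-record tally on random data", {
  set.seed(99)
  classes <- hs_classes()
  for (rep in 1:300) {
    n <- sample(8:40, 1)
    labs <- sample(classes, n, replace = TRUE)
    preds <- sample(classes, n, replace = TRUE)
    cm <- confusion(labs, preds)
    mt <- metrics_from_confusion(cm)
    for (ci in seq_along(classes)) {
      cl <- classes[[ci]]
      npred <- sum(preds == cl); ntrue <- sum(labs == cl)
      prec <- if (npred > 0) sum(labs == cl & preds == cl) / npred else NA_real_
      rec <- if (ntrue > 0) sum(labs == cl & preds == cl) / ntrue else NA_real_
      expect_equal(mt$per_class$precision[[ci]], prec)
      expect_equal(mt$per_class$recall[[ci]], rec)
      spec <- sum(labs != cl & preds != cl) / sum(labs != cl)
      expect_equal(mt$per_class$specificity[[ci]], spec)
    }
    # trace identity and weighted-F1 bounds
    rec <- mt$per_class$recall
    row <- rowSums(cm)
    expect_equal(sum(row[row > 0] * rec[row > 0]), sum(diag(cm)))
    f1 <- mt$per_class$f1
    if (!anyNA(f1)) {
      expect_gte(mt$weighted_f1, min(f1))
      expect_lte(mt$weighted_f1, max(f1))
    }
  }
})

test_that("presentation rounding is half-up at two decimals", {
  expect_equal(round_half_up(0.785), 0.79)
  expect_equal(round_half_up(0.875), 0.88)
  expect_equal(round_half_up(0.7031), 0.70)
  expect_equal(round_half_up(-0.125), -0.13)
})

test_that("one-vs-rest AUC follows the Mann-Whitney convention", {
  # brute-force pair counting (ties credit 1/2) as the independent oracle,
  # on coarse-grid scores so ties actually occur
  brute <- function(labs, s, cl) {
    pos <- s[labs == cl]; neg <- s[labs != cl]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(21)
  labs <- c(rep(hs_classes(), 3), sample(hs_classes(), 8, replace = TRUE))
  P <- matrix(sample(seq(0, 1, 0.25), length(labs) * 4, replace = TRUE),
              ncol = 4)
  P <- (P + 0.1) / rowSums(P + 0.1)
  P <- round(P, 1)  # force ties
  a <- auc_ovr(labs, P)
  for (ci in seq_along(hs_classes()))
    expect_equal(unname(a[[ci]]), brute(labs, P[, ci], hs_classes()[[ci]]))
  # perfectly separated scores give 1
  labs2 <- rep(hs_classes(), each = 3)
  P2 <- matrix(0.05, 12, 4)
  for (i in seq_len(12)) P2[i, (i - 1) %/% 3 + 1] <- 0.85
  expect_equal(unname(auc_ovr(labs2, P2)), rep(1, 4))
  # uninformative scores sit near 1/2
  set.seed(3)
  n <- 4000
  labs3 <- sample(hs_classes(), n, replace = TRUE)
  P3 <- matrix(runif(n * 4), n, 4); P3 <- P3 / rowSums(P3)
  expect_true(all(abs(auc_ovr(labs3, P3) - 0.5) < 0.04))
  # invariant under strictly monotone transforms of the scores
  a1 <- auc_ovr(labs3, P3)
  a2 <- auc_ovr(labs3, exp(3 * P3))
  expect_equal(a1, a2)
  expect_error(auc_ovr(rep("panic", 4), P3[1:4, ]),
               class = "hierscore_degenerate_class")
})

test_that("rank-based AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(8)
  n <- 300
  labs <- sample(hs_classes(), n, replace = TRUE, prob = c(.4, .3, .2, .1))
  P <- matrix(runif(n * 4), n, 4); P <- P / rowSums(P)
  mine <- auc_ovr(labs, P)
  for (ci in seq_along(hs_classes())) {
    ref <- suppressMessages(pROC::auc(
      as.integer(labs == hs_classes()[[ci]]), P[, ci],
      direction = "<", quiet = TRUE))
    expect_equal(unname(mine[[ci]]), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("model evaluation is internally consistent across modes", {
  schema <- fixture_schema()
  tr <- fixture_trained()
  y_all <- cohort_labels(tr$cohort)
  idx <- unlist(lapply(levels(y_all), function(cl) which(y_all == cl)[1:20]))
  coh <- tr$cohort[sort(idx)]
  # dropout 0: point and MCD evaluation coincide
  m0 <- tr$model; m0$dropout_rate <- 0
  ev_pt <- evaluate_model(m0, coh, "point", schema = schema)
  ev_mc <- evaluate_model(m0, coh, "mcd", n_samples = 20, seed = 1,
                          schema = schema)
  expect_equal(ev_pt$per_class, ev_mc$per_class)
  expect_identical(unclass(ev_pt$confusion), unclass(ev_mc$confusion))
  # the metric table equals metrics_from_confusion of its own confusion
  again <- metrics_from_confusion(ev_pt$confusion,
                                  auc = auc_ovr(cohort_labels(coh),
                                                ev_pt$probabilities))
  expect_equal(ev_pt$per_class, again$per_class)
  expect_equal(ev_pt$balanced_accuracy, again$balanced_accuracy)
})

test_that("a memorized tiny cohort evaluates perfectly on itself", {
  schema <- fixture_schema()
  coh <- fixture_cohort(n = 40, effect = 0.6, seed = 77)
  m <- train_model(build_model(schema, seed = 2), coh,
                   train_config(epochs = 400, reg_factor = 1e-4, seed = 2),
                   schema)
  ev <- evaluate_model(m, coh, "point", schema = schema)
  expect_equal(ev$balanced_accuracy, 1)
})
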