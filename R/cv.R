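# Stratified k-fold cross-validation of the regularization factor.

#' Cross-validate the regularization type and factor
#'
#' Runs seeded stratified k-fold cross-validation over a grid of
#' regularization factors for one or both penalty types, scoring each fold
#' by balanced accuracy (mean per-class recall) on the held-out fold, and
#' selects the factor with the best mean score per penalty type (ties toward
#' the smaller factor).
#'
#' @param cohort A labelled `hs_cohort`.
#' @param factors Numeric vector of candidate regularization factors.
#' @param reg_types Character vector, subset of `c("L1", "L2")`.
#' @param k_folds Number of folds (default 5).
#' @param config Base `hs_train_config`; its `reg_type`/`reg_factor` are
#'   overridden per grid point.
#' @param seed Integer seed for fold assignment (training seeds derive from
#'   it deterministically).
#' @param schema An `hs_schema` registry.
#' @return List with `folds` (long data.frame: reg_type, factor, fold,
#'   balanced_accuracy), `table` (mean per grid point) and `selected`
#'   (named numeric vector, best factor per reg_type).
#' @export
cross_validate_regularization <- function(cohort,
                                          factors = c(1e-4, 1e-3, 1e-2),
                                          reg_types = c("L1", "L2"),
                                          k_folds = 5,
                                          config = train_config(),
                                          seed = 1,
                                          schema = load_schema()) {
  stopifnot(is_cohort(cohort), length(factors) >= 1,
            all(reg_types %in% c("L1", "L2")), k_folds >= 2)
  y <- cohort_labels(cohort)
  if (is.null(y))
    hs_error("hierscore_unlabelled_cohort", "cross-validation needs labels")
  counts <- table(y)
  if (any(counts < k_folds))
    hs_error("hierscore_fold_too_small",
             paste0("classes with fewer records than folds: ",
                    paste(names(counts)[counts < k_folds], collapse = ", ")))
  # stratified fold assignment: shuffle within class, deal round-robin
  fold <- integer(length(y))
  with_seed(seed, {
    for (ci in levels(y)) {
      idx <- sample(which(y == ci))
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  })
  rows <- list()
  for (rt in reg_types) {
    for (fac in factors) {
      for (k in seq_len(k_folds)) {
        cfg <- config
        cfg$reg_type <- rt
        cfg$reg_factor <- fac
        cfg$seed <- as.integer((seed * 1009L + k) %% .Machine$integer.max)
        tr <- cohort[fold != k]
        te <- cohort[fold == k]
        m <- build_model(schema, seed = cfg$seed,
                         dropout_rate = cfg$dropout_rate,
                         nonneg_score_weights = cfg$nonneg_score_weights)
        m <- train_model(m, tr, cfg, schema)
        pred <- predict(m, te, type = "class", schema = schema)
        ba <- balanced_accuracy(cohort_labels(te), pred)
        rows[[length(rows) + 1L]] <-
          data.frame(reg_type = rt, factor = fac, fold = k,
                     balanced_accuracy = ba)
      }
    }
  }
  folds <- do.call(rbind, rows)
  tab <- stats::aggregate(balanced_accuracy ~ reg_type + factor, folds, mean)
  names(tab)[names(tab) == "balanced_accuracy"] <- "mean_balanced_accuracy"
  tab <- tab[order(tab$reg_type, tab$factor), ]
  rownames(tab) <- NULL
  selected <- vapply(reg_types, function(rt) {
    sub <- tab[tab$reg_type == rt, ]
    sub$factor[[which.max(sub$mean_balanced_accuracy)]]
  }, numeric(1))
  list(folds = folds, table = tab, selected = selected, fold_assignment = fold)
}
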