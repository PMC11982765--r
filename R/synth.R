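# Class-conditional synthetic cohort generator and stratified splitting.

# run expr with a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic largest-remainder apportionment of n into shares p;
# ties broken by position
apportion <- function(n, p) {
  raw <- p / sum(p) * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    frac <- raw - k
    ord <- order(-frac, seq_along(frac))
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  }
  as.integer(k)
}

#' Synthetic cohort configuration
#'
#' Defines the generative conditions for [generate_cohort()]. Defaults mirror
#' the clinical cohort the model targets: 1068 patients in class proportions
#' 33.6/33.6/24.1/8.7% (depression, panic, social phobia, specific phobia),
#' each class elevated on its signature instrument (PHQ-9, PDSS, SIAS and the
#' Fear Questionnaire avoidance items respectively).
#'
#' @param n_total Number of records (>= 4).
#' @param class_proportions Four non-negative proportions summing to 1.
#' @param effect_size Upward shift of the class-signature instrument's items,
#'   in units of item-range fraction (0 = label carries no signal).
#' @param within_instrument_correlation Correlation of item responses within
#'   one instrument, in \[0, 1).
#' @param demographic_coupling Strength of the mild class association of the
#'   APP/DAD dummies and HasPhobia, in \[0, 1\].
#' @param seed Integer seed; identical `(config, seed)` gives identical
#'   cohorts.
#' @param class_counts Optional exact per-class counts (overrides
#'   `n_total`/`class_proportions`).
#' @return A list of class `hs_cohort_config`.
#' @export
cohort_config <- function(n_total = 1068, class_proportions = c(0.336, 0.336, 0.241, 0.087),
                          effect_size = 0.4,
                          within_instrument_correlation = 0.5,
                          demographic_coupling = 0.3,
                          seed = 1, class_counts = NULL) {
  if (!is.null(class_counts)) {
    stopifnot(length(class_counts) == 4, all(class_counts >= 0))
    n_total <- sum(class_counts)
    class_proportions <- class_counts / n_total
  }
  if (n_total < 4 || abs(sum(class_proportions) - 1) > 1e-9 ||
      any(class_proportions < 0) || effect_size < 0 ||
      within_instrument_correlation < 0 || within_instrument_correlation >= 1)
    hs_error("hierscore_invalid_config", "invalid cohort configuration")
  structure(list(n_total = as.integer(n_total),
                 class_proportions = class_proportions,
                 effect_size = effect_size,
                 within_instrument_correlation = within_instrument_correlation,
                 demographic_coupling = demographic_coupling,
                 seed = as.integer(seed),
                 class_counts = if (is.null(class_counts)) NULL else as.integer(class_counts)),
            class = "hs_cohort_config")
}

#' Configuration preset matching the reference clinical cohort layout
#'
#' Class totals 358/359/257/94 (N = 1068), chosen so the default 75% stratified
#' split lands exactly on 269/269/193/70 training and 89/90/64/24 test
#' records per class.
#'
#' @param seed Integer seed.
#' @param effect_size See [cohort_config()]; default 0.6 gives well-separated
#'   classes.
#' @param ... Further arguments to [cohort_config()].
#' @return An `hs_cohort_config`.
#' @export
reference_cohort_config <- function(seed = 1, effect_size = 0.6, ...) {
  cohort_config(class_counts = c(358L, 359L, 257L, 94L), seed = seed,
                effect_size = effect_size, ...)
}

# instrument groups for latent generation; the signature entry names the
# group shifted upward for each class
.gen_groups <- function(schema) {
  list(phq = schema$score_nodes$phq,
       gad = schema$score_nodes$gad,
       sias = schema$score_nodes$sias,
       pdss = schema$score_nodes$pdss,
       fq_avoid = paste0("Fq", 1:18),
       fq_distress = paste0("Fq", 19:24),
       mansa = c("MansaTen", "MansaTwentyFour", "MansaTwentyFive"))
}

.gen_signature <- c(depression = "phq", panic = "pdss",
                    social_phobia = "sias", specific_phobia = "fq_avoid")

# fixed demographic marginal tables (plausible for an internet-delivered
# CBT clinic population; values are a design choice, documented in the
# methods vignette)
.gen_marginals <- list(
  Education = c(0.06, 0.14, 0.20, 0.20, 0.25, 0.10, 0.05),
  AlcoholIntake = c(0.35, 0.35, 0.15, 0.08, 0.05, 0.02),
  UseOfDrugs = c(0.92, 0.08),
  CurrentMedication = c(0.55, 0.12, 0.13, 0.20),
  DAD = c(0.40, 0.25, 0.20, 0.15),
  INC = c(0.34, 0.08, 0.18, 0.08, 0.16, 0.08, 0.08),
  APP = c(0.35, 0.25, 0.25, 0.15)
)

# sample one categorical level index per row of a prob matrix
.sample_cat <- function(pmat) {
  u <- stats::runif(nrow(pmat))
  cum <- t(apply(pmat, 1, cumsum))
  1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
}

#' Generate a synthetic cohort
#'
#' Per record, a class label is assigned (deterministic largest-remainder
#' apportionment of the configured proportions, then shuffled), and each
#' instrument's items are produced from a shared latent severity draw: item
#' latents are `mu + sqrt(rho) g + sqrt(1-rho) e` with `g` per instrument and
#' `e` per item, discretized through equal-probability normal thresholds onto
#' the item's allowed values. The class-signature instrument's latent mean is
#' shifted upward by `4 * effect_size`, which moves the expected item value
#' by roughly `effect_size` of the item range near the middle of the scale.
#' Demographics come from fixed marginal tables with a mild, configurable
#' class coupling on APP/DAD/HasPhobia. Reverse-scored SIAS items are emitted
#' on the inverted raw scale so that higher severity means a lower raw value.
#'
#' @param config An `hs_cohort_config`.
#' @param schema An `hs_schema` registry.
#' @return A labelled `hs_cohort`; identical `(config, seed)` yields an
#'   identical cohort.
#' @export
generate_cohort <- function(config = cohort_config(), schema = load_schema()) {
  stopifnot(inherits(config, "hs_cohort_config"))
  n <- config$n_total
  counts <- if (!is.null(config$class_counts)) config$class_counts else
    apportion(n, config$class_proportions)
  rho <- config$within_instrument_correlation
  cpl <- config$demographic_coupling
  groups <- .gen_groups(schema)

  with_seed(config$seed, {
    labels <- sample(rep(schema$classes, counts))
    df <- as.data.frame(matrix(0L, n, length(schema$feature_order),
                               dimnames = list(NULL, schema$feature_order)))
    # questionnaire items from latent severities
    for (g in names(groups)) {
      items <- groups[[g]]
      mu_base <- if (g == "mansa") 0.2 else -0.5
      mu <- rep(mu_base, n)
      sig <- labels %in% names(.gen_signature)[.gen_signature == g]
      mu[sig] <- mu[sig] + 4 * config$effect_size
      latent_shared <- stats::rnorm(n)
      for (nm in items) {
        a <- schema$allowed[[nm]]
        K <- length(a)
        cuts <- stats::qnorm(seq_len(K - 1) / K)
        u <- mu + sqrt(rho) * latent_shared + sqrt(1 - rho) * stats::rnorm(n)
        idx <- 1L + rowSums(outer(u, cuts, ">"))
        val <- a[idx]
        i <- match(nm, schema$feature_order)
        if (schema$features$reverse[[i]]) val <- max(a) + min(a) - val
        df[[nm]] <- as.integer(val)
      }
    }
    # plain demographics
    for (nm in c("Education", "AlcoholIntake", "UseOfDrugs",
                 "CurrentMedication")) {
      p <- .gen_marginals[[nm]]
      df[[nm]] <- schema$allowed[[nm]][
        .sample_cat(matrix(p, n, length(p), byrow = TRUE))]
    }
    # HasPhobia: more frequent in the phobia classes
    p1 <- ifelse(labels %in% c("social_phobia", "specific_phobia"),
                 0.15 + 0.5 * cpl, 0.15)
    df$HasPhobia <- as.integer(stats::runif(n) < p1)
    # one-hot groups with mild class coupling
    boost <- 1 + 2 * cpl
    pdad <- matrix(.gen_marginals$DAD, n, 4, byrow = TRUE)
    pdad[labels == "depression", 2] <- pdad[labels == "depression", 2] * boost
    pdad[labels != "depression", 3] <- pdad[labels != "depression", 3] * boost
    pdad <- pdad / rowSums(pdad)
    dad <- .sample_cat(pdad)
    for (i in 0:3) df[[paste0("DAD", i)]] <- as.integer(dad == i + 1L)
    pinc <- matrix(.gen_marginals$INC, n, 7, byrow = TRUE)
    inc <- .sample_cat(pinc)
    for (i in 1:7) df[[paste0("INC_", i)]] <- as.integer(inc == i)
    papp <- matrix(.gen_marginals$APP, n, 4, byrow = TRUE)
    papp[labels == "depression", 2] <- papp[labels == "depression", 2] * boost
    papp[labels != "depression", 1] <- papp[labels != "depression", 1] * boost
    papp <- papp / rowSums(papp)
    app <- .sample_cat(papp)
    for (i in 1:4) df[[paste0("APP_", i)]] <- as.integer(app == i)

    as_cohort(df, labels = labels, schema = schema, validate = FALSE,
              provenance = list(generator = "generate_cohort",
                                config = unclass(config)))
  })
}

#' Stratified train/test split
#'
#' Splits per class as close to `train_fraction` as integer rounding allows:
#' the total training size is `round(train_fraction * n)` and per-class
#' training counts are assigned by largest-remainder apportionment (ties by
#' class order), then record membership is drawn at random within class.
#'
#' @param cohort A labelled `hs_cohort`.
#' @param train_fraction Fraction of records for training, in (0, 1).
#' @param seed Integer seed for the within-class shuffle.
#' @return List with elements `train` and `test`, both `hs_cohort`s; their
#'   union is the input and their intersection is empty.
#' @export
stratified_split <- function(cohort, train_fraction = 0.75, seed = 1) {
  stopifnot(is_cohort(cohort), train_fraction > 0, train_fraction < 1)
  y <- cohort_labels(cohort)
  if (is.null(y))
    hs_error("hierscore_unlabelled_cohort",
             "stratified_split needs a labelled cohort")
  n <- length(y)
  counts <- as.integer(table(y))
  target <- round(train_fraction * n)
  raw <- train_fraction * counts
  k <- pmin(floor(raw), counts)
  rem <- target - sum(k)
  frac <- raw - floor(raw)
  ord <- order(-frac, seq_along(frac))
  i <- 1L
  while (rem > 0 && i <= length(ord)) {
    j <- ord[[i]]
    if (k[[j]] < counts[[j]]) { k[[j]] <- k[[j]] + 1L; rem <- rem - 1L }
    i <- i + 1L
  }
  with_seed(seed, {
    train_idx <- integer(0)
    for (ci in seq_along(levels(y))) {
      idx <- which(as.integer(y) == ci)
      train_idx <- c(train_idx, sample(idx)[seq_len(k[[ci]])])
    }
    train_idx <- sort(train_idx)
    list(train = cohort[train_idx], test = cohort[-train_idx])
  })
}

#' Cohort sampled from a model's own generative distribution
#'
#' Features are drawn uniformly over their allowed values (one level per
#' one-hot group, uniformly), and labels are sampled from the model's point
#' class probabilities. Used as a ground-truth generator for parameter
#' recovery checks.
#'
#' @param model An `hs_model`.
#' @param n Number of records.
#' @param seed Integer seed.
#' @param schema An `hs_schema` registry.
#' @return A labelled `hs_cohort`.
#' @export
planted_weights_cohort <- function(model, n, seed = 1,
                                   schema = load_schema()) {
  stopifnot(inherits(model, "hs_model"), n >= 1)
  with_seed(seed, {
    df <- as.data.frame(matrix(0L, n, length(schema$feature_order),
                               dimnames = list(NULL, schema$feature_order)))
    grouped <- unlist(schema$onehot_groups, use.names = FALSE)
    for (nm in setdiff(schema$feature_order, grouped)) {
      a <- schema$allowed[[nm]]
      df[[nm]] <- a[sample.int(length(a), n, replace = TRUE)]
    }
    for (g in names(schema$onehot_groups)) {
      members <- schema$onehot_groups[[g]]
      lvl <- sample.int(length(members), n, replace = TRUE)
      for (j in seq_along(members))
        df[[members[[j]]]] <- as.integer(lvl == j)
    }
    X <- encode_cohort(df, schema, validate = FALSE)
    P <- forward_matrix(model, X)
    labels <- schema$classes[.sample_cat(P)]
    as_cohort(df, labels = labels, schema = schema, validate = FALSE,
              provenance = list(generator = "planted_weights_cohort",
                                seed = seed))
  })
}
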