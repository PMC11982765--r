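# Shared fixtures, built in code. Heavier objects (a trained model) are
# memoized per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture_schema <- function() {
  if (is.null(.fixture_env$schema)) .fixture_env$schema <- load_schema()
  .fixture_env$schema
}

# a minimal valid raw record: every ordinal at its minimum, first dummy of
# each one-hot group active
zero_record <- function(schema = fixture_schema()) {
  r <- lapply(schema$allowed, function(a) min(a))
  r$DAD0 <- 1L
  r$INC_1 <- 1L
  r$APP_1 <- 1L
  r
}

# a model whose every weight and bias is zero
zero_model <- function(schema = fixture_schema()) {
  m <- build_model(schema, seed = 1)
  for (g in names(m$score_weights)) m$score_weights[[g]][] <- 0
  for (s in names(m$second_weights)) m$second_weights[[s]][] <- 0
  m$W[] <- 0
  m$b[] <- 0
  m
}

# sparse ground-truth model for planted-weight recovery: unit score-layer
# weights, one dominant output weight per class on a distinct pseudosum
# node, and biases centring each class logit at zero under uniform features
# (node means: phq 5, pdss 3.5, sias 10, fq 2.5) so planted labels are
# roughly balanced
planted_truth_model <- function(schema = fixture_schema()) {
  gt <- zero_model(schema)
  for (g in names(gt$score_weights)) gt$score_weights[[g]][] <- 1
  gt$second_weights$fq_total[] <- 1
  gt$W["depression", "phq"] <- 3
  gt$W["panic", "pdss"] <- 3
  gt$W["social_phobia", "sias"] <- 3
  gt$W["specific_phobia", "fq"] <- 3
  gt$b[] <- -3 * c(5, 3.5, 10, 2.5)
  gt
}

# a small well-separated labelled cohort (memoized)
fixture_cohort <- function(n = 240, effect = 0.6, seed = 42) {
  key <- paste0("coh_", n, "_", effect, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(
      cohort_config(n_total = n, effect_size = effect, seed = seed),
      fixture_schema())
  .fixture_env[[key]]
}

# one trained model on the well-separated cohort, shared across test files
fixture_trained <- function() {
  if (is.null(.fixture_env$trained)) {
    schema <- fixture_schema()
    coh <- fixture_cohort(n = 400, effect = 0.6, seed = 42)
    m <- build_model(schema, seed = 42)
    .fixture_env$trained <- list(
      model = train_model(m, coh, train_config(epochs = 150, seed = 42),
                          schema),
      cohort = coh)
  }
  .fixture_env$trained
}

# random valid raw record (uniform over allowed values, one dummy per group)
random_record <- function(schema = fixture_schema()) {
  r <- lapply(schema$allowed, function(a) sample(a, 1))
  for (g in names(schema$onehot_groups)) {
    members <- schema$onehot_groups[[g]]
    for (nm in members) r[[nm]] <- 0L
    r[[sample(members, 1)]] <- 1L
  }
  r
}
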