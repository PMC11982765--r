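# Monte Carlo dropout inference: predictive distributions over repeated
# stochastic forward passes.

#' Monte Carlo dropout predictive distribution for one record
#'
#' Runs `n_samples` forward passes with fresh Bernoulli dropout masks (at
#' the model's dropout rate) before every weight layer, yielding a sampled
#' distribution of class-probability vectors. The per-class sample mean is
#' the prediction probability and the per-class sample variance the
#' epistemic uncertainty measure. Masks use inverted scaling, so a dropout
#' rate of 0 reproduces the point prediction exactly.
#'
#' @param model A trained `hs_model`.
#' @param x Encoded feature vector of length 91 (see [encode_record()]).
#' @param n_samples Number of stochastic passes (default 500).
#' @param seed Integer seed; identical `(model, x, n_samples, seed)` give an
#'   identical sample matrix.
#' @return An object of class `hs_mcd` with fields `samples` (N x 4), `mu`,
#'   `var`, `median`, `iqr`, `n_samples` and `point_class` (argmax of `mu`,
#'   ties toward the lowest class index).
#' @export
mcd_predict <- function(model, x, n_samples = 500, seed = 1) {
  stopifnot(inherits(model, "hs_model"))
  if (n_samples < 1)
    hs_error("hierscore_invalid_sample_count", "n_samples must be >= 1")
  p <- model$dropout_rate
  if (p == 0) {
    # degenerate case: every pass equals the point prediction exactly
    pt <- forward_point(model, x)
    samples <- matrix(pt, n_samples, length(pt), byrow = TRUE)
  } else {
    X <- matrix(rep(as.numeric(x), each = n_samples), nrow = n_samples)
    w <- hm_wiring_cached(model)
    samples <- with_seed(seed, {
      masks <- list(
        m1 = hm_mask(n_samples, ncol(X), p),
        m2 = stats::setNames(lapply(w$second, function(s)
          hm_mask(n_samples, length(w$second_subs[[s]]), p)), w$second),
        m3 = hm_mask(n_samples, length(w$output_nodes), p))
      hm_forward(model, X, masks)$P
    })
  }
  colnames(samples) <- model$classes
  mu <- colMeans(samples)
  new_mcd(samples, mu)
}

new_mcd <- function(samples, mu = colMeans(samples)) {
  vr <- apply(samples, 2, stats::var) * (nrow(samples) - 1) / nrow(samples)
  if (nrow(samples) == 1) vr <- stats::setNames(numeric(ncol(samples)),
                                                colnames(samples))
  # constant columns have exactly zero variance (no rounding residue)
  const <- apply(samples, 2, function(v) all(v == v[[1]]))
  vr[const] <- 0
  med <- apply(samples, 2, stats::median)
  iqr <- apply(samples, 2, function(v)
    diff(stats::quantile(v, c(0.25, 0.75), names = FALSE)))
  structure(list(samples = samples, n_samples = nrow(samples),
                 mu = mu, var = vr, median = med, iqr = iqr,
                 point_class = names(mu)[which.max(mu)]),
            class = "hs_mcd")
}

#' @export
print.hs_mcd <- function(x, ...) {
  cat("<hs_mcd> ", x$n_samples, " samples; point class: ", x$point_class,
      "\n", sep = "")
  print(round(rbind(mu = x$mu, sd = sqrt(x$var), median = x$median,
                    IQR = x$iqr), 4))
  invisible(x)
}

#' Summarize a Monte Carlo dropout distribution
#'
#' Per-class mean, variance (population convention), median, IQR and
#' 2.5/97.5 percentiles. Percentiles use linear interpolation between order
#' statistics (the only supported method).
#'
#' @param object An `hs_mcd` distribution.
#' @param ... Unused.
#' @return data.frame with one row per class.
#' @export
summary.hs_mcd <- function(object, ...) {
  if (object$n_samples < 1)
    hs_error("hierscore_empty_distribution", "empty MCD distribution")
  q <- apply(object$samples, 2, function(v)
    stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7))
  data.frame(class = colnames(object$samples),
             mu = unname(object$mu), var = unname(object$var),
             median = unname(object$median), iqr = unname(object$iqr),
             p2.5 = q[1, ], p97.5 = q[2, ], row.names = NULL)
}

#' Pairwise class-overlap report
#'
#' For each ordered class pair, the sampled exceedance probability: the
#' fraction of Monte Carlo samples in which the lower-mean class's
#' probability exceeds the higher-mean class's (exact ties count one half,
#' the Mann-Whitney convention). Pairs whose exceedance is above the
#' threshold are flagged as competing, signalling low model confidence.
#'
#' @param dist An `hs_mcd` distribution.
#' @param threshold Competing-pair flag threshold (default 0.05).
#' @return data.frame with columns `class_hi`, `class_lo`, `exceedance`,
#'   `competing`.
#' @export
overlap_report <- function(dist, threshold = 0.05) {
  stopifnot(inherits(dist, "hs_mcd"))
  if (dist$n_samples < 1)
    hs_error("hierscore_empty_distribution", "empty MCD distribution")
  cls <- colnames(dist$samples)
  ord <- order(-dist$mu, seq_along(dist$mu))
  rows <- list()
  for (a in seq_len(length(cls) - 1)) {
    for (b in (a + 1):length(cls)) {
      hi <- cls[ord[a]]; lo <- cls[ord[b]]
      d <- dist$samples[, lo] - dist$samples[, hi]
      exc <- mean((d > 0) + 0.5 * (d == 0))
      rows[[length(rows) + 1L]] <-
        data.frame(class_hi = hi, class_lo = lo, exceedance = exc,
                   competing = exc > threshold)
    }
  }
  do.call(rbind, rows)
}
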