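#' Single-state background (null) model
#'
#' The null model used by the log-odds feature: one state with
#' self-transition 1 and emissions equal to background residue frequencies
#' (typically estimated from training data via
#' [background_frequencies()]).
#'
#' @param freqs numeric vector of per-symbol frequencies (summing to 1).
#' @param alphabet residue alphabet.
#' @return A single-state [topology_model()] in table mode.
#' @export
null_model <- function(freqs, alphabet = aa_alphabet()) {
  stopifnot(length(freqs) == length(alphabet), all(freqs > 0))
  e <- matrix(freqs / sum(freqs), nrow = 1,
              dimnames = list("bg", NULL))
  topology_model(states = "bg", label_map = c(bg = "b"), begin = c(bg = 1),
                 trans = matrix(1, 1, 1), emissions = e,
                 alphabet = alphabet)
}

#' Background residue frequencies of a data set
#'
#' @param data list of [labeled_sequence()] objects.
#' @param alphabet residue alphabet.
#' @param pseudocount added per symbol so no frequency is zero.
#' @return Named numeric vector summing to 1.
#' @export
background_frequencies <- function(data, alphabet = aa_alphabet(),
                                   pseudocount = 1) {
  idx <- unlist(lapply(data, `[[`, "idx"))
  counts <- tabulate(idx[!is.na(idx)], nbins = length(alphabet)) +
    pseudocount
  stats::setNames(counts / sum(counts), alphabet)
}

#' Model-derived discrimination features for one sequence
#'
#' The feature vector used by the membrane-protein discriminator:
#' sequence length, log-odds score (`log P(x|model) - log P(x|null)`,
#' natural log), length-normalized log-probability (`log P(x|model) / L`),
#' max probability (maximum over positions of the chosen-label posterior),
#' decoder score, reliability score (mean chosen-label posterior), number of
#' TM segments, and TM/length ratio. The `beta6` subset (used for
#' beta-barrels) enters length, log-odds, log-probability, reliability,
#' segment count and TM ratio into the classifier; `alpha7` swaps
#' log-probability for max probability and decoder score.
#'
#' @param model scoring [topology_model()].
#' @param null the [null_model()].
#' @param seq a [labeled_sequence()].
#' @param prediction a decoded `prediction` for `seq` (e.g. from
#'   [posterior_label_decode()]).
#' @param subset `"beta6"` or `"alpha7"`.
#' @param tm_labels labels counted as TM.
#' @param profile optional profile.
#' @return One-row tibble with all features and the subset flag, or `NULL`
#'   (with a warning) when the model score is `-Inf`.
#' @export
extract_features <- function(model, null, seq, prediction,
                             subset = c("beta6", "alpha7"),
                             tm_labels = "M", profile = NULL) {
  subset <- match.arg(subset)
  stopifnot(inherits(prediction, "prediction"))
  L <- length(seq)
  lp_model <- forward(model, seq, profile = profile)$loglik
  lp_null <- forward(null, seq)$loglik
  if (!is.finite(lp_model) || !prediction$ok) {
    warning("excluding '", seq$id, "': -Inf model score")
    return(NULL)
  }
  tm_segs <- class_segments(project_tm(prediction$labels, tm_labels), TRUE)
  tibble::tibble(
    id = seq$id,
    length = L,
    log_odds = lp_model - lp_null,
    log_probability = lp_model / L,
    max_probability = max(prediction$chosen_posterior),
    decoder_score = prediction$score,
    reliability = reliability(prediction),
    n_tm_segments = nrow(tm_segs),
    tm_ratio = sum(project_tm(prediction$labels, tm_labels)) / L,
    subset = subset)
}

feature_columns <- function(subset) {
  if (subset == "beta6")
    c("length", "log_odds", "log_probability", "reliability",
      "n_tm_segments", "tm_ratio")
  else
    c("length", "log_odds", "max_probability", "decoder_score",
      "reliability", "n_tm_segments", "tm_ratio")
}

#' Fit the logistic discrimination classifier
#'
#' Maximum-likelihood logistic regression on standardized features with a
#' small L2 ridge (`1e-6`) on the slopes for numerical stability, fitted by
#' BFGS with the analytic gradient. Deterministic: refitting on identical
#' data gives identical coefficients.
#'
#' @param features data frame of feature rows (see [extract_features()]).
#' @param class_labels logical or 0/1 vector: `TRUE`/1 for the
#'   membrane-protein class.
#' @param subset feature subset, `"beta6"` or `"alpha7"`; defaults to the
#'   `subset` column of `features` when present.
#' @param ridge L2 penalty on slope coefficients.
#' @return Object of class `logit_discriminator` with coefficients and the
#'   standardization parameters.
#' @export
fit_logistic <- function(features, class_labels, subset = NULL,
                         ridge = 1e-6) {
  y <- as.numeric(class_labels)
  stopifnot(length(y) == nrow(features))
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit the discriminator")
  if (is.null(subset))
    subset <- if ("subset" %in% names(features)) features$subset[1]
              else "beta6"
  cols <- feature_columns(subset)
  X <- as.matrix(features[, cols])
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(X, center, scl)
  softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  nll <- function(b) {
    eta <- as.vector(b[1] + Z %*% b[-1])
    -sum(y * eta - softplus(eta)) + 0.5 * ridge * sum(b[-1]^2)
  }
  gr <- function(b) {
    eta <- as.vector(b[1] + Z %*% b[-1])
    p <- 1 / (1 + exp(-eta))
    r <- p - y
    c(sum(r), as.vector(crossprod(Z, r)) + ridge * b[-1])
  }
  fit <- stats::optim(rep(0, length(cols) + 1L), nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(list(coef = stats::setNames(fit$par, c("(Intercept)", cols)),
                 center = center, scale = scl, subset = subset,
                 ridge = ridge, deviance = 2 * fit$value, n = length(y),
                 converged = fit$convergence == 0),
            class = "logit_discriminator")
}

#' @export
print.logit_discriminator <- function(x, ...) {
  cat("<logit_discriminator> (", x$subset, " features, n = ", x$n, ")\n",
      sep = "")
  print(round(x$coef, 4))
  invisible(x)
}

#' Tidy discriminator coefficients
#'
#' @param x a `logit_discriminator`.
#' @param ... unused.
#' @return Tibble with `term` and `estimate` (on the standardized scale).
#' @export
tidy.logit_discriminator <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' Discriminator fit summary
#'
#' @param x a `logit_discriminator`.
#' @param ... unused.
#' @return One-row tibble: `n`, `deviance`, `converged`, `subset`.
#' @export
glance.logit_discriminator <- function(x, ...) {
  tibble::tibble(n = x$n, deviance = x$deviance, converged = x$converged,
                 subset = x$subset)
}

#' Classify feature vectors
#'
#' @param classifier a fitted `logit_discriminator`.
#' @param features data frame of feature rows.
#' @param threshold decision threshold on the membrane-class probability.
#' @return Tibble with `probability` and logical `decision`.
#' @export
classify <- function(classifier, features, threshold = 0.5) {
  cols <- feature_columns(classifier$subset)
  missing <- setdiff(cols, names(features))
  if (length(missing) > 0L)
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  Z <- scale(as.matrix(features[, cols]), classifier$center,
             classifier$scale)
  eta <- classifier$coef[1] + as.vector(Z %*% classifier$coef[-1])
  p <- 1 / (1 + exp(-eta))
  tibble::tibble(probability = p, decision = p >= threshold)
}

#' Cross-validated discrimination performance
#'
#' Seeded k-fold cross-validation of [fit_logistic()]/[classify()]:
#' each fold is held out once, and the pooled held-out decisions are
#' summarized with [binary_stats()].
#'
#' @param features feature data frame.
#' @param class_labels logical/0-1 class vector.
#' @param folds number of folds.
#' @param seed fold-assignment seed.
#' @param subset feature subset.
#' @param threshold decision threshold.
#' @return One-row tibble: sensitivity, specificity, MCC over pooled
#'   held-out predictions.
#' @export
cv_discriminate <- function(features, class_labels, folds = 5, seed = 1,
                            subset = NULL, threshold = 0.5) {
  y <- as.logical(class_labels)
  n <- length(y)
  stopifnot(folds >= 2, folds <= n)
  assign <- withr::with_seed(seed,
                             sample(rep_len(seq_len(folds), n)))
  dec <- logical(n)
  for (f in seq_len(folds)) {
    test <- assign == f
    cls <- fit_logistic(features[!test, , drop = FALSE], y[!test],
                        subset = subset)
    dec[test] <- classify(cls, features[test, , drop = FALSE],
                          threshold)$decision
  }
  binary_stats(tp = sum(dec & y), fp = sum(dec & !y),
               tn = sum(!dec & !y), fn = sum(!dec & y))
}
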