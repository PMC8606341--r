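#' Viterbi decoding
#'
#' Most-probable single state path, `argmax_pi P(x, pi | theta)`, computed
#' in log space. Ties are broken toward the lowest state index at every
#' backtrack step. Provided for completeness: for discriminatively trained
#' models the optimal-accuracy posterior decoder
#' ([posterior_label_decode()]) is the recommended choice.
#'
#' @param model a [topology_model()].
#' @param seq a [labeled_sequence()].
#' @param profile optional profile.
#' @param E optional precomputed emission scores.
#' @return A `prediction` object (see [posterior_label_decode()]) with the
#'   Viterbi state path in `$states`; `decoder_score` is the log path score
#'   per residue. An all `-Inf` score yields a flagged empty prediction
#'   (`ok = FALSE`).
#' @export
viterbi <- function(model, seq, profile = NULL, E = NULL) {
  if (is.null(E)) E <- emission_scores(model, seq, profile)
  S <- length(model$states)
  L <- nrow(E)
  logE <- log(E)
  logT <- suppressWarnings(log(model$trans))
  logT[!model$allowed] <- -Inf
  V <- matrix(-Inf, L, S)
  back <- matrix(0L, L, S)
  V[1, ] <- suppressWarnings(log(model$begin)) + logE[1, ]
  if (L > 1L) for (i in 2:L) {
    for (l in seq_len(S)) {
      cand <- V[i - 1L, ] + logT[, l]
      k <- which.max(cand)   # first (lowest-index) maximizer
      V[i, l] <- cand[k] + logE[i, l]
      back[i, l] <- k
    }
  }
  final <- V[L, ]
  ei <- end_index(model)
  if (!is.null(ei)) final[-ei] <- -Inf
  if (!any(is.finite(final))) {
    return(structure(list(id = seq$id, ok = FALSE, labels = character(0),
                          states = character(0), decoder = "viterbi",
                          score = -Inf),
                     class = "prediction"))
  }
  path <- integer(L)
  path[L] <- which.max(final)
  if (L > 1L) for (i in L:2) path[i - 1L] <- back[i, path[i]]
  lp <- label_posterior_matrix(model, seq, E)
  labels <- unname(model$label_map[model$states[path]])
  chosen <- lp[cbind(seq_len(L), match(labels, colnames(lp)))]
  structure(list(id = seq$id, ok = TRUE, labels = labels,
                 states = model$states[path],
                 label_posteriors = lp, chosen_posterior = chosen,
                 decoder = "viterbi", score = final[path[L]] / L),
            class = "prediction")
}

# Free-phase per-position label posteriors: states aggregated by label.
label_posterior_matrix <- function(model, seq, E) {
  g <- state_posteriors(model, seq, "free", E = E)
  labs <- model$labels
  lp <- vapply(labs, function(lb) {
    cols <- which(model$label_map[model$states] == lb)
    if (length(cols) == 1L) g[, cols] else rowSums(g[, cols, drop = FALSE])
  }, numeric(nrow(g)))
  lp <- matrix(lp, nrow = nrow(g), dimnames = list(NULL, labs))
  lp
}

#' Optimal-accuracy posterior label decoding
#'
#' Per-position label posteriors are the free-phase state posteriors
#' aggregated over states sharing a label. A dynamic program over the state
#' graph then maximizes the sum of chosen-label posteriors over all label
#' sequences realizable by an allowed state path — so grammar constraints
#' (label adjacency and minimum segment lengths enforced by chained states)
#' are respected exactly. The decoder score is the maximized mean
#' per-position posterior. Ties break toward the lowest state index.
#'
#' @inheritParams viterbi
#' @return A `prediction`: list with `labels`, `states` (a realizing state
#'   path), `label_posteriors` (`L x |labels|`, rows summing to 1),
#'   `chosen_posterior`, `score`, `decoder`, `ok`.
#' @export
posterior_label_decode <- function(model, seq, profile = NULL, E = NULL) {
  if (is.null(E)) E <- emission_scores(model, seq, profile)
  f <- forward(model, seq, E = E)
  if (!f$ok)
    return(structure(list(id = seq$id, ok = FALSE, labels = character(0),
                          states = character(0), decoder = "posterior",
                          score = -Inf),
                     class = "prediction"))
  lp <- label_posterior_matrix(model, seq, E)
  S <- length(model$states)
  L <- nrow(lp)
  state_lab <- match(model$label_map[model$states], colnames(lp))
  V <- matrix(-Inf, L, S)
  back <- matrix(0L, L, S)
  V[1, ] <- ifelse(model$begin > 0, lp[1, state_lab], -Inf)
  if (L > 1L) for (i in 2:L) {
    for (l in seq_len(S)) {
      pred <- which(model$allowed[, l])
      if (length(pred) == 0L) next
      cand <- V[i - 1L, pred]
      k <- which.max(cand)
      if (!is.finite(cand[k])) next
      V[i, l] <- cand[k] + lp[i, state_lab[l]]
      back[i, l] <- pred[k]
    }
  }
  final <- V[L, ]
  ei <- end_index(model)
  if (!is.null(ei)) final[-ei] <- -Inf
  if (!any(is.finite(final)))
    stop("grammar admits no valid label sequence for '", seq$id, "'")
  path <- integer(L)
  path[L] <- which.max(final)
  if (L > 1L) for (i in L:2) path[i - 1L] <- back[i, path[i]]
  labels <- unname(model$label_map[model$states[path]])
  chosen <- lp[cbind(seq_len(L), match(labels, colnames(lp)))]
  structure(list(id = seq$id, ok = TRUE, labels = labels,
                 states = model$states[path],
                 label_posteriors = lp, chosen_posterior = chosen,
                 decoder = "posterior", score = final[path[L]] / L),
            class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  cat("<prediction> ", x$id, " (", x$decoder, " decoder, score ",
      format(x$score), ")\n", sep = "")
  if (x$ok)
    cat("  ", paste(utils::head(x$labels, 60), collapse = ""), "\n",
        sep = "")
  invisible(x)
}

#' Maximal label runs as segments
#'
#' @param labels character vector of per-position labels (or a single
#'   string).
#' @return Tibble with 1-based closed intervals: columns `start`, `end`,
#'   `label`, in sequence order; concatenating the runs reproduces the
#'   input.
#' @export
#' @examples
#' segments(c("M", "M", "i", "i"))
segments <- function(labels) {
  if (length(labels) == 1L && nchar(labels[1]) > 1L)
    labels <- strsplit(labels, "")[[1]]
  stopifnot(length(labels) > 0)
  r <- rle(labels)
  end <- cumsum(r$lengths)
  tibble::tibble(start = end - r$lengths + 1L, end = end, label = r$values)
}

#' Reliability of a decoded prediction
#'
#' Mean over positions of the posterior probability of the chosen label —
#' the package's reliability score, also used as a discrimination feature.
#'
#' @param prediction a `prediction` object.
#' @return Scalar in `[0, 1]`.
#' @export
reliability <- function(prediction) {
  stopifnot(inherits(prediction, "prediction"), prediction$ok)
  mean(prediction$chosen_posterior)
}

#' Write predictions and per-position posteriors
#'
#' Writes the decoded labelings in the 3-line label format and, per protein,
#' a TSV of per-position label posteriors (`position`, one column per label,
#' `chosen`). Reported coordinates are 1-based closed intervals.
#'
#' @param predictions list of `prediction` objects.
#' @param seqs matching list of sequences.
#' @param dir output directory.
#' @return Path of the label file, invisibly.
#' @export
write_predictions <- function(predictions, seqs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labeled <- Map(function(p, s) {
    labeled_sequence(s$id, paste(s$chars, collapse = ""),
                     paste(p$labels, collapse = ""),
                     alphabet = attr(s, "alphabet"))
  }, predictions, seqs)
  path <- file.path(dir, "predictions.lab")
  write_labels(labeled, path)
  for (p in predictions) {
    df <- data.frame(position = seq_along(p$labels),
                     p$label_posteriors, chosen = p$labels,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(p$id, ".posteriors.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Plot per-position label posteriors of a prediction
#'
#' @param object a `prediction`.
#' @param ... unused.
#' @return A ggplot: one line per label across positions.
#' @export
autoplot.prediction <- function(object, ...) {
  stopifnot(object$ok)
  lp <- object$label_posteriors
  df <- data.frame(
    position = rep(seq_len(nrow(lp)), ncol(lp)),
    label = rep(colnames(lp), each = nrow(lp)),
    posterior = as.vector(lp))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$posterior,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = object$id,
                  subtitle = paste0(object$decoder, " decoder"),
                  y = "label posterior") +
    ggplot2::theme_minimal()
}
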