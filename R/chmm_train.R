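#' Conditional maximum likelihood loss for one sequence
#'
#' The discriminative training objective is the negative conditional
#' log-likelihood `l = lc - lf`, with `lc = -log P(x, y | theta)` (clamped
#' phase) and `lf = -log P(x | theta)` (free phase). In CHMM mode
#' `P(x, y) <= P(x)`, so `l >= 0` up to rounding; infeasible labels give
#' `l = +Inf` with `ok = FALSE`.
#'
#' @param model a [topology_model()].
#' @param seq a labeled [labeled_sequence()].
#' @param labels label vector (defaults to `seq$labels`).
#' @param profile optional profile.
#' @param E optional precomputed emission scores.
#' @return Object of class `cml_loss`: list with `lc`, `lf`, `loss`, `ok`.
#' @export
cml_loss <- function(model, seq, labels = seq$labels, profile = NULL,
                     E = NULL) {
  if (is.null(E)) E <- emission_scores(model, seq, profile)
  f <- forward(model, seq, E = E)
  c <- clamped_forward(model, seq, labels, E = E)
  lc <- -c$loglik
  lf <- -f$loglik
  structure(list(lc = lc, lf = lf, loss = lc - lf,
                 ok = is.finite(lc) && is.finite(lf)),
            class = "cml_loss")
}

#' @export
print.cml_loss <- function(x, ...) {
  cat("<cml_loss> l = ", format(x$loss), "  (lc = ", format(x$lc),
      ", lf = ", format(x$lf), ")\n", sep = "")
  invisible(x)
}

# Expected transition counts n_kl and begin counts under one phase's
# forward/backward pair. E must be the same (possibly label-masked) matrix
# the trellises were computed from.
expected_counts <- function(model, fwd, bwd, E) {
  L <- nrow(E); S <- ncol(E)
  n <- matrix(0, S, S)
  if (L > 1L) for (i in seq_len(L - 1L)) {
    xi <- (fwd$alpha[i, ] %o% (E[i + 1L, ] * bwd$beta[i + 1L, ])) *
      model$trans / fwd$scale[i + 1L]
    n <- n + xi
  }
  g <- fwd$alpha * bwd$beta
  g <- g / rowSums(g)
  list(trans = n / sum(fwd$alpha[L, ] * bwd$beta[L, ]) *
         sum(g[L, ]), begin = g[1, ], gamma = g)
}

#' Gradient of the CML loss in unconstrained transition parameters
#'
#' Transitions are reparameterized as row-normalized exponentials of
#' unconstrained reals `z_kl` over structurally allowed entries (softmax
#' rows); the begin distribution is reparameterized the same way. The
#' analytic gradient of the summed loss over a batch is built from the
#' difference of free and clamped expected transition counts chained through
#' the normalization; structurally forbidden entries carry gradient exactly
#' 0.
#'
#' @param model a [topology_model()].
#' @param batch list of labeled sequences.
#' @param profiles optional list of profiles aligned with `batch`.
#' @return List with matrices/vectors `trans` (gradient in `z_kl`) and
#'   `begin`.
#' @export
cml_transition_gradients <- function(model, batch, profiles = NULL) {
  S <- length(model$states)
  gt <- matrix(0, S, S, dimnames = dimnames(model$trans))
  gb <- stats::setNames(numeric(S), model$states)
  for (j in seq_along(batch)) {
    seq <- batch[[j]]
    E <- emission_scores(model, seq,
                         if (!is.null(profiles)) profiles[[j]])
    d <- count_difference(model, seq, E)
    gt <- gt + d$trans
    gb <- gb + d$begin
  }
  # chain through row softmax: d l / d z_kl = d_kl - a_kl * sum_l' d_kl'
  out_t <- gt - model$trans * rowSums(gt)
  out_t[!model$allowed] <- 0
  out_b <- gb - model$begin * sum(gb)
  out_b[model$begin == 0] <- 0
  list(trans = out_t, begin = out_b)
}

# (free - clamped) expected count difference for one sequence.
count_difference <- function(model, seq, E) {
  ff <- forward(model, seq, E = E)
  fb <- backward(model, seq, E = E, fwd = ff)
  cf <- clamped_forward(model, seq, E = E)
  cb <- clamped_backward(model, seq, E = E, fwd = cf)
  if (!ff$ok || !cf$ok)
    stop("CML gradient undefined: -Inf likelihood for '", seq$id, "'")
  Ec <- E * label_mask(model, seq$labels)
  nf <- expected_counts(model, ff, fb, E)
  nc <- expected_counts(model, cf, cb, Ec)
  list(trans = nf$trans - nc$trans, begin = nf$begin - nc$begin,
       gamma_free = nf$gamma, gamma_clamped = nc$gamma,
       loss = ff$loglik - cf$loglik)
}

#' Labeled Baum-Welch (maximum likelihood) training of a CHMM
#'
#' Iterates the clamped expected-count E-step and row-normalizing M-step for
#' transitions, begin probabilities, and (tied) emission tables, maximizing
#' the joint likelihood `P(x, y | theta)` of sequences and labels. The joint
#' log-likelihood is non-decreasing each iteration (EM property); iteration
#' stops when its change drops below `tol` or after `max_iter` iterations.
#' Re-estimated probabilities are floored at `pseudocount` (then
#' renormalized) so no allowed parameter collapses to a hard zero;
#' structural zeros stay exactly 0.
#'
#' @param model a [topology_model()] in CHMM (emission-table) mode.
#' @param data list of labeled sequences.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the joint log-likelihood change.
#' @param pseudocount floor applied to re-estimated probabilities.
#' @return The re-estimated [topology_model()], with attribute
#'   `loglik_trace` (joint log-likelihood per iteration, evaluated at the
#'   parameters entering the iteration).
#' @export
baum_welch_labeled <- function(model, data, max_iter = 200, tol = 1e-6,
                               pseudocount = 1e-10) {
  stopifnot(model$emission_mode == "table")
  S <- length(model$states)
  A <- length(model$alphabet)
  groups <- unique(unname(model$tie))
  trace <- numeric(0)
  prev_ll <- -Inf
  for (it in seq_len(max_iter)) {
    nt <- matrix(0, S, S, dimnames = dimnames(model$trans))
    nb <- stats::setNames(numeric(S), model$states)
    ne <- matrix(0, length(groups), A, dimnames = list(groups, NULL))
    ll <- 0
    for (seq in data) {
      E <- emission_scores(model, seq)
      Ec <- E * label_mask(model, seq$labels)
      cf <- forward_core(model$begin, model$trans, Ec, end_index(model))
      if (!is.finite(cf$loglik))
        stop("labels of '", seq$id, "' are infeasible under the grammar ",
             "(blocked at position ", cf$blocked_at, ")")
      cb <- backward_core(model$begin, model$trans, Ec, cf$scale,
                          end_index(model))
      cnt <- expected_counts(model, cf, cb, Ec)
      nt <- nt + cnt$trans
      nb <- nb + cnt$begin
      for (k in seq_len(S)) {
        gk <- model$tie[[model$states[k]]]
        known <- !is.na(seq$idx)
        ne[gk, ] <- ne[gk, ] + as.vector(
          tapply(cnt$gamma[known, k], factor(seq$idx[known], levels = 1:A),
                 sum, default = 0))
      }
      ll <- ll + cf$loglik
    }
    trace <- c(trace, ll)
    if (is.finite(prev_ll) && abs(ll - prev_ll) < tol) break
    prev_ll <- ll
    model$trans <- renorm_rows(nt, model$allowed, pseudocount)
    model$begin <- renorm_vec(nb, model$begin > 0, pseudocount)
    model$emissions <- renorm_rows(
      ne, matrix(TRUE, nrow(ne), A), pseudocount)
  }
  attr(model, "loglik_trace") <- trace
  validate_topology_model(model)
  model
}

renorm_rows <- function(counts, allowed, floor) {
  out <- counts
  out[!allowed] <- 0
  for (r in seq_len(nrow(out))) {
    a <- allowed[r, ]
    if (!any(a)) next
    s <- sum(out[r, a])
    p <- if (s > 0) out[r, a] / s else rep(1 / sum(a), sum(a))
    p <- pmax(p, floor)
    out[r, a] <- p / sum(p)
  }
  out
}

renorm_vec <- function(counts, allowed, floor) {
  out <- counts
  out[!allowed] <- 0
  s <- sum(out[allowed])
  p <- if (s > 0) out[allowed] / s else rep(1 / sum(allowed), sum(allowed))
  p <- pmax(p, floor)
  out[allowed] <- p / sum(p)
  out
}
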