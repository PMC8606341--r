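#' Per-position emission scores for a sequence
#'
#' Builds the `L x |states|` matrix of emission terms used by the
#' forward-backward recursions: probabilities `e_k(x_i)` looked up in the
#' (tied) emission table in CHMM mode, or network outputs `e_k(s_i; w_k)` in
#' HNN mode. In HNN mode the scores are not a normalized distribution over
#' symbols, so the trellis log-likelihood is a path score rather than a
#' sequence probability (documented behaviour of the hybrid model).
#'
#' Unknown residues emit `1/|alphabet|` in table mode and present an all-zero
#' context block to the networks.
#'
#' @param model a [topology_model()] with emissions.
#' @param seq a [labeled_sequence()].
#' @param profile optional profile for profile-mode context encoding.
#' @param windows optional precomputed [encode_windows()] matrix (HNN mode).
#' @return Numeric `L x |states|` matrix.
#' @export
emission_scores <- function(model, seq, profile = NULL, windows = NULL) {
  L <- length(seq)
  S <- length(model$states)
  if (model$emission_mode == "table") {
    A <- length(model$alphabet)
    E <- matrix(0, L, S)
    for (k in seq_len(S)) {
      row <- model$emissions[model$tie[[model$states[k]]], ]
      e <- row[seq$idx]
      e[is.na(seq$idx)] <- 1 / A
      E[, k] <- e
    }
  } else if (model$emission_mode == "network") {
    if (is.null(windows)) {
      prof <- if (model$encoding == "profile") profile else NULL
      if (model$encoding == "profile" && is.null(profile))
        stop("profile encoding requires a profile for '", seq$id, "'")
      windows <- encode_windows(seq, model$window, prof)
    }
    E <- matrix(0, L, S)
    for (k in seq_len(S))
      E[, k] <- network_emit_matrix(model$emissions[[model$states[k]]],
                                    windows)$e
  } else stop("model has no emissions")
  colnames(E) <- model$states
  E
}

trellis_obj <- function(phase, alpha = NULL, beta = NULL, scale, loglik,
                        blocked_at = NA_integer_) {
  structure(list(phase = phase, alpha = alpha, beta = beta, scale = scale,
                 loglik = loglik, ok = is.finite(loglik),
                 blocked_at = blocked_at),
            class = "trellis")
}

forward_core <- function(begin, trans, E, end_idx = NULL) {
  L <- nrow(E); S <- ncol(E)
  alpha <- matrix(0, L, S)
  scale <- numeric(L)
  a <- begin * E[1, ]
  for (i in seq_len(L)) {
    if (i > 1L) a <- as.vector(a %*% trans) * E[i, ]
    c_i <- sum(a)
    if (c_i <= 0)
      return(trellis_obj("free", alpha, NULL, scale, -Inf, blocked_at = i))
    scale[i] <- c_i
    a <- a / c_i
    alpha[i, ] <- a
  }
  ll <- sum(log(scale))
  if (!is.null(end_idx)) {
    tail_mass <- sum(alpha[L, end_idx])
    if (tail_mass <= 0)
      return(trellis_obj("free", alpha, NULL, scale, -Inf, blocked_at = L))
    ll <- ll + log(tail_mass)
  }
  trellis_obj("free", alpha, NULL, scale, ll)
}

backward_core <- function(begin, trans, E, scale, end_idx = NULL) {
  L <- nrow(E); S <- ncol(E)
  beta <- matrix(0, L, S)
  b <- if (is.null(end_idx)) rep(1, S) else {
    v <- numeric(S); v[end_idx] <- 1; v
  }
  beta[L, ] <- b
  if (L > 1L) for (i in (L - 1L):1L) {
    b <- as.vector(trans %*% (E[i + 1L, ] * b)) / scale[i + 1L]
    beta[i, ] <- b
  }
  first <- sum(begin * E[1, ] * beta[1, ])
  ll <- if (first <= 0) -Inf else {
    log(first) + if (L > 1L) sum(log(scale[-1L])) else 0
  }
  trellis_obj("free", NULL, beta, scale, ll)
}

#' Free-running forward algorithm
#'
#' Computes `P(x | theta)` — the sum over all state paths of
#' `a_B,pi1 * prod_i e_pi_i(x_i) a_pi_i,pi_i+1` — with per-position scaling;
#' the log-likelihood is accumulated from the log scaling factors, keeping
#' the recursion stable for long sequences. A sequence no state can emit
#' yields `loglik = -Inf` with `ok = FALSE` (flagged, not an error).
#'
#' @param model a [topology_model()].
#' @param seq a [labeled_sequence()].
#' @param profile optional profile (profile-mode HNN encoding).
#' @param E optional precomputed [emission_scores()] matrix.
#' @return A `trellis` object: `alpha` (scaled forward matrix), `scale`,
#'   `loglik`, `ok`, `blocked_at`, `phase = "free"`.
#' @export
forward <- function(model, seq, profile = NULL, E = NULL) {
  if (is.null(E)) E <- emission_scores(model, seq, profile)
  forward_core(model$begin, model$trans, E, end_index(model))
}

#' Free-running backward algorithm
#'
#' Mirror of [forward()]; the backward-derived log-likelihood agrees with the
#' forward one within `1e-8`. Scaling factors are taken from a forward pass.
#'
#' @inheritParams forward
#' @param fwd optional precomputed forward trellis (reused for scaling).
#' @return A `trellis` with `beta` filled, `phase = "free"`.
#' @export
backward <- function(model, seq, profile = NULL, E = NULL, fwd = NULL) {
  if (is.null(E)) E <- emission_scores(model, seq, profile)
  if (is.null(fwd)) fwd <- forward_core(model$begin, model$trans, E,
                                        end_index(model))
  if (!fwd$ok) return(trellis_obj("free", NULL, NULL, fwd$scale, -Inf,
                                  fwd$blocked_at))
  backward_core(model$begin, model$trans, E, fwd$scale, end_index(model))
}

#' Clamped forward algorithm
#'
#' Identical recursion to [forward()], but at position `i` only states whose
#' label equals `y_i` participate, so the result is
#' `log P(x, y | theta)` — the sum over label-consistent paths. If the labels
#' demand a forbidden transition the trellis is flagged with the first
#' blocked position.
#'
#' @inheritParams forward
#' @param labels per-residue label vector (defaults to `seq$labels`).
#' @return A `trellis` with `phase = "clamped"`.
#' @export
clamped_forward <- function(model, seq, labels = seq$labels, profile = NULL,
                            E = NULL) {
  if (is.null(labels)) stop("clamped phase requires labels")
  if (is.null(E)) E <- emission_scores(model, seq, profile)
  tr <- forward_core(model$begin, model$trans, E * label_mask(model, labels),
                     end_index(model))
  tr$phase <- "clamped"
  tr
}

#' Clamped backward algorithm
#'
#' @inheritParams clamped_forward
#' @param fwd optional precomputed clamped forward trellis.
#' @return A `trellis` with `phase = "clamped"`.
#' @export
clamped_backward <- function(model, seq, labels = seq$labels, profile = NULL,
                             E = NULL, fwd = NULL) {
  if (is.null(labels)) stop("clamped phase requires labels")
  if (is.null(E)) E <- emission_scores(model, seq, profile)
  Ec <- E * label_mask(model, labels)
  if (is.null(fwd)) fwd <- forward_core(model$begin, model$trans, Ec,
                                        end_index(model))
  if (!fwd$ok) {
    tr <- trellis_obj("clamped", NULL, NULL, fwd$scale, -Inf, fwd$blocked_at)
    return(tr)
  }
  tr <- backward_core(model$begin, model$trans, Ec, fwd$scale,
                      end_index(model))
  tr$phase <- "clamped"
  tr
}

end_index <- function(model) {
  if (is.null(model$end_states)) NULL
  else match(model$end_states, model$states)
}

#' Per-position state posteriors from a forward/backward trellis pair
#'
#' `gamma[i, k] = P(pi_i = k | x, theta)` in the free phase, or conditioned
#' additionally on the labels in the clamped phase. Rows sum to 1 within
#' `1e-9`.
#'
#' @param fwd forward trellis.
#' @param bwd backward trellis of the same phase.
#' @return `L x |states|` posterior matrix.
#' @export
posterior_matrix <- function(fwd, bwd) {
  if (!identical(fwd$phase, bwd$phase))
    stop("forward and backward trellises are from different phases")
  if (!fwd$ok || !bwd$ok) stop("posteriors undefined for -Inf trellises")
  g <- fwd$alpha * bwd$beta
  g / rowSums(g)
}

#' State posteriors for a sequence
#'
#' Convenience wrapper running both passes of the requested phase.
#'
#' @inheritParams clamped_forward
#' @param phase `"free"` or `"clamped"`.
#' @return `L x |states|` posterior matrix (columns named by state).
#' @export
state_posteriors <- function(model, seq, phase = c("free", "clamped"),
                             labels = seq$labels, profile = NULL, E = NULL) {
  phase <- match.arg(phase)
  if (is.null(E)) E <- emission_scores(model, seq, profile)
  if (phase == "free") {
    f <- forward(model, seq, E = E)
    b <- backward(model, seq, E = E, fwd = f)
  } else {
    f <- clamped_forward(model, seq, labels, E = E)
    b <- clamped_backward(model, seq, labels, E = E, fwd = f)
  }
  g <- posterior_matrix(f, b)
  colnames(g) <- model$states
  g
}
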