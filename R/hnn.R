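#' Training configuration
#'
#' @param max_epochs epoch cap for joint CML training (default 50; held-out
#'   error reaches its minimum well within this for the models shipped
#'   here).
#' @param holdout_fraction fraction of sequences (in `(0, 0.5)`) held back
#'   for early stopping; the split is by sequence and seeded.
#' @param patience epochs without held-out improvement before stopping.
#' @param weight_decay L2 coefficient `lambda` added to network gradients
#'   (opt-in; default 0).
#' @param momentum momentum coefficient for the optional plain-gradient
#'   trainer (ignored by RPROP).
#' @param init_loss loss for per-label network initialization: `"CE"`
#'   (cross entropy, default — faster and better training) or `"RMSE"`.
#' @param init_epochs RPROP epochs for per-label initialization.
#' @param seed integer seed driving the holdout split and weight draws.
#' @param clamp output clamp epsilon in `(0, 1e-3]`.
#' @param joint train transitions jointly with the networks (default) or
#'   freeze them.
#' @return List of class `train_config`.
#' @export
train_config <- function(max_epochs = 50, holdout_fraction = 0.1,
                         patience = 10, weight_decay = 0, momentum = 0,
                         init_loss = c("CE", "RMSE"), init_epochs = 50,
                         seed = 1L, clamp = 1e-6, joint = TRUE) {
  init_loss <- match.arg(init_loss)
  stopifnot(holdout_fraction > 0, holdout_fraction < 0.5,
            clamp > 0, clamp <= 1e-3, max_epochs >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 holdout_fraction = holdout_fraction,
                 patience = as.integer(patience),
                 weight_decay = weight_decay, momentum = momentum,
                 init_loss = init_loss,
                 init_epochs = as.integer(init_epochs),
                 seed = as.integer(seed), clamp = clamp, joint = joint),
            class = "train_config")
}

#' CML error signal at the network outputs
#'
#' For each state `k` and position `i`, the derivative of the conditional
#' loss `l = lc - lf` with respect to the pre-activation `h` of that state's
#' emission network evaluated on context `s_i`:
#' `eps_k(x_i) = (gamma_free - gamma_clamped)(k, i) * (1 - e_k(s_i))`,
#' the difference of free and clamped state posteriors chained through the
#' output sigmoid. Entries are zero wherever the two posteriors coincide.
#'
#' @param model a [topology_model()] in HNN mode.
#' @param seq labeled sequence.
#' @param profile optional profile.
#' @param parts optional precomputed list from [hnn_sequence_parts()].
#' @return `L x |states|` matrix of class `error_signal` with attributes
#'   `loss` (the [cml_loss()]) and `gamma_free` / `gamma_clamped`.
#' @export
error_signal <- function(model, seq, profile = NULL, parts = NULL) {
  if (is.null(parts)) parts <- hnn_sequence_parts(model, seq, profile)
  d <- count_difference(model, seq, parts$E)
  eps <- (d$gamma_free - d$gamma_clamped) * (1 - parts$E)
  structure(eps, class = "error_signal",
            gamma_free = d$gamma_free, gamma_clamped = d$gamma_clamped,
            count_diff = d)
}

#' Precompute per-sequence quantities for HNN training
#'
#' Encodes the context windows once and evaluates every state's emission
#' network over them.
#'
#' @inheritParams error_signal
#' @param windows optional precomputed window matrix.
#' @return List with `windows`, `E`, and per-state forward-pass caches.
#' @export
hnn_sequence_parts <- function(model, seq, profile = NULL, windows = NULL) {
  if (is.null(windows)) {
    prof <- if (model$encoding == "profile") profile else NULL
    windows <- encode_windows(seq, model$window, prof)
  }
  S <- length(model$states)
  E <- matrix(0, length(seq), S)
  caches <- vector("list", S)
  for (k in seq_len(S)) {
    caches[[k]] <- network_emit_matrix(model$emissions[[model$states[k]]],
                                       windows)
    E[, k] <- caches[[k]]$e
  }
  colnames(E) <- model$states
  list(windows = windows, E = E, caches = caches)
}

#' Backpropagated CML gradients for a batch
#'
#' Accumulates, over sequences and positions, the gradients of the summed
#' conditional loss with respect to every network weight (standard
#' backpropagation from the [error_signal()]), adds the weight-decay term
#' `lambda * w`, and — when `joint` — the transition/begin gradients in the
#' softmax reparameterization.
#'
#' @param model HNN-mode [topology_model()].
#' @param batch list of labeled sequences.
#' @param profiles optional list of profiles.
#' @param lambda weight-decay coefficient.
#' @param joint include transition gradients.
#' @param parts_list optional precomputed [hnn_sequence_parts()] per
#'   sequence.
#' @return List: `networks` (per-state weight-gradient lists), `trans`,
#'   `begin`, and `loss` (summed CML loss over the batch).
#' @export
backprop_gradients <- function(model, batch, profiles = NULL, lambda = 0,
                               joint = TRUE, parts_list = NULL) {
  S <- length(model$states)
  grads <- lapply(seq_len(S), function(k) {
    net <- model$emissions[[model$states[k]]]
    list(W1 = matrix(0, net$hidden, net$input_dim),
         b1 = numeric(net$hidden), w2 = numeric(net$hidden), b2 = 0)
  })
  names(grads) <- model$states
  gt <- matrix(0, S, S, dimnames = dimnames(model$trans))
  gb <- stats::setNames(numeric(S), model$states)
  total_loss <- 0
  for (j in seq_along(batch)) {
    seq <- batch[[j]]
    parts <- if (!is.null(parts_list)) parts_list[[j]] else
      hnn_sequence_parts(model, seq,
                         if (!is.null(profiles)) profiles[[j]])
    d <- count_difference(model, seq, parts$E)
    eps <- (d$gamma_free - d$gamma_clamped) * (1 - parts$E)
    for (k in seq_len(S)) {
      g <- network_backprop(model$emissions[[model$states[k]]],
                            parts$windows, parts$caches[[k]]$hid, eps[, k])
      grads[[k]]$W1 <- grads[[k]]$W1 + g$W1
      grads[[k]]$b1 <- grads[[k]]$b1 + g$b1
      grads[[k]]$w2 <- grads[[k]]$w2 + g$w2
      grads[[k]]$b2 <- grads[[k]]$b2 + g$b2
    }
    gt <- gt + d$trans
    gb <- gb + d$begin
    total_loss <- total_loss + d$loss
  }
  if (lambda > 0) {
    for (k in seq_len(S)) {
      net <- model$emissions[[model$states[k]]]
      grads[[k]]$W1 <- grads[[k]]$W1 + lambda * net$W1
      grads[[k]]$b1 <- grads[[k]]$b1 + lambda * net$b1
      grads[[k]]$w2 <- grads[[k]]$w2 + lambda * net$w2
      grads[[k]]$b2 <- grads[[k]]$b2 + lambda * net$b2
    }
  }
  trans_grad <- NULL
  begin_grad <- NULL
  if (joint) {
    trans_grad <- gt - model$trans * rowSums(gt)
    trans_grad[!model$allowed] <- 0
    begin_grad <- gb - model$begin * sum(gb)
    begin_grad[model$begin == 0] <- 0
  }
  list(networks = grads, trans = trans_grad, begin = begin_grad,
       loss = total_loss)
}

#' Initialize emission networks per label
#'
#' For every label of the model a network is created and trained separately
#' (full-batch RPROP) to output 1 on windows whose central residue carries
#' that label and 0 otherwise, minimizing cross entropy (default) or RMSE.
#' Each state then receives a copy of its label's network, so states of one
#' label start from identical weights but are subsequently untied unless
#' `tie_networks`. Initial weights are uniform in `[-0.1, 0.1]` from the
#' config seed; identical config and seed give bitwise-identical networks.
#'
#' @param data list of labeled sequences.
#' @param model [topology_model()] (grammar; emissions may be absent).
#' @param config a [train_config()].
#' @param hidden hidden units per network.
#' @param window a [window_spec()] (defaults to the model's).
#' @param profiles optional profiles for profile encoding.
#' @param tie_networks if `TRUE`, states of one label permanently share one
#'   network object.
#' @return The model with `emissions` set to the state -> network map.
#' @export
init_networks <- function(data, model, config = train_config(),
                          hidden = 5, window = model$window,
                          profiles = NULL, tie_networks = FALSE) {
  stopifnot(!is.null(window))
  model$window <- window
  D <- length(model$alphabet) * window$K
  stacked <- do.call(rbind, lapply(seq_along(data), function(j) {
    prof <- if (model$encoding == "profile") profiles[[j]] else NULL
    encode_windows(data[[j]], window, prof)
  }))
  center_labels <- unlist(lapply(data, `[[`, "labels"))
  nets <- list()
  for (lab in model$labels) {
    net <- withr::with_seed(
      config$seed + match(lab, model$labels),
      emission_network(D, hidden))
    if (!any(center_labels == lab)) {
      warning("label '", lab, "' absent from training data; ",
              "its network keeps its random initialization")
    } else {
      net <- train_network_rprop(net, stacked,
                                 as.numeric(center_labels == lab),
                                 loss = config$init_loss,
                                 epochs = config$init_epochs,
                                 clamp = config$clamp)
    }
    nets[[lab]] <- net
  }
  model$emissions <- stats::setNames(
    lapply(model$states, function(st) nets[[model$label_map[[st]]]]),
    model$states)
  if (tie_networks) model$tie <- model$label_map
  model$emission_mode <- "network"
  validate_topology_model(model)
  model
}

# Full-batch RPROP supervised training of one network on targets in {0,1}.
train_network_rprop <- function(net, S, targets, loss = "CE", epochs = 50,
                                clamp = 1e-6) {
  w <- network_params(net)
  st <- rprop_state(length(w))
  for (ep in seq_len(epochs)) {
    net <- network_set_params(net, w)
    fwdp <- network_emit_matrix(net, S, clamp = clamp)
    dh <- if (loss == "CE") {
      fwdp$e - targets                     # d CE / d h for sigmoid output
    } else {
      (fwdp$e - targets) * fwdp$e * (1 - fwdp$e)
    }
    g <- network_backprop(net, S, fwdp$hid, dh)
    up <- rprop_step(st, c(as.vector(g$W1), g$b1, g$w2, g$b2), w)
    w <- up$w
    st <- up$state
  }
  network_set_params(net, w)
}

# Flatten every trainable HNN parameter (all network weights, then softmax
# transition and begin parameters) into one vector for the optimizer.
hnn_pack <- function(model, joint = TRUE) {
  p <- unlist(lapply(model$states,
                     function(st) network_params(model$emissions[[st]])))
  if (joint) {
    zt <- log(pmax(model$trans[model$allowed], 1e-300))
    zb <- log(pmax(model$begin[model$begin > 0], 1e-300))
    p <- c(p, zt, zb)
  }
  p
}

hnn_unpack <- function(model, p, joint = TRUE) {
  pos <- 0L
  for (st in model$states) {
    net <- model$emissions[[st]]
    n <- length(network_params(net))
    model$emissions[[st]] <- network_set_params(net, p[pos + seq_len(n)])
    pos <- pos + n
  }
  if (joint) {
    n_t <- sum(model$allowed)
    zt <- p[pos + seq_len(n_t)]
    pos <- pos + n_t
    zb <- p[pos + seq_len(sum(model$begin > 0))]
    tr <- model$trans
    tr[model$allowed] <- exp(zt - max(zt))
    tr[!model$allowed] <- 0
    tr <- tr / rowSums(tr)
    tr[rowSums(model$allowed) == 0, ] <- 0
    model$trans <- tr
    bi <- model$begin > 0
    eb <- exp(zb - max(zb))
    model$begin[bi] <- eb / sum(eb)
  }
  model
}

hnn_grad_pack <- function(model, grads, joint = TRUE) {
  p <- unlist(lapply(model$states, function(st) {
    g <- grads$networks[[st]]
    c(as.vector(g$W1), g$b1, g$w2, g$b2)
  }))
  if (joint) p <- c(p, grads$trans[model$allowed],
                    grads$begin[model$begin > 0])
  p
}

#' Joint conditional maximum likelihood training of an HNN
#'
#' Full-batch discriminative training: each epoch runs the free and clamped
#' forward-backward passes for every training sequence, accumulates the
#' backpropagated CML gradients for all network weights (plus transition and
#' begin parameters when `joint`), and applies one RPROP update. A seeded
#' fraction of sequences is held back; the held-out loss is tracked every
#' epoch and the returned model is the snapshot at its minimum (early
#' stopping). Training stops at `max_epochs` or when the held-out loss has
#' not improved for `patience` epochs.
#'
#' @param model HNN-mode [topology_model()] (e.g. from [init_networks()]).
#' @param data list of labeled sequences.
#' @param config a [train_config()].
#' @param profiles optional list of profiles aligned with `data`.
#' @return Object of class `hnn_fit`: list with `model` (best snapshot),
#'   `log` (tibble: epoch, train_loss, holdout_loss), `best_epoch`,
#'   `config`.
#' @export
train_hnn <- function(model, data, config = train_config(),
                      profiles = NULL) {
  stopifnot(model$emission_mode == "network")
  n <- length(data)
  n_hold <- max(1L, round(config$holdout_fraction * n))
  hold_idx <- withr::with_seed(config$seed,
                               sort(sample.int(n, n_hold)))
  train_idx <- setdiff(seq_len(n), hold_idx)
  if (length(train_idx) == 0L) stop("no training sequences left after split")
  infeasible <- vapply(data, function(s) {
    E1 <- matrix(1, length(s), length(model$states))
    !forward_core(model$begin, model$trans,
                  E1 * label_mask(model, s$labels), end_index(model))$ok
  }, TRUE)
  if (any(infeasible))
    stop("label sequences infeasible under the grammar: ",
         paste(vapply(data[infeasible], `[[`, "", "id"), collapse = ", "))
  get_parts <- function(idx)
    lapply(idx, function(j) hnn_sequence_parts(
      model, data[[j]], if (!is.null(profiles)) profiles[[j]]))
  holdout_loss <- function(m) {
    sum(vapply(hold_idx, function(j) {
      cml_loss(m, data[[j]],
               profile = if (!is.null(profiles)) profiles[[j]])$loss
    }, 0))
  }
  w <- hnn_pack(model, config$joint)
  st <- rprop_state(length(w))
  best <- list(loss = Inf, w = w, epoch = 0L)
  log_epoch <- integer(0); log_train <- numeric(0); log_hold <- numeric(0)
  since_best <- 0L
  for (ep in seq_len(config$max_epochs)) {
    parts <- get_parts(train_idx)
    g <- backprop_gradients(model, data[train_idx],
                            profiles = if (!is.null(profiles))
                              profiles[train_idx],
                            lambda = config$weight_decay,
                            joint = config$joint, parts_list = parts)
    up <- rprop_step(st, hnn_grad_pack(model, g, config$joint), w)
    w <- up$w
    st <- up$state
    model <- hnn_unpack(model, w, config$joint)
    hl <- holdout_loss(model)
    log_epoch <- c(log_epoch, ep)
    log_train <- c(log_train, g$loss)
    log_hold <- c(log_hold, hl)
    if (hl < best$loss - 1e-12) {
      best <- list(loss = hl, w = w, epoch = ep)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  model <- hnn_unpack(model, best$w, config$joint)
  structure(list(model = model,
                 log = tibble::tibble(epoch = log_epoch,
                                      train_loss = log_train,
                                      holdout_loss = log_hold),
                 best_epoch = best$epoch, holdout = hold_idx,
                 config = config),
            class = "hnn_fit")
}

#' @export
print.hnn_fit <- function(x, ...) {
  cat("<hnn_fit> ", nrow(x$log), " epochs (best held-out loss ",
      format(min(x$log$holdout_loss)), " at epoch ", x$best_epoch, ")\n",
      sep = "")
  invisible(x)
}

#' Summarize an HNN fit
#'
#' @param x an `hnn_fit`.
#' @param ... unused.
#' @return One-row tibble: epochs run, best epoch, initial/final training
#'   loss, best held-out loss.
#' @export
glance.hnn_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), best_epoch = x$best_epoch,
                 initial_train_loss = x$log$train_loss[1],
                 final_train_loss = x$log$train_loss[nrow(x$log)],
                 best_holdout_loss = min(x$log$holdout_loss))
}
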