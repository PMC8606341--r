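# Brute-force path-enumeration oracles for tiny models, independent of the
# package's scaled forward-backward implementation, plus seeded random
# model/sequence generators used across the suite.

test_alphabet <- function(A = 4) c("A", "C", "G", "T")[seq_len(A)]

# all state paths of length L over S states
all_paths <- function(S, L) {
  as.matrix(expand.grid(rep(list(seq_len(S)), L)))
}

path_score <- function(model, path, E) {
  L <- length(path)
  p <- model$begin[path[1]] * E[1, path[1]]
  if (L > 1) for (i in 2:L)
    p <- p * model$trans[path[i - 1], path[i]] * E[i, path[i]]
  if (!is.null(model$end_states) &&
      !model$states[path[L]] %in% model$end_states) p <- 0
  unname(p)
}

# label_filter: NULL (free) or a label vector (clamped)
enum_likelihood <- function(model, seq, labels = NULL, E = NULL) {
  if (is.null(E)) E <- emission_scores(model, seq)
  L <- length(seq)
  paths <- all_paths(length(model$states), L)
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    if (!is.null(labels) &&
        !all(model$label_map[model$states[path]] == labels)) next
    tot <- tot + path_score(model, path, E)
  }
  tot
}

enum_state_posteriors <- function(model, seq, labels = NULL) {
  E <- emission_scores(model, seq)
  L <- length(seq)
  S <- length(model$states)
  paths <- all_paths(S, L)
  g <- matrix(0, L, S)
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    if (!is.null(labels) &&
        !all(model$label_map[model$states[path]] == labels)) next
    w <- path_score(model, path, E)
    tot <- tot + w
    for (i in seq_len(L)) g[i, path[i]] <- g[i, path[i]] + w
  }
  g / tot
}

enum_viterbi <- function(model, seq) {
  E <- emission_scores(model, seq)
  paths <- all_paths(length(model$states), length(seq))
  best <- -Inf
  bp <- NULL
  for (r in seq_len(nrow(paths))) {
    w <- path_score(model, paths[r, ], E)
    if (w > best && w > 0) { best <- w; bp <- paths[r, ] }
  }
  list(logscore = log(best), path = bp)
}

# brute-force optimal-accuracy labeling: maximize summed label posteriors
# over labelings realizable by a positive-probability state path
enum_label_decode <- function(model, seq) {
  E <- emission_scores(model, seq)
  lp <- hnntm:::label_posterior_matrix(model, seq, E)
  L <- length(seq)
  paths <- all_paths(length(model$states), L)
  best <- -Inf
  bl <- NULL
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    ok <- model$begin[path[1]] > 0 &&
      (L == 1 || all(model$trans[cbind(path[-L], path[-1])] > 0)) &&
      (is.null(model$end_states) ||
         model$states[path[L]] %in% model$end_states)
    if (!ok) next
    labs <- unname(model$label_map[model$states[path]])
    val <- sum(lp[cbind(seq_len(L), match(labs, colnames(lp)))])
    if (val > best + 1e-12) { best <- val; bl <- labs }
  }
  list(score = best / L, labels = bl)
}

# random row-stochastic matrix with a given support pattern
random_stochastic <- function(mask) {
  m <- matrix(0, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    v <- stats::runif(sum(mask[r, ]), 0.05, 1)
    m[r, mask[r, ]] <- v / sum(v)
  }
  m
}

# seeded random CHMM with <= 3 states over a small alphabet; with
# prob. dense = 1 fully connected, otherwise some transitions are removed
random_tiny_chmm <- function(S = sample(2:3, 1), A = 4, n_labels = 2,
                             dense = 0.7) {
  alphabet <- test_alphabet(A)
  states <- paste0("s", seq_len(S))
  mask <- matrix(TRUE, S, S)
  if (stats::runif(1) > dense && S > 1) {
    drop <- sample(S * S, 1)
    mask[drop] <- FALSE
    # keep every row alive
    for (r in seq_len(S)) if (!any(mask[r, ])) mask[r, r] <- TRUE
  }
  trans <- random_stochastic(mask)
  dimnames(trans) <- list(states, states)
  labels <- LETTERS[seq_len(n_labels)]
  label_map <- stats::setNames(
    sample(labels, S, replace = TRUE), states)
  label_map[seq_len(min(S, n_labels))] <- labels[seq_len(min(S, n_labels))]
  emissions <- random_stochastic(matrix(TRUE, S, A))
  rownames(emissions) <- states
  bg <- stats::runif(S, 0.05, 1)
  topology_model(states, label_map, stats::setNames(bg / sum(bg), states),
                 trans, emissions = emissions, alphabet = alphabet)
}

random_seq_for <- function(model, L, labeled = TRUE) {
  alphabet <- model$alphabet
  res <- sample(alphabet, L, replace = TRUE)
  labels <- NULL
  if (labeled) {
    # draw labels from a realizable state path so clamping is feasible
    S <- length(model$states)
    path <- integer(L)
    path[1] <- sample.int(S, 1, prob = model$begin)
    if (L > 1) for (i in 2:L)
      path[i] <- sample.int(S, 1, prob = model$trans[path[i - 1], ])
    labels <- unname(model$label_map[model$states[path]])
  }
  labeled_sequence("t", res, labels, alphabet = alphabet)
}

# random tiny HNN sharing the grammar of a random CHMM
random_tiny_hnn <- function(S = 2, A = 4, K_left = 1, H = 2) {
  base <- random_tiny_chmm(S = S, A = A)
  ws <- window_spec(K_left)
  nets <- lapply(base$states, function(s)
    emission_network(A * ws$K, H))
  names(nets) <- base$states
  topology_model(base$states, base$label_map, base$begin, base$trans,
                 emissions = nets, alphabet = base$alphabet, window = ws)
}

numeric_gradient <- function(f, w, h = 1e-5) {
  vapply(seq_along(w), function(j) {
    wp <- w; wp[j] <- wp[j] + h
    wm <- w; wm[j] <- wm[j] - h
    (f(wp) - f(wm)) / (2 * h)
  }, 0)
}

expect_rel_equal <- function(actual, expected, rel_tol, abs_floor = 1e-8) {
  err <- abs(actual - expected) / pmax(abs(expected), abs_floor)
  expect_lt(max(err), rel_tol)
}
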