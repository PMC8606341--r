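#' Construct a one-hidden-layer emission network
#'
#' The emission network of a state scores how well the context window around
#' a position matches that state: a multilayer perceptron with `input_dim =
#' |alphabet| * K` inputs, `hidden` units, and a single sigmoid output unit
#' producing `e_k(s_i; w_k)` in (0, 1). `h` denotes the weighted input to the
#' output unit (its pre-activation). Parameter count is
#' `input_dim * hidden + hidden + hidden + 1`.
#'
#' @param input_dim input dimension.
#' @param hidden number of hidden units.
#' @param activation hidden activation: `"sigmoid"`, `"tanh"`, or
#'   `"msigmoid"` (the sigmoid recentred to (-1, 1), `tanh(x/2)`). The
#'   output activation is always the standard asymmetrical sigmoid.
#' @param W1,b1,w2,b2 optional explicit weights (hidden x input matrix,
#'   hidden bias vector, hidden-to-output weights, output bias). When
#'   omitted, weights are drawn uniformly from `[-0.1, 0.1]` (seed the RNG
#'   beforehand for reproducibility).
#' @return An object of class `emission_network`.
#' @export
#' @examples
#' set.seed(1)
#' net <- emission_network(140, 5)
#' length(network_params(net))  # 140*5 + 5 + 5 + 1
emission_network <- function(input_dim, hidden,
                             activation = c("sigmoid", "tanh", "msigmoid"),
                             W1 = NULL, b1 = NULL, w2 = NULL, b2 = NULL) {
  activation <- match.arg(activation)
  if (is.null(W1))
    W1 <- matrix(stats::runif(hidden * input_dim, -0.1, 0.1),
                 nrow = hidden, ncol = input_dim)
  if (is.null(b1)) b1 <- stats::runif(hidden, -0.1, 0.1)
  if (is.null(w2)) w2 <- stats::runif(hidden, -0.1, 0.1)
  if (is.null(b2)) b2 <- stats::runif(1, -0.1, 0.1)
  stopifnot(nrow(W1) == hidden, ncol(W1) == input_dim,
            length(b1) == hidden, length(w2) == hidden, length(b2) == 1L)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), activation = activation,
                 W1 = W1, b1 = b1, w2 = w2, b2 = as.numeric(b2)),
            class = "emission_network")
}

#' @export
print.emission_network <- function(x, ...) {
  cat("<emission_network> ", x$input_dim, " -> ", x$hidden, " (",
      x$activation, ") -> 1 (sigmoid); ",
      length(network_params(x)), " parameters\n", sep = "")
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

hidden_act <- function(z, activation) {
  switch(activation,
         sigmoid = sigmoid(z),
         tanh = tanh(z),
         msigmoid = tanh(z / 2))
}

hidden_act_deriv <- function(a, activation) {
  # derivative expressed through the activation value a
  switch(activation,
         sigmoid = a * (1 - a),
         tanh = 1 - a^2,
         msigmoid = (1 - a^2) / 2)
}

#' Evaluate an emission network on one context vector
#'
#' `hidden = act(W1 s + b1)`, `h = w2 . hidden + b2`, output
#' `sigma(h)` clamped to `[clamp, 1 - clamp]` so that log scores stay
#' finite for any input.
#'
#' @param net an [emission_network()].
#' @param s numeric context vector of length `input_dim`.
#' @param clamp output clamp epsilon.
#' @return Scalar in `(0, 1)`.
#' @export
network_emit <- function(net, s, clamp = 1e-6) {
  if (length(s) != net$input_dim)
    stop("context vector has length ", length(s), "; network expects ",
         net$input_dim)
  network_emit_matrix(net, matrix(s, nrow = 1))$e[1]
}

# Vectorized forward pass over the rows of a window matrix.
# Returns e (clamped output), h (output pre-activation), hid (hidden
# activations) for reuse in backpropagation.
network_emit_matrix <- function(net, S, clamp = 1e-6) {
  Z <- S %*% t(net$W1)
  Z <- sweep(Z, 2, net$b1, `+`)
  Hid <- hidden_act(Z, net$activation)
  h <- as.vector(Hid %*% net$w2) + net$b2
  e <- pmin(pmax(sigmoid(h), clamp), 1 - clamp)
  list(e = e, h = h, hid = Hid)
}

# Backpropagate dE/dh (one value per row of S) to weight gradients.
network_backprop <- function(net, S, hid, dh) {
  gw2 <- as.vector(crossprod(hid, dh))
  gb2 <- sum(dh)
  dZ <- outer(dh, net$w2) * hidden_act_deriv(hid, net$activation)
  gW1 <- crossprod(dZ, S)  # H x D, matching W1
  gb1 <- colSums(dZ)
  list(W1 = gW1, b1 = gb1, w2 = gw2, b2 = gb2)
}

#' Build a K = 1 network that reproduces an emission table
#'
#' Constructs a one-hot, window-size-1 emission network whose output on
#' symbol `a` equals `probs[a]` up to saturation error: one hidden sigmoid
#' unit per symbol driven to saturation (`W1 = C I`, `b1 = -C/2`), with
#' output weights `logit(probs)`. This embeds a CHMM emission distribution
#' in the HNN parameterization; with `C = 40` the log-likelihood
#' discrepancy is below `1e-4` for probabilities within the output clamp.
#'
#' @param probs emission probability vector (values in `(clamp, 1-clamp)`).
#' @param C saturation gain.
#' @return An [emission_network()] with `input_dim = length(probs)`.
#' @export
saturated_table_network <- function(probs, C = 40) {
  A <- length(probs)
  stopifnot(all(probs > 0), all(probs < 1))
  emission_network(
    input_dim = A, hidden = A, activation = "sigmoid",
    W1 = diag(C, A), b1 = rep(-C / 2, A),
    w2 = stats::qlogis(probs), b2 = 0)
}

#' Flatten network weights to a parameter vector
#'
#' Order: `W1` (row-major by hidden unit), `b1`, `w2`, `b2`.
#'
#' @param net an [emission_network()].
#' @return Numeric vector.
#' @export
network_params <- function(net) {
  c(as.vector(net$W1), net$b1, net$w2, net$b2)
}

#' Rebuild a network from a parameter vector
#'
#' @param net template [emission_network()] (defines shapes/activation).
#' @param p parameter vector in [network_params()] order.
#' @return An [emission_network()].
#' @export
network_set_params <- function(net, p) {
  H <- net$hidden; D <- net$input_dim
  stopifnot(length(p) == H * D + 2 * H + 1)
  net$W1 <- matrix(p[seq_len(H * D)], nrow = H, ncol = D)
  p <- p[-seq_len(H * D)]
  net$b1 <- p[seq_len(H)]
  net$w2 <- p[H + seq_len(H)]
  net$b2 <- p[2 * H + 1]
  net
}
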