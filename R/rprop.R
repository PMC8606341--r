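#' Initialize RPROP optimizer state
#'
#' Resilient backpropagation adapts one step size per weight from the sign
#' history of its partial derivative: consistent signs grow the step by
#' `e_a > 1`, a sign flip shrinks it by `e_d < 1`. The variant implemented is
#' iRPROP- : on a sign flip the stored derivative is zeroed, so the weight is
#' not moved on that step and no step reversal is performed.
#'
#' @param n number of parameters.
#' @param delta0 initial step size.
#' @param ea step-increase factor (`> 1`).
#' @param ed step-decrease factor (`< 1`).
#' @param dmin,dmax step-size bounds; steps stay in `[dmin, dmax]`
#'   elementwise at all times.
#' @return An object of class `rprop_state`.
#' @export
rprop_state <- function(n, delta0 = 0.01, ea = 1.2, ed = 0.5,
                        dmin = 1e-8, dmax = 1.0) {
  stopifnot(ea > 1, ed < 1, ed > 0, dmin > 0, dmax >= dmin,
            delta0 >= dmin, delta0 <= dmax)
  structure(list(delta = rep(delta0, n), prev = rep(0, n),
                 ea = ea, ed = ed, dmin = dmin, dmax = dmax),
            class = "rprop_state")
}

#' One RPROP update
#'
#' Per weight: if the current and stored derivatives share a sign, the step
#' grows (`min(delta * ea, dmax)`); on a sign change it shrinks
#' (`max(delta * ed, dmin)`) and the stored derivative is zeroed (iRPROP-).
#' Each weight then moves opposite to the sign of its derivative by its own
#' step size.
#'
#' @param state an [rprop_state()].
#' @param grad gradient vector, same length as the weights.
#' @param w current weight vector.
#' @return List with updated `w` and `state`.
#' @export
#' @examples
#' # minimize (w - 3)^2 from w = 0
#' st <- rprop_state(1); w <- 0
#' for (t in 1:100) { up <- rprop_step(st, 2 * (w - 3), w); w <- up$w; st <- up$state }
#' abs(w - 3) < 1e-3
rprop_step <- function(state, grad, w) {
  stopifnot(length(grad) == length(w), length(w) == length(state$delta))
  s <- state$prev * grad
  up <- s > 0
  dn <- s < 0
  state$delta[up] <- pmin(state$delta[up] * state$ea, state$dmax)
  state$delta[dn] <- pmax(state$delta[dn] * state$ed, state$dmin)
  g <- grad
  g[dn] <- 0
  w <- w - sign(g) * state$delta
  state$prev <- g
  list(w = w, state = state)
}
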