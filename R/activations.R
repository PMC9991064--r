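#' Activation functions
#'
#' Constructor for the activation functions used by both layers of the
#' circuit. The sigmoidal parametrization is
#' \deqn{\Psi(x) = 1 / (1 + \exp(-\Theta_1 (x - \Theta_2)))}
#' where `theta1` (> 0) sets the steepness -- the gain, defined as the slope
#' at `x = theta2`, equals `theta1 / 4` -- and `theta2` sets the threshold
#' (the midpoint, where the function crosses 1/2). A `"linear"` activation
#' (the identity) is provided for degenerate-case analysis; with a linear
#' intermediate layer the context-dependent task is not linearly separable
#' and the theory develops a singularity.
#'
#' @param type `"sigmoid"` or `"linear"`.
#' @param theta1 steepness parameter, dimensionless, > 0 (sigmoid only).
#' @param theta2 threshold parameter, dimensionless (sigmoid only).
#' @return An object of class `"activation"`.
#' @examples
#' psi <- activation("sigmoid", theta1 = 2, theta2 = 1)
#' act_fun(1, psi)        # 0.5 at the threshold
#' act_deriv(1, psi)      # theta1 / 4 at the threshold
#' @export
activation <- function(type = c("sigmoid", "linear"), theta1 = 1, theta2 = 0) {
  type <- match.arg(type)
  if (type == "sigmoid") {
    stopifnot(is.numeric(theta1), length(theta1) == 1L, is.finite(theta1),
              is.numeric(theta2), length(theta2) == 1L, is.finite(theta2))
    if (theta1 <= 0) stop("`theta1` must be > 0")
  }
  structure(list(type = type, theta1 = theta1, theta2 = theta2),
            class = "activation")
}

#' @export
print.activation <- function(x, ...) {
  if (x$type == "linear") {
    cat("<activation> linear (identity)\n")
  } else {
    cat(sprintf("<activation> sigmoid: theta1 = %g (gain %g), theta2 = %g\n",
                x$theta1, x$theta1 / 4, x$theta2))
  }
  invisible(x)
}

check_act <- function(p) {
  if (!inherits(p, "activation")) stop("expected an `activation` object")
  p
}

#' Evaluate an activation function
#'
#' Vectorized elementwise over `x`. For the sigmoid the evaluation uses
#' [stats::plogis()], which is numerically stable for large `|theta1 * (x -
#' theta2)|` (no overflow; values saturate smoothly at 0 and 1).
#'
#' @param x numeric vector/matrix of synaptic drives; must be finite.
#' @param p an [activation()] object.
#' @return Values in (0, 1) for the sigmoid; `x` itself for linear.
#' @export
act_fun <- function(x, p) {
  check_act(p)
  if (!all(is.finite(x))) stop("`x` must be finite")
  if (p$type == "linear") return(x)
  out <- stats::plogis(p$theta1 * (x - p$theta2))
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Derivative of an activation function
#'
#' For the sigmoid, `theta1 * psi * (1 - psi)`; its maximum `theta1 / 4` is
#' attained at `x = theta2` and it is symmetric about the threshold.
#'
#' @inheritParams act_fun
#' @export
act_deriv <- function(x, p) {
  check_act(p)
  if (!all(is.finite(x))) stop("`x` must be finite")
  if (p$type == "linear") {
    out <- rep(1, length(x))
    if (is.matrix(x)) dim(out) <- dim(x)
    return(out)
  }
  s <- stats::plogis(p$theta1 * (x - p$theta2))
  out <- p$theta1 * s * (1 - s)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Inverse of an activation function
#'
#' For the sigmoid, `theta2 + qlogis(z) / theta1`, defined for `z` strictly
#' inside (0, 1). The inverse exists because the activation is monotonically
#' increasing; it is used to translate readout targets into target synaptic
#' drives once the loss has been driven to zero.
#'
#' @param z numeric in (0, 1) (any numeric for linear activations).
#' @param p an [activation()] object.
#' @export
act_inv <- function(z, p) {
  check_act(p)
  if (p$type == "linear") return(z)
  if (!all(is.finite(z)) || any(z <= 0) || any(z >= 1))
    stop("`z` must lie strictly in (0, 1)")
  p$theta2 + stats::qlogis(z) / p$theta1
}
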