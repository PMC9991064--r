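#' Circuit parameters
#'
#' The circuit is a feedforward network with an input layer and an
#' intermediate layer of identical size `N`, connected by an `N x N` weight
#' matrix `u`, and a single readout neuron with weight vector `w`.
#' Intermediate-layer activity is `y = psi(u x + b)` and the readout is
#' `z = phi(w . y)`. Weights are initialized i.i.d. Gaussian with mean zero
#' and variance `1/N`, which keeps synaptic drives and activity O(1) in the
#' circuit size. The per-neuron bias `b` is zero in the base model; the
#' structured/heterogeneous task variant draws it with standard deviation
#' `bias_sd = 0.2`.
#'
#' @param N layer width (integer >= 2).
#' @param psi intermediate-layer [activation()].
#' @param phi readout [activation()].
#' @param bias_sd standard deviation of the fixed per-neuron bias (>= 0).
#' @param seed integer seed; the draw order is `u`, then `w`, then `b`.
#' @return An object of class `"circuit_params"`.
#' @export
circuit_params <- function(N, psi = activation("sigmoid", 1, 0),
                           phi = activation("sigmoid", 1, 0),
                           bias_sd = 0, seed = 1L) {
  stopifnot(is.numeric(N), length(N) == 1L, N == round(N))
  if (N < 2) stop("`N` must be at least 2")
  if (bias_sd < 0) stop("`bias_sd` must be >= 0")
  check_act(psi); check_act(phi)
  structure(list(N = as.integer(N), psi = psi, phi = phi,
                 bias_sd = bias_sd, seed = as.integer(seed)),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("<circuit_params> N = %d, bias_sd = %g, seed = %d\n",
              x$N, x$bias_sd, x$seed))
  cat("  psi: "); print(x$psi)
  cat("  phi: "); print(x$phi)
  invisible(x)
}

#' Initialize a circuit
#'
#' Draws `u` (N x N) and `w` (length N) i.i.d. from a zero-mean Gaussian
#' with variance `1/N`, and `b` from a zero-mean Gaussian with standard
#' deviation `bias_sd` (identically zero when `bias_sd = 0`). Fully
#' reproducible from `params$seed`.
#'
#' @param params a [circuit_params()] object.
#' @return An object of class `"circuit_state"` with elements `u`, `w`, `b`
#'   and `params`.
#' @export
init_circuit <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  N <- params$N
  set.seed(params$seed)
  sd0 <- 1 / sqrt(N)
  u <- matrix(stats::rnorm(N * N, 0, sd0), N, N)
  w <- stats::rnorm(N, 0, sd0)
  b <- if (params$bias_sd > 0) stats::rnorm(N, 0, params$bias_sd) else numeric(N)
  structure(list(u = u, w = w, b = b, params = params),
            class = "circuit_state")
}

#' @export
print.circuit_state <- function(x, ...) {
  cat(sprintf("<circuit_state> N = %d (var u = %.3g, var w = %.3g, target 1/N = %.3g)\n",
              x$params$N, stats::var(as.vector(x$u)), stats::var(x$w),
              1 / x$params$N))
  invisible(x)
}

#' Forward pass
#'
#' Computes, for each trial (row of `X`), the intermediate synaptic drives
#' `K = X u' + b`, the intermediate activity `Y = psi(K)`, the readout
#' drives `H = Y w` and the readout activity `Z = phi(H)`. With
#' variance-`1/N` weights and unit-variance inputs all of these are O(1) in
#' the circuit size.
#'
#' @param state a [init_circuit()] state.
#' @param X trials x N input matrix.
#' @return An object of class `"forward_result"`: list with `K`, `Y`
#'   (trials x N), `H`, `Z` (length trials).
#' @export
forward <- function(state, X) {
  stopifnot(inherits(state, "circuit_state"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  N <- state$params$N
  if (ncol(X) != N)
    stop(sprintf("input has %d columns but the circuit width is %d", ncol(X), N))
  K <- tcrossprod(X, state$u)
  if (any(state$b != 0)) K <- sweep(K, 2L, state$b, "+")
  Y <- act_fun(K, state$params$psi)
  H <- as.vector(Y %*% state$w)
  Z <- act_fun(H, state$params$phi)
  structure(list(K = K, Y = Y, H = H, Z = Z), class = "forward_result")
}

#' Pre-learning synaptic drives for very wide circuits
#'
#' Computes the initial intermediate-layer drives `K0 = X u0'` without ever
#' materializing the full `N x N` weight matrix: rows of `u0` are drawn in
#' blocks and immediately contracted against the inputs. This makes drive
#' statistics at initialization accessible at widths (N of order 1e4-1e5)
#' where the full matrix would not fit in memory. The sampled `u0` is
#' reproducible from `seed` but is drawn in a different order than
#' [init_circuit()] uses, so the two are distinct samplers.
#'
#' @param X trials x N input matrix.
#' @param seed integer seed for `u0`.
#' @param block number of intermediate neurons sampled per block.
#' @return trials x N matrix of initial drives.
#' @export
initial_drives <- function(X, seed = 1L, block = 512L) {
  stopifnot(is.matrix(X))
  N <- ncol(X)
  set.seed(as.integer(seed))
  sd0 <- 1 / sqrt(N)
  K0 <- matrix(0, nrow(X), N)
  i <- 1L
  while (i <= N) {
    j <- min(i + block - 1L, N)
    U <- matrix(stats::rnorm((j - i + 1L) * N, 0, sd0), j - i + 1L, N)
    K0[, i:j] <- tcrossprod(X, U)
    i <- j + 1L
  }
  K0
}
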