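#' Training configuration
#'
#' Full-batch vanilla gradient descent on the quadratic loss, with
#' independent learning rates for the two weight sets: the intermediate
#' weights `u` use `eta_u` (default 0.1) and the readout vector `w` uses
#' `eta_u * eta_ratio`. With `eta_ratio = 0` the readout is frozen at its
#' initial value. Training stops when the loss drops below `loss_tol`
#' (default 1e-5) or after `max_epochs` epochs; runs whose loss exceeds
#' `divergence_tol` abort with a diagnostic.
#'
#' @param eta_u learning rate for `u` (> 0).
#' @param eta_ratio ratio `eta_w / eta_u` (>= 0).
#' @param loss_tol stopping loss (> 0).
#' @param max_epochs epoch cap.
#' @param record_epochs integer vector of epochs at which to snapshot the
#'   full weight state (epoch 0, the initial state, is always recorded).
#' @param divergence_tol loss level treated as divergence.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(eta_u = 0.1, eta_ratio = 0, loss_tol = 1e-5,
                         max_epochs = 500000L, record_epochs = integer(),
                         divergence_tol = 1e3) {
  if (eta_u <= 0) stop("`eta_u` must be > 0")
  if (eta_ratio < 0) stop("`eta_ratio` must be >= 0")
  if (loss_tol <= 0) stop("`loss_tol` must be > 0")
  structure(list(eta_u = eta_u, eta_ratio = eta_ratio, loss_tol = loss_tol,
                 max_epochs = as.integer(max_epochs),
                 record_epochs = as.integer(record_epochs),
                 divergence_tol = divergence_tol),
            class = "train_config")
}

#' Quadratic readout loss
#'
#' `E = (1 / 2P) * sum_s (target_s - Z_s)^2`.
#'
#' @param Z readout activity, length P.
#' @param target readout targets, length P.
#' @export
mse_loss <- function(Z, target) {
  if (length(Z) == 0L) stop("empty input")
  if (length(Z) != length(target)) stop("`Z` and `target` lengths differ")
  sum((target - Z)^2) / (2 * length(Z))
}

#' Exact gradients of the loss
#'
#' Analytic backpropagation of the quadratic loss through the two-layer
#' network. With the per-trial error signal
#' `eps_s = (target_s - phi(h_s)) * phi'(h_s)`, the gradients are
#' `dE/dw = -(1/P) sum_s eps_s psi(k_s)` and
#' `dE/du = -(1/P) sum_s eps_s (w * psi'(k_s)) x_s'` (outer product), so
#' that descent subtracts `eta * gradient`.
#'
#' @param state a `"circuit_state"`.
#' @param task a `"task_data"` with matching width.
#' @return list with `du` (N x N) and `dw` (length N).
#' @export
gradients <- function(state, task) {
  fw <- forward(state, task$X)
  P <- task$P
  eps <- (task$target - fw$Z) * act_deriv(fw$H, state$params$phi)
  dw <- -as.vector(crossprod(fw$Y, eps)) / P
  Dpsi <- act_deriv(fw$K, state$params$psi)
  E <- (eps / P) * (Dpsi * rep(state$w, each = P))
  du <- -crossprod(E, task$X)
  list(du = du, dw = dw)
}

#' Train a circuit by full-batch gradient descent
#'
#' Iterates `u <- u - eta_u * dE/du`, `w <- w - eta_u * eta_ratio * dE/dw`
#' until the loss drops below `config$loss_tol` or `max_epochs` is reached.
#' The loss is recorded every epoch; full weight snapshots are kept at epoch
#' 0 and at `config$record_epochs`.
#'
#' @param state initial `"circuit_state"`.
#' @param task a `"task_data"`.
#' @param config a [train_config()].
#' @return An object of class `"trajectory"`: list with `losses` (per-epoch,
#'   starting at epoch 0), `snapshots` (named list of `"circuit_state"`s),
#'   `final_state`, `initial_state`, `converged`, `diverged`, `final_epoch`,
#'   `config`.
#' @export
train <- function(state, task, config = train_config()) {
  stopifnot(inherits(state, "circuit_state"), inherits(task, "task_data"),
            inherits(config, "train_config"))
  if (task$N != state$params$N)
    stop("task input dimension does not match circuit width")
  psi <- state$params$psi; phi <- state$params$phi
  # psi'(K) recovered from Y itself (theta1 * Y * (1 - Y) for the sigmoid):
  # saves one full logistic evaluation over the P x N drive matrix per epoch
  deriv_from_Y <- if (psi$type == "sigmoid") {
    function(Y) psi$theta1 * Y * (1 - Y)
  } else {
    function(Y) { d <- Y; d[] <- 1; d }
  }
  u <- state$u; w <- state$w; b <- state$b
  has_b <- any(b != 0)
  X <- task$X; tgt <- task$target; P <- task$P
  eta_u <- config$eta_u; eta_w <- config$eta_u * config$eta_ratio
  snapshots <- list(`0` = state)
  losses <- numeric(config$max_epochs + 1L)
  converged <- FALSE; diverged <- FALSE
  epoch <- 0L
  repeat {
    K <- tcrossprod(X, u)
    if (has_b) K <- sweep(K, 2L, b, "+")
    Y <- act_fun(K, psi)
    H <- as.vector(Y %*% w)
    Z <- act_fun(H, phi)
    loss <- sum((tgt - Z)^2) / (2 * P)
    losses[epoch + 1L] <- loss
    if (loss > config$divergence_tol) {
      diverged <- TRUE
      warning(sprintf("training diverged at epoch %d (loss %.3g)", epoch, loss))
      break
    }
    if (loss < config$loss_tol) { converged <- TRUE; break }
    if (epoch >= config$max_epochs) break
    eps <- (tgt - Z) * act_deriv(H, phi)
    E <- (eps / P) * (deriv_from_Y(Y) * rep(w, each = P))
    u <- u + eta_u * crossprod(E, X)
    if (eta_w > 0) w <- w + eta_w * as.vector(crossprod(Y, eps)) / P
    epoch <- epoch + 1L
    if (epoch %in% config$record_epochs) {
      st <- state; st$u <- u; st$w <- w
      snapshots[[as.character(epoch)]] <- st
    }
  }
  final_state <- state; final_state$u <- u; final_state$w <- w
  structure(list(losses = losses[seq_len(epoch + 1L)],
                 snapshots = snapshots,
                 initial_state = state, final_state = final_state,
                 converged = converged, diverged = diverged,
                 final_epoch = epoch, config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d epochs, final loss %.3g, %s\n",
              x$final_epoch, x$losses[length(x$losses)],
              if (x$converged) "converged" else
                if (x$diverged) "DIVERGED" else "epoch cap reached"))
  invisible(x)
}

#' Weight-change norms along a trajectory
#'
#' Root-mean-square entrywise changes `|u - u0|` and `|w - w0|` for every
#' snapshot plus the final state, together with the corresponding RMS of the
#' initial weights. In wide circuits the theory predicts
#' `delta u ~ O(N^{-3/2})` and `delta w ~ O(N^{-1})`, both asymptotically
#' small relative to the `O(N^{-1/2})` initial weights.
#'
#' @param traj a `"trajectory"`.
#' @return data frame with columns `epoch`, `rms_du`, `rms_dw`, `rel_du`,
#'   `rel_dw`.
#' @export
weight_change_norms <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  u0 <- traj$initial_state$u; w0 <- traj$initial_state$w
  rms <- function(x) sqrt(mean(x^2))
  states <- c(traj$snapshots[-1L], list(final = traj$final_state))
  epochs <- c(as.integer(names(traj$snapshots)[-1L]), traj$final_epoch)
  out <- data.frame(
    epoch = c(0L, epochs),
    rms_du = c(0, vapply(states, function(s) rms(s$u - u0), 0)),
    rms_dw = c(0, vapply(states, function(s) rms(s$w - w0), 0)))
  out$rel_du <- out$rms_du / rms(u0)
  out$rel_dw <- out$rms_dw / rms(w0)
  rownames(out) <- NULL
  out
}
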