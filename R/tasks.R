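#' @title Categorization task datasets
#' @description Generators for the three task variants. In all of them the
#'   circuit must map each of `P` sensory input vectors to one of two
#'   readout targets, `zA` (high) for category A and `zB` (low) for
#'   category B; the defaults are `zA = 0.75`, `zB = 0.25`.
#'
#'   * *simple*: `P = Q` stimuli, each represented by an i.i.d. standard
#'     Gaussian vector; the first half of the stimuli belongs to category A,
#'     the second half to B. At large `N` the inputs are orthonormal.
#'   * *structured*: as the simple task, but each input mixes a private
#'     Gaussian component with a shared two-dimensional continuous component
#'     at angle `2*pi*s/Q`, so that nearby stimuli are correlated
#'     (`sigma^2 * cos(2*pi*(s - s')/Q)`).
#'   * *context*: `P = Q^2` trials, one per (stimulus, context-cue) pair,
#'     with input `(mu_S + nu_C) / sqrt(2)`. Cues `1..Q/2` signal context 1,
#'     the rest context 2; the stimulus-to-category mapping is reversed
#'     between contexts, so for `Q = 2` the task is an XOR and for every `Q`
#'     the inputs are not linearly separable.
#' @name tasks
NULL

new_task <- function(X, stimulus, cue, context, category, zA, zB, kind, Q, seed) {
  structure(list(
    X = X, stimulus = stimulus, cue = cue, context = context,
    category = category, target = ifelse(category == "A", zA, zB),
    kind = kind, N = ncol(X), Q = Q, P = nrow(X), zA = zA, zB = zB,
    seed = seed), class = "task_data")
}

#' @export
print.task_data <- function(x, ...) {
  cat(sprintf("<task_data> %s task: P = %d trials, Q = %d, N = %d, targets %g/%g\n",
              x$kind, x$P, x$Q, x$N, x$zA, x$zB))
  invisible(x)
}

check_Q <- function(Q) {
  stopifnot(is.numeric(Q), length(Q) == 1L, Q == round(Q))
  if (Q < 2 || Q %% 2 != 0) stop("`Q` must be a positive even integer")
  as.integer(Q)
}

#' Simple categorization task
#'
#' @param N input dimension.
#' @param Q number of stimuli (even); the first `Q/2` are category A.
#' @param zA,zB readout targets for the two categories, in (0, 1).
#' @param seed integer seed (stimulus vectors are re-drawn per seed).
#' @return A `"task_data"` object.
#' @rdname tasks
#' @export
make_simple_task <- function(N, Q = 20L, zA = 0.75, zB = 0.25, seed = 1L) {
  Q <- check_Q(Q)
  if (Q >= N) warning("`Q` >= `N`: outside the large-width regime the theory assumes")
  set.seed(as.integer(seed))
  X <- matrix(stats::rnorm(Q * N), Q, N)
  category <- rep(c("A", "B"), each = Q / 2)
  new_task(X, stimulus = seq_len(Q), cue = NULL, context = NULL,
           category = category, zA = zA, zB = zB, kind = "simple",
           Q = Q, seed = seed)
}

#' Structured simple task (continuous tuning)
#'
#' @param sigma fraction of input variance that is continuous, in [0, 1);
#'   the default 1/3 gives weak but non-vanishing neighbour correlations.
#' @rdname tasks
#' @export
make_structured_task <- function(N, Q = 12L, sigma = 1 / 3, zA = 0.75,
                                 zB = 0.25, seed = 1L) {
  Q <- check_Q(Q)
  if (sigma < 0 || sigma >= 1) stop("`sigma` must lie in [0, 1)")
  set.seed(as.integer(seed))
  mu <- matrix(stats::rnorm(Q * N), Q, N)
  xi1 <- stats::rnorm(N)
  xi2 <- stats::rnorm(N)
  theta <- 2 * pi * seq_len(Q) / Q
  X <- sqrt(1 - sigma^2) * mu +
    sigma * (outer(cos(theta), xi1) + outer(sin(theta), xi2))
  category <- rep(c("A", "B"), each = Q / 2)
  tk <- new_task(X, stimulus = seq_len(Q), cue = NULL, context = NULL,
                 category = category, zA = zA, zB = zB, kind = "structured",
                 Q = Q, seed = seed)
  tk$sigma <- sigma
  tk
}

#' Context-dependent categorization task
#'
#' @rdname tasks
#' @export
make_context_task <- function(N, Q = 8L, zA = 0.75, zB = 0.25, seed = 1L) {
  Q <- check_Q(Q)
  set.seed(as.integer(seed))
  mu <- matrix(stats::rnorm(Q * N), Q, N)
  nu <- matrix(stats::rnorm(Q * N), Q, N)
  grid <- expand.grid(S = seq_len(Q), C = seq_len(Q))
  X <- (mu[grid$S, , drop = FALSE] + nu[grid$C, , drop = FALSE]) / sqrt(2)
  context <- ifelse(grid$C <= Q / 2, 1L, 2L)
  first_half <- grid$S <= Q / 2
  category <- ifelse((context == 1L) == first_half, "A", "B")
  new_task(X, stimulus = grid$S, cue = grid$C, context = context,
           category = category, zA = zA, zB = zB, kind = "context",
           Q = Q, seed = seed)
}

#' Trial-by-trial input correlation matrix
#'
#' `mode = "empirical"` returns the normalized dot products
#' `x_s . x_s' / N` of the generated inputs; `mode = "theoretical"` returns
#' their exact leading-order (large N) values: the identity for the simple
#' task, `sigma^2 cos(2 pi (s - s')/Q) + (1 - sigma^2) delta_ss'` for the
#' structured task, and the 1 / 1/2 / 0 pattern (same trial / shared
#' stimulus or cue / neither) for the context task.
#'
#' @param task a `"task_data"` object.
#' @param mode `"empirical"` or `"theoretical"`.
#' @return P x P numeric matrix.
#' @export
input_correlation <- function(task, mode = c("empirical", "theoretical")) {
  stopifnot(inherits(task, "task_data"))
  mode <- match.arg(mode)
  if (mode == "empirical") return(tcrossprod(task$X) / task$N)
  theoretical_input_pattern(task$kind, task$Q,
                            sigma = if (!is.null(task$sigma)) task$sigma else 0)
}

# leading-order input-correlation pattern, constructed without sampling
theoretical_input_pattern <- function(kind, Q, sigma = 0) {
  if (kind == "simple") return(diag(Q))
  if (kind == "structured") {
    s <- seq_len(Q)
    M <- sigma^2 * cos(2 * pi * outer(s, s, "-") / Q)
    diag(M) <- 1
    return(M)
  }
  grid <- expand.grid(S = seq_len(Q), C = seq_len(Q))
  sameS <- outer(grid$S, grid$S, "==")
  sameC <- outer(grid$C, grid$C, "==")
  M <- 0.5 * (sameS + sameC)  # 1 when both match, 1/2 when one, 0 when none
  M
}

#' Export a tabular trial manifest
#'
#' Writes one row per trial with columns `trial`, `stimulus`, `cue`,
#' `context`, `category`, `target`.
#'
#' @param task a `"task_data"` object.
#' @param path output CSV path.
#' @return The manifest data frame, invisibly.
#' @export
write_trial_manifest <- function(task, path) {
  stopifnot(inherits(task, "task_data"))
  df <- data.frame(
    trial = seq_len(task$P),
    stimulus = task$stimulus,
    cue = if (is.null(task$cue)) NA_integer_ else task$cue,
    context = if (is.null(task$context)) NA_integer_ else task$context,
    category = task$category,
    target = task$target)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
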