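#' @title Large-width analytical theory
#' @description In wide circuits, learning-induced weight changes are small
#'   and post-learning activity is linear in them: activity moves along
#'   fixed spanning vectors `v^{qs}` proportional to the initial readout
#'   `w0` gated by products of initial response gains, with coefficients
#'   (activity coordinates) that solve a reduced linear system. All
#'   population statistics then reduce to Gaussian averages of the
#'   activation function and its derivative, evaluated here by
#'   Gauss-Hermite quadrature.
#' @name theory
NULL

gh_rule <- function(order) {
  g <- pracma::gaussHermite(order)
  list(x = sqrt(2) * g$x, w = g$w / sqrt(pi))   # probabilists' weighting
}

#' Gaussian average of a function
#'
#' `E[F(a)]` for standard Gaussian `a`, by Gauss-Hermite quadrature with
#' probabilists' weighting.
#'
#' @param f vectorized function of one argument.
#' @param order quadrature size (default 201).
#' @export
gauss_avg <- function(f, order = 201L) {
  if (order < 2) stop("`order` must be >= 2")
  r <- gh_rule(order)
  sum(r$w * f(r$x))
}

#' Correlated two-point Gaussian average
#'
#' `E[F(a) F(b)]` for unit-variance Gaussians with covariance `cov`,
#' computed via the shared-variable decomposition
#' `a = sqrt(cov) u + sqrt(1 - cov) v1`, `b = sqrt(cov) u + sqrt(1 - cov) v2`
#' and nested quadrature. The covariance-1/2 case corresponds to the
#' context task, where two trials sharing a stimulus or a cue have drives
#' `(s + b1)/sqrt(2)` and `(s + b2)/sqrt(2)` with a common component.
#'
#' @param f vectorized function.
#' @param cov covariance in [0, 1].
#' @param order quadrature size per dimension.
#' @export
gauss_avg_pair <- function(f, cov = 0.5, order = 201L) {
  if (cov < 0 || cov > 1) stop("`cov` must lie in [0, 1]")
  if (order < 2) stop("`order` must be >= 2")
  r <- gh_rule(order)
  inner <- vapply(r$x, function(u)
    sum(r$w * f(sqrt(cov) * u + sqrt(1 - cov) * r$x)), 0)
  sum(r$w * inner^2)
}

# per-dimension quadrature orders for shared-variable integrals
quad_order_for <- function(nvars) c(101L, 61L, 31L, 19L, 13L)[min(nvars, 5L)]

#' Multi-point Gaussian average over a coincidence pattern
#'
#' `E[prod_t F(k_t)]` where each trial `t` has drive
#' `k_t = (a_{S[t]} + b_{C[t]}) / sqrt(2)` and the `a`/`b` variables are
#' independent standard Gaussians shared exactly according to the stimulus
#' and cue indices. Trials whose variables are disjoint from the rest
#' factorize exactly (e.g. all indices distinct gives `<F>^m`; a single
#' shared stimulus pair gives `<FF> <F>^(m-2)`); the remaining connected
#' blocks are evaluated by tensor-grid quadrature over their shared
#' variables.
#'
#' @param f vectorized function.
#' @param S,C integer vectors (one entry per trial) of stimulus and cue
#'   indices.
#' @param order optional quadrature size per dimension; by default chosen
#'   from the number of shared dimensions in each block.
#' @export
gauss_avg_quad <- function(f, S, C, order = NULL) {
  m <- length(S)
  if (length(C) != m || m < 1L) stop("`S` and `C` must have equal length >= 1")
  avar <- paste0("a", S); bvar <- paste0("b", C)
  # connected components of the trial/variable graph
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (comp[i] != comp[j] && (avar[i] == avar[j] || bvar[i] == bvar[j])) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  val <- 1
  for (cc in unique(comp)) {
    tr <- which(comp == cc)
    vars <- unique(c(avar[tr], bvar[tr]))
    n <- if (is.null(order)) quad_order_for(length(vars)) else order
    r <- gh_rule(n)
    idx <- as.matrix(do.call(expand.grid,
                             rep(list(seq_len(n)), length(vars))))
    colnames(idx) <- vars
    wprod <- Reduce(`*`, lapply(vars, function(v) r$w[idx[, v]]))
    fprod <- Reduce(`*`, lapply(tr, function(t)
      f((r$x[idx[, avar[t]]] + r$x[idx[, bvar[t]]]) / sqrt(2))))
    val <- val * sum(wprod * fprod)
  }
  val
}

#' Gaussian population averages of an activation function
#'
#' The scalar averages that parametrize all theoretical predictions:
#' `m1 = <psi>`, `m2 = <psi^2>`, `d1 = <psi'>`, `d2 = <psi'^2>`,
#' `d4 = <psi'^4>` over a standard Gaussian drive, plus the correlated
#' pair averages at covariance 1/2, `mm = <psi psi>` and `dd = <psi' psi'>`.
#'
#' @param psi an [activation()].
#' @param order quadrature size.
#' @return An object of class `"gaussian_averages"`.
#' @export
gaussian_averages <- function(psi, order = 201L) {
  check_act(psi)
  fv <- function(a) act_fun(a, psi)
  fd <- function(a) act_deriv(a, psi)
  structure(list(
    m1 = gauss_avg(fv, order), m2 = gauss_avg(function(a) fv(a)^2, order),
    d1 = gauss_avg(fd, order), d2 = gauss_avg(function(a) fd(a)^2, order),
    d4 = gauss_avg(function(a) fd(a)^4, order),
    mm = gauss_avg_pair(fv, 0.5, order), dd = gauss_avg_pair(fd, 0.5, order),
    psi = psi, order = as.integer(order)), class = "gaussian_averages")
}

#' @export
print.gaussian_averages <- function(x, ...) {
  cat(sprintf(paste0("<gaussian_averages> m1 = %.4f, m2 = %.4f, d1 = %.4f, ",
                     "d2 = %.4f, d4 = %.5f, mm = %.4f, dd = %.4f\n"),
              x$m1, x$m2, x$d1, x$d2, x$d4, x$mm, x$dd)); invisible(x)
}

singularity_error <- function(msg) {
  stop(structure(class = c("singularity_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

solve_coordinates <- function(alpha, beta, zA, zB, phi, task, Q, eta_ratio, ga) {
  ihA <- act_inv(zA, phi); ihB <- act_inv(zB, phi)
  gamma <- beta / alpha * (ihA - ihB)
  cA <- (ihA + gamma) / (alpha + 2 * beta)
  cB <- (ihB - gamma) / (alpha + 2 * beta)
  structure(list(task = task, alpha = alpha, beta = beta, gamma = gamma,
                 cA = cA, cB = cB, Q = Q, eta_ratio = eta_ratio,
                 zA = zA, zB = zB, phi = phi, ga = ga),
            class = "theory_prediction")
}

#' @export
print.theory_prediction <- function(x, ...) {
  cat(sprintf("<theory_prediction> %s task, Q = %d, eta_ratio = %g\n",
              x$task, x$Q, x$eta_ratio))
  cat(sprintf("  alpha = %.5f, beta = %.5f, gamma = %.5f\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  cA = %.4f, cB = %.4f\n", x$cA, x$cB))
  invisible(x)
}

#' Activity coordinates for the simple task
#'
#' Solves the reduced 2 x 2 linear system for the category-dependent
#' coordinates:
#' `phi^-1(zA) = alpha cA + beta (cA + cB)` and likewise for `zB`, with
#' `alpha = <psi'^2> + r (<psi^2> - <psi>^2)` and
#' `beta = r (Q/2) <psi>^2`, where `r = eta_w / eta_u`. The shift
#' `gamma = (beta/alpha)(phi^-1(zA) - phi^-1(zB))` is positive, hence
#' `cA > cB` always. The non-self-averaging initial readout drive `h0` is
#' dropped (average-behaviour solution); see
#' [activity_coordinates_full()] for the per-realization variant.
#'
#' @param ga a [gaussian_averages()] object.
#' @param Q number of stimuli.
#' @param eta_ratio learning-rate ratio `eta_w / eta_u`.
#' @param zA,zB readout targets.
#' @param phi readout [activation()].
#' @return A `"theory_prediction"` with `alpha`, `beta`, `gamma`, `cA`, `cB`.
#' @export
simple_coordinates <- function(ga, Q, eta_ratio = 0, zA = 0.75, zB = 0.25,
                               phi = activation("sigmoid", 1, 0)) {
  stopifnot(inherits(ga, "gaussian_averages"))
  r <- eta_ratio
  alpha <- ga$d2 + r * (ga$m2 - ga$m1^2)
  beta <- r * (Q / 2) * ga$m1^2
  if (alpha <= 1e-8)
    singularity_error("alpha vanishes: the coordinate system is singular")
  solve_coordinates(alpha, beta, zA, zB, phi, "simple", as.integer(Q),
                    eta_ratio, ga)
}

#' Context-task coefficients alpha and beta
#'
#' Relative to the simple task, input correlations between trials sharing a
#' stimulus or a cue add covariance-1/2 pair terms:
#' `alpha = <psi'^2> + r(<psi^2> - <psi>^2)
#'          - 2 [ <psi' psi'>/2 + r(<psi psi> - <psi>^2) ]` and
#' `beta = Q [ <psi' psi'>/2 + r(<psi psi> - <psi>^2) ] + r (Q^2/2) <psi>^2`.
#' For a linear intermediate layer `alpha` vanishes identically -- the
#' signature of the task's linear non-separability.
#'
#' @inheritParams simple_coordinates
#' @return named numeric vector with elements `alpha`, `beta`.
#' @export
context_alpha_beta <- function(ga, Q, eta_ratio = 0) {
  stopifnot(inherits(ga, "gaussian_averages"))
  r <- eta_ratio
  shared <- 0.5 * ga$dd + r * (ga$mm - ga$m1^2)
  c(alpha = ga$d2 + r * (ga$m2 - ga$m1^2) - 2 * shared,
    beta = Q * shared + r * (Q^2 / 2) * ga$m1^2)
}

#' Activity coordinates for the context-dependent task
#'
#' Same 2 x 2 solve as [simple_coordinates()] with the context-task
#' `alpha`, `beta` of [context_alpha_beta()]. When `alpha` falls below the
#' singularity tolerance (as it does exactly for a linear intermediate
#' activation) a `"singularity_error"` is raised: the coordinates diverge
#' because the sensory inputs are not linearly separable.
#'
#' @inheritParams simple_coordinates
#' @param tol singularity tolerance on `alpha`.
#' @export
context_coordinates <- function(ga, Q, eta_ratio = 0, zA = 0.75, zB = 0.25,
                                phi = activation("sigmoid", 1, 0),
                                tol = 1e-8) {
  ab <- context_alpha_beta(ga, Q, eta_ratio)
  if (ab[["alpha"]] <= tol)
    singularity_error(paste0(
      "alpha = ", format(ab[["alpha"]]), " <= tolerance: with an ",
      "(effectively) linear intermediate activation the context task is ",
      "not linearly separable and the activity coordinates diverge"))
  solve_coordinates(ab[["alpha"]], ab[["beta"]], zA, zB, phi, "context",
                    as.integer(Q), eta_ratio, ga)
}

#' Per-realization activity coordinates (full linear system)
#'
#' Solves the full P-dimensional linear system for the coordinates of one
#' specific circuit realization, retaining the non-self-averaging initial
#' readout drives `h0^s` on the left-hand side and using the empirical
#' population averages of the realization on the right-hand side. The
#' reduced solvers describe the average behaviour; this variant describes
#' one circuit.
#'
#' @param state pre-learning `"circuit_state"`.
#' @param task a `"task_data"`.
#' @param eta_ratio learning-rate ratio.
#' @return numeric vector of per-trial coordinates `c_s`.
#' @export
activity_coordinates_full <- function(state, task, eta_ratio = 0) {
  fw <- forward(state, task$X)
  Dpsi <- act_deriv(fw$K, state$params$psi)
  N <- task$N
  M <- (tcrossprod(task$X) / N) * (tcrossprod(Dpsi) / N) +
    eta_ratio * tcrossprod(fw$Y) / N
  rhs <- act_inv(task$target, state$params$phi) - fw$H
  as.vector(solve(M, rhs))
}

#' Linearized (lazy-regime) prediction of post-learning activity
#'
#' Builds the spanning-vector expansion `y^s = y0^s + sum_q c_q v^{qs}`
#' with `v^{qs} = <x^q . x^s>/N * w0 * psi'(k0^q) * psi'(k0^s)`, using the
#' theoretical input correlations (identity for the simple task; the
#' 1 / 1/2 / 0 neighbour pattern for the context task) to select the
#' non-zero terms. Drives are predicted analogously without the second
#' gain factor.
#'
#' @param state0 pre-learning `"circuit_state"`.
#' @param task a simple or context `"task_data"`.
#' @param coords a `"theory_prediction"` from the matching solver.
#' @return list with predicted `Y`, `K` and changes `dY`, `dK`, plus the
#'   initial `Y0`, `K0`.
#' @export
linearized_prediction <- function(state0, task, coords) {
  stopifnot(inherits(coords, "theory_prediction"))
  if (!task$kind %in% c("simple", "context"))
    stop("linearized predictions cover the simple and context tasks")
  if (task$kind != coords$task)
    stop("coordinates were solved for the ", coords$task, " task")
  fw <- forward(state0, task$X)
  Dpsi <- act_deriv(fw$K, state0$params$psi)
  M <- theoretical_input_pattern(task$kind, task$Q)
  cvec <- ifelse(task$category == "A", coords$cA, coords$cB)
  P <- task$P
  dK <- (M %*% (cvec * Dpsi)) * rep(state0$w, each = P)
  dY <- Dpsi * dK
  list(Y = fw$Y + dY, K = fw$K + dK, dY = dY, dK = dK,
       Y0 = fw$Y, K0 = fw$K)
}

#' Closed-form activity-measure predictions for the simple task
#'
#' Average category selectivity, category clustering and category
#' correlation (pairwise and label-averaged definitions) implied by the
#' coordinates. `selectivity` keeps the full finite-size denominator
#' (identical to the clustering expression); `selectivity_leading` is the
#' leading-order form `(cA - cB)^2 <psi'^2>^2 / (4 N (<psi^2> - <psi>^2))`.
#' The sign of both correlation predictions is the sign of `cA * cB`.
#'
#' @param coords a simple-task `"theory_prediction"`.
#' @param N circuit width.
#' @return list of scalar predictions.
#' @export
simple_theory_measures <- function(coords, N) {
  stopifnot(inherits(coords, "theory_prediction"), coords$task == "simple")
  ga <- coords$ga; cA <- coords$cA; cB <- coords$cB; Q <- coords$Q
  v0 <- ga$m2 - ga$m1^2
  num <- (cA - cB)^2 * ga$d2^2
  sel_lead <- num / (4 * N * v0)
  sel_full <- num /
    (4 * N * v0 + 2 * (cA^2 + cB^2) * ga$d4 - (cA + cB)^2 * ga$d2^2)
  corr <- cA * cB * ga$d2^2 /
    sqrt((N * v0 + cA^2 * ga$d4) * (N * v0 + cB^2 * ga$d4))
  corr_lead <- cA * cB * ga$d2^2 / (N * v0)
  den_avg <- function(cc)
    (2 / Q) * N * v0 + cc^2 * (ga$d2^2 + (2 / Q) * (ga$d4 - ga$d2^2))
  corr_avg <- cA * cB * ga$d2^2 / sqrt(den_avg(cA) * den_avg(cB))
  list(selectivity = sel_full, selectivity_leading = sel_lead,
       clustering = sel_full,
       correlation = corr, correlation_leading = corr_lead,
       correlation_averaged = corr_avg,
       correlation_averaged_leading = (Q / 2) * corr_lead)
}

#' Predicted table of normalized activity dot products (simple task)
#'
#' `<y_i^s y_i^s'>_i` for every trial pair: `<psi^2> + c_s^2 <psi'^4>/N` on
#' the diagonal and `<psi>^2 + c_s c_s' <psi'^2>^2 / N` off it.
#'
#' @inheritParams simple_theory_measures
#' @return Q x Q matrix.
#' @export
simple_dot_products <- function(coords, N) {
  stopifnot(inherits(coords, "theory_prediction"), coords$task == "simple")
  ga <- coords$ga; Q <- coords$Q
  cvec <- rep(c(coords$cA, coords$cB), each = Q / 2)
  M <- ga$m1^2 + outer(cvec, cvec) * ga$d2^2 / N
  diag(M) <- ga$m2 + cvec^2 * ga$d4 / N
  M
}

#' Predicted response-change variances per category
#'
#' Variance across the population of the learning-induced,
#' stimulus-averaged response change: `var_A = cA^2 <psi'^2>^2 / N` (and
#' `cB` for B). The two variances coincide iff `cA^2 = cB^2`, i.e. for
#' symmetric target drives.
#'
#' @inheritParams simple_theory_measures
#' @export
asymmetry_prediction <- function(coords, N) {
  stopifnot(inherits(coords, "theory_prediction"))
  ga <- coords$ga
  list(var_A = coords$cA^2 * ga$d2^2 / N,
       var_B = coords$cB^2 * ga$d2^2 / N)
}

#' Variability decomposition of the initial readout drive
#'
#' Splits `h0^s` into a frozen, realization-specific component
#' `<psi> kappa` with `kappa = sum_i w0_i`, and a stimulus-specific
#' fluctuation `eps^s` with unit variance set by `<psi^2> - <psi>^2`. Also
#' returns the coordinate correction `delta^s = -h0^s / <psi'^2>` valid in
#' the slow-readout regime (`eta_w << eta_u`).
#'
#' @param h0 initial readout drives (length P).
#' @param ga a [gaussian_averages()].
#' @param w0 initial readout vector.
#' @export
variability_decomposition <- function(h0, ga, w0) {
  kappa <- sum(w0)
  list(kappa = kappa,
       eps = (h0 - ga$m1 * kappa) / sqrt(ga$m2 - ga$m1^2),
       delta = -h0 / ga$d2)
}

#' Context-selectivity growth coefficient
#'
#' `A1 - A2 = (Q/2) (<psi' psi'> - <psi'>^2)`, the dominant (in Q)
#' coefficient of the drive-level context-selectivity change. It is
#' strictly positive for any strictly nonlinear activation and vanishes for
#' a linear one, showing that the growth of context selectivity is a
#' nonlinearity effect.
#'
#' @param ga a [gaussian_averages()].
#' @param Q number of stimuli/cues.
#' @export
a1_minus_a2 <- function(ga, Q) (Q / 2) * (ga$dd - ga$d1^2)

#' Pre-learning drive geometry of the XOR task
#'
#' For `Q = 2` the four trials' initial synaptic drives sit on a square:
#' trials sharing exactly one of stimulus/cue (consecutive vertices,
#' different categories) have squared distance `2 - 2 (1/2) = 1`, trials
#' sharing neither (opposite vertices, same category) have `2 - 0 = 2`.
#' The resulting drive-level category clustering is `(1 - 2)/(1 + 2) = -1/3`.
#'
#' @return list with `d_consecutive2`, `d_opposite2`, `initial_clustering`.
#' @export
xor_geometry <- function() {
  M <- theoretical_input_pattern("context", 2L)
  grid <- expand.grid(S = 1:2, C = 1:2)
  context <- ifelse(grid$C <= 1L, 1L, 2L)
  catA <- (context == 1L) == (grid$S <= 1L)
  D2 <- 2 - 2 * M
  diff_pairs <- outer(catA, catA, "!=")
  same_pairs <- outer(catA, catA, "==") & !(diag(4L) > 0)
  dd <- mean(D2[diff_pairs]); ds <- mean(D2[same_pairs])
  list(d_consecutive2 = unique(D2[diff_pairs])[1L],
       d_opposite2 = unique(D2[same_pairs])[1L],
       initial_clustering = (dd - ds) / (dd + ds))
}

# ---- context-task dot-product tables -------------------------------------

# encode the equality pattern of four index values as an integer key
eq_key4 <- function(v1, v2, v3, v4) {
  (v1 == v2) + 2L * (v1 == v3) + 4L * (v1 == v4) +
    8L * (v2 == v3) + 16L * (v2 == v4) + 32L * (v3 == v4)
}

# memoized four-point gain average <psi'(k_q) psi'(k_s) psi'(k_q') psi'(k_s')>
four_point_cache <- function(psi) {
  cache <- new.env(parent = emptyenv())
  fd <- function(a) act_deriv(a, psi)
  function(Sq, Ss, Sq2, Ss2, Cq, Cs, Cq2, Cs2) {
    keys <- paste0(eq_key4(Sq, Ss, Sq2, Ss2), "_", eq_key4(Cq, Cs, Cq2, Cs2))
    out <- numeric(length(keys))
    for (k in unique(keys)) {
      if (is.null(cache[[k]])) {
        i <- match(k, keys)
        cache[[k]] <- gauss_avg_quad(
          fd, S = c(Sq[i], Ss[i], Sq2[i], Ss2[i]),
          C = c(Cq[i], Cs[i], Cq2[i], Cs2[i]))
      }
      out[keys == k] <- cache[[k]]
    }
    out
  }
}

# signature of a trial pair: everything the predicted dot product can
# depend on, by within-half permutation symmetry of the task
pair_signature <- function(S1, C1, S2, C2, Q) {
  paste(S1 <= Q / 2, S2 <= Q / 2, S1 == S2,
        C1 <= Q / 2, C2 <= Q / 2, C1 == C2, sep = "|")
}

#' Predicted dot-product tables for the context task
#'
#' Builds the P x P tables of predicted normalized dot products, pre and
#' post learning, for both the activity and the synaptic drive. The
#' pre-learning activity table follows the three-case input pattern
#' (`<psi^2>` same trial, `<psi psi>` shared stimulus or cue, `<psi>^2`
#' otherwise); the learning-induced part sums four-point (activity) or
#' two-point (drive) gain averages over the neighbour sets of both trials,
#' weighted by the input correlations, with a `1/N` prefactor. Averages are
#' evaluated once per index-coincidence pattern and shared across trial
#' pairs via the task's permutation symmetry.
#'
#' @param coords a context-task `"theory_prediction"`.
#' @param N circuit width.
#' @return list of P x P matrices `y0`, `y`, `k0`, `k`.
#' @export
context_dot_products <- function(coords, N) {
  stopifnot(inherits(coords, "theory_prediction"), coords$task == "context")
  ga <- coords$ga; Q <- coords$Q
  psi <- ga$psi
  grid <- expand.grid(S = seq_len(Q), C = seq_len(Q))
  P <- Q^2
  context <- ifelse(grid$C <= Q / 2, 1L, 2L)
  catA <- (context == 1L) == (grid$S <= Q / 2)
  cvec <- ifelse(catA, coords$cA, coords$cB)
  M <- theoretical_input_pattern("context", Q)

  # pre-learning tables
  y0 <- matrix(ga$m1^2, P, P)
  y0[M == 0.5] <- ga$mm
  diag(y0) <- ga$m2
  k0 <- M

  fp <- four_point_cache(psi)
  two_point <- function(key) {
    # key: 2 = same trial, 1 = share one index, 0 = none
    if (key == 2) ga$d2 else if (key == 1) ga$dd else ga$d1^2
  }

  # learning-induced parts, computed once per pair signature
  dy <- matrix(0, P, P); dk <- matrix(0, P, P)
  sig <- outer(seq_len(P), seq_len(P), function(i, j)
    pair_signature(grid$S[i], grid$C[i], grid$S[j], grid$C[j], Q))
  for (sg in unique(as.vector(sig))) {
    ij <- which(sig == sg, arr.ind = TRUE)[1L, ]
    s1 <- ij[1L]; s2 <- ij[2L]
    nb1 <- which(M[, s1] > 0); nb2 <- which(M[, s2] > 0)
    gq <- expand.grid(q = nb1, q2 = nb2)
    wts <- M[cbind(gq$q, rep(s1, nrow(gq)))] * M[cbind(gq$q2, rep(s2, nrow(gq)))]
    cc <- cvec[gq$q] * cvec[gq$q2]
    fv <- fp(grid$S[gq$q], rep(grid$S[s1], nrow(gq)),
             grid$S[gq$q2], rep(grid$S[s2], nrow(gq)),
             grid$C[gq$q], rep(grid$C[s1], nrow(gq)),
             grid$C[gq$q2], rep(grid$C[s2], nrow(gq)))
    dy[sig == sg] <- sum(wts * cc * fv) / N
    nshared <- (grid$S[gq$q] == grid$S[gq$q2]) + (grid$C[gq$q] == grid$C[gq$q2])
    tp <- vapply(nshared, two_point, 0)
    dk[sig == sg] <- sum(wts * cc * tp) / N
  }
  list(y0 = y0, y = y0 + dy, k0 = k0, k = k0 + dk)
}

measures_from_dots <- function(D, Q, mu) {
  P <- Q^2
  grid <- expand.grid(S = seq_len(Q), C = seq_len(Q))
  context <- ifelse(grid$C <= Q / 2, 1L, 2L)
  catA <- (context == 1L) == (grid$S <= Q / 2)
  eye <- diag(P) > 0
  n <- diag(D)
  d2 <- outer(n, n, "+") - 2 * D
  pear <- (D - mu^2) / sqrt(outer(n - mu^2, n - mu^2))
  sets <- list(
    category = list(diff = outer(catA, catA, "!="),
                    same = outer(catA, catA, "==") & !eye),
    context = list(diff = outer(context, context, "!="),
                   same = outer(context, context, "==") & !eye &
                     outer(grid$C, grid$C, "!=")),
    context2 = list(diff = outer(context, context, "!="),
                    same = outer(context, context, "==") & !eye))
  cl <- lapply(sets, function(s) {
    dd <- mean(d2[s$diff]); ds <- mean(d2[s$same]); (dd - ds) / (dd + ds)
  })
  avg_corr <- function(lab) {
    g1 <- lab == sort(unique(lab))[1L]
    ab <- mean(D[g1, !g1]); aa <- mean(D[g1, g1]); bb <- mean(D[!g1, !g1])
    (ab - mu^2) / sqrt((aa - mu^2) * (bb - mu^2))
  }
  list(clustering_category = cl$category,
       clustering_context = cl$context,
       clustering_context2 = cl$context2,
       correlation_category = mean(pear[sets$category$diff]),
       correlation_context = mean(pear[sets$context$diff]),
       correlation_category_avg = avg_corr(catA),
       correlation_context_avg = avg_corr(context))
}

#' Predicted activity measures for the context task
#'
#' Evaluates category/context clustering (primary and cue-inclusive
#' definitions) and category/context correlations (pairwise and
#' label-averaged) from the predicted dot-product tables, for activity and
#' synaptic drive, before and after learning.
#'
#' @inheritParams context_dot_products
#' @return nested list `layer (activity, drive) -> stage (pre, post) ->`
#'   named scalars.
#' @export
context_theory_measures <- function(coords, N) {
  dp <- context_dot_products(coords, N)
  Q <- coords$Q; m1 <- coords$ga$m1
  list(activity = list(pre = measures_from_dots(dp$y0, Q, m1),
                       post = measures_from_dots(dp$y, Q, m1)),
       drive = list(pre = measures_from_dots(dp$k0, Q, 0),
                    post = measures_from_dots(dp$k, Q, 0)))
}
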