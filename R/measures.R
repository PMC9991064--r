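#' Activity matrix with trial labels
#'
#' Light container pairing a trials x neurons matrix of intermediate-layer
#' activity (or synaptic drive) with the trial labels of the task that
#' generated it. All activity measures operate on this object.
#'
#' @param values P x N numeric matrix.
#' @param task the `"task_data"` whose trials index the rows.
#' @param layer `"activity"` or `"drive"`.
#' @return An object of class `"activity_matrix"`.
#' @export
activity_matrix <- function(values, task, layer = c("activity", "drive")) {
  layer <- match.arg(layer)
  stopifnot(is.matrix(values), inherits(task, "task_data"))
  if (nrow(values) != task$P)
    stop("row count does not match the number of trials")
  structure(list(values = values, task = task, layer = layer),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix> %s, %d trials x %d neurons (%s task)\n",
              x$layer, nrow(x$values), ncol(x$values), x$task$kind))
  invisible(x)
}

# mean squared difference per neuron over the trial pairs flagged in the
# symmetric indicator matrix `A` (computed from second moments, no pair loop)
pair_msd <- function(Y, A) {
  npair <- sum(A)
  if (npair == 0) stop("empty trial-pair set")
  rc <- rowSums(A) + colSums(A)
  t1 <- as.vector(rc %*% Y^2)
  t2 <- colSums(Y * (A %*% Y))
  (t1 - 2 * t2) / npair
}

pair_sets <- function(task, variable, exclude_same_cue = TRUE) {
  P <- task$P
  eye <- diag(P) > 0
  if (variable == "category") {
    a <- task$category == "A"
    diffm <- outer(a, a, "!=")
    samem <- outer(a, a, "==") & !eye
  } else {
    if (is.null(task$context)) stop("task has no context labels")
    cx <- task$context
    diffm <- outer(cx, cx, "!=")
    samem <- outer(cx, cx, "==") & !eye
    if (variable == "context" && exclude_same_cue)
      samem <- samem & outer(task$cue, task$cue, "!=")
  }
  list(diff = diffm, same = samem)
}

selectivity_index <- function(Y, sets) {
  D <- pair_msd(Y, sets$diff)
  S <- pair_msd(Y, sets$same)
  den <- D + S
  flagged <- den <= .Machine$double.eps * 100
  idx <- ifelse(flagged, 0, (D - S) / den)
  list(per_neuron = idx, average = mean(idx[!flagged]),
       flagged = flagged, D = D, S = S)
}

#' Category selectivity index
#'
#' For each neuron, `(D - S) / (D + S)` where `D` and `S` are the mean
#' squared response differences over different-category and same-category
#' trial pairs (`s != s'` in both averages). The index lies in [-1, 1]; it
#' is zero on average before learning and becomes positive over learning.
#' Neurons with a vanishing denominator (constant response) are flagged and
#' reported as 0; the population average excludes them.
#'
#' @param act an [activity_matrix()].
#' @return list with `per_neuron`, `average`, `flagged`.
#' @export
category_selectivity <- function(act) {
  stopifnot(inherits(act, "activity_matrix"))
  sets <- pair_sets(act$task, "category")
  selectivity_index(act$values, sets)[c("per_neuron", "average", "flagged")]
}

#' Context selectivity index
#'
#' Same form as [category_selectivity()] over different-/same-context trial
#' pairs. With `exclude_same_cue = TRUE` (the primary definition),
#' same-context pairs that share the context cue are omitted, so an increase
#' cannot be driven merely by responses to the same cue becoming more
#' similar; with `FALSE` all same-context pairs (`s != s'`) enter (the
#' secondary definition).
#'
#' @param act an [activity_matrix()] from a context task.
#' @param exclude_same_cue logical.
#' @export
context_selectivity <- function(act, exclude_same_cue = TRUE) {
  stopifnot(inherits(act, "activity_matrix"))
  sets <- pair_sets(act$task, "context", exclude_same_cue)
  selectivity_index(act$values, sets)[c("per_neuron", "average", "flagged")]
}

#' Population clustering index
#'
#' The population-pooled analogue of average selectivity: the mean squared
#' distance between full activity vectors (averaged over neurons first) is
#' computed over different- and same-label pairs, and the ratio
#' `(D - S) / (D + S)` is formed afterwards. For `variable = "context"`
#' same-context pairs sharing a cue are excluded; `"context2"` keeps them.
#'
#' @param act an [activity_matrix()].
#' @param variable `"category"`, `"context"` or `"context2"`.
#' @return scalar in [-1, 1].
#' @export
clustering <- function(act, variable = c("category", "context", "context2")) {
  stopifnot(inherits(act, "activity_matrix"))
  variable <- match.arg(variable)
  sets <- pair_sets(act$task,
                    if (variable == "category") "category" else "context",
                    exclude_same_cue = (variable == "context"))
  r <- selectivity_index(act$values, sets)
  D <- mean(r$D); S <- mean(r$S)
  (D - S) / (D + S)
}

#' Trial-by-trial signal correlation matrix
#'
#' Entry (s, s') is the Pearson correlation across neurons between the
#' activity vectors of trials s and s'. Zero-variance trials yield zero
#' entries and are flagged in the `"flagged"` attribute.
#'
#' @param act an [activity_matrix()].
#' @return P x P matrix with unit diagonal.
#' @export
signal_correlation_matrix <- function(act) {
  stopifnot(inherits(act, "activity_matrix"))
  V <- t(act$values)                    # neurons x trials
  sds <- apply(V, 2L, stats::sd)
  flagged <- sds <= .Machine$double.eps * 100
  M <- suppressWarnings(stats::cor(V))
  M[flagged, ] <- 0; M[, flagged] <- 0
  diag(M) <- 1
  attr(M, "flagged") <- flagged
  M
}

#' Average correlation across different-label trial pairs
#'
#' Mean of the Pearson entries of `corr` over trial pairs whose `variable`
#' labels differ (the pairwise definition of category/context correlation).
#'
#' @param corr P x P correlation matrix (e.g. from
#'   [signal_correlation_matrix()]).
#' @param task the matching `"task_data"`.
#' @param variable `"category"` or `"context"`.
#' @export
block_correlation <- function(corr, task, variable = c("category", "context")) {
  variable <- match.arg(variable)
  lab <- if (variable == "category") task$category else task$context
  if (is.null(lab)) stop("task has no ", variable, " labels")
  mean(corr[outer(lab, lab, "!=")])
}

#' Correlation between label-averaged response profiles
#'
#' The alternative correlation definition: average activity per neuron
#' within each label value first, then compute the Pearson correlation
#' across neurons between the two label-value profiles.
#'
#' @param act an [activity_matrix()].
#' @param variable `"category"` or `"context"`.
#' @export
averaged_response_correlation <- function(act,
                                          variable = c("category", "context")) {
  stopifnot(inherits(act, "activity_matrix"))
  variable <- match.arg(variable)
  lab <- if (variable == "category") act$task$category else act$task$context
  if (is.null(lab)) stop("task has no ", variable, " labels")
  vals <- sort(unique(lab))
  p1 <- colMeans(act$values[lab == vals[1L], , drop = FALSE])
  p2 <- colMeans(act$values[lab == vals[2L], , drop = FALSE])
  stats::cor(p1, p2)
}

#' Asymmetry of the category response
#'
#' Per-neuron responses averaged over the trials of each category; returns
#' how many neurons respond more strongly to A than to B, and the population
#' mean and variance of the two averaged responses. Symmetric targets
#' (`phi^-1(zA) = -phi^-1(zB)`) give balanced counts and equal variances;
#' asymmetric targets bias the representation toward one category.
#'
#' @param act an [activity_matrix()].
#' @return list with `n_prefer_A`, `n_prefer_B`, `mean_A`, `mean_B`,
#'   `var_A`, `var_B`, `per_neuron_A`, `per_neuron_B`.
#' @export
response_asymmetry <- function(act) {
  stopifnot(inherits(act, "activity_matrix"))
  a <- act$task$category == "A"
  rA <- colMeans(act$values[a, , drop = FALSE])
  rB <- colMeans(act$values[!a, , drop = FALSE])
  list(n_prefer_A = sum(rA > rB), n_prefer_B = sum(rB > rA),
       mean_A = mean(rA), mean_B = mean(rB),
       var_A = stats::var(rA), var_B = stats::var(rB),
       per_neuron_A = rA, per_neuron_B = rB)
}

#' Selectivity change versus initial readout connectivity
#'
#' Pearson correlation between per-neuron selectivity changes and the
#' magnitude (and square) of the initial readout weights. The theory
#' predicts the learning-induced selectivity of neuron i scales with
#' `w0_i^2`, so trained circuits show a strong positive relation that is
#' absent before learning.
#'
#' @param sel_change per-neuron selectivity change (post minus pre, same
#'   circuit realization).
#' @param w0 initial readout vector.
#' @return list with `cor_abs` (vs `|w0|`) and `cor_sq` (vs `w0^2`).
#' @export
selectivity_vs_readout <- function(sel_change, w0) {
  if (length(sel_change) != length(w0)) stop("length mismatch")
  list(cor_abs = stats::cor(sel_change, abs(w0)),
       cor_sq = stats::cor(sel_change, w0^2))
}

#' Initial-gain pattern statistics for the context task
#'
#' From the pre-learning synaptic drives, computes per neuron and per
#' context cue the gain difference
#' `D^C_i(C) = <psi'(k0)>_{S in first half} - <psi'(k0)>_{S in second half}`,
#' the analogous per-stimulus statistic `D^S_i(S)` over the two halves of
#' the context cues, and the summary `G_i = <|D^C_i|>_C - <|D^S_i|>_S`.
#' Neurons that develop mixed category-and-context selectivity have larger
#' `G` than neurons with pure category selectivity.
#'
#' @param act an [activity_matrix()] with `layer = "drive"` holding the
#'   pre-learning drives of a context task.
#' @param psi the intermediate-layer [activation()].
#' @return list with matrices `DC` (N x Q), `DS` (N x Q) and vector `G`.
#' @export
gain_pattern_stats <- function(act, psi) {
  stopifnot(inherits(act, "activity_matrix"))
  task <- act$task
  if (task$kind != "context") stop("gain patterns are defined for the context task")
  Dpsi <- act_deriv(act$values, psi)       # P x N
  Q <- task$Q
  half_S <- task$stimulus <= Q / 2
  half_C <- task$cue <= Q / 2
  DC <- vapply(seq_len(Q), function(C) {
    i <- task$cue == C
    colMeans(Dpsi[i & half_S, , drop = FALSE]) -
      colMeans(Dpsi[i & !half_S, , drop = FALSE])
  }, numeric(ncol(Dpsi)))
  DS <- vapply(seq_len(Q), function(S) {
    i <- task$stimulus == S
    colMeans(Dpsi[i & half_C, , drop = FALSE]) -
      colMeans(Dpsi[i & !half_C, , drop = FALSE])
  }, numeric(ncol(Dpsi)))
  list(DC = DC, DS = DS, G = rowMeans(abs(DC)) - rowMeans(abs(DS)))
}
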