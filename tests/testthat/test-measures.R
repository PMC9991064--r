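toy_context <- function(Q = 4, N = 30, seed = 1) {
  suppressWarnings(make_context_task(N, Q, seed = seed))
}

test_that("category selectivity: perfect, flagged and invariance cases", {
  tk <- make_simple_task(30, 6, seed = 1)
  Y <- matrix(0.2, 6, 3)
  Y[tk$category == "A", 1] <- 0.8   # neuron 1 perfectly selective
  Y[, 3] <- 0.5                     # neuron 3 constant -> flagged
  Y[, 2] <- runif(6)
  sel <- category_selectivity(activity_matrix(Y, tk))
  expect_equal(sel$per_neuron[1], 1)
  expect_true(sel$flagged[3])
  expect_equal(sel$per_neuron[3], 0)
  expect_equal(sel$average, mean(sel$per_neuron[1:2]))
  # invariance under trial relabeling within a category
  p <- c(2, 1, 3, 5, 4, 6)
  tk2 <- tk; tk2$X <- tk$X[p, ]
  sel2 <- category_selectivity(activity_matrix(Y[p, ], tk))
  expect_equal(sel2$per_neuron, sel$per_neuron)
})

test_that("context selectivity: pure context is 1, pure stimulus is 0", {
  tk <- toy_context(4)
  ctx_act <- matrix(ifelse(tk$context == 1, 0.7, 0.3), tk$P, 2)
  sel <- context_selectivity(activity_matrix(ctx_act, tk))
  expect_equal(sel$per_neuron, c(1, 1))
  # activity depending only on the stimulus: the primary definition is
  # exactly balanced between the same- and different-context pair sets
  stim_val <- runif(4)
  stim_act <- matrix(stim_val[tk$stimulus], tk$P, 2)
  sel2 <- context_selectivity(activity_matrix(stim_act, tk))
  expect_equal(sel2$per_neuron, c(0, 0), tolerance = 1e-12)
  simple4 <- suppressWarnings(make_simple_task(2, 4, seed = 1))
  expect_error(context_selectivity(
    activity_matrix(stim_act[1:4, ], simple4)))
})

test_that("clustering: point clusters give 1; pools before the ratio", {
  tk <- make_simple_task(30, 6, seed = 2)
  Y <- matrix(rep(ifelse(tk$category == "A", 0.9, 0.1), 5), 6, 5)
  expect_equal(clustering(activity_matrix(Y, tk), "category"), 1)
  # clustering uses pooled numerator/denominator, not the index average
  Y2 <- cbind(Y[, 1], matrix(0.5 + rnorm(6 * 4, 0, 1e-3), 6, 4))
  cl <- clustering(activity_matrix(Y2, tk), "category")
  avg <- category_selectivity(activity_matrix(Y2, tk))$average
  expect_false(isTRUE(all.equal(cl, avg, tolerance = 0.2)))
})

test_that("signal correlations: duplicates, independence, zero variance", {
  tk <- make_simple_task(10000, 4, seed = 3)
  Y <- matrix(runif(4 * 10000), 4, 10000)
  Y[2, ] <- Y[1, ]
  M <- signal_correlation_matrix(activity_matrix(Y, tk))
  expect_equal(M[1, 2], 1)
  expect_lt(abs(M[3, 4]), 0.03)
  Yz <- Y; Yz[4, ] <- 0.5
  Mz <- signal_correlation_matrix(activity_matrix(Yz, tk))
  expect_true(attr(Mz, "flagged")[4])
  expect_equal(Mz[4, 1], 0)
  expect_equal(unname(diag(Mz)), rep(1, 4))
})

test_that("block correlation averages different-label entries", {
  tk <- make_simple_task(20, 4, seed = 1)
  M <- matrix(0.4, 4, 4); diag(M) <- 1
  expect_equal(block_correlation(M, tk, "category"), 0.4)
  M[1, 3] <- M[3, 1] <- -0.2; M[1, 4] <- M[4, 1] <- 0.6
  a <- tk$category == "A"
  expect_equal(block_correlation(M, tk, "category"),
               mean(M[outer(tk$category, tk$category, "!=")]))
})

test_that("averaged-response correlation: identical profiles give 1", {
  tk <- make_simple_task(50, 6, seed = 2)
  prof <- runif(50)
  Y <- matrix(rep(prof, each = 6), 6, 50)
  Y <- Y + rnorm(6 * 50, 0, 1e-9)
  expect_equal(averaged_response_correlation(activity_matrix(Y, tk),
                                             "category"), 1,
               tolerance = 1e-3)
})

test_that("response asymmetry is balanced for unstructured activity", {
  tk <- make_simple_task(4000, 20, seed = 5)
  Y <- matrix(runif(20 * 4000), 20, 4000)
  ra <- response_asymmetry(activity_matrix(Y, tk))
  expect_equal(ra$n_prefer_A + ra$n_prefer_B, 4000)
  expect_lt(abs(ra$n_prefer_A - ra$n_prefer_B), 4 * sqrt(4000))
  expect_equal(ra$var_A, ra$var_B, tolerance = 0.15)
})

test_that("selectivity-versus-readout correlation is exact for proportionality", {
  w0 <- rnorm(200, 0, 0.1)
  sel <- 3.2 * w0^2
  sv <- selectivity_vs_readout(sel, w0)
  expect_equal(sv$cor_sq, 1)
  expect_gt(sv$cor_abs, 0.9)
  expect_error(selectivity_vs_readout(sel, w0[-1]))
})

simple4b <- function() suppressWarnings(make_simple_task(2, 4, seed = 1))

test_that("gain patterns: zero in the linear regime, manual toy value", {
  tk <- toy_context(2, N = 2, seed = 3)
  K <- matrix(c(0.5, -0.3, 0.2, 0.9,
                -1.0, 0.4, 0.0, 0.6), 4, 2)
  act <- activity_matrix(K, tk, layer = "drive")
  gp <- gain_pattern_stats(act, activation("linear"))
  expect_equal(gp$G, c(0, 0))
  psi <- activation("sigmoid", 2, 0)
  gp2 <- gain_pattern_stats(act, psi)
  d <- act_deriv(K, psi)
  # Q = 2: D^C(C) = psi'(k at S=1, C) - psi'(k at S=2, C), per neuron
  for (i in 1:2) {
    DC <- sapply(1:2, function(C)
      d[tk$stimulus == 1 & tk$cue == C, i] - d[tk$stimulus == 2 & tk$cue == C, i])
    DS <- sapply(1:2, function(S)
      d[tk$stimulus == S & tk$cue == 1, i] - d[tk$stimulus == S & tk$cue == 2, i])
    expect_equal(unname(gp2$DC[i, ]), unname(DC))
    expect_equal(gp2$G[i], mean(abs(DC)) - mean(abs(DS)))
  }
  expect_error(gain_pattern_stats(
    activity_matrix(K, simple4b(), "drive"), psi))
})
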