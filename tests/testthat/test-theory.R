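psi10 <- activation("sigmoid", 1, 0)

test_that("one-point quadrature: polynomial exactness and sigmoid symmetry", {
  expect_equal(gauss_avg(identity), 0, tolerance = 1e-12)
  expect_equal(gauss_avg(function(a) a^2), 1, tolerance = 1e-12)
  expect_equal(gauss_avg(function(a) act_fun(a, psi10)), 0.5,
               tolerance = 1e-12)
  expect_error(gauss_avg(identity, order = 1))
})

test_that("two-point quadrature: covariance limits and an MC spot check", {
  f <- function(a) act_fun(a, psi10)
  expect_equal(gauss_avg_pair(f, cov = 1),
               gauss_avg(function(a) f(a)^2), tolerance = 1e-10)
  expect_equal(gauss_avg_pair(f, cov = 0), gauss_avg(f)^2,
               tolerance = 1e-10)
  expect_equal(gauss_avg_pair(f, cov = 0.5),
               mc_pair(f, 0.5, nsamp = 2e6, seed = 42), tolerance = 2e-3)
  expect_error(gauss_avg_pair(f, cov = 1.5))
})

test_that("four-point averages factorize over disjoint variable blocks", {
  ga <- cached("ga_1_0", gaussian_averages(psi10))
  fd <- function(a) act_deriv(a, psi10)
  expect_equal(gauss_avg_quad(fd, S = 1:4, C = 5:8), ga$d1^4,
               tolerance = 1e-8)
  expect_equal(gauss_avg_quad(fd, S = c(1, 1, 2, 3), C = c(4, 5, 6, 7)),
               ga$dd * ga$d1^2, tolerance = 1e-8)
  expect_equal(gauss_avg_quad(fd, S = c(1, 1), C = c(2, 2)), ga$d2,
               tolerance = 1e-8)
  expect_error(gauss_avg_quad(fd, S = 1:3, C = 1:2))
})

test_that("quadrature is converged at the default order for all presets", {
  pp <- unique(study_presets()[, c("psi_theta1", "psi_theta2")])
  for (i in seq_len(nrow(pp))) {
    psi <- activation("sigmoid", pp$psi_theta1[i], pp$psi_theta2[i])
    g1 <- gaussian_averages(psi)
    g2 <- gaussian_averages(psi, order = 401)
    for (f in c("m1", "m2", "d1", "d2", "d4", "mm", "dd"))
      expect_lt(abs(g1[[f]] - g2[[f]]), 1e-8)
  }
})

test_that("population averages satisfy the positivity inequalities", {
  for (th in list(c(1, 0), c(1, 2), c(2.5, 2))) {
    ga <- gaussian_averages(activation("sigmoid", th[1], th[2]))
    expect_true(ga$m1 > 0 && ga$m1 < 1)
    expect_true(ga$m1^2 <= ga$m2 && ga$m2 <= ga$m1)
    expect_gte(ga$d2, ga$d1^2)
    expect_gte(ga$mm, ga$m1^2)
    expect_gte(ga$dd, ga$d1^2)
  }
  gal <- gaussian_averages(activation("linear"))
  expect_equal(gal$m1, 0, tolerance = 1e-10)
  expect_equal(gal$m2, 1, tolerance = 1e-10)
  expect_equal(gal$d2, 1, tolerance = 1e-10)
  expect_equal(gal$mm, 0.5, tolerance = 1e-10)
  expect_equal(gal$dd, 1, tolerance = 1e-10)
})

test_that("simple-task coordinates: limits, ordering and signs", {
  ga <- cached("ga_1_0", gaussian_averages(psi10))
  co0 <- simple_coordinates(ga, 20, eta_ratio = 0)
  expect_equal(co0$beta, 0); expect_equal(co0$gamma, 0)
  expect_equal(co0$cA, act_inv(0.75, co0$phi) / ga$d2)
  expect_equal(co0$cB, act_inv(0.25, co0$phi) / ga$d2)
  for (r in c(0, 0.2, 0.8)) {
    co <- simple_coordinates(ga, 20, r)
    expect_gt(co$cA, co$cB)
    d <- act_inv(0.75, co$phi) - act_inv(0.25, co$phi)
    expect_equal(co$cA - co$cB,
                 d * (1 + 2 * co$beta / co$alpha) / (co$alpha + 2 * co$beta))
  }
  # opposite-sign target drives force negative cA * cB
  co <- simple_coordinates(ga, 20, 0.4, phi = activation("sigmoid", 1, 0))
  expect_lt(co$cA * co$cB, 0)
})

test_that("context coordinates: nonlinear alpha positive, ordering holds", {
  ga <- cached("ga_1_0", gaussian_averages(psi10))
  ab <- context_alpha_beta(ga, 8, 0)
  expect_equal(ab[["alpha"]], ga$d2 - ga$dd)
  expect_gt(ab[["alpha"]], 0)
  for (r in c(0, 0.2)) {
    co <- context_coordinates(ga, 8, r, phi = activation("sigmoid", 1, 4))
    expect_gt(co$cA, co$cB)
  }
})

test_that("initial readout drive decomposes into frozen and trial noise", {
  ga <- cached("ga_1_0", gaussian_averages(psi10))
  st <- init_circuit(circuit_params(N = 2000, psi = psi10, seed = 12))
  tk <- make_simple_task(2000, 100, seed = 13)
  h0 <- forward(st, tk$X)$H
  vd <- variability_decomposition(h0, ga, st$w)
  expect_equal(vd$kappa, sum(st$w))
  se <- sqrt((ga$m2 - ga$m1^2) / 100)
  expect_lt(abs(mean(h0) - ga$m1 * vd$kappa), 2 * se)
  expect_equal(var(h0), ga$m2 - ga$m1^2, tolerance = 0.2)
  expect_equal(vd$delta, -h0 / ga$d2)
  expect_equal(variability_decomposition(h0, ga, numeric(2000))$kappa, 0)
})

test_that("asymmetry prediction: symmetric targets give equal variances", {
  ga <- cached("ga_1_0", gaussian_averages(psi10))
  co <- simple_coordinates(ga, 20, 0)   # phi threshold 0: cA = -cB
  ap <- asymmetry_prediction(co, 200)
  expect_equal(ap$var_A, ap$var_B)
  co2 <- simple_coordinates(ga, 20, 0, phi = activation("sigmoid", 1, 2))
  ap2 <- asymmetry_prediction(co2, 200)
  expect_gt(ap2$var_A, ap2$var_B)
})

test_that("XOR geometry: unit and double squared distances, -1/3 clustering", {
  g <- xor_geometry()
  expect_equal(g$d_consecutive2, 1)
  expect_equal(g$d_opposite2, 2)
  expect_equal(g$initial_clustering, -1 / 3)
})

test_that("context-selectivity coefficient: zero for linear, positive else", {
  expect_equal(a1_minus_a2(gaussian_averages(activation("linear")), 8), 0,
               tolerance = 1e-10)
  ga <- cached("ga_1_0", gaussian_averages(psi10))
  expect_gt(a1_minus_a2(ga, 8), 0)
  # oracle from the defining sums at Q = 4: A1 - A2 = 2 (dd - d1^2)
  fd <- function(a) act_deriv(a, psi10)
  dd_mc <- mc_pattern(fd, S = c(1, 1), C = c(2, 3), nsamp = 2e6, seed = 17)
  d1_mc <- mc_avg(fd, nsamp = 2e6, seed = 18)
  A1 <- 2 * dd_mc + 2 * d1_mc^2
  A2 <- 4 * d1_mc^2
  expect_equal(a1_minus_a2(ga, 4), A1 - A2, tolerance = 5e-3)
})

test_that("linearized prediction: zero coordinates reproduce initial activity", {
  ga <- cached("ga_1_0", gaussian_averages(psi10))
  st <- init_circuit(circuit_params(N = 80, psi = psi10, seed = 3))
  tk <- make_simple_task(80, 6, seed = 4)
  co <- simple_coordinates(ga, 6, 0)
  co0 <- co; co0$cA <- 0; co0$cB <- 0
  lp <- linearized_prediction(st, tk, co0)
  expect_equal(lp$Y, lp$Y0)
  expect_equal(lp$K, lp$K0)
  # activity changes align with the sign of w0 for positive coordinates
  cop <- co; cop$cA <- 1; cop$cB <- 1
  lp2 <- linearized_prediction(st, tk, cop)
  expect_true(all(sign(lp2$dY) == rep(sign(st$w), each = 6)))
  expect_error(linearized_prediction(st, make_context_task(80, 2, seed = 1), co))
})

test_that("simple-task measure predictions: degenerate and sign cases", {
  ga <- cached("ga_1_0", gaussian_averages(psi10))
  co <- simple_coordinates(ga, 20, 0)
  co_eq <- co; co_eq$cB <- co_eq$cA
  tm <- simple_theory_measures(co_eq, 500)
  expect_equal(tm$selectivity, 0)
  expect_equal(tm$selectivity_leading, 0)
  co_sym <- co    # phi threshold 0 gives cA = -cB exactly
  expect_equal(co_sym$cA, -co_sym$cB)
  tm2 <- simple_theory_measures(co_sym, 500)
  expect_lt(tm2$correlation, 0)
  expect_lt(tm2$correlation_averaged, 0)
  # averaged definition is Q/2 times the pairwise one at leading order
  expect_equal(tm2$correlation_averaged_leading /
                 tm2$correlation_leading, 10)
  # predicted dot products: diagonal exceeds off-diagonal within category
  dp <- simple_dot_products(co, 500)
  expect_true(isSymmetric(dp))
  expect_gt(dp[1, 1], dp[1, 2])
})

test_that("context theory measures: pre-learning limits and drive invariance", {
  ga <- cached("ga_1_0", gaussian_averages(psi10))
  co <- context_coordinates(ga, 4, 0)
  ctm <- cached("ctm_ga10_Q4", context_theory_measures(co, 600))
  # drive-level category clustering does not change over learning
  expect_equal(ctm$drive$post$clustering_category,
               ctm$drive$pre$clustering_category, tolerance = 1e-10)
  # pre-learning: category clustering weakly negative, context zero
  expect_lt(ctm$drive$pre$clustering_category, 0)
  expect_equal(ctm$activity$pre$clustering_context, 0, tolerance = 1e-10)
  # context clustering increases for activity and drive
  expect_gt(ctm$activity$post$clustering_context,
            ctm$activity$pre$clustering_context)
  expect_gt(ctm$drive$post$clustering_context,
            ctm$drive$pre$clustering_context)
  # zero coordinates: the XOR pre-learning drive clustering is -1/3
  co2 <- context_coordinates(ga, 2, 0)
  co2$cA <- 0; co2$cB <- 0
  ctm2 <- context_theory_measures(co2, 600)
  expect_equal(ctm2$drive$post$clustering_category, -1 / 3)
})

test_that("per-realization coordinate solve matches the trained circuit", {
  run <- get_tiny_run()
  traj <- run$traj; tk <- run$task
  cs <- activity_coordinates_full(traj$initial_state, tk, eta_ratio = 0)
  # reconstruct the learned readout drive from the coordinates
  st0 <- traj$initial_state
  fw0 <- forward(st0, tk$X)
  Dpsi <- act_deriv(fw0$K, st0$params$psi)
  M <- (tcrossprod(tk$X) / tk$N) * (tcrossprod(Dpsi) / tk$N)
  h_pred <- fw0$H + as.vector(M %*% cs)
  expect_equal(h_pred, act_inv(tk$target, st0$params$phi), tolerance = 1e-6)
})
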