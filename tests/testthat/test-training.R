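test_that("quadratic loss: exact values and permutation invariance", {
  expect_equal(mse_loss(c(0.75, 0.25), c(0.75, 0.25)), 0)
  expect_equal(mse_loss(c(0.5, 0.5), c(0.75, 0.25)), 0.03125)
  z <- runif(9); tg <- runif(9)
  p <- sample(9)
  expect_equal(mse_loss(z, tg), mse_loss(z[p], tg[p]))
  expect_error(mse_loss(numeric(0), numeric(0)))
  expect_error(mse_loss(1, c(1, 2)))
})

test_that("analytic gradients match central differences on a tiny circuit", {
  st <- init_circuit(circuit_params(N = 3, seed = 2,
                                    psi = activation("sigmoid", 2, 0.5),
                                    phi = activation("sigmoid", 1, 1)))
  tk <- make_simple_task(3, 2, seed = 3)
  gr <- gradients(st, tk)
  loss_at <- function(u, w) {
    s <- st; s$u <- u; s$w <- w
    mse_loss(forward(s, tk$X)$Z, tk$target)
  }
  h <- 1e-6
  for (idx in list(c(1, 1), c(2, 3), c(3, 2))) {
    up <- st$u; up[idx[1], idx[2]] <- up[idx[1], idx[2]] + h
    um <- st$u; um[idx[1], idx[2]] <- um[idx[1], idx[2]] - h
    fd <- (loss_at(up, st$w) - loss_at(um, st$w)) / (2 * h)
    expect_equal(gr$du[idx[1], idx[2]], fd, tolerance = 1e-6)
  }
  for (i in 1:3) {
    wp <- st$w; wp[i] <- wp[i] + h
    wm <- st$w; wm[i] <- wm[i] - h
    fd <- (loss_at(st$u, wp) - loss_at(st$u, wm)) / (2 * h)
    expect_equal(gr$dw[i], fd, tolerance = 1e-6)
  }
})

test_that("training converges on a small simple task and hits the targets", {
  run <- get_tiny_run()
  traj <- run$traj; tk <- run$task
  expect_true(traj$converged)
  expect_lt(traj$losses[length(traj$losses)], 1e-5)
  expect_true(all(diff(traj$losses) <= 1e-12))      # non-increasing loss
  Z <- forward(traj$final_state, tk$X)$Z
  expect_true(all(abs(Z - tk$target) < 0.01))
})

test_that("frozen readout (eta_ratio = 0) leaves w untouched; epoch cap works", {
  run <- get_tiny_run()
  traj <- run$traj; tk <- run$task
  expect_identical(traj$final_state$w, traj$initial_state$w)
  st <- traj$initial_state
  t0 <- train(st, tk, train_config(max_epochs = 0L))
  expect_equal(t0$final_epoch, 0L)
  expect_length(t0$losses, 1L)
  expect_identical(t0$final_state$u, st$u)
})

test_that("halving the learning rate leaves converged activity almost unchanged", {
  run <- get_tiny_run()
  st <- run$traj$initial_state; tk <- run$task
  slow <- train(st, tk, train_config(eta_u = 0.05, max_epochs = 200000L))
  expect_true(slow$converged)
  Y1 <- forward(run$traj$final_state, tk$X)$Y
  Y2 <- forward(slow$final_state, tk$X)$Y
  a1 <- category_selectivity(activity_matrix(Y1, tk))$average
  a2 <- category_selectivity(activity_matrix(Y2, tk))$average
  expect_equal(a1, a2, tolerance = 0.02)
})

test_that("linear intermediate layer cannot learn the XOR context task", {
  st <- init_circuit(circuit_params(N = 120, seed = 4,
                                    psi = activation("linear"),
                                    phi = activation("sigmoid", 1, 0)))
  tk <- make_context_task(120, 2, seed = 5)
  traj <- train(st, tk, train_config(max_epochs = 4000L))
  expect_false(traj$converged)
  expect_gt(traj$losses[length(traj$losses)], 1e-4)   # loss plateau
})

test_that("weight changes shrink with width at the predicted rate", {
  norms <- lapply(c(400, 800), function(N) {
    st <- init_circuit(circuit_params(N = N, seed = 6,
                                      psi = activation("sigmoid", 1, 0),
                                      phi = activation("sigmoid", 1, 0)))
    tk <- make_simple_task(N, 20, seed = 7)
    traj <- train(st, tk, train_config(eta_ratio = 0.2,
                                       max_epochs = 100000L))
    expect_true(traj$converged)
    utils::tail(weight_change_norms(traj), 1L)
  })
  # delta u ~ N^(-3/2): doubling N shrinks the RMS by about 2^1.5 = 2.8
  ratio_u <- norms[[1]]$rms_du / norms[[2]]$rms_du
  expect_gt(ratio_u, 1.8); expect_lt(ratio_u, 4.2)
  # delta w ~ N^(-1) stays small relative to the O(N^-1/2) initial weights
  expect_lt(norms[[2]]$rel_dw, 0.2)
})

test_that("weight-change norms vanish on an untrained trajectory", {
  st <- init_circuit(circuit_params(N = 30, seed = 1))
  tk <- make_simple_task(30, 4, seed = 1)
  tr <- train(st, tk, train_config(max_epochs = 0L))
  n <- weight_change_norms(tr)
  expect_equal(n$rms_du, c(0, 0))
  expect_equal(n$rms_dw, c(0, 0))
})
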