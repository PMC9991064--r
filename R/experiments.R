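#' Built-in parameter presets
#'
#' The named operating points used throughout the study: combinations of
#' task kind, width `N`, stimulus count `Q`, learning-rate ratio and the
#' two activation parametrizations. Presets whose readout inverse targets
#' have opposite signs (`*_balanced`) produce negative post-learning
#' category correlation; presets with a shifted readout threshold
#' (`*_positive_thresh`, `context_offset`) produce positive correlation.
#' Targets are `zA = 0.75`, `zB = 0.25` everywhere.
#'
#' The `core` flag marks the main-study rows (the default operating points
#' at the printed widths N = 200/600); the remaining rows are the
#' supplementary operating points (reference/low-threshold sigmoids,
#' structured inputs with heterogeneity, high-threshold context circuits).
#'
#' @return data frame, one row per preset.
#' @export
study_presets <- function() {
  p <- function(name, task, N, Q, ratio, p1, p2, f1, f2, bias_sd = 0, sigma = 0,
                core = TRUE)
    data.frame(name = name, task = task, N = N, Q = Q, eta_ratio = ratio,
               psi_theta1 = p1, psi_theta2 = p2,
               phi_theta1 = f1, phi_theta2 = f2,
               bias_sd = bias_sd, sigma = sigma, core = core)
  rbind(
    p("simple_balanced",        "simple",     200, 20, 0.0, 1.0, 2, 1, 0),
    p("simple_positive_thresh", "simple",     200, 20, 0.0, 1.0, 2, 1, 2),
    p("simple_shared_rates",    "simple",     200, 20, 0.4, 2.0, 2, 1, 2),
    p("simple_reference",       "simple",     200, 20, 0.0, 1.0, 0, 1, 0, core = FALSE),
    p("simple_reference_offset","simple",     200, 20, 0.0, 1.0, 0, 1, 2, core = FALSE),
    p("structured_balanced",    "structured", 200, 12, 0.0, 1.0, 2, 1, 0,
      bias_sd = 0.2, sigma = 1 / 3, core = FALSE),
    p("structured_offset",      "structured", 200, 12, 0.0, 1.0, 2, 1, 2,
      bias_sd = 0.2, sigma = 1 / 3, core = FALSE),
    p("context_balanced",       "context",    600,  8, 0.0, 1.0, 0, 1, 0),
    p("context_offset",         "context",    600,  8, 0.0, 1.0, 0, 1, 4),
    p("context_readout_plastic","context",    600,  8, 0.2, 2.5, 2, 1, 0),
    p("context_high_thresh",    "context",    600,  8, 0.0, 1.0, 3, 1, 0, core = FALSE),
    p("context_high_thresh_offset", "context", 600, 8, 0.0, 1.0, 3, 1, 4,
      core = FALSE))
}

preset_row <- function(preset) {
  pp <- study_presets()
  if (is.character(preset)) {
    i <- match(preset, pp$name)
    if (is.na(i))
      stop("unknown preset '", preset, "'; available: ",
           paste(pp$name, collapse = ", "))
    pp[i, ]
  } else as.data.frame(preset)
}

make_task_for <- function(row, N = row$N, seed = 1L) {
  switch(row$task,
         simple = make_simple_task(N, row$Q, seed = seed),
         structured = make_structured_task(N, row$Q, sigma = row$sigma,
                                           seed = seed),
         context = make_context_task(N, row$Q, seed = seed),
         stop("unknown task kind"))
}

circuit_for <- function(row, N = row$N, seed = 1L) {
  init_circuit(circuit_params(
    N = N,
    psi = activation("sigmoid", row$psi_theta1, row$psi_theta2),
    phi = activation("sigmoid", row$phi_theta1, row$phi_theta2),
    bias_sd = row$bias_sd, seed = seed))
}

run_measures <- function(Y, task) {
  act <- activity_matrix(Y, task)
  out <- list(selectivity_category = category_selectivity(act),
              clustering_category = clustering(act, "category"),
              correlation_category =
                block_correlation(signal_correlation_matrix(act), task,
                                  "category"))
  if (!is.null(task$context)) {
    out$selectivity_context <- context_selectivity(act, TRUE)
    out$selectivity_context2 <- context_selectivity(act, FALSE)
    out$clustering_context <- clustering(act, "context")
    out$clustering_context2 <- clustering(act, "context2")
    out$correlation_context <-
      block_correlation(signal_correlation_matrix(act), task, "context")
  }
  out
}

#' Run one preset end to end
#'
#' Initializes a circuit, generates the task, trains to convergence and
#' returns pre- and post-learning activity measures together with the
#' theoretical prediction (for simple and context tasks) and the
#' trajectory metadata.
#'
#' @param preset preset name (see [study_presets()]) or a one-row data
#'   frame with the same columns.
#' @param seed integer seed used for both the circuit and the task
#'   (circuit weights are drawn first).
#' @param max_epochs epoch cap passed to [train_config()].
#' @param N,Q optional overrides of the preset's width and stimulus count.
#' @return An object of class `"circuit_report"`.
#' @export
reproduce_circuit <- function(preset, seed = 1L, max_epochs = 200000L,
                              N = NULL, Q = NULL) {
  row <- preset_row(preset)
  if (!is.null(N)) row$N <- N
  if (!is.null(Q)) row$Q <- Q
  state0 <- circuit_for(row, seed = seed)
  task <- make_task_for(row, seed = seed + 10000L)
  traj <- train(state0, task,
                train_config(eta_ratio = row$eta_ratio,
                             max_epochs = max_epochs))
  fw0 <- forward(state0, task$X)
  fw1 <- forward(traj$final_state, task$X)
  theory <- NULL
  if (row$task %in% c("simple", "context")) {
    ga <- gaussian_averages(state0$params$psi)
    solver <- if (row$task == "simple") simple_coordinates else
      context_coordinates
    theory <- tryCatch(
      solver(ga, row$Q, row$eta_ratio, task$zA, task$zB, state0$params$phi),
      singularity_error = function(e) e)
  }
  structure(list(row = row, seed = seed, task = task,
                 state0 = state0, state1 = traj$final_state,
                 converged = traj$converged, final_epoch = traj$final_epoch,
                 final_loss = traj$losses[length(traj$losses)],
                 K0 = fw0$K, Y0 = fw0$Y, K1 = fw1$K, Y1 = fw1$Y,
                 pre = run_measures(fw0$Y, task),
                 post = run_measures(fw1$Y, task),
                 theory = theory),
            class = "circuit_report")
}

#' @export
print.circuit_report <- function(x, ...) {
  cat(sprintf("<circuit_report> %s (seed %d): %s after %d epochs\n",
              x$row$name, x$seed,
              if (x$converged) "converged" else "NOT converged",
              x$final_epoch))
  cat(sprintf("  category selectivity: %.4f -> %.4f\n",
              x$pre$selectivity_category$average,
              x$post$selectivity_category$average))
  cat(sprintf("  category correlation: %.4f -> %.4f\n",
              x$pre$correlation_category, x$post$correlation_category))
  if (!is.null(x$pre$selectivity_context))
    cat(sprintf("  context selectivity:  %.4f -> %.4f\n",
                x$pre$selectivity_context$average,
                x$post$selectivity_context$average))
  invisible(x)
}

#' Parameter sweep with theory comparison
#'
#' Runs every row of `grid` for `n_seeds` seeds and collects pre/post
#' scalar measures, convergence flags and (where available) the matching
#' theoretical predictions. Only converged runs enter the per-row means;
#' the number of non-converged runs is reported.
#'
#' @param grid data frame with the [study_presets()] columns.
#' @param n_seeds seeds per grid row (1..n_seeds).
#' @param max_epochs epoch cap per run.
#' @return data frame, one row per (grid row, seed), plus summary columns.
#' @export
run_sweep <- function(grid, n_seeds = 10L, max_epochs = 200000L) {
  out <- list()
  for (i in seq_len(nrow(grid))) {
    for (seed in seq_len(n_seeds)) {
      rep <- tryCatch(
        reproduce_circuit(grid[i, ], seed = seed, max_epochs = max_epochs),
        error = function(e) e)
      if (inherits(rep, "error")) {
        out[[length(out) + 1L]] <- data.frame(
          name = grid$name[i], seed = seed, converged = FALSE,
          error = conditionMessage(rep))
        next
      }
      df <- data.frame(
        name = grid$name[i], seed = seed, converged = rep$converged,
        error = NA_character_,
        final_epoch = rep$final_epoch,
        sel_cat_pre = rep$pre$selectivity_category$average,
        sel_cat_post = rep$post$selectivity_category$average,
        corr_cat_pre = rep$pre$correlation_category,
        corr_cat_post = rep$post$correlation_category)
      if (!is.null(rep$pre$selectivity_context)) {
        df$sel_ctx_pre <- rep$pre$selectivity_context$average
        df$sel_ctx_post <- rep$post$selectivity_context$average
        df$sel_ctx2_pre <- rep$pre$selectivity_context2$average
        df$sel_ctx2_post <- rep$post$selectivity_context2$average
      } else {
        df$sel_ctx_pre <- df$sel_ctx_post <- NA_real_
        df$sel_ctx2_pre <- df$sel_ctx2_post <- NA_real_
      }
      if (inherits(rep$theory, "theory_prediction")) {
        df$cA <- rep$theory$cA; df$cB <- rep$theory$cB
        if (rep$row$task == "simple") {
          tm <- simple_theory_measures(rep$theory, rep$row$N)
          df$sel_theory <- tm$selectivity
          df$corr_theory <- tm$correlation
        } else { df$sel_theory <- NA_real_; df$corr_theory <- NA_real_ }
      } else {
        df$cA <- df$cB <- df$sel_theory <- df$corr_theory <- NA_real_
      }
      out[[length(out) + 1L]] <- df
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Classify neurons into pure- and mixed-selective groups
#'
#' Thresholds the per-neuron changes in category and context selectivity at
#' the top `top_fraction` quantile of each: neurons above both thresholds
#' are `mixed`, above only the category threshold `pure_category`, above
#' only the context threshold `pure_context`, and `other` otherwise.
#' Optionally attaches the mean initial-gain statistic `G` per group
#' (mixed-selective neurons are predicted to have larger `G` than
#' pure-category ones).
#'
#' @param d_category,d_context per-neuron selectivity changes (post - pre).
#' @param G optional per-neuron gain statistic from [gain_pattern_stats()].
#' @param top_fraction fraction defining the "top" group (default 0.15).
#' @return list with `group` (factor), `sizes`, and `G_mean` per group.
#' @export
mixed_pure_classification <- function(d_category, d_context, G = NULL,
                                      top_fraction = 0.15) {
  stopifnot(length(d_category) == length(d_context),
            top_fraction > 0, top_fraction <= 1)
  thr_cat <- stats::quantile(d_category, 1 - top_fraction)
  thr_ctx <- stats::quantile(d_context, 1 - top_fraction)
  top_cat <- d_category >= thr_cat
  top_ctx <- d_context >= thr_ctx
  group <- factor(ifelse(top_cat & top_ctx, "mixed",
                  ifelse(top_cat, "pure_category",
                  ifelse(top_ctx, "pure_context", "other"))),
                  levels = c("mixed", "pure_category", "pure_context",
                             "other"))
  out <- list(group = group, sizes = table(group))
  if (!is.null(G)) {
    stopifnot(length(G) == length(group))
    out$G_mean <- tapply(G, group, mean)
  }
  out
}
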