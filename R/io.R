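#' @title Persistence, configuration and command-line entry points
#' @description Runs are described by a YAML configuration with `task`,
#'   `circuit` and `training` blocks plus a `seed`; results are written as
#'   plain-text containers (TSV arrays with a JSON metadata block), so a
#'   run directory is self-describing and fully reproducible from its
#'   manifest.
#' @name cli_io
NULL

#' Save / load a circuit state
#'
#' Writes `u`, `w`, `b` as TSV files plus a `meta.json` block holding the
#' parameters and seed; `read_state_dir` restores the state and checks
#' dimensional consistency.
#'
#' @param state a `"circuit_state"`.
#' @param dir directory to create/use.
#' @export
write_state_dir <- function(state, dir) {
  stopifnot(inherits(state, "circuit_state"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(state$u, file.path(dir, "u.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(w = state$w, b = state$b),
                     file.path(dir, "wb.tsv"), sep = "\t", row.names = FALSE)
  p <- state$params
  meta <- list(N = p$N, bias_sd = p$bias_sd, seed = p$seed,
               psi = unclass(p$psi), phi = unclass(p$phi))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_state_dir
#' @export
read_state_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  u <- as.matrix(utils::read.table(file.path(dir, "u.tsv"), sep = "\t"))
  dimnames(u) <- NULL
  wb <- utils::read.table(file.path(dir, "wb.tsv"), sep = "\t", header = TRUE)
  params <- circuit_params(
    N = meta$N,
    psi = activation(meta$psi$type, meta$psi$theta1, meta$psi$theta2),
    phi = activation(meta$phi$type, meta$phi$theta1, meta$phi$theta2),
    bias_sd = meta$bias_sd, seed = meta$seed)
  if (!all(dim(u) == c(meta$N, meta$N))) stop("stored `u` has wrong shape")
  structure(list(u = u, w = wb$w, b = wb$b, params = params),
            class = "circuit_state")
}

#' Read a run configuration
#'
#' YAML with blocks `task` (`kind`, `Q`, optional `sigma`, `zA`, `zB`),
#' `circuit` (`N`, `psi`/`phi` as `[theta1, theta2]`, optional `bias_sd`),
#' `training` (`eta_u`, `eta_ratio`, `loss_tol`, `max_epochs`) and a
#' top-level `seed`. Missing optional fields take the package defaults;
#' missing required fields raise an error.
#'
#' @param path YAML file path.
#' @return list with `row` (a preset-style data frame row), `train`
#'   (a [train_config()]) and `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `N`/`n` key as a boolean; accept both spellings
  get_field <- function(block, field) {
    b <- cfg[[block]]
    for (k in c(field, if (field == "N") c("FALSE", "n")))
      if (!is.null(b[[k]])) return(b[[k]])
    NULL
  }
  need <- function(block, field) {
    v <- get_field(block, field)
    if (is.null(v)) stop("config is missing required field `",
                         block, "$", field, "`")
    v
  }
  task <- need("task", "kind")
  Q <- need("task", "Q")
  N <- need("circuit", "N")
  psi <- cfg$circuit$psi %||% c(1, 0)
  phi <- cfg$circuit$phi %||% c(1, 0)
  row <- data.frame(
    name = cfg$name %||% "custom", task = task, N = N, Q = Q,
    eta_ratio = cfg$training$eta_ratio %||% 0,
    psi_theta1 = psi[[1L]], psi_theta2 = psi[[2L]],
    phi_theta1 = phi[[1L]], phi_theta2 = phi[[2L]],
    bias_sd = cfg$circuit$bias_sd %||% 0,
    sigma = cfg$task$sigma %||% 0)
  tc <- train_config(eta_u = cfg$training$eta_u %||% 0.1,
                     eta_ratio = row$eta_ratio,
                     loss_tol = cfg$training$loss_tol %||% 1e-5,
                     max_epochs = cfg$training$max_epochs %||% 200000L)
  list(row = row, train = tc, seed = as.integer(cfg$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a configured run and persist its results
#'
#' Trains the configured circuit, then writes to `out_dir`: the per-epoch
#' loss (`loss.csv`), the trial manifest, pre/post scalar measures
#' (`measures.json`) and a run manifest (`manifest.json`: configuration,
#' seed, convergence status, package version). Returns the exit status a
#' command-line wrapper should use: 0 on convergence, 2 otherwise.
#'
#' @param config_path YAML configuration path.
#' @param out_dir output directory.
#' @return integer status, invisibly; the `"circuit_report"` is attached
#'   as attribute `"report"`.
#' @export
cli_simulate <- function(config_path, out_dir) {
  cfg <- read_run_config(config_path)
  rep <- reproduce_circuit(cfg$row, seed = cfg$seed,
                           max_epochs = cfg$train$max_epochs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trial_manifest(rep$task, file.path(out_dir, "trials.csv"))
  scalars <- function(m) {
    s <- list(selectivity_category = m$selectivity_category$average,
              clustering_category = m$clustering_category,
              correlation_category = m$correlation_category)
    if (!is.null(m$selectivity_context)) {
      s$selectivity_context <- m$selectivity_context$average
      s$selectivity_context2 <- m$selectivity_context2$average
      s$clustering_context <- m$clustering_context
      s$correlation_context <- m$correlation_context
    }
    s
  }
  jsonlite::write_json(list(pre = scalars(rep$pre), post = scalars(rep$post)),
                       file.path(out_dir, "measures.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(config = yaml::read_yaml(config_path), seed = cfg$seed,
         converged = rep$converged, final_epoch = rep$final_epoch,
         final_loss = rep$final_loss,
         package_version = as.character(utils::packageVersion("circuitcat"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  status <- if (rep$converged) 0L else 2L
  invisible(structure(status, report = rep))
}

#' Theoretical predictions for a configured run
#'
#' Computes the Gaussian averages, the activity coordinates and the
#' predicted measures for the configured task and writes them as JSON.
#' Returns status 0, or 3 if the coordinate system is singular (linear
#' intermediate activation on the context task).
#'
#' @param config_path YAML configuration path.
#' @param out_path output JSON path.
#' @export
cli_theory <- function(config_path, out_path) {
  cfg <- read_run_config(config_path)
  row <- cfg$row
  psi <- activation("sigmoid", row$psi_theta1, row$psi_theta2)
  phi <- activation("sigmoid", row$phi_theta1, row$phi_theta2)
  ga <- gaussian_averages(psi)
  solver <- if (row$task == "context") context_coordinates else
    simple_coordinates
  coords <- tryCatch(solver(ga, row$Q, row$eta_ratio, phi = phi),
                     singularity_error = function(e) e)
  if (inherits(coords, "singularity_error")) {
    message("singular coordinate system: ", conditionMessage(coords))
    return(invisible(3L))
  }
  out <- list(averages = unclass(ga)[c("m1", "m2", "d1", "d2", "d4",
                                       "mm", "dd")],
              coordinates = list(alpha = coords$alpha, beta = coords$beta,
                                 gamma = coords$gamma, cA = coords$cA,
                                 cB = coords$cB))
  if (row$task == "simple")
    out$measures <- simple_theory_measures(coords, row$N)
  else
    out$measures <- context_theory_measures(coords, row$N)
  jsonlite::write_json(out, out_path, auto_unbox = TRUE, digits = NA)
  invisible(0L)
}

#' Generate small pinned fixtures for fast tests
#'
#' Writes deterministic miniature datasets (an `N = 64`, `Q = 6` simple
#' task and an `N = 64`, `Q = 4` context task) as trial manifests plus
#' input TSVs, together with a checksum file (MD5 of the serialized
#' inputs), under `dir`.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return named character vector of checksums, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tasks <- list(simple = make_simple_task(64, 6, seed = seed),
                context = make_context_task(64, 4, seed = seed + 1L))
  sums <- character()
  for (nm in names(tasks)) {
    tk <- tasks[[nm]]
    write_trial_manifest(tk, file.path(dir, paste0(nm, "_trials.csv")))
    xp <- file.path(dir, paste0(nm, "_inputs.tsv"))
    utils::write.table(round(tk$X, 10), xp, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    sums[nm] <- tools::md5sum(xp)[[1L]]
  }
  writeLines(paste(names(sums), sums), file.path(dir, "checksums.txt"))
  invisible(sums)
}
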