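# Session-wide cache so expensive trained circuits are shared across test
# files (test files run sequentially in one process).
cc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(cc_cache[[key]])) cc_cache[[key]] <- expr
  cc_cache[[key]]
}

get_report <- function(preset, seed = 1L, ...) {
  nm <- if (is.character(preset)) preset else preset$name
  cached(paste("report", nm, seed, sep = "_"),
         reproduce_circuit(preset, seed = seed, ...))
}

# small trained simple-task circuit shared by several test files
get_tiny_run <- function() {
  cached("tiny_run", {
    st <- init_circuit(circuit_params(N = 150, seed = 1,
                                      psi = activation("sigmoid", 1, 0),
                                      phi = activation("sigmoid", 1, 0)))
    tk <- make_simple_task(150, 6, seed = 2)
    list(traj = train(st, tk, train_config(max_epochs = 100000L)), task = tk)
  })
}

# the shallow-gain operating point used for the theory-vs-simulation harness
lazy_reference_row <- function() {
  data.frame(name = "lazy_reference", task = "simple", N = 800, Q = 20,
             eta_ratio = 0, psi_theta1 = 0.5, psi_theta2 = 0,
             phi_theta1 = 1, phi_theta2 = 0, bias_sd = 0, sigma = 0)
}
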