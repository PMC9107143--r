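# Shared MCMC settings and cached fixture fits (fitted once per test run).

.fit_cache <- new.env(parent = emptyenv())

# production-quality settings used for replication checks on the fixtures
replication_config <- function(seed = 20260926) {
  nma_config(chains = 3, iterations = 20000, burn_in = 5000, seed = seed)
}

# short chains for structural / property tests on small synthetic networks
quick_config <- function(seed = 1, iterations = 2500, burn_in = 1000,
                         chains = 2, ...) {
  nma_config(chains = chains, iterations = iterations, burn_in = burn_in,
             seed = seed, adapt = 500, ...)
}

cached <- function(name, expr) {
  if (is.null(.fit_cache[[name]])) .fit_cache[[name]] <- force(expr)
  .fit_cache[[name]]
}

poison_fit <- function() {
  cached("poison", suppressWarnings(fit_nma(poison_network(),
                                            replication_config())))
}

stair_fit <- function() {
  cached("stair", suppressWarnings(fit_nma(stair_gate_network(),
                                           replication_config())))
}

# tiny deterministic three-intervention network used across tests
chain_network <- function(n = 300, seed = 11, d_true = c(0, 0.2, 0.4),
                          tau = 0.1,
                          contrasts = list(c(1, 2), c(1, 3), c(1, 2),
                                           c(1, 3), c(2, 3))) {
  simulate_network(3, length(contrasts),
                   synthetic_truth(d_true, tau, seed = seed),
                   arm_size = n, contrasts = contrasts)
}
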