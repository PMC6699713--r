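# Shared builders for small test systems.

# Two-input / two-species linear-law system with explicit allocations to
# substrate 1 (per species) and arbitrary kinetics.
two_input_system <- function(e1, e2, c1 = 0.5, v1 = 0.5, c2 = 0.5, v2 = 0.5,
                             Q1 = 5, Q2 = 5, D = 0.02, mu = 0, n = 2,
                             growth_law = "linear") {
  E <- if (n == 2) rbind(c(e1, 1 - e1), c(e2, 1 - e2)) else c(e1, 1 - e1)
  make_preset("two_input", Q = c(Q1, Q2, 0), v = c(v1, v2), c = c(c1, c2),
              D = D, E = E, n = n, mu = mu, growth_law = growth_law)
}

# The four-step specialist chain with its reference kinetics.
chain_system <- function(D = 0.01, Q1 = 0.5) {
  make_preset("linear_chain_4", Q = c(Q1, 0, 0, 0, 0), D = D)
}

chain_params <- list(D = 0.01, Q1 = 0.5, v = rep(0.2, 4), K = rep(1, 4),
                     c = c(1.56, 0.80, 0.89, 1.45))

# A random valid state for a community spec (fixed by the caller's seed).
random_state <- function(spec, smax = 2, nmax = 1) {
  list(S = runif(spec$pathway$m, 0, smax),
       N = runif(spec$n, 0, nmax))
}

# A random gut community with kinetics drawn like the experiments do.
random_gut_spec <- function(a = 1, mu = 0, generalist = TRUE) {
  pw <- gut_pathway()
  ns <- length(pw$metabolized)
  A <- if (generalist) random_generalist_allocation(ns) else diag(ns)
  make_preset("gut_11",
              v = runif(ns, 0.13, 1), K = runif(ns, 0.13, 1),
              c = runif(ns, 0.13, 1), D = runif(1, 0.01, 0.05),
              a = a, mu = mu, E = expand_substrate_allocation(A, pw))
}
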