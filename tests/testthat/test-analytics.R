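test_that("chain closed form gives the documented steady state", {
  sol <- do.call(specialist_chain_solution, chain_params)
  expect_equal(sol$S_tilde[1], 0.01 * 1 / (1.56 * 0.2 - 0.01),
               tolerance = 1e-12)
  expect_true(all(sol$viable))
  # total steady-state concentration equals the inflow
  expect_equal(sum(sol$S_tilde), 0.5, tolerance = 1e-12)
  # per-substrate concentration is independent of the supply
  sol2 <- specialist_chain_solution(0.01, 5, chain_params$v, chain_params$K,
                                    chain_params$c)
  expect_equal(sol2$S_tilde[1:4], sol$S_tilde[1:4])
})

test_that("chain concentrations respond monotonically to D, K and c v", {
  base <- do.call(specialist_chain_solution, chain_params)
  up_D <- specialist_chain_solution(0.012, 0.5, chain_params$v,
                                    chain_params$K, chain_params$c)
  expect_true(all(up_D$S_tilde[1:4] > base$S_tilde[1:4]))
  up_K <- specialist_chain_solution(0.01, 0.5, chain_params$v,
                                    chain_params$K * 1.5, chain_params$c)
  expect_true(all(up_K$S_tilde[1:4] > base$S_tilde[1:4]))
  up_cv <- specialist_chain_solution(0.01, 0.5, chain_params$v * 1.5,
                                     chain_params$K, chain_params$c)
  expect_true(all(up_cv$S_tilde[1:4] < base$S_tilde[1:4]))
})

test_that("washout cascades down the chain", {
  thr1 <- 1.56 * 0.2 * 0.5 / 1.5
  sol <- specialist_chain_solution(1.5 * thr1, 0.5, chain_params$v,
                                   chain_params$K, chain_params$c)
  expect_false(any(sol$viable))
  expect_equal(sol$S_tilde, c(0.5, 0, 0, 0, 0))
  expect_equal(sol$N_tilde, rep(0, 4))
  # intermediate washout: kill species 3 only (low c v)
  v <- chain_params$v; cc <- chain_params$c
  cc[3] <- 0.051  # c3 v3 just above D, but growth on its supply below D
  sol3 <- specialist_chain_solution(0.01, 0.5, v, chain_params$K, cc)
  expect_true(all(sol3$viable[1:2]))
  expect_false(sol3$viable[3])
  # substrate 3 accumulates the remaining supply, nothing flows further
  expect_equal(sol3$S_tilde[4:5], c(0, 0))
  expect_equal(sum(sol3$S_tilde), 0.5, tolerance = 1e-12)
})

test_that("coexistence threshold matches its special cases", {
  # symmetric parameters: threshold one half
  expect_equal(e_thresh(0.5, 0.5, 0.5, 0.5, 5, 5, 0.02), 0.5)
  # substrate 2 exactly at bare viability: threshold 1
  c2 <- 0.4; v2 <- 0.5; D <- 0.02
  expect_equal(e_thresh(0.7, 0.6, c2, v2, 4, D / (c2 * v2), D), 1,
               tolerance = 1e-12)
  expect_error(e_thresh(1, 1, 1, 1, 0.01, 0.005, 0.0075), "degenerate")
})

test_that("threshold classification agrees with ODE survival on random draws", {
  set.seed(3)
  n <- 60
  hits <- 0
  for (i in seq_len(n)) {
    c1 <- runif(1, 0.13, 1); c2 <- runif(1, 0.13, 1)
    v1 <- runif(1, 0.13, 1); v2 <- runif(1, 0.13, 1)
    D <- runif(1, 0.01, 0.05); Q <- broken_stick(10, 2)
    e1 <- runif(1); e2 <- runif(1)
    spec <- two_input_system(e1, e2, c1, v1, c2, v2, Q[1], Q[2], D)
    res <- simulate_community(spec, t_end = 4e5, n_out = 3)
    pred <- predict_two_species_survival(e1, e2, c1, v1, c2, v2,
                                         Q[1], Q[2], D)
    hits <- hits + identical(unname(res$survival), pred)
  }
  expect_gte(hits / n, 0.95)
})

test_that("evolved generalist equilibrium covers interior and boundary", {
  eq <- evolved_generalist_equilibrium(0.5, 0.5, 0.5, 0.5, 5, 5, 0.02)
  expect_equal(eq$E1, 0.5)
  expect_equal(eq$S_tilde, rep(0.02 / 0.25, 2))
  # substrate 2 unsustainable: a specialist on substrate 1 evolves
  c2 <- 0.5; v2 <- 0.5; D <- 0.02
  eqb <- evolved_generalist_equilibrium(0.5, 0.5, c2, v2, 5, D / (c2 * v2), D)
  expect_equal(eqb$E1, 1)
  # neither substrate viable: extinction
  eq0 <- evolved_generalist_equilibrium(0.5, 0.5, 0.5, 0.5, 0.01, 0.01, 0.02)
  expect_equal(eq0$N_tilde, 0)
})

test_that("optimal dilution matches the numeric argmax", {
  set.seed(13)
  for (i in 1:25) {
    c1 <- runif(1, 0.1, 2); v1 <- runif(1, 0.1, 2)
    K1 <- runif(1, 0.05, 5); Q1 <- runif(1, 0.2, 10)
    dopt <- optimal_dilution(c1, v1, K1, Q1)
    degr <- function(D) {
      s <- specialist_chain_solution(D, Q1, v1, K1, c1)
      D * (Q1 - s$S_tilde[1])
    }
    num <- optimize(degr, c(1e-6, c1 * v1 * Q1 / (K1 + Q1)),
                    maximum = TRUE, tol = 1e-10)$maximum
    expect_equal(dopt, num, tolerance = 1e-6)
  }
  # limits: ample supply or vanishing saturation push the optimum to washout
  expect_equal(optimal_dilution(0.5, 0.4, 1, 1e9), 0.2, tolerance = 1e-4)
  expect_equal(optimal_dilution(0.5, 0.4, 1e-9, 1), 0.2, tolerance = 1e-4)
})

test_that("each intermediate concentration peaks at its consumer's threshold", {
  # on the reference chain, S~_i(D) rises with D until species i + 1 (the
  # consumer of substrate i + 1... i.e. species i itself for substrate i)
  # drops out; the maximizing D is that species' persistence threshold
  p <- chain_params
  S2_of_D <- function(D) specialist_chain_solution(D, p$Q1, p$v, p$K,
                                                   p$c)$S_tilde[2]
  opt <- optimize(S2_of_D, c(0.001, 0.2), maximum = TRUE, tol = 1e-9)$maximum
  # persistence threshold of species 2: c2 v2 A / (K2 + A) at its supply
  supply <- function(D) p$Q1 - specialist_chain_solution(
    D, p$Q1, p$v, p$K, p$c)$S_tilde[1]
  thr <- uniroot(function(D) p$c[2] * p$v[2] * supply(D) /
                   (p$K[2] + supply(D)) - D, c(0.001, 0.2))$root
  expect_equal(opt, thr, tolerance = 1e-3)
})

test_that("functioning metrics agree between closed form and simulation", {
  sol <- do.call(specialist_chain_solution, chain_params)
  m1 <- functioning_metrics(sol)
  res <- simulate_community(chain_system(), t_end = 50000, n_out = 5)
  m2 <- functioning_metrics(res)
  expect_equal(m1$input_concentration, m2$input_concentration,
               tolerance = 1e-4)
  expect_equal(m1$degradation_rate, m2$degradation_rate, tolerance = 1e-4)
  expect_equal(m1$end_product, m2$end_product, tolerance = 1e-4)
  expect_equal(m1$total_biomass, m2$total_biomass, tolerance = 1e-4)
  expect_equal(m1$degradation_rate,
               0.01 * (0.5 - 0.01 * 1 / (1.56 * 0.2 - 0.01)),
               tolerance = 1e-12)
  # a washed-out chain degrades nothing
  thr1 <- 1.56 * 0.2 * 0.5 / 1.5
  dead <- specialist_chain_solution(2 * thr1, 0.5, chain_params$v,
                                    chain_params$K, chain_params$c)
  expect_equal(functioning_metrics(dead)$degradation_rate, 0)
  # refuse non-steady input
  early <- simulate_community(chain_system(), t_end = 10, n_out = 3)
  expect_error(functioning_metrics(early), "not converged|converged")
})
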