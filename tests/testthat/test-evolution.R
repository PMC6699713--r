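test_that("selection gradient matches its closed form", {
  spec <- two_input_system(0.5, 0.5, c1 = 1, v1 = 0.5, c2 = 1, v2 = 0.5,
                           Q1 = 1, Q2 = 1, growth_law = "monod")
  # monod, a = 1: entry c v S / (K + S), independent of E
  g <- selection_gradient(spec, c(1, 1, 0), species = 1)
  expect_equal(unname(g[1]), 0.25)
  g2 <- selection_gradient(spec, c(1, 1, 0), species = 1, E = c(0.9, 0.1))
  expect_equal(g, g2)
  # a > 1: no selection to gain an absent enzyme through this term
  spec2 <- two_input_system(0.5, 0.5, growth_law = "monod")
  spec2$a <- 2
  g3 <- selection_gradient(spec2, c(1, 1, 0), species = 1, E = c(1, 0))
  expect_equal(unname(g3[2]), 0)
  spec2$a <- 0.5
  expect_error(selection_gradient(spec2, c(1, 1, 0)), ">= 1")
})

test_that("selection gradient agrees with numeric differentiation", {
  set.seed(21)
  h <- 1e-6
  for (law in c("monod", "linear")) {
    for (a in c(1, 2)) {
      spec <- random_gut_spec(a = a)
      spec$growth_law <- law
      S <- runif(spec$pathway$m, 0.05, 2)
      E <- as.vector(expand_substrate_allocation(
        broken_stick(1, 8), spec$pathway))
      g <- selection_gradient(spec, S, species = 1, E = E)
      for (r in sample(spec$pathway$n_reactions, 4)) {
        Ep <- Em <- E
        Ep[r] <- E[r] + h; Em[r] <- E[r] - h
        fd <- (per_capita_growth(spec, S, Ep) -
                 per_capita_growth(spec, S, Em)) / (2 * h)
        expect_equal(unname(g[r]), unname(fd[1]), tolerance = 1e-6)
      }
    }
  }
})

test_that("allocation change conserves the enzyme budget", {
  spec <- two_input_system(0.6, 0.4, mu = 0.01)
  # a uniform gradient is a null direction of the G-matrix
  d0 <- enzyme_derivatives(spec, c(1, 1, 0), species = 1, E = c(0.5, 0.5))
  expect_equal(d0, c(0, 0), tolerance = 1e-15)
  # with 2 enzymes the genetic correlation is -1: changes mirror exactly
  spec2 <- two_input_system(0.6, 0.4, c1 = 1, v1 = 1, mu = 0.01)
  d <- enzyme_derivatives(spec2, c(2, 1, 0), species = 1, E = c(0.6, 0.4))
  expect_gt(d[1], 0)
  expect_equal(d[2], -d[1], tolerance = 1e-15)
})

test_that("boundary truncation keeps the allocation inside the simplex", {
  set.seed(31)
  spec <- random_gut_spec(mu = 0.02)
  res <- simulate_evolution(spec, t_end = 5000, n_out = 51)
  R <- spec$pathway$n_reactions
  Etraj <- res$E_trajectory
  expect_gte(min(Etraj), -1e-8)
  expect_lte(max(Etraj), 1 + 1e-8)
  # row sums of every species' allocation conserved along the trajectory
  for (k in seq_len(spec$n)) {
    sums <- rowSums(Etraj[, (k - 1) * R + seq_len(R), drop = FALSE])
    expect_lt(max(abs(sums - 1)), 1e-6)
  }
})

test_that("a single evolving generalist reaches its closed-form equilibrium", {
  c1 <- 0.6; v1 <- 0.4; c2 <- 0.3; v2 <- 0.7; Q1 <- 4; Q2 <- 6; D <- 0.02
  eq <- evolved_generalist_equilibrium(c1, v1, c2, v2, Q1, Q2, D)
  spec <- two_input_system(0.7, NA, c1, v1, c2, v2, Q1, Q2, D,
                           mu = 0.01, n = 1)
  res <- simulate_evolution(spec, t_end = 50000, n_out = 5)
  expect_equal(unname(res$final$S[1:2]), eq$S_tilde, tolerance = 1e-4)
  expect_equal(unname(res$final$E[1, 1]), eq$E1, tolerance = 1e-3)
  expect_equal(unname(res$final$N), eq$N_tilde, tolerance = 1e-3)
})

test_that("mu = 0 reproduces the ecological trajectory", {
  spec <- two_input_system(0.8, 0.3, mu = 0)
  a <- simulate_evolution(spec, t_end = 2000, n_out = 21)
  b <- simulate_community(spec, t_end = 2000, n_out = 21)
  expect_equal(a$S, b$S, tolerance = 1e-8)
  expect_equal(a$N, b$N, tolerance = 1e-8)
  expect_equal(max(abs(a$E_trajectory -
                         rep(as.vector(t(spec$E)),
                             each = nrow(a$E_trajectory)))), 0)
})

test_that("two evolving species settle in the coexistence band, endpoint set by the start", {
  # symmetric reference system: threshold allocation is 1/2
  s1 <- two_input_system(0.9, 0.75, mu = 0.01)
  r1 <- simulate_evolution(s1, t_end = 20000, n_out = 5)
  expect_true(all(r1$survival))
  expect_gt(r1$final$E[1, 1], 0.5)
  expect_lt(r1$final$E[2, 1], 0.5)
  s2 <- two_input_system(0.6, 0.2, mu = 0.01)
  r2 <- simulate_evolution(s2, t_end = 20000, n_out = 5)
  expect_true(all(r2$survival))
  # different starting allocations give different endpoints (neutral band)
  expect_gt(abs(r1$final$E[1, 1] - r2$final$E[1, 1]), 1e-3)
  # substrate concentrations are the specialist solutions regardless
  expect_equal(unname(r1$final$S[1:2]), unname(r2$final$S[1:2]),
               tolerance = 1e-6)
})

test_that("starting specialists converge in profile under a linear trade-off", {
  set.seed(41)
  spec <- random_gut_spec(mu = 0.01, generalist = FALSE)
  res <- simulate_evolution(spec, t_end = 20000, n_out = 3)
  A0 <- group_by_substrate(spec$E, spec$pathway)
  A1 <- group_by_substrate(res$final$E, spec$pathway)
  expect_lt(mean_pairwise_distance(A1), mean_pairwise_distance(A0))
})

test_that("with a concave trade-off species specialize and partition", {
  set.seed(43)
  spec <- random_gut_spec(a = 2, mu = 0.01)
  res <- simulate_evolution(spec, t_end = 20000, n_out = 3)
  A0 <- group_by_substrate(spec$E, spec$pathway)
  surv <- res$survival
  A1 <- group_by_substrate(res$final$E, spec$pathway)
  A1 <- A1 / rowSums(A1)
  # mean allocation to each survivor's leading enzyme increases
  expect_gt(mean(apply(A1[surv, ], 1, max)), mean(apply(A0[surv, ], 1, max)))
  # final profiles are not all alike
  expect_gt(mean_pairwise_distance(A1[surv, ]), 0.05)
})

test_that("invasion fitness is zero for residents and positive in empty niches", {
  spec <- two_input_system(0.8, 0.2, mu = 0.01)
  res <- simulate_evolution(spec, t_end = 20000, n_out = 5)
  expect_true(res$converged)
  # a surviving resident's own profile cannot grow when rare
  expect_lt(abs(invasion_fitness(res, res$final$E[1, ])), 1e-8)
  # neutrality: the perfect generalist and the two specialists all have
  # invasion fitness 0 at the evolved equilibrium
  expect_lt(abs(invasion_fitness(res, c(0.5, 0.5))), 1e-6)
  expect_lt(abs(invasion_fitness(res, c(1, 0))), 1e-6)
  expect_lt(abs(invasion_fitness(res, c(0, 1))), 1e-6)

  # a washed-out niche: substrate 2 left at Q2, specialist invades iff
  # growth there beats dilution
  spec1 <- two_input_system(1, 0, Q2 = 0.5, n = 1, c2 = 0.5, v2 = 0.5)
  r1 <- simulate_community(spec1, t_end = 20000, n_out = 5)
  expect_equal(unname(r1$final$S[2]), 0.5, tolerance = 1e-8)
  f2 <- invasion_fitness(r1, c(0, 1))
  expect_equal(f2, 0.5 * 0.5 * 0.5 - spec1$D, tolerance = 1e-8)

  # refuse a non-converged resident
  r0 <- simulate_community(two_input_system(0.8, 0.2), t_end = 5, n_out = 3)
  expect_error(invasion_fitness(r0, c(0.5, 0.5)), "converged")
})
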