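#' Selection gradient on enzyme allocation
#'
#' Partial derivatives of a species' per-capita growth rate with respect to
#' each of its enzyme allocations, at substrate concentrations `S`. For the
#' Monod law the entry for a reaction converting substrate `i` is
#' `c * v * a * E^(a-1) * S_i / (K + S_i)`; the linear law drops the
#' denominator. At `a = 1` the gradient does not depend on the current
#' allocation: selection simply favours the reactions with the highest
#' yield-weighted flux per unit enzyme.
#'
#' @param spec A [community_spec()] with `a >= 1`.
#' @param S Substrate concentrations.
#' @param species Species index (row of `spec$E` and of the kinetic
#'   matrices).
#' @param E Optional allocation vector for that species, overriding
#'   `spec$E[species, ]` (needed only when `a > 1`).
#' @return Numeric vector, one entry per reaction.
#' @export
selection_gradient <- function(spec, S, species = 1, E = NULL) {
  if (spec$a < 1) stop("cost-of-generalism exponent `a` must be >= 1")
  if (any(S < 0)) stop("negative substrate concentration")
  if (is.null(E)) E <- spec$E[species, ]
  if (any(E < 0 | E > 1)) stop("allocation outside [0, 1]")
  Ss <- S[spec$pathway$src]
  v <- spec$v[species, ]; K <- spec$K[species, ]; cc <- spec$c[species, ]
  mono <- if (spec$growth_law == "monod") Ss / (K + Ss) else Ss
  g <- cc * v * mono * (if (spec$a == 1) 1 else spec$a * E^(spec$a - 1))
  stats::setNames(g, reaction_labels(spec$pathway))
}

#' Allocation derivative for one species
#'
#' The rate of change of a species' allocation vector under the
#' quantitative-genetic model: the G-matrix (diagonal `mu`, off-diagonal
#' `-mu/(nE - 1)`, rows summing to zero so the total allocation is conserved)
#' multiplied by the selection gradient, followed by truncation at the
#' \[0, 1\] boundary. Truncation scales components that would push an
#' allocation outside the simplex down to zero over a narrow smooth boundary
#' layer and re-balances the remaining components, keeping the derivative sum
#' at zero.
#'
#' @inheritParams selection_gradient
#' @param N Species densities (unused by the mean-trait model itself; kept so
#'   a full state can be passed through).
#' @return Numeric derivative vector summing to zero (within rounding).
#' @export
enzyme_derivatives <- function(spec, S, species = 1, E = NULL, N = NULL) {
  if (is.null(E)) E <- spec$E[species, ]
  g <- selection_gradient(spec, S, species, E)
  p <- .model_env(spec, evolve = TRUE)
  dE <- p$mu_fac[species] * (g - mean(g))
  as.vector(.truncate_dE(matrix(E, ncol = 1), matrix(dE, ncol = 1)))
}

#' Simulate coupled eco-evolutionary dynamics
#'
#' Jointly integrates substrate concentrations, species densities and every
#' species' enzyme-allocation vector. With `mu = 0` the trajectory reduces to
#' the purely ecological [simulate_community()].
#'
#' @inheritParams simulate_community
#' @param init Optional initial state; may include an `E` matrix (defaults to
#'   `spec$E`).
#' @return A `simulation_result` whose `E_trajectory` holds the allocation
#'   time courses and whose `final$E` is the evolved allocation matrix.
#' @examples
#' spec <- make_preset("two_input", E = rbind(c(0.9, 0.1), c(0.6, 0.4)),
#'                     mu = 0.01)
#' res <- simulate_evolution(spec, t_end = 4000)
#' res$final$E
#' @export
simulate_evolution <- function(spec, init = NULL, t_end = 2000, n_out = 201,
                               rtol = 1e-8, atol = 1e-10,
                               survival_threshold = 1e-4, compiled = TRUE) {
  sol <- .run_ode(spec, init, t_end, n_out, rtol, atol, evolve = TRUE,
                  compiled = compiled)
  .as_result(sol, spec, evolve = TRUE, survival_threshold)
}

#' Invasion fitness of a rare phenotype
#'
#' Per-capita growth rate, net of dilution, of an invader with the given
#' allocation profile introduced at vanishing density into the resident
#' community's steady-state environment. Residents that persist sit at zero
#' net growth, so an invader identical to a surviving resident has invasion
#' fitness zero; a positive value means the phenotype can increase when
#' rare. The invader is assumed to share the community's enzyme kinetics
#' (those of the first resident species).
#'
#' @param resident A converged `simulation_result`.
#' @param invader_profile Allocation vector over the pathway's reactions
#'   (entries in \[0, 1\] summing to 1).
#' @return Scalar invasion fitness.
#' @export
invasion_fitness <- function(resident, invader_profile) {
  if (!inherits(resident, "simulation_result"))
    stop("`resident` must be a simulation_result")
  if (!resident$converged)
    stop("resident community has not converged to steady state; ",
         "run it longer before assessing invasion")
  spec <- resident$spec
  validate_allocation(matrix(invader_profile, nrow = 1))
  as.numeric(per_capita_growth(spec, resident$final$S,
                               E = invader_profile)) - spec$D
}
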