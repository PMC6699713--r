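#' Closed-form steady state of a specialist chain
#'
#' For a linear pathway of `m` substrates in which substrate `i` (for
#' `i < m`) is metabolized by its own specialist species under Monod
#' kinetics, the steady state is available in closed form: each viable
#' species holds its substrate at `S_i = D K_i / (c_i v_i - D)` —
#' independently of the supply — and reaches density
#' `N_i = c_i (Q1 - Y_i)` where `Y_i` is the cumulative concentration of
#' substrates 1..i. The final, unmetabolized substrate carries the remainder
#' `Q1 - Y_m`, so the steady-state concentrations sum to the inflow `Q1`.
#'
#' Species `i` persists only if its growth on the supply reaching it beats
#' dilution, `c_i v_i A_i / (K_i + A_i) > D` with `A_i` the concentration
#' available after upstream consumption. A non-viable species washes out: its
#' substrate accumulates to the full supply, nothing flows further down the
#' chain, and all downstream substrates and species are zero.
#'
#' @param D Dilution rate.
#' @param Q1 Inflow concentration of the input substrate.
#' @param v,K,c Kinetic parameter vectors, one entry per reaction/species
#'   along the chain.
#' @return An object of class `chain_solution`: list with `S_tilde` (length
#'   `m = length(v) + 1`), `N_tilde`, `Y` (cumulative concentrations),
#'   `viable` (per species) and the inputs.
#' @examples
#' sol <- specialist_chain_solution(D = 0.01, Q1 = 0.5, v = rep(0.2, 4),
#'                                  K = rep(1, 4), c = c(1.56, 0.80, 0.89, 1.45))
#' sol$S_tilde
#' @export
specialist_chain_solution <- function(D, Q1, v, K, c) {
  stopifnot(D > 0, Q1 > 0, length(v) == length(K), length(v) == length(c),
            all(v > 0), all(K > 0), all(c > 0))
  ns <- length(v)
  S <- numeric(ns + 1); N <- numeric(ns); viable <- logical(ns)
  supply <- Q1
  for (i in seq_len(ns)) {
    cv <- c[i] * v[i]
    grows <- cv > D && supply > 0 && cv * supply / (K[i] + supply) > D
    if (grows) {
      S[i] <- D * K[i] / (cv - D)
      N[i] <- c[i] * (supply - S[i])
      viable[i] <- TRUE
      supply <- supply - S[i]
    } else {
      S[i] <- supply
      supply <- 0
    }
  }
  S[ns + 1] <- supply
  structure(list(S_tilde = S, N_tilde = N, Y = cumsum(S[seq_len(ns)]),
                 viable = viable, D = D, Q1 = Q1, v = v, K = K, c = c),
            class = "chain_solution")
}

#' @export
print.chain_solution <- function(x, ...) {
  cat("Specialist chain steady state (D =", x$D, ", Q1 =", x$Q1, ")\n")
  cat("  S~:", paste(signif(x$S_tilde, 4), collapse = " "), "\n")
  cat("  N~:", paste(signif(x$N_tilde, 4), collapse = " "),
      " viable:", paste(x$viable, collapse = " "), "\n")
  invisible(x)
}

#' Coexistence threshold allocation for two species on two inputs
#'
#' Under the linear growth law with two input substrates and two species,
#' two species coexist exactly when their allocations to substrate 1
#' straddle the threshold
#' `(c1 v1 v2 Q1 - v2 D) / (c1 v1 v2 Q1 + c2 v1 v2 Q2 - v1 D - v2 D)`.
#' With identical parameters and inflows on both substrates the threshold is
#' one half: any split in which one species leans towards substrate 1 and
#' the other towards substrate 2 permits coexistence.
#'
#' @param c1,v1,c2,v2 Kinetic parameters of the two enzymes.
#' @param Q1,Q2 Inflow concentrations.
#' @param D Dilution rate.
#' @return Threshold allocation to substrate 1.
#' @export
e_thresh <- function(c1, v1, c2, v2, Q1, Q2, D) {
  den <- c1 * v1 * v2 * Q1 + c2 * v1 * v2 * Q2 - v1 * D - v2 * D
  if (abs(den) < .Machine$double.eps * 100)
    stop("degenerate parameters: threshold denominator is zero")
  (c1 * v1 * v2 * Q1 - v2 * D) / den
}

#' Predict two-species coexistence from the threshold allocation
#'
#' @inheritParams e_thresh
#' @param E1,E2 Each species' allocation to substrate 1.
#' @return One of `"coexist"`, `"species1"`, `"species2"` (the more
#'   generalist competitor excludes the other when both sit on the same side
#'   of the threshold).
#' @export
classify_coexistence <- function(E1, E2, c1, v1, c2, v2, Q1, Q2, D) {
  th <- e_thresh(c1, v1, c2, v2, Q1, Q2, D)
  if ((E1 - th) * (E2 - th) < 0) return("coexist")
  ## both on the same side: the species nearer the threshold persists alone
  if (E1 > th) {
    if (E1 < E2) "species1" else "species2"
  } else {
    if (E1 > E2) "species1" else "species2"
  }
}

#' Predict two-species survival on two inputs from the threshold allocation
#'
#' Combines the coexistence threshold with the substrate viability
#' conditions: both species persist when both substrates can sustain growth
#' (`Q_i > D / (c_i v_i)`) and the allocations straddle the threshold;
#' otherwise the competitively favoured species (see
#' [classify_coexistence()]) persists alone provided its growth on the full
#' inflow concentrations beats dilution, and the other washes out.
#'
#' @inheritParams classify_coexistence
#' @return Logical vector of length 2: predicted survival of each species.
#' @export
predict_two_species_survival <- function(E1, E2, c1, v1, c2, v2, Q1, Q2, D) {
  th <- e_thresh(c1, v1, c2, v2, Q1, Q2, D)
  if (Q1 > D / (c1 * v1) && Q2 > D / (c2 * v2) &&
      (E1 - th) * (E2 - th) < 0)
    return(c(TRUE, TRUE))
  w <- if (classify_coexistence(E1, E2, c1, v1, c2, v2, Q1, Q2, D) ==
             "species1") 1L else 2L
  ew <- c(E1, E2)[w]
  out <- c(FALSE, FALSE)
  out[w] <- ew * c1 * v1 * Q1 + (1 - ew) * c2 * v2 * Q2 > D
  out
}

#' Evolved equilibrium of a single generalist on two inputs
#'
#' Closed-form endpoint of allocation evolution for one species on two input
#' substrates under the linear growth law: each substrate it uses settles at
#' `S_i = D / (c_i v_i)`, the allocation to substrate 1 equals the
#' coexistence threshold, and the density is
#' `(c1 v1 v2 Q1 + c2 v1 v2 Q2 - v1 D - v2 D) / (v1 v2)`. When one substrate
#' cannot sustain growth (`Q_i <= D / (c_i v_i)`) a specialist on the other
#' substrate evolves; when neither can, the species washes out.
#'
#' @inheritParams e_thresh
#' @return List with `S_tilde` (length 2), `E1` (allocation to substrate 1)
#'   and `N_tilde`.
#' @export
evolved_generalist_equilibrium <- function(c1, v1, c2, v2, Q1, Q2, D) {
  viable1 <- Q1 > D / (c1 * v1)
  viable2 <- Q2 > D / (c2 * v2)
  if (viable1 && viable2) {
    list(S_tilde = c(D / (c1 * v1), D / (c2 * v2)),
         E1 = e_thresh(c1, v1, c2, v2, Q1, Q2, D),
         N_tilde = (c1 * v1 * v2 * Q1 + c2 * v1 * v2 * Q2 -
                      v1 * D - v2 * D) / (v1 * v2))
  } else if (viable1) {
    ## substrate 2 cannot sustain growth: a specialist on substrate 1 evolves
    S1 <- D / (c1 * v1)
    list(S_tilde = c(S1, Q2), E1 = 1, N_tilde = c1 * (Q1 - S1))
  } else if (viable2) {
    S2 <- D / (c2 * v2)
    list(S_tilde = c(Q1, S2), E1 = 0, N_tilde = c2 * (Q2 - S2))
  } else {
    list(S_tilde = c(Q1, Q2), E1 = NA_real_, N_tilde = 0)
  }
}

#' Dilution rate maximizing the degradation rate
#'
#' The degradation rate of the input substrate at steady state,
#' `D (Q1 - S1(D))` with `S1 = D K1 / (c1 v1 - D)`, has a single interior
#' maximum at `D_opt = c1 v1 (K1 + Q1 - sqrt(K1 (K1 + Q1))) / (K1 + Q1)`,
#' which always lies below the washout threshold.
#'
#' @param c1,v1,K1 Kinetics of the input reaction.
#' @param Q1 Inflow concentration.
#' @return Optimal dilution rate.
#' @export
optimal_dilution <- function(c1, v1, K1, Q1) {
  stopifnot(c1 > 0, v1 > 0, K1 > 0, Q1 > 0)
  c1 * v1 * (K1 + Q1 - sqrt(K1 * (K1 + Q1))) / (K1 + Q1)
}

#' Community functioning metrics
#'
#' Standard summaries of a steady state, computed identically for a
#' closed-form [specialist_chain_solution()] and for a converged
#' [simulate_community()] result: the outflow concentration of the input
#' substrate, the degradation rate of the input `D (Q1 - S1)`, intermediate
#' concentrations, the end-product concentration, and total biomass.
#'
#' @param solution A `chain_solution` or a converged `simulation_result`.
#' @return Named list: `input_concentration`, `degradation_rate`,
#'   `intermediates` (named vector; empty when the pathway has none),
#'   `end_product`, `total_biomass`.
#' @export
functioning_metrics <- function(solution) {
  if (inherits(solution, "chain_solution")) {
    S <- solution$S_tilde
    m <- length(S)
    D <- solution$D; Qtot <- solution$Q1
    N <- solution$N_tilde
    S_in <- S[1]
    inter <- if (m > 2) stats::setNames(S[2:(m - 1)], paste0("S", 2:(m - 1)))
             else numeric(0)
    S_end <- S[m]
  } else if (inherits(solution, "simulation_result")) {
    if (!solution$converged)
      stop("simulation has not converged; metrics would not be steady-state")
    pw <- solution$spec$pathway
    S <- solution$final$S
    D <- solution$spec$D
    Qtot <- sum(pw$Q)
    N <- solution$final$N
    inflow <- which(pw$Q > 0)
    S_in <- sum(S[inflow])
    inter <- S[setdiff(pw$metabolized, inflow)]
    S_end <- sum(S[pw$terminal])
  } else stop("unsupported solution type")
  list(input_concentration = unname(S_in),
       degradation_rate = D * (Qtot - S_in),
       intermediates = inter,
       end_product = unname(S_end),
       total_biomass = sum(N))
}
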