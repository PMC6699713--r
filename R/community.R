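#' Per-cell metabolic flux of a reaction
#'
#' The rate per cell at which one reaction converts its substrate, given the
#' enzyme allocation `E` devoted to it. Under Monod kinetics the flux is
#' `v * E^a * S / (K + S)`; under the linear growth law it is `v * E^a * S`.
#' The exponent `a >= 1` is the cost of generalism: at `a = 1` the allocation
#' trade-off is linear, while `a > 1` penalizes spreading enzyme across
#' several reactions (all `E < 1` are devalued).
#'
#' All arguments are vectorized elementwise.
#'
#' @param v Maximum reaction rate per unit enzyme (> 0).
#' @param E Enzyme allocation in \[0, 1\].
#' @param K Half-saturation constant (> 0 for Monod; ignored by the linear
#'   law).
#' @param S Substrate concentration (>= 0).
#' @param a Cost-of-generalism exponent (>= 1, default 1).
#' @param growth_law `"monod"` or `"linear"`.
#' @return Numeric flux, zero exactly when `E = 0` or `S = 0`.
#' @examples
#' reaction_flux(v = 0.2, E = 1, K = 1, S = 1)        # 0.1
#' reaction_flux(v = 1, E = 0.5, K = 1, S = 1, a = 2) # 0.125
#' @export
reaction_flux <- function(v, E, K, S, a = 1, growth_law = c("monod", "linear")) {
  growth_law <- match.arg(growth_law)
  if (any(S < 0)) stop("negative substrate concentration at index ",
                       which(S < 0)[1])
  if (any(E < 0 | E > 1)) stop("enzyme allocation outside [0, 1] at index ",
                               which(E < 0 | E > 1)[1])
  if (any(v < 0)) stop("negative rate parameter v at index ", which(v < 0)[1])
  if (a < 1) stop("cost-of-generalism exponent `a` must be >= 1")
  if (growth_law == "monod") {
    if (any(K <= 0)) stop("half-saturation constant K must be positive")
    v * E^a * S / (K + S)
  } else {
    v * E^a * S
  }
}

#' Assemble a community specification
#'
#' Bundles a pathway with a species set: per-reaction kinetic parameters, an
#' enzyme-allocation matrix, chemostat settings and the growth law. Kinetic
#' parameters may be given per reaction (vectors recycled across species, the
#' usual case: an enzyme's kinetics do not depend on which species carries
#' it) or as full species-specific matrices.
#'
#' @param pathway A [pathway_spec()].
#' @param n Number of species.
#' @param v,K,c Kinetic parameters: maximum reaction rate per unit enzyme,
#'   half-saturation constant, and conversion of metabolized substrate to
#'   cell density. Each is a scalar, a vector of length `n_reactions`, or an
#'   `n` x `n_reactions` matrix.
#' @param E Allocation matrix, `n` species by `n_reactions` reactions; each
#'   row must lie in \[0, 1\] and sum to 1 (tolerance 1e-9). A vector is
#'   accepted for a single species.
#' @param D Dilution rate (> 0).
#' @param a Cost-of-generalism exponent (>= 1).
#' @param growth_law `"monod"` or `"linear"`.
#' @param mu Heritable variance in enzyme allocation per species (scalar or
#'   length-`n`); only used by [simulate_evolution()].
#' @param g_matrix_n How to count the trait dimension `nE` entering the
#'   G-matrix off-diagonal `-mu/(nE - 1)`: `"reactions"` (all pathway
#'   reactions, default) or `"substrates"` (metabolized substrates).
#' @param species Optional species labels.
#'
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(pathway, n, v, K, c, E, D, a = 1,
                           growth_law = c("monod", "linear"),
                           mu = 0, g_matrix_n = c("reactions", "substrates"),
                           species = NULL) {
  growth_law <- match.arg(growth_law)
  g_matrix_n <- match.arg(g_matrix_n)
  stopifnot(inherits(pathway, "pathway_spec"))
  R <- pathway$n_reactions
  n <- as.integer(n)
  if (n < 1) stop("need at least one species")
  as_par <- function(x, nm) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(n, R)))
        stop("`", nm, "` matrix must be n species x n_reactions")
      return(x)
    }
    if (length(x) == 1) x <- rep(x, R)
    if (length(x) != R)
      stop("`", nm, "` must have length 1, n_reactions, or be a matrix")
    matrix(x, n, R, byrow = TRUE)
  }
  v <- as_par(v, "v"); K <- as_par(K, "K"); c <- as_par(c, "c")
  if (any(v <= 0) || any(K <= 0) || any(c <= 0))
    stop("kinetic parameters v, K, c must be positive")
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  if (!all(dim(E) == c(n, R)))
    stop("`E` must be an n species x n_reactions allocation matrix")
  validate_allocation(E)
  if (D <= 0) stop("dilution rate D must be positive")
  if (a < 1) stop("cost-of-generalism exponent `a` must be >= 1")
  mu <- rep_len(as.numeric(mu), n)
  if (any(mu < 0)) stop("mutation parameter mu must be nonnegative")
  if (is.null(species)) species <- paste0("sp", seq_len(n))
  dimnames(E) <- list(species, reaction_labels(pathway))
  structure(list(pathway = pathway, n = n, v = v, K = K, c = c, E = E,
                 D = D, a = a, growth_law = growth_law, mu = mu,
                 g_matrix_n = g_matrix_n, species = species),
            class = "community_spec")
}

validate_allocation <- function(E, tol = 1e-9) {
  if (any(E < -tol | E > 1 + tol)) {
    bad <- which(E < -tol | E > 1 + tol, arr.ind = TRUE)[1, ]
    stop("allocation outside [0, 1] for species ", bad[1],
         ", reaction ", bad[2])
  }
  rs <- rowSums(E)
  if (any(abs(rs - 1) > 1e-9))
    stop("allocation rows must sum to 1; species ",
         which(abs(rs - 1) > 1e-9)[1], " sums to ",
         rs[which(abs(rs - 1) > 1e-9)[1]])
  invisible(TRUE)
}

#' @export
print.community_spec <- function(x, ...) {
  cat("Community of", x$n, "species on a", x$pathway$m, "substrate pathway\n")
  cat("  growth law:", x$growth_law, " D =", x$D, " a =", x$a, "\n")
  if (any(x$mu > 0)) cat("  evolving, mu =", paste(unique(x$mu), collapse = ", "), "\n")
  invisible(x)
}

#' Per-capita growth rate of each species
#'
#' Growth per cell per unit time at substrate concentrations `S`, summing the
#' yield-weighted metabolic fluxes `c * J` over all reactions (growth on
#' multiple substrates is additive). Dilution is not subtracted; it enters
#' through the density dynamics.
#'
#' @param spec A [community_spec()].
#' @param S Substrate concentrations (length `m`, >= 0).
#' @param E Optional allocation matrix overriding `spec$E` (species x
#'   reaction, or a vector for one species).
#' @return Numeric vector of per-capita growth rates, one per row of the
#'   allocation matrix.
#' @export
per_capita_growth <- function(spec, S, E = NULL) {
  if (length(S) != spec$pathway$m)
    stop("`S` must have one entry per substrate")
  if (any(S < 0)) stop("negative substrate concentration")
  if (is.null(E)) E <- spec$E
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  if (ncol(E) != spec$pathway$n_reactions)
    stop("allocation has wrong number of reactions")
  Ss <- S[spec$pathway$src]
  kin_rows <- if (nrow(E) == spec$n) seq_len(nrow(E)) else rep_len(1L, nrow(E))
  v <- spec$v[kin_rows, , drop = FALSE]
  K <- spec$K[kin_rows, , drop = FALSE]
  cc <- spec$c[kin_rows, , drop = FALSE]
  ## K is species x reaction; recycle the source concentrations across rows
  Sm <- matrix(Ss, nrow(E), length(Ss), byrow = TRUE)
  mono <- if (spec$growth_law == "monod") Sm / (K + Sm) else Sm
  Ea <- if (spec$a == 1) E else E^spec$a
  rowSums(cc * v * Ea * mono)
}

#' Specialist allocation matrix
#'
#' One species per metabolized substrate, in pathway order, with each
#' species' full enzyme budget on its substrate (split equally among branch
#' reactions).
#'
#' @param pathway A [pathway_spec()].
#' @return Allocation matrix, species x reaction.
#' @export
specialist_allocation <- function(pathway) {
  ns <- length(pathway$metabolized)
  expand_substrate_allocation(diag(ns), pathway)
}

#' Built-in model systems
#'
#' Fully wired community presets:
#' \describe{
#'   \item{`two_input`}{Two input substrates both metabolized into one shared
#'     waste product by two species; linear growth law. Defaults follow the
#'     symmetric reference case (`v = c = 0.5`, `Q = (5, 5, 0)`,
#'     `D = 0.02`), with the two species as specialists.}
#'   \item{`input_derived`}{One input substrate degraded to a derived
#'     substrate that is itself metabolized into terminal waste; two
#'     species, linear law, `Q1 = 5`.}
#'   \item{`linear_chain_4`}{Four-step linear chain (5 substrates) run by 4
#'     specialists under Monod kinetics: `D = 0.01`, `Q1 = 0.5`, `v = 0.2`,
#'     `K = 1`, `c = (1.56, 0.80, 0.89, 1.45)`.}
#'   \item{`gut_11`}{An 11-substrate, 8-species fermentation pathway modelled
#'     on polysaccharide breakdown in the gut: starch (inflow 3) and inulin
#'     (inflow 2) are degraded via oligosaccharides and hexoses to lactate
#'     and acetate and on to the terminal products propionate, butyrate and
#'     waste gas. 8 metabolized substrates, 13 reactions, 3 terminal
#'     substrates; Monod kinetics. Kinetic defaults are neutral midpoints
#'     (`v = K = c = 0.5`, `D = 0.03`); the experiment harness redraws them
#'     per replicate. Branch reactions out of the same substrate share
#'     kinetic parameters.}
#' }
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [community_spec()] (e.g. `E`, `D`, `a`,
#'   `mu`, `growth_law`, `v`, `K`, `c`) or, for `gut_11`, `reactions` to
#'   supply an alternative edge set for the pathway.
#' @return A [community_spec()].
#' @examples
#' make_preset("linear_chain_4")$pathway
#' @export
make_preset <- function(preset = c("two_input", "input_derived",
                                 "linear_chain_4", "gut_11"), ...) {
  preset <- match.arg(preset)
  dots <- list(...)
  take <- function(key, default) {
    if (key %in% names(dots)) dots[[key]] else default
  }
  build <- function(pathway, defaults) {
    args <- modifyList(defaults, dots[setdiff(names(dots), c("reactions", "Q"))])
    do.call(community_spec, c(list(pathway = pathway), args))
  }
  switch(preset,
    two_input = {
      pw <- pathway_spec(c("S1", "S2", "W"),
                         rbind(c(1, 3), c(2, 3)),
                         Q = take("Q", c(5, 5, 0)))
      build(pw, list(n = 2, v = 0.5, K = 1, c = 0.5,
                     E = diag(2), D = 0.02, growth_law = "linear"))
    },
    input_derived = {
      pw <- pathway_spec(c("S1", "S2", "W"),
                         rbind(c(1, 2), c(2, 3)),
                         Q = take("Q", c(5, 0, 0)))
      build(pw, list(n = 2, v = 0.5, K = 1, c = 0.5,
                     E = diag(2), D = 0.02, growth_law = "linear"))
    },
    linear_chain_4 = {
      pw <- pathway_spec(paste0("S", 1:5),
                         cbind(1:4, 2:5),
                         Q = take("Q", c(0.5, 0, 0, 0, 0)))
      build(pw, list(n = 4, v = 0.2, K = 1,
                     c = c(1.56, 0.80, 0.89, 1.45),
                     E = diag(4), D = 0.01, growth_law = "monod"))
    },
    gut_11 = {
      pw <- gut_pathway(Q = take("Q", NULL),
                        reactions = take("reactions", NULL))
      ns <- length(pw$metabolized)
      kin <- function(x) substrate_kinetics(pw, rep_len(x, ns))
      defaults <- list(n = ns,
                       v = kin(take("v", 0.5)),
                       K = kin(take("K", 0.5)),
                       c = kin(take("c", 0.5)),
                       E = specialist_allocation(pw),
                       D = 0.03, growth_law = "monod")
      dots$v <- dots$K <- dots$c <- NULL
      args <- modifyList(defaults, dots[setdiff(names(dots), c("reactions", "Q"))])
      do.call(community_spec, c(list(pathway = pw), args))
    }
  )
}

#' The gut fermentation pathway
#'
#' The 11-substrate decomposition network used by the 8-species experiments:
#' starch -> malto-oligosaccharides -> glucose and inulin ->
#' fructo-oligosaccharides -> fructose; each hexose feeds lactate and
#' acetate; lactate branches to propionate, butyrate and acetate; acetate
#' branches to butyrate and waste gas. The exact published edge set is not
#' fully recoverable, so the reaction list is an argument: supply
#' `reactions` to study topology variants.
#'
#' @param Q Inflow concentrations (default starch 3, inulin 2, others 0).
#' @param reactions Optional replacement reaction list (labels or indices).
#' @return A [pathway_spec()] with 8 metabolized and 3 terminal substrates
#'   under the default edge set.
#' @export
gut_pathway <- function(Q = NULL, reactions = NULL) {
  nm <- c("starch", "inulin", "maltooligo", "fructooligo", "glucose",
          "fructose", "lactate", "acetate", "propionate", "butyrate", "gas")
  if (is.null(Q)) {
    Q <- numeric(11)
    Q[1] <- 3; Q[2] <- 2
  }
  if (is.null(reactions)) {
    reactions <- rbind(
      c("starch", "maltooligo"),
      c("inulin", "fructooligo"),
      c("maltooligo", "glucose"),
      c("fructooligo", "fructose"),
      c("glucose", "lactate"), c("glucose", "acetate"),
      c("fructose", "lactate"), c("fructose", "acetate"),
      c("lactate", "acetate"), c("lactate", "propionate"),
      c("lactate", "butyrate"),
      c("acetate", "butyrate"), c("acetate", "gas"))
  }
  pathway_spec(nm, reactions, Q)
}

#' Per-substrate kinetic parameters expanded to reactions
#'
#' Maps one parameter value per metabolized substrate onto that substrate's
#' outgoing reactions, so that branch reactions out of the same substrate
#' share rate parameters and yields.
#'
#' @param pathway A [pathway_spec()].
#' @param x Numeric vector, one value per metabolized substrate.
#' @return Numeric vector, one value per reaction.
#' @export
substrate_kinetics <- function(pathway, x) {
  if (length(x) != length(pathway$metabolized))
    stop("`x` must have one value per metabolized substrate")
  x[pathway$enzyme_group]
}
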