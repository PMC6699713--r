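## Fast internal representation of a community for the ODE right-hand sides.
## Precomputes the transposed (reaction x species) parameter matrices, the
## m x R net incidence matrix (production minus consumption) and index maps
## into the packed state vector.
.model_env <- function(spec, evolve = FALSE) {
  pw <- spec$pathway
  m <- pw$m; n <- spec$n; R <- pw$n_reactions
  A <- matrix(0, m, R)
  A[cbind(pw$src, seq_len(R))] <- -1
  A[cbind(pw$dst, seq_len(R))] <- A[cbind(pw$dst, seq_len(R))] + 1
  nE <- switch(spec$g_matrix_n,
               reactions = R,
               substrates = length(pw$metabolized))
  list(m = m, n = n, R = R, src = pw$src, dst = pw$dst, A = A, Q = pw$Q,
       D = spec$D,
       a = spec$a, monod = spec$growth_law == "monod",
       vT = t(spec$v), KT = t(spec$K), cT = t(spec$c), ET = t(spec$E),
       iS = seq_len(m), iN = m + seq_len(n),
       iE = if (evolve) m + n + seq_len(R * n) else integer(0),
       mu_fac = spec$mu * nE / (nE - 1))
}

.rhs_eco <- function(t, y, p) {
  S <- y[p$iS]; S[S < 0] <- 0
  N <- y[p$iN]; N[N < 0] <- 0
  if (any(!is.finite(S)) || any(!is.finite(N)))
    stop("non-finite state at t = ", t)
  Ss <- S[p$src]
  mono <- if (p$monod) Ss / (p$KT + Ss) else matrix(Ss, p$R, p$n)
  Ea <- if (p$a == 1) p$ET else p$ET^p$a
  J <- p$vT * Ea * mono
  q <- as.vector(J %*% N)
  dS <- p$D * (p$Q - S) + as.vector(p$A %*% q)
  dN <- (colSums(p$cT * J) - p$D) * N
  list(c(dS, dN))
}

## Truncate allocation change at the [0, 1] boundary. Outward components are
## scaled down smoothly over a narrow boundary layer of width `delta` (so the
## right-hand side stays Lipschitz and the solver does not chatter at the
## simplex boundary), and the removed change is redistributed across the
## other components in proportion to their room to absorb it, keeping each
## species' allocation derivative summing to zero.
.truncate_dE <- function(E, dE, delta = 1e-6) {
  E <- pmin(pmax(E, 0), 1)
  w <- matrix(1, nrow(dE), ncol(dE))
  down <- dE < 0
  w[down] <- pmin(E[down] / delta, 1)
  up <- dE > 0
  w[up] <- pmin((1 - E[up]) / delta, 1)
  dE <- dE * w
  deficit <- colSums(dE)
  for (k in which(abs(deficit) > 0)) {
    u <- if (deficit[k] > 0) pmin(E[, k] / delta, 1)
         else pmin((1 - E[, k]) / delta, 1)
    su <- sum(u)
    if (su > 1e-12) dE[, k] <- dE[, k] - deficit[k] * u / su
  }
  dE
}

.rhs_evo <- function(t, y, p) {
  S <- y[p$iS]; S[S < 0] <- 0
  N <- y[p$iN]; N[N < 0] <- 0
  E <- matrix(y[p$iE], p$R, p$n)
  E[E < 0] <- 0; E[E > 1] <- 1
  if (any(!is.finite(S)) || any(!is.finite(N)))
    stop("non-finite state at t = ", t)
  Ss <- S[p$src]
  mono <- if (p$monod) Ss / (p$KT + Ss) else matrix(Ss, p$R, p$n)
  Ea <- if (p$a == 1) E else E^p$a
  J <- p$vT * Ea * mono
  q <- as.vector(J %*% N)
  dS <- p$D * (p$Q - S) + as.vector(p$A %*% q)
  dN <- (colSums(p$cT * J) - p$D) * N
  ## selection gradient of per-capita growth w.r.t. each allocation
  g <- p$cT * p$vT * mono * (if (p$a == 1) p$a else p$a * E^(p$a - 1))
  dE <- rep(p$mu_fac, each = p$R) * (g - rep(colMeans(g), each = p$R))
  dE <- .truncate_dE(E, dE)
  list(c(dS, dN, as.vector(dE)))
}

#' Time derivatives of the chemostat system
#'
#' Evaluates the coupled substrate/density equations at one state: substrates
#' change by dilution `D (Q - S)`, consumption by all species' metabolism and
#' production from upstream reactions; species grow by their yield-weighted
#' metabolic flux and wash out at `D`. With `E` present in the state and a
#' positive `mu`, enzyme allocations change by the G-matrix times the
#' selection gradient, truncated at the \[0, 1\] boundary.
#'
#' @param state List with numeric elements `S` (length `m`), `N` (length
#'   `n`), and optionally `E` (species x reaction allocation matrix).
#' @param spec A [community_spec()].
#' @return List with `dS`, `dN`, and `dE` when `E` was supplied.
#' @export
derivatives <- function(state, spec) {
  pw <- spec$pathway
  if (length(state$S) != pw$m || length(state$N) != spec$n)
    stop("state dimensions do not match the community spec")
  evolve <- !is.null(state$E)
  p <- .model_env(spec, evolve = evolve)
  if (evolve) {
    E <- state$E
    if (is.null(dim(E))) E <- matrix(E, nrow = 1)
    out <- .rhs_evo(0, c(state$S, state$N, as.vector(t(E))), p)[[1]]
    dE <- t(matrix(out[p$iE], p$R, spec$n))
    dimnames(dE) <- dimnames(spec$E)
    list(dS = out[p$iS], dN = out[p$iN], dE = dE)
  } else {
    out <- .rhs_eco(0, c(state$S, state$N), p)[[1]]
    list(dS = out[p$iS], dN = out[p$iN])
  }
}

#' Default initial state
#'
#' The chemostat vessel starts filled with fresh medium (`S = Q`) and a small
#' even inoculum of every species.
#'
#' @param spec A [community_spec()].
#' @param N0 Initial density per species (default 0.1).
#' @return List with `S` and `N`.
#' @export
default_init <- function(spec, N0 = 0.1) {
  list(S = spec$pathway$Q, N = rep(N0, spec$n))
}

## Pack the model into the flat double vector expected by the compiled rhs.
.pack_parms <- function(p, evolve) {
  c(p$m, p$n, p$R, p$D, p$a, as.numeric(p$monod), as.numeric(evolve),
    p$Q, p$src, p$dst,
    as.vector(p$vT), as.vector(p$KT), as.vector(p$cT), as.vector(p$ET),
    p$mu_fac)
}

.run_ode <- function(spec, init, t_end, n_out, rtol, atol, evolve,
                     compiled = TRUE) {
  p <- .model_env(spec, evolve = evolve)
  if (is.null(init)) init <- default_init(spec)
  if (is.null(init$S)) init$S <- spec$pathway$Q
  if (is.null(init$N)) init$N <- rep(0.1, spec$n)
  y0 <- c(init$S, init$N)
  if (evolve) {
    E0 <- if (!is.null(init$E)) init$E else spec$E
    if (is.null(dim(E0))) E0 <- matrix(E0, nrow = 1)
    validate_allocation(E0)
    y0 <- c(y0, as.vector(t(E0)))
  }
  if (t_end < 0) stop("`t_end` must be nonnegative")
  if (t_end == 0)  # nothing to integrate: the trajectory is the initial state
    return(matrix(c(0, y0), nrow = 1))
  times <- unique(seq(0, t_end, length.out = max(2, n_out)))
  sol <- try(suppressWarnings({
    if (compiled) {
      .Call(chemevo_set_parms, .pack_parms(p, evolve))
      deSolve::ode(y = y0, times = times, func = "chemevo_derivs",
                   dllname = "chemevo", parms = NULL,
                   method = "lsoda", rtol = rtol, atol = atol,
                   maxsteps = 50000)
    } else {
      deSolve::ode(y = y0, times = times,
                   func = if (evolve) .rhs_evo else .rhs_eco, parms = p,
                   method = "lsoda", rtol = rtol, atol = atol,
                   maxsteps = 50000)
    }
  }), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("ODE solver failed: ", attr(sol, "condition")$message)
  if (nrow(sol) < length(times)) {
    last <- sol[nrow(sol), ]
    stop("ODE solver stopped at t = ", last[1], " of ", t_end,
         "; last state: ", paste(signif(last[-1], 4), collapse = ", "))
  }
  sol
}

.as_result <- function(sol, spec, evolve, survival_threshold) {
  pw <- spec$pathway
  m <- pw$m; n <- spec$n; R <- pw$n_reactions
  times <- sol[, 1]
  S <- sol[, 1 + seq_len(m), drop = FALSE]
  N <- sol[, 1 + m + seq_len(n), drop = FALSE]
  S[S < 0] <- 0; N[N < 0] <- 0
  colnames(S) <- pw$names
  colnames(N) <- spec$species
  Etraj <- NULL
  Efinal <- spec$E
  if (evolve) {
    Etraj <- sol[, 1 + m + n + seq_len(R * n), drop = FALSE]
    Efinal <- t(matrix(Etraj[nrow(Etraj), ], R, n))
    Efinal[Efinal < 0] <- 0; Efinal[Efinal > 1] <- 1
    dimnames(Efinal) <- dimnames(spec$E)
  }
  final <- list(t = times[length(times)],
                S = S[nrow(S), ], N = N[nrow(N), ], E = Efinal)
  fin_spec <- spec
  fin_spec$E <- Efinal
  d <- derivatives(list(S = final$S, N = final$N), fin_spec)
  scale <- max(abs(c(pw$Q, 1)))
  converged <- max(abs(c(d$dS, d$dN))) < 1e-6 * scale
  res <- structure(list(
    times = times, S = S, N = N, E_trajectory = Etraj,
    final = final, spec = spec, evolved = evolve,
    converged = converged,
    survival = classify_survival(final$N, survival_threshold),
    survival_threshold = survival_threshold
  ), class = "simulation_result")
  res
}

#' Simulate ecological dynamics
#'
#' Integrates the substrate/density ODEs with fixed enzyme allocations from
#' `t = 0` to `t_end` using a stiff-capable adaptive solver (lsoda), and
#' classifies survival from the final densities.
#'
#' @param spec A [community_spec()].
#' @param init Optional initial state, a list with `S` and `N` (defaults to
#'   [default_init()]).
#' @param t_end Final time.
#' @param n_out Number of equally spaced output times stored in the
#'   trajectory (solver stepping is independent of this grid).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param survival_threshold Density below which a species is classified as
#'   washed out.
#' @param compiled Use the compiled right-hand side (default); `FALSE`
#'   evaluates the pure-R reference implementation, useful for
#'   cross-checking.
#' @return A `simulation_result`: output times, substrate and density
#'   trajectories (matrices), the final state, a convergence flag (all
#'   derivatives near zero at the final state) and per-species survival.
#' @examples
#' res <- simulate_community(make_preset("linear_chain_4"), t_end = 5000)
#' res$final$S
#' @export
simulate_community <- function(spec, init = NULL, t_end = 2000, n_out = 201,
                               rtol = 1e-8, atol = 1e-10,
                               survival_threshold = 1e-4, compiled = TRUE) {
  sol <- .run_ode(spec, init, t_end, n_out, rtol, atol, evolve = FALSE,
                  compiled = compiled)
  .as_result(sol, spec, evolve = FALSE, survival_threshold)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Chemostat simulation to t =", x$final$t,
      if (x$evolved) "(evolving)" else "(ecological)", "\n")
  cat("  converged:", x$converged,
      " survivors:", sum(x$survival), "of", length(x$survival), "\n")
  cat("  final S:", paste(signif(x$final$S, 4), collapse = " "), "\n")
  invisible(x)
}

#' Classify species survival
#'
#' A species counts as surviving when its density exceeds a small threshold;
#' washed-out species decay exponentially towards zero, so outcomes are
#' insensitive to the exact cutoff over several orders of magnitude.
#'
#' @param N Final densities.
#' @param threshold Survival cutoff (default 1e-4, on the density scale of
#'   the built-in presets, where viable species sit around 0.1-10).
#' @return Logical vector.
#' @export
classify_survival <- function(N, threshold = 1e-4) {
  if (any(!is.finite(N))) stop("non-finite densities")
  N > threshold
}

#' Per-variable time to steady state
#'
#' For each state variable, the earliest output time after which it stays
#' within `rel_tol` of its final value for the remainder of the run.
#' Variables whose final value is effectively zero have no meaningful
#' relative criterion and are returned as `NA`.
#'
#' @param result A `simulation_result`.
#' @param rel_tol Relative band around the final value (default 0.01).
#' @param abs_floor Final values below this are flagged `NA`.
#' @return Named numeric vector of convergence times (substrates then
#'   species), `NA` where undefined or not converged within the run.
#' @export
detect_steady_state <- function(result, rel_tol = 0.01, abs_floor = 1e-8) {
  X <- cbind(result$S, result$N)
  times <- result$times
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    xf <- x[length(x)]
    if (abs(xf) < abs_floor) return(NA_real_)
    ok <- abs(x - xf) <= rel_tol * abs(xf)
    ## last index before which the band is violated
    if (!all(ok[length(ok)])) return(NA_real_)
    first_bad <- max(c(0L, which(!ok)))
    if (first_bad == length(ok)) return(NA_real_)
    times[first_bad + 1L]
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Tidy trajectory table
#'
#' @param x A `simulation_result`.
#' @param ... Unused.
#' @return Long data.frame with columns `time`, `kind` (substrate, species or
#'   enzyme), `label` and `value`.
#' @export
as.data.frame.simulation_result <- function(x, ...) {
  long <- function(M, kind, labels) {
    data.frame(time = rep(x$times, ncol(M)),
               kind = kind,
               label = rep(labels, each = nrow(M)),
               value = as.vector(M))
  }
  out <- rbind(long(x$S, "substrate", colnames(x$S)),
               long(x$N, "species", colnames(x$N)))
  if (!is.null(x$E_trajectory)) {
    rl <- reaction_labels(x$spec$pathway)
    labs <- as.vector(outer(rl, x$spec$species,
                            function(r, s) paste(s, r, sep = ":")))
    out <- rbind(out, long(x$E_trajectory, "enzyme", labs))
  }
  out
}
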