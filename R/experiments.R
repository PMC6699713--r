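#' Broken-stick partition
#'
#' Uniform random partition of a total into `k` nonnegative parts: `k - 1`
#' uniform cut points on `[0, total]`, sorted and differenced. Each part is
#' marginally distributed as the minimum-spacing law of the uniform stick;
#' for `k = 2` each part is Uniform(0, total).
#'
#' @param total Positive total to partition.
#' @param k Number of parts (>= 1).
#' @return Numeric vector of length `k` summing exactly to `total`.
#' @export
broken_stick <- function(total, k) {
  stopifnot(total > 0, k >= 1)
  if (k == 1) return(total)
  diff(c(0, sort(runif(k - 1, 0, total)), total))
}

#' Random complementary (doubly stochastic) enzyme allocation
#'
#' Draws an allocation matrix in which every species' allocation sums to 1
#' and every enzyme sums to 1 across species, so each run's starting
#' inoculum carries the same total amount of each enzyme regardless of how
#' enzymes are packaged into species. Requires as many species as enzymes.
#'
#' Three samplers are available. `"stick"` (default) starts from each
#' species' allocation as an independent broken-stick random partition of 1
#' and makes the profiles complementary by Sinkhorn-Knopp alternating
#' row/column normalization to tolerance `tol`; this matches drawing every
#' species' allocation as a random partition of its unit enzyme budget.
#' `"sinkhorn"` applies the same normalization to an i.i.d. Uniform(0,1)
#' matrix (more even profiles); `"birkhoff"` mixes random permutation
#' matrices with broken-stick weights (more specialist-like profiles). All
#' are exchangeable in rows and columns, so every cell has expectation
#' `1/n`.
#'
#' @param n_species Number of species.
#' @param n_enzymes Number of enzymes; must equal `n_species`.
#' @param method Sampler.
#' @param tol Convergence tolerance for the Sinkhorn iteration.
#' @return `n_species` x `n_enzymes` doubly stochastic matrix.
#' @export
random_generalist_allocation <- function(n_species, n_enzymes = n_species,
                                         method = c("stick", "sinkhorn",
                                                    "birkhoff"),
                                         tol = 1e-10) {
  method <- match.arg(method)
  if (n_species != n_enzymes)
    stop("complementary allocation requires n_species == n_enzymes")
  n <- n_species
  if (method %in% c("stick", "sinkhorn")) {
    A <- if (method == "stick")
      t(vapply(seq_len(n), function(i) broken_stick(1, n), numeric(n)))
    else matrix(runif(n * n), n, n)
    for (it in seq_len(10000)) {
      A <- A / rowSums(A)
      A <- t(t(A) / colSums(A))
      if (max(abs(rowSums(A) - 1)) < tol && max(abs(colSums(A) - 1)) < tol)
        break
    }
  } else {
    w <- broken_stick(1, n)
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      P <- diag(n)[sample.int(n), , drop = FALSE]
      A <- A + w[i] * P
    }
  }
  A
}

#' Mean pairwise Euclidean distance between allocation profiles
#'
#' @param A Matrix of species by enzyme allocations (rows are profiles).
#' @return Mean over all unordered pairs of rows; `NA` with fewer than two
#'   rows.
#' @export
mean_pairwise_distance <- function(A) {
  if (is.null(dim(A)) || nrow(A) < 2) return(NA_real_)
  mean(stats::dist(A))
}

#' Parameter-draw configuration for replicate experiments
#'
#' Uniform ranges for the per-substrate kinetic parameters and the dilution
#' rate, following the regime used for the diverse-pathway experiments:
#' `c`, `v`, `K` between 0.13 and 1 and `D` between 0.01 and 0.05, values
#' shared between the arms of a replicate pair.
#'
#' @param c_range,v_range,K_range,D_range Length-2 numeric bounds.
#' @param t_end Run length per replicate (time units).
#' @param a Cost-of-generalism exponent.
#' @param mu Heritable variance used by the evolving arms.
#' @param survival_threshold Density cutoff for survival classification.
#' @param dist_tol Mean pairwise allocation distance below which surviving
#'   evolved species count as effectively identical phenotypes.
#' @param allocation_method Sampler for the generalist arms (see
#'   [random_generalist_allocation()]).
#' @param rtol,atol Solver tolerances.
#' @param n_out Trajectory output points per run.
#' @return List of class `draw_config`.
#' @export
draw_config <- function(c_range = c(0.13, 1), v_range = c(0.13, 1),
                        K_range = c(0.13, 1), D_range = c(0.01, 0.05),
                        t_end = 20000, a = 1, mu = 0.01,
                        survival_threshold = 1e-4, dist_tol = 0.05,
                        allocation_method = "stick",
                        rtol = 1e-8, atol = 1e-10, n_out = 3) {
  chk <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] <= 0)
      stop("`", nm, "` must be positive ordered bounds")
    r
  }
  structure(list(c_range = chk(c_range, "c_range"),
                 v_range = chk(v_range, "v_range"),
                 K_range = chk(K_range, "K_range"),
                 D_range = chk(D_range, "D_range"),
                 t_end = t_end, a = a, mu = mu,
                 survival_threshold = survival_threshold,
                 dist_tol = dist_tol,
                 allocation_method = allocation_method,
                 rtol = rtol, atol = atol, n_out = n_out),
            class = "draw_config")
}

## One replicate's random inputs, drawn from the current RNG state.
.draw_gut_replicate <- function(pathway, config) {
  ns <- length(pathway$metabolized)
  list(c = runif(ns, config$c_range[1], config$c_range[2]),
       v = runif(ns, config$v_range[1], config$v_range[2]),
       K = runif(ns, config$K_range[1], config$K_range[2]),
       D = runif(1, config$D_range[1], config$D_range[2]),
       A_gen = random_generalist_allocation(ns, ns,
                                            method = config$allocation_method))
}

.arm_modes <- c("specialist_eco", "generalist_eco",
                "specialist_evo", "generalist_evo")

## Summary row for one finished arm.
.arm_record <- function(result, pathway, config, A_start) {
  surv <- result$survival
  N <- result$final$N
  A_end <- group_by_substrate(result$final$E, pathway)
  A_end <- A_end / rowSums(A_end)  # guard tiny truncation drift
  if (any(surv)) {
    dist_end <- mean_pairwise_distance(A_end[surv, , drop = FALSE])
    lead_end <- mean(apply(A_end[surv, , drop = FALSE], 1, max))
  } else {
    dist_end <- NA_real_
    lead_end <- NA_real_
  }
  all_survive <- all(surv)
  S <- result$final$S
  data.frame(
    D = result$spec$D,
    survivors = sum(surv),
    all_survive = all_survive,
    dominance_pct = if (any(surv)) 100 * max(N) / sum(N) else NA_real_,
    biomass = sum(N),
    dist_start = mean_pairwise_distance(A_start),
    dist_end = dist_end,
    lead_start = mean(apply(A_start, 1, max)),
    lead_end = lead_end,
    divergent = all_survive && !is.na(dist_end) && dist_end > config$dist_tol,
    converged = result$converged,
    t(stats::setNames(S, paste0("S_", pathway$names)))
  )
}

#' Run one paired specialist/generalist replicate
#'
#' Builds the requested arms of the gut-pathway experiment from a single set
#' of random inputs — kinetic parameters and dilution rate drawn once and
#' shared bitwise across arms — and integrates each to the configured run
#' length. Specialist arms put one species on each metabolized substrate;
#' generalist arms use the replicate's random complementary allocation;
#' `_evo` arms additionally evolve the allocations.
#'
#' @param draw Replicate inputs as produced internally: list with
#'   per-substrate `c`, `v`, `K`, scalar `D`, and a doubly stochastic
#'   substrate-level allocation `A_gen`.
#' @param arms Character subset of `specialist_eco`, `generalist_eco`,
#'   `specialist_evo`, `generalist_evo`.
#' @param config A [draw_config()].
#' @param reactions Optional alternative gut-pathway edge set.
#' @return Named list of one-row data.frames, one per arm (an arm whose
#'   solver fails is returned as `NULL` with a warning).
#' @export
run_paired_replicate <- function(draw, arms = c("specialist_eco",
                                                "generalist_eco"),
                                 config = draw_config(), reactions = NULL) {
  arms <- match.arg(arms, .arm_modes, several.ok = TRUE)
  pw <- gut_pathway(reactions = reactions)
  A_spec <- diag(length(pw$metabolized))
  out <- lapply(arms, function(arm) {
    generalist <- startsWith(arm, "generalist")
    evolve <- endsWith(arm, "evo")
    A0 <- if (generalist) draw$A_gen else A_spec
    spec <- make_preset("gut_11", reactions = reactions,
                        v = draw$v, K = draw$K, c = draw$c, D = draw$D,
                        a = config$a, mu = if (evolve) config$mu else 0,
                        E = expand_substrate_allocation(A0, pw))
    res <- try({
      f <- if (evolve) simulate_evolution else simulate_community
      f(spec, t_end = config$t_end, n_out = config$n_out,
        rtol = config$rtol, atol = config$atol,
        survival_threshold = config$survival_threshold)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning("solver failure in arm ", arm, ": ",
              attr(res, "condition")$message)
      return(NULL)
    }
    cbind(arm = arm, .arm_record(res, pw, config, A0))
  })
  stats::setNames(out, arms)
}

#' Run the paired gut-pathway experiment
#'
#' The replication harness for the 8-species, 11-substrate fermentation
#' pathway: for each replicate, kinetic parameters and the dilution rate are
#' drawn once and reused across all requested arms, the generalist arms get a
#' fresh random complementary allocation, and every arm is integrated to the
#' configured run length. A base seed spawns one child seed per replicate so
#' the whole experiment is reproducible and individual replicates can be
#' re-run in isolation.
#'
#' @param reps Number of replicates.
#' @param seed Base seed.
#' @param arms Arms to run (see [run_paired_replicate()]).
#' @param config A [draw_config()].
#' @param reactions Optional alternative gut-pathway edge set.
#' @param progress Print a dot every 10 replicates.
#' @return `experiment_records`: a data.frame with one row per replicate and
#'   arm, carrying survival, dominance, biomass, allocation-distance and
#'   steady-state concentration summaries; the configuration is attached as
#'   attributes.
#' @examples
#' \donttest{
#' rec <- run_gut_experiment(reps = 5, seed = 1)
#' summarize_experiment(rec)
#' }
#' @export
run_gut_experiment <- function(reps, seed = 1,
                               arms = c("specialist_eco", "generalist_eco"),
                               config = draw_config(), reactions = NULL,
                               progress = FALSE) {
  stopifnot(reps >= 1)
  arms <- match.arg(arms, .arm_modes, several.ok = TRUE)
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, reps)
  pw <- gut_pathway(reactions = reactions)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    set.seed(child[r])
    draw <- .draw_gut_replicate(pw, config)
    recs <- run_paired_replicate(draw, arms, config, reactions)
    ok <- !vapply(recs, is.null, logical(1))
    if (any(ok))
      rows[[r]] <- cbind(rep = r, seed = child[r],
                         do.call(rbind, recs[ok]))
    if (progress && r %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "arms") <- arms
  class(out) <- c("experiment_records", "data.frame")
  out
}

#' Aggregate replicate statistics
#'
#' Per-arm means and spreads of survival, dominance, biomass and allocation
#' structure, plus the paired contrasts between arms that share each
#' replicate's kinetic draws: the generalist-versus-specialist biomass
#' advantage, shifts of survivors' allocation distance and leading-enzyme
#' allocation relative to the starting species, and the evolving-arm counts
#' of full survival and functional divergence.
#'
#' @param records An `experiment_records` data.frame from
#'   [run_gut_experiment()].
#' @return List of class `experiment_summary` with elements `n_reps`,
#'   `per_arm` (data.frame) and `paired` (list).
#' @export
summarize_experiment <- function(records) {
  if (!nrow(records)) stop("no replicate records to summarize")
  arms <- unique(records$arm)
  per_arm <- do.call(rbind, lapply(arms, function(a) {
    d <- records[records$arm == a, ]
    data.frame(arm = a, n = nrow(d),
               all_survive = sum(d$all_survive),
               mean_survivors = mean(d$survivors),
               sd_survivors = sd(d$survivors),
               mean_dominance_pct = mean(d$dominance_pct, na.rm = TRUE),
               sd_dominance_pct = sd(d$dominance_pct, na.rm = TRUE),
               mean_biomass = mean(d$biomass),
               mean_dist_end = mean(d$dist_end, na.rm = TRUE),
               sd_dist_end = sd(d$dist_end, na.rm = TRUE),
               divergent = sum(d$divergent))
  }))
  wide <- function(col) {
    sapply(arms, function(a) {
      d <- records[records$arm == a, ]
      stats::setNames(d[[col]], d$rep)[as.character(sort(unique(records$rep)))]
    })
  }
  paired <- list()
  if (all(c("specialist_eco", "generalist_eco") %in% arms)) {
    B <- wide("biomass")
    pct <- 100 * (B[, "generalist_eco"] - B[, "specialist_eco"]) /
      B[, "specialist_eco"]
    paired$biomass_pct_gen_vs_spec <- mean(pct, na.rm = TRUE)
    paired$biomass_higher_gen <- sum(B[, "generalist_eco"] >
                                       B[, "specialist_eco"], na.rm = TRUE)
    Scols <- grep("^S_", names(records), value = TRUE)
    gm <- colMeans(records[records$arm == "generalist_eco", Scols])
    sm <- colMeans(records[records$arm == "specialist_eco", Scols])
    paired$mean_S_gen_minus_spec <- gm - sm
  }
  g <- records[records$arm == "generalist_eco", ]
  if (nrow(g)) {
    paired$dist_higher_than_start <- sum(g$dist_end > g$dist_start,
                                         na.rm = TRUE)
    paired$dist_pct_vs_start <- mean(100 * (g$dist_end - g$dist_start) /
                                       g$dist_start, na.rm = TRUE)
    paired$lead_higher_than_start <- sum(g$lead_end > g$lead_start,
                                         na.rm = TRUE)
    paired$lead_pct_vs_start <- mean(100 * (g$lead_end - g$lead_start) /
                                       g$lead_start, na.rm = TRUE)
  }
  ev <- records[records$arm == "generalist_evo", ]
  if (nrow(ev)) {
    paired$evo_all_survive <- sum(ev$all_survive)
    paired$evo_divergent <- sum(ev$divergent)
    paired$evo_mean_dist_divergent <- mean(ev$dist_end[ev$divergent],
                                           na.rm = TRUE)
  }
  structure(list(n_reps = length(unique(records$rep)),
                 per_arm = per_arm, paired = paired),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat("Paired gut-pathway experiment,", x$n_reps, "replicates\n")
  print(x$per_arm, row.names = FALSE, digits = 3)
  p <- x$paired
  if (!is.null(p$biomass_pct_gen_vs_spec))
    cat(sprintf("  biomass: generalist > specialist in %d/%d pairs, %+.1f%% on average\n",
                p$biomass_higher_gen, x$n_reps, p$biomass_pct_gen_vs_spec))
  if (!is.null(p$evo_all_survive))
    cat(sprintf("  evolving generalists: all survive in %d/%d, functionally divergent in %d/%d (mean distance %.3f)\n",
                p$evo_all_survive, x$n_reps, p$evo_divergent, x$n_reps,
                p$evo_mean_dist_divergent))
  invisible(x)
}
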