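.config_defaults <- function() {
  list(preset = "gut_11", mode = "simulate", seed = 1L, reps = 100L,
       arms = c("specialist_eco", "generalist_eco"),
       a = 1, mu = 0.01, t_end = 2000, D = NULL, Q = NULL,
       growth_law = NULL, survival_threshold = 1e-4, dist_tol = 0.05,
       rtol = 1e-8, atol = 1e-10, n_out = 201,
       allocation_method = "sinkhorn", reactions = NULL, out = ".")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys, validates values against
#' the model invariants and fills every unstated option with the package
#' default, so the returned object is a complete, auditable record of the run
#' (the "effective configuration"): serializing it with [write_results()] and
#' reloading reproduces the same object.
#'
#' @param path Path to a YAML file, or a list already in memory.
#' @return List of class `run_config` with every option populated.
#' @export
load_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- .config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, raw)
  if (!cfg$preset %in% c("two_input", "input_derived", "linear_chain_4",
                         "gut_11"))
    stop("unknown preset: ", cfg$preset)
  if (!cfg$mode %in% c("simulate", "evolve", "experiment"))
    stop("unknown mode: ", cfg$mode)
  if (!is.null(cfg$D) && cfg$D <= 0) stop("dilution rate D must be positive")
  if (cfg$a < 1) stop("cost-of-generalism exponent `a` must be >= 1")
  if (cfg$mu < 0) stop("mu must be nonnegative")
  if (cfg$t_end < 0) stop("t_end must be nonnegative")
  if (cfg$reps < 1) stop("reps must be at least 1")
  bad <- setdiff(cfg$arms, .arm_modes)
  if (length(bad)) stop("unknown arm(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$reactions)) {
    cfg$reactions <- do.call(rbind, lapply(cfg$reactions, function(r) {
      if (length(r) != 2) stop("each reaction must be a (source, target) pair")
      unlist(r)
    }))
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$reps <- as.integer(cfg$reps)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Effective run configuration:\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  for (k in names(flat))
    cat(sprintf("  %s: %s\n", k,
                paste(format(flat[[k]]), collapse = ", ")))
  invisible(x)
}

#' Write run outputs to a directory
#'
#' Serializes a simulation or experiment result as tidy CSV plus JSON
#' aggregates, together with a manifest recording the effective
#' configuration, its hash, the seed and the package version. File contents
#' are deterministic given identical runs.
#'
#' @param x A `simulation_result`, `experiment_records` data.frame, or
#'   `experiment_summary`.
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` to record alongside the results.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(x, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (inherits(x, "simulation_result")) {
    f <- file.path(dir, "trajectory.csv")
    write.csv(as.data.frame(x), f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "final_state.json")
    jsonlite::write_json(list(t = x$final$t, S = as.list(x$final$S),
                              N = as.list(x$final$N),
                              survival = as.list(x$survival),
                              converged = x$converged),
                         f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f)
  } else if (inherits(x, "experiment_records")) {
    f <- file.path(dir, "replicates.csv")
    write.csv(as.data.frame(x), f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "summary.json")
    s <- summarize_experiment(x)
    jsonlite::write_json(list(n_reps = s$n_reps, per_arm = s$per_arm,
                              paired = s$paired),
                         f, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    files <- c(files, f)
  } else if (inherits(x, "experiment_summary")) {
    f <- file.path(dir, "summary.json")
    jsonlite::write_json(list(n_reps = x$n_reps, per_arm = x$per_arm,
                              paired = x$paired),
                         f, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    files <- c(files, f)
  } else stop("unsupported result type")

  cfg_file <- file.path(dir, "config.yaml")
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                     cfg_file)
    files <- c(files, cfg_file)
  }
  manifest <- list(
    package = "chemevo",
    version = as.character(utils::packageVersion("chemevo")),
    seed = if (!is.null(config)) config$seed else NA,
    config_hash = if (!is.null(config))
      unname(tools::md5sum(cfg_file)) else NA,
    files = basename(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
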