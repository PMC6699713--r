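#' Define a catabolic pathway
#'
#' A pathway is a set of `m` substrates connected by directed reactions, each
#' converting one substrate into one downstream substrate (1:1 stoichiometry).
#' Catabolism is unidirectional: under the substrate ordering every reaction
#' must point "down" the pathway (source index < target index). Substrates
#' with no outgoing reaction are terminal (unmetabolized waste or end
#' products).
#'
#' @param names Character vector of substrate labels (defines the ordering).
#' @param reactions Two-column matrix or data.frame of reactions; entries are
#'   substrate labels or integer indices, first column the source substrate,
#'   second the target.
#' @param Q Numeric vector of inflow concentrations, one per substrate
#'   (abstract concentration units). Must be nonnegative with at least one
#'   positive entry, and every substrate absent from the inflow must be
#'   reachable from an inflow substrate through the reaction list.
#'
#' @return An object of class `pathway_spec`: a list with elements `m`,
#'   `names`, `src`, `dst` (integer reaction endpoints), `n_reactions`, `Q`,
#'   `metabolized` (indices of substrates with outgoing reactions),
#'   `terminal`, and `enzyme_group` (for each reaction, the position of its
#'   source substrate within `metabolized`; reactions sharing a source share
#'   an enzyme group).
#' @examples
#' pw <- pathway_spec(c("S1", "S2", "W"),
#'                    rbind(c("S1", "W"), c("S2", "W")),
#'                    Q = c(5, 5, 0))
#' pw$terminal
#' @export
pathway_spec <- function(names, reactions, Q) {
  stopifnot(is.character(names), length(names) >= 2, !anyDuplicated(names))
  m <- length(names)
  reactions <- as.matrix(reactions)
  if (ncol(reactions) != 2L)
    stop("`reactions` must have two columns (source, target)")
  to_idx <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    i <- match(x, names)
    if (anyNA(i)) stop("unknown substrate label(s): ",
                       paste(unique(x[is.na(i)]), collapse = ", "))
    i
  }
  src <- to_idx(reactions[, 1])
  dst <- to_idx(reactions[, 2])
  if (any(src < 1 | src > m | dst < 1 | dst > m))
    stop("reaction endpoints out of range")
  bad <- which(src >= dst)
  if (length(bad))
    stop("catabolism must be unidirectional (source index < target index); ",
         "offending reaction(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(cbind(src, dst)))
    stop("duplicated reactions")
  Q <- as.numeric(Q)
  if (length(Q) != m) stop("`Q` must have one entry per substrate")
  if (any(Q < 0)) stop("inflow concentrations Q must be nonnegative")
  if (all(Q == 0)) stop("at least one substrate must have Q > 0")

  ## every substrate without inflow must be producible from an inflow substrate
  reach <- Q > 0
  repeat {
    new <- reach[src] & !reach[dst]
    if (!any(new)) break
    reach[dst[new]] <- TRUE
  }
  if (!all(reach))
    stop("substrate(s) unreachable from any inflow substrate: ",
         paste(names[!reach], collapse = ", "))

  metabolized <- sort(unique(src))
  terminal <- setdiff(seq_len(m), metabolized)
  structure(list(
    m = m, names = names, src = src, dst = dst,
    n_reactions = length(src), Q = Q,
    metabolized = metabolized, terminal = terminal,
    enzyme_group = match(src, metabolized)
  ), class = "pathway_spec")
}

#' @export
print.pathway_spec <- function(x, ...) {
  cat("Catabolic pathway:", x$m, "substrates,", x$n_reactions, "reactions\n")
  cat("  inflow: ",
      paste(sprintf("%s=%g", x$names[x$Q > 0], x$Q[x$Q > 0]), collapse = ", "),
      "\n", sep = "")
  cat("  reactions: ",
      paste(sprintf("%s->%s", x$names[x$src], x$names[x$dst]), collapse = ", "),
      "\n", sep = "")
  cat("  terminal: ", paste(x$names[x$terminal], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reaction labels of a pathway
#'
#' @param pathway A [pathway_spec()].
#' @return Character vector `"source->target"` per reaction.
#' @export
reaction_labels <- function(pathway) {
  paste0(pathway$names[pathway$src], "->", pathway$names[pathway$dst])
}

#' Group per-reaction quantities by source substrate
#'
#' Collapses a per-reaction allocation (or any per-reaction quantity) to the
#' "one enzyme per metabolized substrate" view by summing over each
#' substrate's outgoing reactions.
#'
#' @param E Matrix of species-by-reaction values (rows = species), or a
#'   vector for a single species.
#' @param pathway A [pathway_spec()].
#' @return Matrix of species by metabolized substrate, columns named by
#'   substrate label.
#' @export
group_by_substrate <- function(E, pathway) {
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  if (ncol(E) != pathway$n_reactions)
    stop("`E` must have one column per reaction")
  out <- t(rowsum(t(E), group = pathway$enzyme_group))
  colnames(out) <- pathway$names[pathway$metabolized]
  out
}

#' Expand substrate-level allocations to per-reaction allocations
#'
#' Inverse of [group_by_substrate()] under the equal-branch-split convention:
#' a species' allocation to a metabolized substrate is divided equally among
#' that substrate's outgoing reactions.
#'
#' @param A Matrix of species by metabolized substrate (rows sum to 1), or a
#'   vector for a single species.
#' @inheritParams group_by_substrate
#' @return Matrix of species by reaction.
#' @export
expand_substrate_allocation <- function(A, pathway) {
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  ns <- length(pathway$metabolized)
  if (ncol(A) != ns)
    stop("`A` must have one column per metabolized substrate (", ns, ")")
  n_branch <- tabulate(pathway$enzyme_group, nbins = ns)
  E <- A[, pathway$enzyme_group, drop = FALSE] /
    rep(n_branch[pathway$enzyme_group], each = nrow(A))
  colnames(E) <- reaction_labels(pathway)
  E
}
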