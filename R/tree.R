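#' Read a rooted species tree from newick
#'
#' Parses a newick string or file into an \code{ape} \code{phylo} object and
#' validates the invariants every downstream covariance kernel relies on:
#' the tree is rooted, all branch lengths are present and strictly positive,
#' and tip labels are unique. Branch lengths are interpreted as millions of
#' years (My) throughout the package, so the OU selection strength
#' \code{alpha} has units 1/My.
#'
#' @param newick A newick string, or the path to a file containing one.
#' @return A \code{phylo} object (class as used by \pkg{ape}).
#' @seealso [write_species_tree()], [example_species_tree()]
#' @export
read_species_tree <- function(newick) {
  stopifnot(is.character(newick), length(newick) == 1L)
  tr <- tryCatch({
    if (file.exists(newick) && !grepl("\\(", newick))
      ape::read.tree(file = newick)
    else ape::read.tree(text = newick)
  }, error = function(e) stop("malformed newick: ", conditionMessage(e)),
     warning = function(w) stop("malformed newick: ", conditionMessage(w)))
  if (is.null(tr)) stop("malformed newick: could not parse input")
  validate_species_tree(tr)
  tr
}

#' Write a species tree to newick
#'
#' @param tree A \code{phylo} object.
#' @param file Optional path; if \code{NULL} the newick string is returned.
#' @param validate Check the species-tree invariants first (default TRUE;
#'   set FALSE for derived trees such as NJ expression trees, which may
#'   carry zero-length branches).
#' @return The newick string, invisibly when written to a file.
#' @export
write_species_tree <- function(tree, file = NULL, validate = TRUE) {
  if (validate) validate_species_tree(tree) else stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Validate a species tree
#'
#' Checks rootedness, positive branch lengths and unique tip labels; records
#' whether the tree is ultrametric (within numerical tolerance) in the
#' \code{"ultrametric"} attribute.
#'
#' @param tree A \code{phylo} object.
#' @return The tree, invisibly, with the \code{"ultrametric"} attribute set.
#' @export
validate_species_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("all branches must carry a length")
  if (any(tree$edge.length <= 0)) stop("all branch lengths must be > 0")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  attr(tree, "ultrametric") <- ape::is.ultrametric(tree, tol = 1e-6)
  invisible(tree)
}

#' The packaged six-species Drosophila tree
#'
#' A rooted ultrametric phylogeny for the six species analysed throughout the
#' package documentation: D. melanogaster, D. simulans, D. sechellia,
#' D. santomea, D. erecta and D. suzukii. Node ages (in My) are calibrated
#' within the 0.25--15 My range spanned by these species: sim/sec split at
#' 0.25, melanogaster vs (sim,sec) at 3, san/ere at 6, the subgroup crown at
#' 10 and the suzukii split at 15.
#'
#' @return A \code{phylo} object with 6 tips; total depth 15 My.
#' @export
example_species_tree <- function() {
  read_species_tree(system.file("extdata", "species_tree.nwk",
                                package = "exprevol", mustWork = TRUE))
}

## ---- edge bookkeeping -------------------------------------------------

#' Label tree edges by their child node
#'
#' Every edge of a rooted tree is identified by the node it leads to: tip
#' edges get the tip label, internal edges a label \code{"n<node>"} (or the
#' node label when present). These labels index regimes, shift
#' configurations and change events.
#'
#' @param tree A \code{phylo} object.
#' @return Character vector, one label per row of \code{tree$edge}.
#' @export
edge_labels <- function(tree) {
  child <- tree$edge[, 2L]
  ntip <- length(tree$tip.label)
  lab <- character(nrow(tree$edge))
  is_tip <- child <= ntip
  lab[is_tip] <- tree$tip.label[child[is_tip]]
  inner <- child[!is_tip]
  if (!is.null(tree$node.label) &&
      all(nzchar(tree$node.label[inner - ntip]))) {
    lab[!is_tip] <- tree$node.label[inner - ntip]
  } else {
    lab[!is_tip] <- paste0("n", inner)
  }
  lab
}

# row index in tree$edge of the parent edge of each edge (0 for root edges)
parent_edge_index <- function(tree) {
  match(tree$edge[, 1L], tree$edge[, 2L], nomatch = 0L)
}

# list (per tip, in tip.label order) of edge row indices on the root-to-tip
# path, ordered root-first; plus node times needed for OU mean propagation
root_to_tip_paths <- function(tree) {
  parent <- parent_edge_index(tree)
  ntip <- length(tree$tip.label)
  lapply(seq_len(ntip), function(tip) {
    e <- match(tip, tree$edge[, 2L])
    path <- integer(0)
    while (!is.na(e) && e != 0L) {
      path <- c(e, path)
      e <- parent[e]
    }
    path
  })
}

## ---- covariance kernels -----------------------------------------------

#' Brownian-motion tip covariance
#'
#' Under BM with drift variance rate \code{sigma2}, the covariance of two
#' tips equals \code{sigma2} times the shared path length from the root to
#' their most recent common ancestor.
#'
#' @param tree A \code{phylo} object.
#' @param sigma2 Drift variance rate (expression units squared per My), > 0.
#' @return A symmetric positive semi-definite matrix, tips in
#'   \code{tree$tip.label} order.
#' @export
bm_covariance <- function(tree, sigma2 = 1) {
  validate_species_tree(tree)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
    stop("sigma2 must be a positive scalar")
  v <- ape::vcv(tree)
  sigma2 * v[tree$tip.label, tree$tip.label]
}

#' OU parameter container
#'
#' @param alpha Selection strength towards the optimum (1/My), >= 0; 0
#'   degenerates to BM.
#' @param sigma2 Drift variance rate (expression units squared per My), > 0.
#' @param sigma2_e Within-species replicate variance (expression units
#'   squared), >= 0.
#' @return An object of class \code{ou_params}.
#' @export
ou_params <- function(alpha, sigma2, sigma2_e = 0) {
  stopifnot(is.finite(alpha), is.finite(sigma2), is.finite(sigma2_e))
  if (alpha < 0) stop("alpha must be >= 0")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (sigma2_e < 0) stop("sigma2_e must be >= 0")
  structure(list(alpha = alpha, sigma2 = sigma2, sigma2_e = sigma2_e),
            class = "ou_params")
}

#' OU tip covariance (stationary or fixed-root)
#'
#' The stationary kernel (default, used throughout the pipeline) draws the
#' root state from the stationary distribution: tip variance is
#' \code{sigma2 / (2 alpha)} and covariance decays as \code{exp(-alpha d)}
#' with patristic distance d. The fixed-root kernel conditions on the root
#' state: \code{Cov(i,j) = sigma2/(2 alpha) exp(-alpha d_ij)
#' (1 - exp(-2 alpha t_ij))} with \code{t_ij} the shared root-to-MRCA time.
#' Only the fixed-root kernel converges to the BM covariance as
#' \code{alpha -> 0}; the stationary kernel's root variance diverges in
#' that limit.
#'
#' @param tree A \code{phylo} object.
#' @param params An [ou_params()] object with \code{alpha > 0}.
#' @param stationary Use the stationary-root kernel (default TRUE).
#' @return A symmetric positive definite matrix, tips in tip-label order.
#' @export
ou_covariance <- function(tree, params, stationary = TRUE) {
  validate_species_tree(tree)
  if (!inherits(params, "ou_params")) stop("params must be ou_params")
  if (params$alpha <= 0)
    stop("alpha must be > 0 for the OU kernel; use bm_covariance for alpha = 0")
  d <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  v <- (params$sigma2 / (2 * params$alpha)) * exp(-params$alpha * d)
  if (!stationary) {
    tshared <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
    v <- v * (1 - exp(-2 * params$alpha * tshared))
  }
  v
}

#' Replicate-level covariance
#'
#' Expands a species-level covariance to replicate observations: replicates
#' of one species share the species covariance, and the replicate variance
#' \code{sigma2_e} is added to the diagonal only.
#'
#' @param species_cov Species-level covariance matrix (named).
#' @param species Character vector assigning each observation to a species.
#' @param sigma2_e Within-species replicate variance, >= 0.
#' @return Covariance matrix over observations.
#' @export
replicate_covariance <- function(species_cov, species, sigma2_e = 0) {
  idx <- match(species, rownames(species_cov))
  if (anyNA(idx)) stop("unknown species in 'species'")
  v <- species_cov[idx, idx, drop = FALSE]
  diag(v) <- diag(v) + sigma2_e
  dimnames(v) <- list(species, species)
  v
}

## ---- regimes -----------------------------------------------------------

#' Optimum regime on a tree
#'
#' A regime assigns every edge an optimum index (1-based); the root lineage
#' carries optimum 1. Shift edges are those whose index differs from their
#' parent edge's index; the number of distinct optima equals the number of
#' shift edges plus one.
#'
#' @param tree A \code{phylo} object.
#' @param edge_optimum Integer vector, one optimum index per row of
#'   \code{tree$edge}.
#' @param optima Numeric vector of optimum values (expression units,
#'   typically log2(TPM+1)); may be \code{NA} when the regime only encodes
#'   structure for fitting.
#' @return An object of class \code{regime}.
#' @seealso [regime_from_shifts()]
#' @export
regime <- function(tree, edge_optimum, optima = rep(NA_real_, max(edge_optimum))) {
  validate_species_tree(tree)
  edge_optimum <- as.integer(edge_optimum)
  if (length(edge_optimum) != nrow(tree$edge))
    stop("edge_optimum must have one entry per edge")
  if (any(edge_optimum < 1L)) stop("optimum indices are 1-based positive")
  if (length(optima) < max(edge_optimum))
    stop("optima shorter than the largest optimum index")
  parent <- parent_edge_index(tree)
  parent_opt <- edge_optimum[pmax(parent, 1L)]
  parent_opt[parent == 0L] <- 1L   # root lineage carries optimum 1
  shift_edges <- which(edge_optimum != parent_opt)
  # optimum 1 (ancestral) always exists even when every root-adjacent edge
  # shifts away from it: it parameterises the root state distribution
  opt_ids <- sort(unique(c(1L, edge_optimum)))
  if (!identical(opt_ids, seq_len(length(shift_edges) + 1L)))
    stop("regime invariant violated: distinct optima must equal shifts + 1")
  structure(list(tree = tree, edge_optimum = edge_optimum,
                 optima = as.numeric(optima), shift_edges = shift_edges,
                 edge_label = edge_labels(tree)),
            class = "regime")
}

#' Build a regime from a set of shift edges
#'
#' Each shift edge starts a new optimum that is inherited by its whole
#' subtree until overridden by a deeper shift. Shift edges are numbered in
#' tree preorder, so optimum 1 is the ancestral regime and optimum k+1
#' belongs to the k-th shift.
#'
#' @param tree A \code{phylo} object.
#' @param shift_edges Integer edge row indices (rows of \code{tree$edge}),
#'   possibly empty.
#' @param optima Optional optimum values of length \code{length(shift_edges) + 1}.
#' @return A [regime()] object.
#' @export
regime_from_shifts <- function(tree, shift_edges = integer(0), optima = NULL) {
  validate_species_tree(tree)
  shift_edges <- sort(unique(as.integer(shift_edges)))
  if (length(shift_edges) && (min(shift_edges) < 1L ||
                              max(shift_edges) > nrow(tree$edge)))
    stop("shift edge index out of range")
  parent <- parent_edge_index(tree)
  # preorder over edges: parents appear before children
  ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 1L]])
  edge_optimum <- integer(nrow(tree$edge))
  next_idx <- 1L
  shift_idx <- integer(nrow(tree$edge))
  for (e in ord) {
    base <- if (parent[e] == 0L) 1L else edge_optimum[parent[e]]
    if (e %in% shift_edges) {
      next_idx <- next_idx + 1L
      edge_optimum[e] <- next_idx
    } else {
      edge_optimum[e] <- base
    }
  }
  # renumber so indices are dense 1..k (they already are by construction)
  if (is.null(optima)) optima <- rep(NA_real_, length(shift_edges) + 1L)
  if (length(optima) != length(shift_edges) + 1L)
    stop("optima must have length shifts + 1")
  regime(tree, edge_optimum, optima)
}

#' Expected tip values under a multi-optimum OU model
#'
#' Propagates the OU mean along each root-to-tip path: with the root drawn
#' from the stationary distribution around the ancestral optimum, the
#' expected tip value is a convex combination of the regime optima with
#' weights determined by \code{alpha} and the times spent in each regime.
#'
#' @param reg A [regime()] object with optimum values set.
#' @param alpha Selection strength (1/My), > 0.
#' @return Named numeric vector of expected values, one per tip.
#' @export
ou_tip_means <- function(reg, alpha) {
  w <- oum_design(reg$tree, reg, alpha)
  drop(w %*% reg$optima[seq_len(ncol(w))])
}

#' Visibility of an optimum shift per branch
#'
#' Under an OU process with selection strength \code{alpha}, an optimum
#' shift on an edge displaces a descendant tip by
#' \code{exp(-alpha d) (1 - exp(-alpha len))} times the optimum change,
#' where \code{len} is the edge length and \code{d} the time from the edge
#' end to the tip: shifts on branches that end long before any tip revert
#' toward the ancestral optimum and become statistically invisible. This
#' returns, per edge, the maximum displacement fraction over descendant
#' tips.
#'
#' @param tree A \code{phylo} object.
#' @param alpha Selection strength (1/My), > 0.
#' @return Named numeric vector in (0, 1], one entry per edge (names from
#'   [edge_labels()]).
#' @export
edge_visibility <- function(tree, alpha) {
  validate_species_tree(tree)
  stopifnot(alpha > 0)
  depth <- ape::node.depth.edgelength(tree)
  paths <- root_to_tip_paths(tree)
  vis <- stats::setNames(rep(0, nrow(tree$edge)), edge_labels(tree))
  for (tip in seq_along(paths)) {
    for (e in paths[[tip]]) {
      t0 <- depth[tree$edge[e, 1L]]; t1 <- depth[tree$edge[e, 2L]]
      w <- exp(-alpha * (depth[tip] - t1)) * (1 - exp(-alpha * (t1 - t0)))
      vis[e] <- max(vis[e], w)
    }
  }
  vis
}

# tips x optima weight matrix; rows sum to 1
oum_design <- function(tree, reg, alpha) {
  stopifnot(alpha > 0)
  paths <- root_to_tip_paths(tree)
  depth <- ape::node.depth.edgelength(tree)
  k <- max(reg$edge_optimum)
  w <- matrix(0, length(tree$tip.label), k,
              dimnames = list(tree$tip.label, NULL))
  for (tip in seq_along(paths)) {
    total <- depth[tip]
    w[tip, 1L] <- exp(-alpha * total)
    for (e in paths[[tip]]) {
      t0 <- depth[tree$edge[e, 1L]]
      t1 <- depth[tree$edge[e, 2L]]
      w[tip, reg$edge_optimum[e]] <- w[tip, reg$edge_optimum[e]] +
        exp(-alpha * (total - t1)) - exp(-alpha * (total - t0))
    }
  }
  w
}
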