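## Expression specificity (tau), expression calls, gain/loss parsimony and
## group comparisons.

#' Tau expression-specificity index
#'
#' tau = sum_i (1 - x_hat_i) / (n - 1) with x_hat_i = x_i / max(x); 0 for a
#' gene expressed uniformly across entities, 1 for expression restricted to
#' a single entity. Values are log1p-transformed first by default (the
#' transform sharpens specificity estimates for skewed expression data).
#'
#' @param x Non-negative expression vector over n >= 2 entities (tissues or
#'   cell clusters).
#' @param log_transform Apply log1p before the formula (default TRUE).
#' @return tau in [0, 1]; \code{NA} with a \code{"not_expressed"} attribute
#'   for an all-zero vector.
#' @export
tau <- function(x, log_transform = TRUE) {
  if (length(x) < 2) stop("tau needs at least 2 entities")
  if (any(x < 0)) stop("expression must be non-negative")
  if (max(x) == 0) {
    out <- NA_real_
    attr(out, "not_expressed") <- TRUE
    return(out)
  }
  if (log_transform) x <- log1p(x)
  xhat <- x / max(x)
  sum(1 - xhat) / (length(x) - 1)
}

#' Tau over cell clusters of an atlas
#'
#' @param atlas An [atlas_summary()].
#' @param gene Gene identifier present in the atlas.
#' @param variant \code{"mean"} uses per-cluster mean expression,
#'   \code{"fraction"} the fraction of cells expressing the gene (both give
#'   very similar distributions on real atlases).
#' @param log_transform Passed to [tau()].
#' @return tau in [0, 1].
#' @export
cell_tau <- function(atlas, gene, variant = c("mean", "fraction"),
                     log_transform = TRUE) {
  stopifnot(inherits(atlas, "atlas_summary"))
  variant <- match.arg(variant)
  if (!gene %in% atlas$genes) stop("gene ", gene, " absent from atlas")
  x <- if (variant == "mean") atlas$mean_expression[, gene]
       else atlas$fraction_expressing[, gene]
  tau(x, log_transform = log_transform)
}

#' Expression call from mean TPM
#'
#' Mean TPM above 3 calls a gene expressed, below 0.5 unexpressed; the
#' interval in between is an ambiguous dead zone excluded from gain/loss
#' analysis.
#'
#' @param mean_tpm Non-negative mean TPM value(s).
#' @param expressed_min TPM threshold for "expressed" (default 3).
#' @param unexpressed_max TPM threshold for "unexpressed" (default 0.5).
#' @return Character vector: \code{"expressed"}, \code{"unexpressed"} or
#'   \code{"ambiguous"}.
#' @export
expression_call <- function(mean_tpm, expressed_min = 3,
                            unexpressed_max = 0.5) {
  if (any(mean_tpm < 0)) stop("TPM must be non-negative")
  ifelse(mean_tpm > expressed_min, "expressed",
         ifelse(mean_tpm < unexpressed_max, "unexpressed", "ambiguous"))
}

## ---- Fitch parsimony gain/loss ----------------------------------------

# exhaustive minimum-change reconstructions of a binary character on a
# rooted tree; tips with NA states are pruned by the caller.
enumerate_reconstructions <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- match(tip_states[tree$tip.label], c("unexpressed", "expressed")) - 1L
  if (anyNA(states)) stop("tip states must be expressed/unexpressed")
  combos <- as.matrix(expand.grid(rep(list(0:1), nnode)))
  changes <- apply(combos, 1, function(internal) {
    full <- c(states, internal)
    sum(full[tree$edge[, 1L]] != full[tree$edge[, 2L]])
  })
  best <- min(changes)
  list(min_changes = best,
       labelings = combos[changes == best, , drop = FALSE],
       tip_states = states)
}

#' Gain/loss assignment of expression on the species tree
#'
#' Maps binary expressed/unexpressed calls to branches by parsimony:
#' the minimum number of state changes (Fitch score) is computed, and every
#' most-parsimonious reconstruction is enumerated on the (small) tree.
#' Branches that change state in all reconstructions are reported as
#' definite gains/losses; branches changing in only some are unresolved.
#' Species with ambiguous calls are pruned before reconstruction.
#'
#' @param calls Named character vector of calls per species
#'   (\code{"expressed"} / \code{"unexpressed"} / \code{"ambiguous"}).
#' @param tree Species tree.
#' @return List with \code{min_changes}, \code{events} (data.frame edge,
#'   type = gain/loss, status = definite/unresolved), \code{n_used}
#'   species; or \code{verdict = "no_call"} when fewer than 2 species are
#'   unambiguous.
#' @export
gain_loss <- function(calls, tree) {
  validate_species_tree(tree)
  use <- names(calls)[calls %in% c("expressed", "unexpressed")]
  if (length(use) < 2)
    return(list(verdict = "no_call",
                reason = "fewer than 2 unambiguous species"))
  sub <- if (length(use) < length(tree$tip.label))
    ape::keep.tip(tree, use) else tree
  rec <- enumerate_reconstructions(sub, calls[use])
  if (rec$min_changes == 0)
    return(list(min_changes = 0L,
                events = data.frame(edge = character(0), type = character(0),
                                    status = character(0)),
                n_used = length(use)))
  elab <- edge_labels(sub)
  ntip <- length(sub$tip.label)
  per_edge <- matrix(0L, nrow(rec$labelings), nrow(sub$edge))
  for (i in seq_len(nrow(rec$labelings))) {
    full <- c(rec$tip_states, rec$labelings[i, ])
    per_edge[i, ] <- ifelse(full[sub$edge[, 2L]] > full[sub$edge[, 1L]], 1L,
                            ifelse(full[sub$edge[, 2L]] < full[sub$edge[, 1L]],
                                   -1L, 0L))
  }
  any_change <- apply(per_edge != 0L, 2, any)
  all_same <- apply(per_edge, 2, function(col)
    all(col == col[1]) && col[1] != 0L)
  events <- do.call(rbind, lapply(which(any_change), function(e) {
    vals <- per_edge[, e]
    data.frame(edge = elab[e],
               type = if (all_same[e]) {
                 if (vals[1] > 0) "gain" else "loss"
               } else if (all(vals[vals != 0] > 0)) "gain"
               else if (all(vals[vals != 0] < 0)) "loss" else "gain_or_loss",
               status = if (all_same[e]) "definite" else "unresolved",
               stringsAsFactors = FALSE)
  }))
  rownames(events) <- NULL
  list(min_changes = rec$min_changes, events = events, n_used = length(use))
}

#' Compare specificity (or any score) between two gene groups
#'
#' Two-sample Wilcoxon rank-sum test with the direction of the effect.
#'
#' @param group_a,group_b Numeric vectors (e.g. tau values).
#' @param alternative Passed to [stats::wilcox.test()] (default
#'   \code{"two.sided"}).
#' @return List with \code{p}, \code{statistic}, \code{direction}
#'   (\code{"A_higher"}, \code{"B_higher"} or \code{"none"}),
#'   \code{median_a}, \code{median_b}.
#' @export
compare_specificity <- function(group_a, group_b,
                                alternative = "two.sided") {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  if (length(unique(c(group_a, group_b))) == 1L)
    return(list(p = 1, statistic = NA_real_, direction = "none",
                median_a = stats::median(group_a),
                median_b = stats::median(group_b)))
  wt <- stats::wilcox.test(group_a, group_b, alternative = alternative,
                           exact = length(group_a) < 50 &&
                             length(group_b) < 50)
  ma <- stats::median(group_a); mb <- stats::median(group_b)
  list(p = wt$p.value, statistic = unname(wt$statistic),
       direction = if (ma > mb) "A_higher" else if (mb > ma) "B_higher"
                   else "none",
       median_a = ma, median_b = mb)
}
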