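## Tissue-overlap patterns of expression changes and the coincidental
## index: did a gene's multi-tissue changes land on one branch of the
## phylogeny (coincidental) or on dispersed branches?

validate_events <- function(events, tissues = NULL, tree = NULL) {
  need <- c("gene", "tissue", "edge")
  if (!all(need %in% names(events)))
    stop("events need columns: ", paste(need, collapse = ", "))
  if (!is.null(tissues) && length(events$tissue) &&
      !all(events$tissue %in% tissues))
    stop("unknown tissue in events: ",
         paste(setdiff(unique(events$tissue), tissues), collapse = ", "))
  if (!is.null(tree) && length(events$edge) &&
      !all(events$edge %in% edge_labels(tree)))
    stop("unknown edge in events")
  invisible(events)
}

#' Tissue-overlap table of expression changes
#'
#' Bins genes by the exact set of tissues in which they carry at least one
#' change event (UpSet semantics): every changed gene is counted in exactly
#' one tissue combination.
#'
#' @param events data.frame of change events (gene, tissue, edge,
#'   direction), e.g. from [change_events()].
#' @param tissues The full tissue panel (validates event tissues).
#' @param branch Optional edge label restricting the scope to changes on
#'   one branch (as in per-branch overlap plots); default all branches.
#' @return data.frame with columns \code{tissues} (combination label,
#'   "+"-separated, sorted), \code{n_tissues}, \code{n_genes}.
#' @export
tissue_overlap <- function(events, tissues, branch = NULL) {
  validate_events(events, tissues)
  if (!is.null(branch)) events <- events[events$edge == branch, , drop = FALSE]
  if (!nrow(events))
    return(data.frame(tissues = character(0), n_tissues = integer(0),
                      n_genes = integer(0)))
  combos <- tapply(events$tissue, events$gene, function(tt)
    paste(sort(unique(tt)), collapse = "+"))
  tab <- table(combos)
  out <- data.frame(tissues = names(tab),
                    n_tissues = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    n_genes = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$n_genes), , drop = FALSE]
}

#' Coincidental index of one gene's expression changes
#'
#' Over the branches (time points) where the gene has at least one change,
#' the index is the total number of tissue changes divided by the maximum
#' possible: sum_t n_obs(t) / sum_t T, with n_obs(t) the number of tissues
#' changed on branch t and T the number of tissues analysed. It is 0 for a
#' gene with no changes, 1/T for a single-tissue change, and 1 when every
#' change-bearing branch carries changes in all T tissues.
#'
#' @param events data.frame of change events for one gene (gene, tissue,
#'   edge).
#' @param n_tissues T, the number of tissues analysed.
#' @return Numeric scalar in \{0\} U [1/T, 1].
#' @export
coincidental_index <- function(events, n_tissues) {
  if (n_tissues < 1) stop("n_tissues must be >= 1")
  if (is.null(events) || !nrow(events)) return(0)
  validate_events(events)
  if (length(unique(events$gene)) > 1)
    stop("coincidental_index is per gene; got multiple genes")
  n_obs <- tapply(events$tissue, events$edge, function(tt)
    length(unique(tt)))
  if (any(n_obs > n_tissues))
    stop("more distinct tissues on one branch than n_tissues")
  sum(n_obs) / (n_tissues * length(n_obs))
}

#' Coincidental index for every gene in an event table
#'
#' @param events data.frame of change events (any number of genes).
#' @param n_tissues T, the number of tissues analysed.
#' @param genes Optional gene universe; genes without events score 0.
#' @return data.frame gene, index.
#' @export
coincidental_index_all <- function(events, n_tissues, genes = NULL) {
  validate_events(events)
  if (is.null(genes)) genes <- unique(events$gene)
  idx <- vapply(genes, function(g)
    coincidental_index(events[events$gene == g, , drop = FALSE], n_tissues),
    numeric(1))
  data.frame(gene = genes, index = idx, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Association between coincidental changes and branch length
#'
#' Spearman correlation between per-branch counts of coincidental events
#' (branches where a gene changed in more than one tissue; all events with
#' \code{min_tissues = 1}) and branch lengths, with a permutation null that
#' redistributes the same number of events uniformly over branches.
#'
#' @param events data.frame of change events.
#' @param tree Species tree supplying branch lengths.
#' @param n_perm Number of permutations (default 1e4).
#' @param min_tissues Count a (gene, branch) only when at least this many
#'   tissues changed there (2 isolates coincidental changes).
#' @param seed Integer seed.
#' @return List with \code{rho}, one-sided \code{p_greater}, two-sided
#'   \code{p}, per-edge \code{counts}, or verdict \code{"not_applicable"}
#'   when fewer than 2 distinct branch lengths exist.
#' @export
coincidence_vs_branch_length <- function(events, tree, n_perm = 1e4,
                                         min_tissues = 2, seed = 1) {
  validate_events(events, tree = tree)
  elab <- edge_labels(tree)
  len <- tree$edge.length
  if (length(unique(len)) < 2 || length(len) < 2)
    return(list(verdict = "not_applicable",
                reason = "fewer than 2 distinct branch lengths"))
  per_gene_edge <- unique(events[, c("gene", "edge", "tissue")])
  tab <- table(per_gene_edge$gene, per_gene_edge$edge)
  qualifying <- which(tab >= min_tissues, arr.ind = TRUE)
  counts <- stats::setNames(integer(length(elab)), elab)
  if (nrow(qualifying)) {
    hit <- table(colnames(tab)[qualifying[, 2]])
    counts[names(hit)] <- as.integer(hit)
  }
  total <- sum(counts)
  if (total == 0)
    return(list(verdict = "not_applicable", reason = "no qualifying events",
                counts = counts))
  rho <- stats::cor(counts, len, method = "spearman")
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      cts <- stats::rmultinom(1, total, rep(1 / length(len), length(len)))[, 1]
      stats::cor(cts, len, method = "spearman")
    }, numeric(1))
  })
  list(rho = rho,
       p_greater = (sum(perm >= rho) + 1) / (n_perm + 1),
       p = (sum(abs(perm) >= abs(rho)) + 1) / (n_perm + 1),
       counts = counts, n_perm = n_perm, seed = seed)
}
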