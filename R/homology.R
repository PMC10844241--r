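## Cluster marker identification and the cross-tissue cell-type homology
## score: the product of the (clipped) correlation of cluster mean
## expression over shared markers and the fraction of markers shared.

#' Find positive marker genes per cluster
#'
#' For each cluster, genes expressed in at least \code{min_frac} of its
#' cells, with log2 fold change (cluster vs rest) of at least
#' \code{min_lfc}, and a one-sided rank-sum p-value below \code{alpha};
#' ranked by fold change and truncated at \code{top_n}. Positive markers
#' only.
#'
#' @param atlas An [atlas_summary()] carrying cell-level matrices.
#' @param min_frac Minimum in-cluster fraction expressing (default 0.25).
#' @param min_lfc Minimum log2 fold change vs all other cells (default
#'   0.25).
#' @param alpha Rank-sum significance threshold (default 0.001).
#' @param top_n Marker list cap per cluster (default 100).
#' @return Named list of character vectors of marker genes per cluster.
#' @export
find_markers <- function(atlas, min_frac = 0.25, min_lfc = 0.25,
                         alpha = 0.001, top_n = 100) {
  stopifnot(inherits(atlas, "atlas_summary"))
  if (is.null(atlas$cells))
    stop("marker testing needs cell-level matrices in the atlas")
  if (length(atlas$clusters) < 2) stop("need >= 2 clusters")
  all_cells <- do.call(cbind, atlas$cells)
  cl_of <- rep(atlas$clusters, vapply(atlas$cells, ncol, integer(1)))
  out <- vector("list", length(atlas$clusters))
  names(out) <- atlas$clusters
  for (cl in atlas$clusters) {
    inn <- all_cells[, cl_of == cl, drop = FALSE]
    if (ncol(inn) < 3) {
      warning("cluster ", cl, " has < 3 cells; skipped")
      out[[cl]] <- character(0)
      next
    }
    outc <- all_cells[, cl_of != cl, drop = FALSE]
    frac_in <- rowMeans(inn > 0)
    mean_in <- rowMeans(inn); mean_out <- rowMeans(outc)
    lfc <- log2((mean_in + 1) / (mean_out + 1))
    cand <- which(frac_in >= min_frac & lfc >= min_lfc)
    if (!length(cand)) { out[[cl]] <- character(0); next }
    pv <- vapply(cand, function(g)
      stats::wilcox.test(inn[g, ], outc[g, ], alternative = "greater",
                         exact = FALSE)$p.value, numeric(1))
    keep <- cand[pv < alpha]
    keep <- keep[order(-lfc[keep])]
    out[[cl]] <- atlas$genes[utils::head(keep, top_n)]
  }
  out
}

#' Cross-tissue cell-type homology score
#'
#' score(i, j) = clip0(Pearson correlation of log1p cluster-mean expression
#' of clusters i and j over the union of their markers) x (shared-marker
#' fraction |Mi n Mj| / min(|Mi|, |Mj|)). 0 corresponds to completely
#' unrelated cell types and 1 to identical cell types.
#'
#' @param atlas_a,atlas_b [atlas_summary()] objects sharing a gene universe.
#' @param markers_a,markers_b Marker lists per cluster, e.g. from
#'   [find_markers()].
#' @param method Correlation method (default \code{"pearson"}).
#' @return Matrix clusters_a x clusters_b with entries in [0, 1]; pairs
#'   with an empty shared-marker union score 0 and are recorded in the
#'   \code{"empty_union"} attribute.
#' @export
homology_score <- function(atlas_a, atlas_b, markers_a, markers_b,
                           method = c("pearson", "spearman")) {
  stopifnot(inherits(atlas_a, "atlas_summary"),
            inherits(atlas_b, "atlas_summary"))
  method <- match.arg(method)
  shared_genes <- intersect(atlas_a$genes, atlas_b$genes)
  if (!length(shared_genes)) stop("no shared gene universe")
  score <- matrix(0, length(atlas_a$clusters), length(atlas_b$clusters),
                  dimnames = list(atlas_a$clusters, atlas_b$clusters))
  empty <- NULL
  for (i in atlas_a$clusters) {
    for (j in atlas_b$clusters) {
      mi <- intersect(markers_a[[i]], shared_genes)
      mj <- intersect(markers_b[[j]], shared_genes)
      uni <- union(mi, mj)
      if (!length(uni) || !length(mi) || !length(mj)) {
        empty <- rbind(empty, data.frame(cluster_a = i, cluster_b = j))
        next
      }
      overlap <- length(intersect(mi, mj)) / min(length(mi), length(mj))
      if (overlap == 0) next
      xi <- log1p(atlas_a$mean_expression[i, uni])
      xj <- log1p(atlas_b$mean_expression[j, uni])
      r <- if (stats::sd(xi) == 0 || stats::sd(xj) == 0) 0
           else stats::cor(xi, xj, method = method)
      score[i, j] <- min(1, max(0, r) * overlap)
    }
  }
  attr(score, "empty_union") <- empty
  score
}

#' Match clusters between two atlases by homology score
#'
#' @param score Matrix from [homology_score()].
#' @param min_score Minimum score to call a match (default 0).
#' @return data.frame cluster_a, cluster_b, score (argmax per row).
#' @export
match_clusters <- function(score, min_score = 0) {
  hit <- apply(score, 1, which.max)
  out <- data.frame(cluster_a = rownames(score),
                    cluster_b = colnames(score)[hit],
                    score = score[cbind(seq_len(nrow(score)), hit)],
                    stringsAsFactors = FALSE)
  out[out$score > min_score, , drop = FALSE]
}
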