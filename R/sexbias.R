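## Simplified negative-binomial Wald engine and sex-bias classification.
##
## The engine is deliberately self-contained: median-of-ratios size
## factors, gene-wise method-of-moments dispersions (no empirical-Bayes
## shrinkage), per-gene NB GLMs with log link and size-factor offsets, and
## Wald tests on the per-tissue sex contrast. It is validated against its
## own simulation contracts, not against any external DE tool's output.

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median ratio of its counts to the
#' geometric-mean pseudo-reference over genes nonzero in all samples.
#' Falls back to library-size scaling (with a warning) when no gene is
#' nonzero everywhere.
#'
#' @param counts Genes x samples integer matrix.
#' @return Positive numeric vector of per-sample factors (geometric mean 1
#'   for the fallback).
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2) stop("need >= 2 samples")
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    warning("no gene nonzero in all samples; falling back to library-size scaling")
    ls <- colSums(counts)
    return(ls / exp(mean(log(ls))))
  }
  lg <- log(counts[all_pos, , drop = FALSE])
  ref <- rowMeans(lg)
  apply(lg, 2, function(col) exp(stats::median(col - ref)))
}

#' Filter genes by normalized-count support
#'
#' Keeps a gene when at least \code{min_samples} samples have a normalized
#' count of at least \code{min_count}.
#'
#' @param norm_counts Genes x samples matrix of normalized counts.
#' @param min_count Minimum normalized count (default 5).
#' @param min_samples Minimum qualifying samples (default 3).
#' @return Logical gene mask.
#' @export
filter_expressed <- function(norm_counts, min_count = 5, min_samples = 3) {
  rowSums(norm_counts >= min_count) >= min_samples
}

# gene-wise method-of-moments NB dispersion from normalized counts,
# pooled over design cells; floored at 1e-8
mom_dispersion <- function(q, groups, floor = 1e-8) {
  ug <- unique(groups)
  est <- vapply(ug, function(g) {
    x <- q[groups == g]
    if (length(x) < 2) return(NA_real_)
    m <- mean(x)
    if (m <= 0) return(NA_real_)
    (stats::var(x) - m) / m^2
  }, numeric(1))
  est <- est[is.finite(est)]
  if (!length(est)) return(floor)
  max(mean(est), floor)
}

#' Negative-binomial Wald tests for sex differences
#'
#' Fits a per-gene NB GLM with log link and size-factor offsets under the
#' design \code{~ tissue + sex + tissue:sex} (reducing to \code{~ sex} for
#' a single tissue) and Wald-tests the male-vs-female contrast within each
#' tissue. Fold changes are male relative to female. p-values are
#' BH-adjusted across genes within each tissue.
#'
#' @param counts Genes x samples integer matrix.
#' @param meta data.frame with columns \code{sample}, \code{tissue},
#'   \code{sex} matching the count columns.
#' @param min_count,min_samples Expression filter on normalized counts
#'   (defaults 5 and 3).
#' @return data.frame with one row per gene x tissue: \code{gene},
#'   \code{tissue}, \code{lfc} (log2 male/female), \code{se}, \code{z},
#'   \code{p}, \code{padj}, \code{dispersion}; non-convergent genes are
#'   flagged in the \code{converged} column and excluded from adjustment.
#' @export
nb_wald <- function(counts, meta, min_count = 5, min_samples = 3) {
  stopifnot(all(c("sample", "tissue", "sex") %in% names(meta)))
  meta <- meta[meta$sex %in% c("male", "female"), , drop = FALSE]
  if (!nrow(meta)) stop("no male/female samples in metadata")
  counts <- counts[, meta$sample, drop = FALSE]
  cell <- interaction(meta$tissue, meta$sex, drop = TRUE)
  if (any(table(cell) < 2)) stop("need >= 2 replicates per sex x tissue cell")
  sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, `/`)
  keep <- filter_expressed(q, min_count, min_samples)
  tissues <- sort(unique(meta$tissue))
  multi <- length(tissues) > 1
  tissue_f <- factor(meta$tissue, levels = tissues)
  sex_f <- factor(meta$sex, levels = c("female", "male"))
  X <- if (multi) stats::model.matrix(~ tissue_f + sex_f + tissue_f:sex_f)
       else stats::model.matrix(~ sex_f)
  off <- log(sf)
  cn <- colnames(X)
  contrast_for <- function(tt) {
    cc <- numeric(ncol(X))
    cc[cn == "sex_fmale"] <- 1
    if (multi && tt != tissues[1])
      cc[cn == paste0("tissue_f", tt, ":sex_fmale")] <- 1
    cc
  }
  rows <- vector("list", sum(keep) * length(tissues)); ri <- 0L
  for (g in which(keep)) {
    y <- counts[g, ]
    disp <- mom_dispersion(q[g, ], cell)
    fit <- tryCatch(suppressWarnings(
      stats::glm.fit(X, y, offset = off,
                     family = MASS::negative.binomial(theta = 1 / disp))),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged && all(is.finite(fit$coefficients))
    vc <- NULL
    if (ok) {
      w <- fit$weights
      xtx <- crossprod(X * sqrt(w))
      vc <- tryCatch(solve(xtx), error = function(e) NULL)
      ok <- !is.null(vc)
    }
    for (tt in tissues) {
      ri <- ri + 1L
      if (!ok) {
        rows[[ri]] <- data.frame(gene = rownames(counts)[g], tissue = tt,
                                 lfc = NA_real_, se = NA_real_, z = NA_real_,
                                 p = NA_real_, dispersion = disp,
                                 converged = FALSE, stringsAsFactors = FALSE)
        next
      }
      cc <- contrast_for(tt)
      est <- sum(cc * fit$coefficients)
      se <- sqrt(drop(t(cc) %*% vc %*% cc))
      z <- est / se
      rows[[ri]] <- data.frame(gene = rownames(counts)[g], tissue = tt,
                               lfc = est / log(2), se = se / log(2), z = z,
                               p = 2 * stats::pnorm(-abs(z)),
                               dispersion = disp, converged = TRUE,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  out$padj <- NA_real_
  for (tt in tissues) {
    m <- out$tissue == tt & out$converged
    out$padj[m] <- stats::p.adjust(out$p[m], method = "BH")
  }
  rownames(out) <- NULL
  out
}

#' Classify sex bias from test results
#'
#' Male-biased when the male/female fold change is at least \code{fc_min}
#' with adjusted p below \code{alpha}; female-biased for the reciprocal;
#' otherwise none.
#'
#' @param results data.frame from [nb_wald()] (columns \code{lfc},
#'   \code{padj}).
#' @param fc_min Fold-change floor, linear scale (default 1.5). With
#'   \code{scale = "log2"} the floor applies to |log2 FC| instead.
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param scale \code{"linear"} (default) or \code{"log2"}.
#' @return The input with a \code{bias} column in
#'   \{\code{male}, \code{female}, \code{none}\}.
#' @export
classify_bias <- function(results, fc_min = 1.5, alpha = 0.01,
                          scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  thr <- if (scale == "linear") log2(fc_min) else fc_min
  sig <- !is.na(results$padj) & results$padj < alpha
  results$bias <- ifelse(sig & results$lfc >= thr, "male",
                         ifelse(sig & results$lfc <= -thr, "female", "none"))
  results
}

#' Overlap of sex-biased gene sets and hypergeometric enrichment
#'
#' Counts genes sharing the same direction of bias across sets (e.g.
#' species or tissues) pairwise and in all sets, and optionally tests a
#' query annotation (e.g. chemosensory genes) for enrichment among the
#' conserved-bias genes with an upper-tail hypergeometric test.
#'
#' @param bias_sets Named list of data.frames with columns \code{gene},
#'   \code{bias} (from [classify_bias()], bias != "none" rows used).
#' @param universe Character vector of tested genes.
#' @param query Optional annotation gene set; trimmed to the universe with
#'   a warning if needed.
#' @return List with \code{pairwise} (data.frame set_a, set_b, overlap),
#'   \code{shared_all} (genes biased in the same direction in every set),
#'   and when \code{query} given, \code{enrichment} (hits, drawn,
#'   annotated, universe, p).
#' @export
bias_overlap <- function(bias_sets, universe, query = NULL) {
  stopifnot(length(bias_sets) >= 2, !is.null(names(bias_sets)))
  dirs <- lapply(bias_sets, function(df) {
    df <- df[df$bias %in% c("male", "female"), , drop = FALSE]
    stats::setNames(df$bias, df$gene)
  })
  nm <- names(bias_sets)
  pw <- do.call(rbind, lapply(utils::combn(nm, 2, simplify = FALSE),
    function(pr) {
      g <- intersect(names(dirs[[pr[1]]]), names(dirs[[pr[2]]]))
      data.frame(set_a = pr[1], set_b = pr[2],
                 overlap = sum(dirs[[pr[1]]][g] == dirs[[pr[2]]][g]),
                 stringsAsFactors = FALSE)
    }))
  common <- Reduce(intersect, lapply(dirs, names))
  same <- common[vapply(common, function(g)
    length(unique(vapply(dirs, `[[`, character(1), g))) == 1L, logical(1))]
  out <- list(pairwise = pw, shared_all = same)
  if (!is.null(query)) {
    extra <- setdiff(query, universe)
    if (length(extra)) {
      warning(length(extra), " query gene(s) outside the universe trimmed")
      query <- intersect(query, universe)
    }
    drawn <- intersect(same, universe)
    hits <- length(intersect(drawn, query))
    out$enrichment <- list(
      hits = hits, drawn = length(drawn), annotated = length(query),
      universe = length(universe),
      p = hypergeom_enrichment(length(universe), length(query),
                               length(drawn), hits))
  }
  out
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= hits) drawing \code{drawn} genes from a universe of size
#' \code{universe} containing \code{annotated} annotated genes.
#'
#' @param universe,annotated,drawn,hits Integers.
#' @return p-value.
#' @export
hypergeom_enrichment <- function(universe, annotated, drawn, hits) {
  stopifnot(annotated <= universe, drawn <= universe, hits <= drawn)
  stats::phyper(hits - 1, annotated, universe - annotated, drawn,
                lower.tail = FALSE)
}
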