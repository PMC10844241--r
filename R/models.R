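## Per-gene BM / OU / multi-optimum model fitting and selection.
##
## All likelihoods are replicate-aware multivariate normals: observations are
## species means evolved on the tree plus iid Gaussian replicate error with
## variance sigma2_e. sigma2 and the mean parameters are profiled
## analytically, so numerical optimisation is at most two-dimensional
## (log alpha, log gamma) with gamma = sigma2_e / sigma2.

# flatten a species x replicate matrix (possibly with NA padding) into
# y / species-index vectors
flatten_traits <- function(traits, tree) {
  if (is.null(dim(traits))) traits <- matrix(traits, ncol = 1,
                                             dimnames = list(names(traits), NULL))
  sp <- rownames(traits)
  if (is.null(sp)) stop("traits must have species rownames")
  missing <- setdiff(tree$tip.label, sp)
  if (length(missing)) stop("traits missing species: ",
                            paste(missing, collapse = ", "))
  traits <- traits[tree$tip.label, , drop = FALSE]
  keep <- !is.na(traits)
  y <- traits[keep]
  z <- match(rep(rownames(traits), ncol(traits))[keep], tree$tip.label)
  list(y = as.numeric(y), z = z)
}

# profiled Gaussian log-likelihood for correlation structure W = C[z,z]+g*I
# and mean design X (rows = observations). Returns logL, beta, sigma2.
# reml = TRUE gives the restricted likelihood and the bias-corrected
# sigma2 = RSS/(N - p); REML logLs are not comparable across designs.
gls_profile <- function(y, z, X, C, gamma, reml = FALSE) {
  W <- C[z, z, drop = FALSE]
  diag(W) <- diag(W) + gamma
  U <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(U)) {
    U <- tryCatch(chol(W + diag(1e-10, nrow(W))), error = function(e) NULL)
    if (is.null(U)) return(list(logL = -Inf))
  }
  n <- length(y)
  yt <- backsolve(U, y, transpose = TRUE)
  Xt <- backsolve(U, X, transpose = TRUE)
  fit <- tryCatch(qr(Xt), error = function(e) NULL)
  if (is.null(fit) || fit$rank < ncol(Xt)) {
    beta <- tryCatch(qr.coef(fit, yt), error = function(e) NULL)
    if (is.null(beta)) return(list(logL = -Inf))
    beta[is.na(beta)] <- 0
  } else beta <- qr.coef(fit, yt)
  resid <- yt - Xt %*% beta
  rss <- sum(resid^2)
  if (rss <= 0) rss <- .Machine$double.eps
  if (reml) {
    p <- ncol(X)
    sigma2 <- rss / (n - p)
    xtx <- crossprod(Xt)
    logL <- -0.5 * (n - p) * (log(2 * pi * sigma2) + 1) -
      sum(log(diag(U))) - 0.5 * determinant(xtx)$modulus[1]
  } else {
    sigma2 <- rss / n
    logL <- -0.5 * n * (log(2 * pi * sigma2) + 1) - sum(log(diag(U)))
  }
  list(logL = logL, beta = as.numeric(beta), sigma2 = sigma2)
}

# OU species correlation kernel scaled so sigma2 factors out:
# Cov = sigma2 * exp(-alpha d) / (2 alpha)
ou_corr <- function(dmat, alpha) exp(-alpha * dmat) / (2 * alpha)

# expand a tips x optima design to observation rows
expand_design <- function(Xsp, z) Xsp[z, , drop = FALSE]

#' Fit a Brownian-motion model to one gene's traits
#'
#' Maximum likelihood for root state, drift rate \code{sigma2} and replicate
#' variance \code{sigma2_e} under BM on the tree, with the mean and
#' \code{sigma2} profiled and the variance ratio optimised numerically.
#'
#' @param traits Matrix of trait values, species in rows (rownames matching
#'   the tree tips), replicates in columns; \code{NA}s allowed for unequal
#'   replication. Typically log2(TPM+1).
#' @param tree A \code{phylo} species tree.
#' @param method \code{"REML"} (default) gives the standard bias-corrected
#'   variance-component estimates; \code{"ML"} the maximum likelihood used
#'   for model comparison (REML likelihoods are not comparable across mean
#'   structures, so [select_model()] always scores with ML).
#' @return A list with elements \code{model = "BM"}, \code{root},
#'   \code{sigma2}, \code{sigma2_e}, \code{logL}, \code{k} (free parameter
#'   count) and \code{degenerate}.
#' @export
fit_bm <- function(traits, tree, method = c("REML", "ML")) {
  method <- match.arg(method)
  reml <- method == "REML"
  validate_species_tree(tree)
  fl <- flatten_traits(traits, tree)
  if (stats::var(fl$y) < 1e-12)
    return(list(model = "BM", degenerate = TRUE, logL = Inf, k = 3L,
                root = fl$y[1], sigma2 = NA_real_, sigma2_e = NA_real_))
  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  X <- matrix(1, length(fl$y), 1)
  obj <- function(lg) -gls_profile(fl$y, fl$z, X, C, exp(lg), reml)$logL
  opt <- stats::optimize(obj, interval = c(-20, 20), tol = 1e-8)
  g <- exp(opt$minimum)
  best <- gls_profile(fl$y, fl$z, X, C, g, reml)
  list(model = "BM", degenerate = FALSE, root = best$beta[1],
       sigma2 = best$sigma2, sigma2_e = g * best$sigma2,
       gamma = g, logL = best$logL, k = 3L)
}

#' Fit an OU model (single- or multi-optimum) to one gene's traits
#'
#' Maximum likelihood under a stationary OU process with a fixed regime of
#' optima. Optima and \code{sigma2} are profiled; \code{alpha} and the error
#' ratio \code{gamma = sigma2_e/sigma2} are optimised by bounded
#' quasi-Newton from a deterministic grid of starts, unless supplied fixed.
#'
#' @inheritParams fit_bm
#' @param reg A [regime()]; \code{NULL} means a single optimum (OU1).
#' @param alpha,gamma Optional fixed values; when given, only the remaining
#'   free ones are optimised (both fixed reduces to one GLS solve).
#' @param alpha_bounds Search bounds on \code{alpha} (1/My). Beyond these the
#'   likelihood surface is flat at this tree depth.
#' @param stationary Root drawn from the stationary distribution (default
#'   TRUE, the pipeline's model); FALSE conditions on the root state, the
#'   parameterisation whose likelihood converges to BM as
#'   \code{alpha -> 0}.
#' @param method \code{"REML"} (default) for bias-corrected variance
#'   estimates; \code{"ML"} for likelihoods comparable across regimes.
#' @return A list with \code{model} ("OU1" or "OUM"), \code{alpha},
#'   \code{gamma}, \code{sigma2}, \code{sigma2_e}, \code{theta} (optimum
#'   values, ancestral first), \code{logL}, \code{k}, \code{shift_edges},
#'   \code{convergence}.
#' @export
fit_ou <- function(traits, tree, reg = NULL, alpha = NULL, gamma = NULL,
                   alpha_bounds = c(1e-6, 50), stationary = TRUE,
                   method = c("REML", "ML")) {
  method <- match.arg(method)
  reml <- method == "REML"
  validate_species_tree(tree)
  if (is.null(reg)) reg <- regime_from_shifts(tree)
  n_shift <- length(reg$shift_edges)
  fl <- flatten_traits(traits, tree)
  if (stats::var(fl$y) < 1e-12)
    return(list(model = if (n_shift) "OUM" else "OU1", degenerate = TRUE,
                logL = Inf, k = n_shift + 4L, theta = rep(fl$y[1], n_shift + 1L),
                alpha = NA_real_, gamma = NA_real_,
                sigma2 = NA_real_, sigma2_e = NA_real_,
                shift_edges = reg$shift_edges, convergence = 0L))
  dmat <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  tshared <- if (stationary) NULL
             else ape::vcv(tree)[tree$tip.label, tree$tip.label]

  eval_fit <- function(a, g) {
    Xsp <- oum_design(tree, reg, a)
    C <- ou_corr(dmat, a)
    if (!stationary) C <- C * (1 - exp(-2 * a * tshared))
    gls_profile(fl$y, fl$z, expand_design(Xsp, fl$z), C, g, reml)
  }
  conv <- 0L
  if (!is.null(alpha) && !is.null(gamma)) {
    a <- alpha; g <- gamma
  } else if (!is.null(alpha)) {
    a <- alpha
    opt <- stats::optimize(function(lg) -eval_fit(a, exp(lg))$logL,
                           interval = c(-20, 20), tol = 1e-8)
    g <- exp(opt$minimum)
  } else {
    obj <- function(p) {
      ll <- eval_fit(exp(p[1]), exp(p[2]))$logL
      if (!is.finite(ll)) 1e10 else -ll
    }
    lo <- c(log(alpha_bounds[1]), -20)
    hi <- c(log(alpha_bounds[2]), 20)
    starts <- expand.grid(la = log(c(0.02, 0.2, 1, 5, 25)), lg = log(0.5))
    best_opt <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(
        stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                     lower = lo, upper = hi,
                     control = list(factr = 1e8)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best_opt) || o$value < best_opt$value))
        best_opt <- o
    }
    if (is.null(best_opt))
      return(list(model = if (n_shift) "OUM" else "OU1", degenerate = FALSE,
                  logL = -Inf, k = n_shift + 4L, convergence = 1L,
                  theta = rep(NA_real_, n_shift + 1L), alpha = NA_real_,
                  gamma = NA_real_, sigma2 = NA_real_, sigma2_e = NA_real_,
                  shift_edges = reg$shift_edges))
    a <- exp(best_opt$par[1]); g <- exp(best_opt$par[2])
    conv <- best_opt$convergence
  }
  best <- eval_fit(a, g)
  list(model = if (n_shift) "OUM" else "OU1", degenerate = FALSE,
       alpha = a, gamma = g, sigma2 = best$sigma2,
       sigma2_e = g * best$sigma2, theta = best$beta,
       logL = best$logL, k = n_shift + 4L,
       shift_edges = reg$shift_edges, convergence = conv)
}

#' Enumerate shift configurations up to a maximum number of shifts
#'
#' All subsets of tree edges of size 0..\code{max_shifts}, each returned as a
#' [regime()]. On the rooted binary 6-taxon tree (10 edges) with
#' \code{max_shifts = 3} this yields 1 + 10 + 45 + 120 = 176 configurations.
#'
#' @param tree A \code{phylo} object.
#' @param max_shifts Maximum number of optimum shifts (default 3, half the
#'   number of taxa on a 6-species tree).
#' @return List of regimes, ordered by increasing shift count.
#' @export
enumerate_shift_configs <- function(tree, max_shifts = 3) {
  validate_species_tree(tree)
  if (max_shifts < 0) stop("max_shifts must be >= 0")
  n_edge <- nrow(tree$edge)
  if (max_shifts > n_edge) {
    warning("max_shifts exceeds edge count; capped at ", n_edge)
    max_shifts <- n_edge
  }
  configs <- list(regime_from_shifts(tree))
  for (s in seq_len(max_shifts)) {
    sets <- utils::combn(n_edge, s, simplify = FALSE)
    configs <- c(configs, lapply(sets, function(e) regime_from_shifts(tree, e)))
  }
  configs
}

# pBIC-lite: BIC plus the combinatorial model-count correction for choosing
# s shift edges among E candidates
pbic <- function(logL, k, n_obs, n_edges, n_shifts) {
  -2 * logL + k * log(n_obs) + 2 * lchoose(n_edges, n_shifts)
}

#' Select the best evolutionary model for one gene
#'
#' Fits BM, a single-optimum OU (OU1) and every multi-optimum configuration
#' up to \code{max_shifts} shifts, scores each with a combinatorially
#' corrected BIC ("pBIC-lite"), and returns the minimiser. Ties break toward
#' fewer shifts, then BM before OU1. Multi-optimum candidates are scored
#' with \code{alpha} and the error ratio fixed at the OU1 maximum-likelihood
#' estimates while optima and \code{sigma2} are re-profiled per
#' configuration (two-stage estimation in the style of lasso-based shift
#' detectors).
#'
#' @inheritParams fit_bm
#' @param max_shifts Maximum number of optimum shifts searched (default 3).
#' @param refine_top Number of top-ranked shift configurations re-fitted
#'   with free \code{(alpha, gamma)} before final scoring (default 3); 0
#'   disables refinement and scores all configurations at the OU1
#'   estimates.
#' @param gene Optional gene identifier carried through to the result.
#' @param tissue Optional tissue label carried through to the result.
#' @return An object of class \code{gene_fit}: selected model, parameter
#'   estimates, shift edges with direction (\code{"up"}/\code{"down"}),
#'   per-edge branch classes (\code{neutral}/\code{constrained}/
#'   \code{divergent}), and the score table of all candidates.
#' @export
select_model <- function(traits, tree, max_shifts = 3, refine_top = 3,
                         gene = NA_character_, tissue = NA_character_) {
  validate_species_tree(tree)
  fl <- flatten_traits(traits, tree)
  n_obs <- length(fl$y)
  n_edge <- nrow(tree$edge)
  elab <- edge_labels(tree)
  if (stats::var(fl$y) < 1e-12) {
    return(structure(list(gene = gene, tissue = tissue, degenerate = TRUE,
                          selected = NA_character_, shift_edges = integer(0),
                          directions = character(0),
                          branch_class = stats::setNames(rep(NA_character_, n_edge), elab)),
                     class = "gene_fit"))
  }
  bm <- fit_bm(traits, tree, method = "ML")
  ou1 <- fit_ou(traits, tree, method = "ML")
  cand <- list(
    list(model = "BM", n_shifts = 0L, fit = bm,
         score = pbic(bm$logL, bm$k, n_obs, n_edge, 0L)),
    list(model = "OU1", n_shifts = 0L, fit = ou1,
         score = pbic(ou1$logL, ou1$k, n_obs, n_edge, 0L)))

  if (max_shifts > 0 && is.finite(ou1$logL)) {
    dmat <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
    C <- ou_corr(dmat, ou1$alpha)
    for (s in seq_len(min(max_shifts, n_edge))) {
      sets <- utils::combn(n_edge, s, simplify = FALSE)
      pen <- 2 * lchoose(n_edge, s)
      for (set in sets) {
        reg <- regime_from_shifts(tree, set)
        Xsp <- oum_design(tree, reg, ou1$alpha)
        gp <- gls_profile(fl$y, fl$z, expand_design(Xsp, fl$z), C, ou1$gamma)
        cand[[length(cand) + 1L]] <- list(
          model = "OUM", n_shifts = s,
          fit = list(model = "OUM", alpha = ou1$alpha, gamma = ou1$gamma,
                     sigma2 = gp$sigma2, sigma2_e = ou1$gamma * gp$sigma2,
                     theta = gp$beta, logL = gp$logL, k = s + 4L,
                     shift_edges = reg$shift_edges, regime = reg),
          score = -2 * gp$logL + (s + 4L) * log(n_obs) + pen)
      }
    }
  }

  ## refinement: the fixed-(alpha, gamma) screen ranks configurations; the
  ## top few are re-fitted at their own ML before the final comparison
  if (refine_top > 0 && length(cand) > 2) {
    oum_idx <- which(vapply(cand, `[[`, character(1), "model") == "OUM")
    oum_scores <- vapply(cand[oum_idx], `[[`, numeric(1), "score")
    for (i in oum_idx[order(oum_scores)][seq_len(min(refine_top,
                                                     length(oum_idx)))]) {
      reg <- cand[[i]]$fit$regime
      ref <- fit_ou(traits, tree, reg, method = "ML")
      if (is.finite(ref$logL) && ref$logL > cand[[i]]$fit$logL) {
        ref$regime <- reg
        cand[[i]]$fit <- ref
        cand[[i]]$score <- pbic(ref$logL, ref$k, n_obs, n_edge,
                                cand[[i]]$n_shifts)
      }
    }
  }

  scores <- vapply(cand, `[[`, numeric(1), "score")
  shifts <- vapply(cand, `[[`, integer(1), "n_shifts")
  ord <- order(scores + 1e-9 * shifts +
                 1e-10 * (vapply(cand, `[[`, character(1), "model") != "BM"))
  best <- cand[[ord[1]]]

  shift_edges <- integer(0); directions <- character(0)
  branch_class <- stats::setNames(rep("constrained", n_edge), elab)
  if (best$model == "BM") branch_class[] <- "neutral"
  if (best$model == "OUM") {
    reg <- best$fit$regime
    shift_edges <- reg$shift_edges
    parent <- parent_edge_index(tree)
    dirs <- vapply(shift_edges, function(e) {
      own <- best$fit$theta[reg$edge_optimum[e]]
      anc_idx <- if (parent[e] == 0L) 1L else reg$edge_optimum[parent[e]]
      if (own >= best$fit$theta[anc_idx]) "up" else "down"
    }, character(1))
    directions <- dirs
    branch_class[shift_edges] <- "divergent"
  }
  score_table <- data.frame(
    model = vapply(cand, `[[`, character(1), "model"),
    n_shifts = shifts,
    logL = vapply(cand, function(x) x$fit$logL, numeric(1)),
    pBIC = scores)
  structure(list(gene = gene, tissue = tissue, degenerate = FALSE,
                 selected = best$model, n_shifts = best$n_shifts,
                 fit = best$fit, bm = bm, ou1 = ou1,
                 shift_edges = shift_edges,
                 shift_edge_labels = elab[shift_edges],
                 directions = directions,
                 branch_class = branch_class,
                 scores = score_table),
            class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("gene_fit:", x$gene, if (!is.na(x$tissue)) paste0("(", x$tissue, ")"), "\n")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate (no variance); excluded from selection\n")
    return(invisible(x))
  }
  cat("  selected model:", x$selected, "\n")
  if (length(x$shift_edges))
    cat("  shifts:", paste(x$shift_edge_labels, x$directions,
                           sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Fit and select models for every gene in a traits list
#'
#' @param traits_list Named list of species x replicate matrices (one per
#'   gene), or a 3-d array genes can be supplied via [panel_traits()].
#' @param tree A \code{phylo} species tree.
#' @param max_shifts Passed to [select_model()].
#' @param tissue Optional tissue label stored in each fit.
#' @return List of \code{gene_fit} objects, named by gene.
#' @export
fit_gene_models <- function(traits_list, tree, max_shifts = 3,
                            tissue = NA_character_) {
  out <- vector("list", length(traits_list))
  names(out) <- names(traits_list)
  for (i in seq_along(traits_list)) {
    out[[i]] <- select_model(traits_list[[i]], tree, max_shifts = max_shifts,
                             gene = names(traits_list)[i] %||% as.character(i),
                             tissue = tissue)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate branch classifications over genes
#'
#' Genes best fit by BM contribute all-neutral edges, OU1 genes all
#' constrained edges, and multi-optimum genes divergent shift edges within
#' otherwise constrained trees. Degenerate genes are excluded.
#'
#' @param fits List of \code{gene_fit} objects for one tissue.
#' @return List with \code{counts} (class x edge matrix), \code{fractions}
#'   (named length-3 vector over genes x edges) and \code{n_genes} used.
#' @export
classify_branches <- function(fits) {
  fits <- Filter(function(f) !isTRUE(f$degenerate), fits)
  if (!length(fits)) stop("no non-degenerate fits to classify")
  classes <- c("neutral", "constrained", "divergent")
  elab <- names(fits[[1]]$branch_class)
  counts <- matrix(0L, 3, length(elab), dimnames = list(classes, elab))
  for (f in fits) {
    tab <- table(factor(f$branch_class, levels = classes))
    for (cl in classes) counts[cl, ] <- counts[cl, ] +
        (f$branch_class == cl)
  }
  total <- sum(counts)
  list(counts = counts,
       fractions = rowSums(counts) / total,
       n_genes = length(fits))
}

#' Extract expression-change events from selected fits
#'
#' One event per (gene, tissue, shift edge) for genes whose selected model
#' has optimum shifts; direction is the sign of the optimum change along the
#' edge.
#'
#' @param fits List of \code{gene_fit} objects.
#' @param tissue Tissue label to stamp on events when the fits carry none.
#' @return A data.frame with columns \code{gene}, \code{tissue},
#'   \code{edge} (edge label), \code{direction}.
#' @export
change_events <- function(fits, tissue = NULL) {
  rows <- lapply(fits, function(f) {
    if (isTRUE(f$degenerate) || !length(f$shift_edges)) return(NULL)
    data.frame(gene = f$gene,
               tissue = if (!is.null(tissue)) tissue else f$tissue,
               edge = f$shift_edge_labels,
               direction = f$directions,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), tissue = character(0),
                      edge = character(0), direction = character(0))
  rownames(out) <- NULL
  out
}
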