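## Synthetic-data generators. Every input the pipeline consumes can be
## simulated with known ground truth: expression panels evolved on a tree,
## negative-binomial count tables, toy cell atlases with planted markers,
## and toy multi-species alignments with planted gap runs.
##
## All generators are pure functions of (spec, seed): the RNG state is
## saved and restored so simulation never perturbs the caller's stream.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic expression panel
#'
#' Defaults mirror the study design the package emulates: 6 species, 3
#' replicates, five chemosensory tissues of which three are sampled in both
#' sexes, expression simulated on the log2(TPM+1) scale.
#'
#' @param tree Species tree (default [example_species_tree()]).
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per species (and per sex where sexed),
#'   >= 2.
#' @param tissues Tissue panel.
#' @param sexed_tissues Subset of \code{tissues} sampled for both sexes.
#' @param model Evolutionary model for background genes: \code{"BM"} or
#'   \code{"OU1"}, or a per-gene character vector.
#' @param params [ou_params()] for the trait process (on log2(TPM+1)
#'   scale). The default (alpha 0.02/My, sigma2 0.05, sigma2_e 0.01)
#'   reproduces the correlation scale of real transcriptomes: species-mean
#'   correlations ~0.75--0.99 across 0.25--15 My, replicate correlations
#'   ~0.99. Gene-level model-selection studies typically override alpha.
#' @param root_mean Ancestral mean expression, log2(TPM+1).
#' @param changers List describing planted expression changes:
#'   \code{n} genes, \code{delta} optimum shift in stationary-SD units,
#'   \code{tissues_per} tissues affected per gene,
#'   \code{coincidental_fraction} probability that all affected tissues
#'   shift on the same branch, and optional \code{min_visibility}
#'   restricting planted shifts to branches where the optimum change
#'   displaces at least one tip by that fraction of the shift (see
#'   [edge_visibility()]; shifts that revert before reaching any tip are
#'   statistically invisible to any method).
#' @param sex_effect List: \code{fraction} of genes spiked with a sex
#'   effect, \code{lfc} log2 fold change added to male samples of sexed
#'   tissues.
#' @param nb_dispersion Negative-binomial dispersion used by
#'   [panel_to_counts()].
#' @param seed Integer seed recorded in the panel metadata.
#' @return A \code{sim_spec} list.
#' @export
sim_spec <- function(tree = example_species_tree(), n_genes = 200,
                     n_replicates = 3,
                     tissues = c("antenna", "proboscis", "foreleg",
                                 "ovipositor", "larva"),
                     sexed_tissues = c("antenna", "proboscis", "foreleg"),
                     model = "OU1",
                     params = ou_params(alpha = 0.02, sigma2 = 0.05,
                                        sigma2_e = 0.01),
                     root_mean = 6,
                     changers = list(n = 0, delta = 4, tissues_per = 1,
                                     coincidental_fraction = 0),
                     sex_effect = list(fraction = 0, lfc = 2),
                     nb_dispersion = 0.1, seed = 1) {
  validate_species_tree(tree)
  stopifnot(n_replicates >= 2, n_genes >= 1)
  if (!all(sexed_tissues %in% tissues)) stop("sexed_tissues must be tissues")
  cf <- changers$coincidental_fraction %||% 0
  if (cf < 0 || cf > 1) stop("coincidental_fraction must be in [0,1]")
  sf <- sex_effect$fraction %||% 0
  if (sf < 0 || sf > 1) stop("sex_effect fraction must be in [0,1]")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  structure(list(tree = tree, n_genes = n_genes, n_replicates = n_replicates,
                 tissues = tissues, sexed_tissues = sexed_tissues,
                 model = model, params = params, root_mean = root_mean,
                 changers = changers, sex_effect = sex_effect,
                 nb_dispersion = nb_dispersion, seed = seed),
            class = "sim_spec")
}

# draw n_genes x n_tips species means with per-gene mean rows `mu`
# (n_genes x tips) and common tip covariance `V`
draw_species_means <- function(mu, V) {
  L <- chol(V)
  z <- matrix(stats::rnorm(nrow(mu) * ncol(mu)), nrow(mu), ncol(mu))
  mu + z %*% L
}

#' Simulate an expression panel on the tree
#'
#' Per gene, species means evolve under the requested process (BM, OU1, or
#' a multi-optimum OU for planted changer genes); replicates add iid
#' Gaussian error \code{sigma2_e}. Simulation happens on the log2(TPM+1)
#' scale and is exponentiated to TPM, keeping Gaussianity exact where the
#' likelihoods operate.
#'
#' @param spec A [sim_spec()].
#' @return An \code{expression_panel}: list with \code{tpm} (genes x
#'   samples), \code{meta} (sample metadata: species, tissue, sex,
#'   replicate), \code{truth} (planted changes: gene, tissue, edge,
#'   direction), \code{gene_model} (per-gene background model), \code{units
#'   = "TPM"}, and the generating \code{spec}.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  tree <- spec$tree
  tips <- tree$tip.label
  p <- spec$params
  sd_st <- sqrt(p$sigma2 / (2 * max(p$alpha, 1e-8)))
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  model <- rep(spec$model, length.out = spec$n_genes)
  elab <- edge_labels(tree)

  with_seed(spec$seed, {
    ## plan planted changes
    ch <- spec$changers
    truth <- NULL
    changer_plan <- list()
    if ((ch$n %||% 0) > 0) {
      candidate_edges <- if (is.null(ch$min_visibility)) {
        seq_len(nrow(tree$edge))
      } else {
        which(edge_visibility(tree, max(p$alpha, 1e-8)) >= ch$min_visibility)
      }
      if (!length(candidate_edges))
        stop("no branch satisfies changers$min_visibility")
      idx <- sample.int(spec$n_genes, ch$n)
      for (g in idx) {
        tiss <- sample(spec$tissues, min(ch$tissues_per %||% 1,
                                         length(spec$tissues)))
        coincidental <- stats::runif(1) < (ch$coincidental_fraction %||% 0)
        shared_edge <- sample(candidate_edges, 1)
        dirs <- if (stats::runif(1) < 0.5) "up" else "down"
        plan <- lapply(tiss, function(tt) {
          e <- if (coincidental) shared_edge else sample(candidate_edges, 1)
          list(tissue = tt, edge = e, direction = dirs)
        })
        changer_plan[[as.character(g)]] <- plan
        truth <- rbind(truth, data.frame(
          gene = genes[g],
          tissue = vapply(plan, `[[`, character(1), "tissue"),
          edge = elab[vapply(plan, `[[`, integer(1), "edge")],
          direction = dirs, stringsAsFactors = FALSE))
      }
    }

    ## covariance kernels shared across genes
    V_bm <- bm_covariance(tree, p$sigma2)
    V_ou <- if (p$alpha > 0) ou_covariance(tree, p) else NULL

    ## sex-effect genes
    n_sex <- round((spec$sex_effect$fraction %||% 0) * spec$n_genes)
    sex_genes <- if (n_sex > 0) sample.int(spec$n_genes, n_sex) else integer(0)
    sex_dir <- sample(c(1, -1), length(sex_genes), replace = TRUE)

    expr <- NULL; meta <- NULL
    for (tt in spec$tissues) {
      mu <- matrix(spec$root_mean, spec$n_genes, length(tips),
                   dimnames = list(genes, tips))
      ## planted multi-optimum means for changers in this tissue
      for (gch in names(changer_plan)) {
        for (pl in changer_plan[[gch]]) {
          if (pl$tissue != tt) next
          g <- as.integer(gch)
          th1 <- spec$root_mean
          th2 <- th1 + (if (pl$direction == "up") 1 else -1) * ch$delta * sd_st
          reg <- regime_from_shifts(tree, pl$edge, optima = c(th1, th2))
          mu[g, ] <- ou_tip_means(reg, max(p$alpha, 1e-8))[tips]
        }
      }
      means <- mu
      is_bm <- model == "BM"
      if (any(is_bm))
        means[is_bm, ] <- draw_species_means(mu[is_bm, , drop = FALSE], V_bm)
      if (any(!is_bm)) {
        if (is.null(V_ou)) stop("OU genes require alpha > 0 in params")
        means[!is_bm, ] <- draw_species_means(mu[!is_bm, , drop = FALSE], V_ou)
      }
      sexes <- if (tt %in% spec$sexed_tissues) c("female", "male") else "mixed"
      for (sx in sexes) {
        for (r in seq_len(spec$n_replicates)) {
          vals <- means + matrix(stats::rnorm(length(means), 0, sqrt(p$sigma2_e)),
                                 nrow(means), ncol(means))
          if (sx == "male" && length(sex_genes))
            vals[sex_genes, ] <- vals[sex_genes, ] +
              sex_dir * spec$sex_effect$lfc
          cols <- paste(tips, tt, sx, paste0("r", r), sep = "_")
          expr <- cbind(expr, structure(vals, dimnames = list(genes, cols)))
          meta <- rbind(meta, data.frame(
            sample = cols, species = tips, tissue = tt, sex = sx,
            replicate = r, stringsAsFactors = FALSE))
        }
      }
    }
    tpm <- pmax(2^expr - 1, 0)
    if (is.null(truth))
      truth <- data.frame(gene = character(0), tissue = character(0),
                          edge = character(0), direction = character(0))
    structure(list(tpm = tpm, meta = meta, truth = truth,
                   gene_model = stats::setNames(model, genes),
                   units = "TPM", spec = spec, seed = spec$seed),
              class = "expression_panel")
  })
}

#' Simulate species-mean expression only
#'
#' A lean generator for distance and rate-test studies: one genes x species
#' matrix of TPM values per call, no replicates or tissues. Rates can be
#' scaled per species to plant lineage-specific acceleration.
#'
#' @param tree Species tree.
#' @param n_genes Number of genes.
#' @param params [ou_params()]; \code{alpha = 0} simulates BM. The default
#'   (alpha 0.02/My, sigma2 0.05) reproduces the correlation scale of real
#'   cross-species transcriptomes over 0.25--15 My of divergence
#'   (species-mean correlations ~0.75--0.99).
#' @param root_mean Ancestral mean, log2(TPM+1) scale.
#' @param rate_scale Named per-species variance multipliers (1 = equal
#'   rates): the species' tip variance is multiplied by the factor via
#'   extra independent terminal variance, emulating a lineage whose
#'   evolutionary rate (sigma2) is scaled by that factor.
#' @param seed Integer seed.
#' @return Genes x species TPM matrix.
#' @export
simulate_species_means <- function(tree, n_genes,
                                   params = ou_params(0.02, 0.05),
                                   root_mean = 6, rate_scale = NULL,
                                   seed = 1) {
  validate_species_tree(tree)
  tips <- tree$tip.label
  V <- if (params$alpha > 0) ou_covariance(tree, params)
       else bm_covariance(tree, params$sigma2)
  if (!is.null(rate_scale)) {
    if (any(rate_scale < 1)) stop("rate_scale must be >= 1")
    sc <- rate_scale[names(rate_scale) %in% tips]
    extra <- rep(0, length(tips)); names(extra) <- tips
    extra[names(sc)] <- (sc - 1) * diag(V)[names(sc)]
    diag(V) <- diag(V) + extra
  }
  with_seed(seed, {
    mu <- matrix(root_mean, n_genes, length(tips),
                 dimnames = list(sprintf("g%04d", seq_len(n_genes)), tips))
    pmax(2^draw_species_means(mu, V) - 1, 0)
  })
}

#' Convert a TPM panel to a negative-binomial count table
#'
#' Counts are drawn as NB(mean = TPM x library_size / 1e6, dispersion);
#' dispersion 0 gives Poisson sampling.
#'
#' @param panel An \code{expression_panel}, or a genes x samples TPM matrix.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion mu^2),
#'   >= 0.
#' @param library_sizes Per-sample library sizes; default 1e6 (counts equal
#'   TPM in expectation).
#' @param seed Integer seed.
#' @return Integer matrix of counts, same dimnames as the TPM input.
#' @export
panel_to_counts <- function(panel, nb_dispersion = NULL, library_sizes = NULL,
                            seed = 1) {
  tpm <- if (inherits(panel, "expression_panel")) panel$tpm else panel
  if (any(tpm < 0)) stop("panel must be in positive TPM-like units")
  if (is.null(nb_dispersion))
    nb_dispersion <- if (inherits(panel, "expression_panel"))
      panel$spec$nb_dispersion else 0.1
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (is.null(library_sizes)) library_sizes <- rep(1e6, ncol(tpm))
  if (length(library_sizes) != ncol(tpm))
    stop("library_sizes must match sample count")
  mu <- sweep(tpm, 2, library_sizes / 1e6, `*`)
  with_seed(seed, {
    counts <- if (nb_dispersion == 0) {
      stats::rpois(length(mu), lambda = mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
    }
    matrix(as.integer(counts), nrow(mu), ncol(mu), dimnames = dimnames(mu))
  })
}

#' Atlas summary container
#'
#' Cluster-level summary of a single-cell atlas: per-cluster mean expression
#' and fraction of cells expressing each gene, with optional cell-level
#' matrices for marker testing.
#'
#' @param mean_expression Clusters x genes matrix (linear scale).
#' @param fraction_expressing Clusters x genes matrix in [0,1].
#' @param n_cells Per-cluster cell counts.
#' @param cells Optional list (per cluster) of genes x cells matrices.
#' @return An \code{atlas_summary} object.
#' @export
atlas_summary <- function(mean_expression, fraction_expressing, n_cells,
                          cells = NULL) {
  stopifnot(identical(dim(mean_expression), dim(fraction_expressing)),
            identical(dimnames(mean_expression),
                      dimnames(fraction_expressing)))
  if (any(fraction_expressing < 0 | fraction_expressing > 1))
    stop("fractions must be in [0,1]")
  if (length(n_cells) != nrow(mean_expression))
    stop("n_cells must have one entry per cluster")
  structure(list(clusters = rownames(mean_expression),
                 genes = colnames(mean_expression),
                 mean_expression = mean_expression,
                 fraction_expressing = fraction_expressing,
                 n_cells = n_cells, cells = cells),
            class = "atlas_summary")
}

#' Simulate a pair of cell atlases with known cluster homology
#'
#' Builds two toy atlases sharing a gene universe. The first
#' \code{n_shared_clusters} clusters of each atlas are homologous: their
#' mean-expression profiles are correlated at \code{planted_cor} and they
#' carry identical planted marker sets. Remaining clusters get fresh
#' profiles and disjoint markers.
#'
#' @param n_clusters Clusters per atlas.
#' @param n_genes Size of the shared gene universe.
#' @param n_shared_clusters Number of homologous cluster pairs,
#'   <= \code{n_clusters}.
#' @param n_markers Planted markers per cluster.
#' @param planted_cor Correlation of homologous profiles (1 = identical).
#' @param n_cells Cells simulated per cluster.
#' @param seed Integer seed.
#' @return List: \code{atlas_a}, \code{atlas_b} ([atlas_summary()]s) and
#'   \code{truth} (data.frame cluster_a, cluster_b).
#' @export
simulate_atlas_pair <- function(n_clusters = 8, n_genes = 300,
                                n_shared_clusters = 4, n_markers = 15,
                                planted_cor = 0.9, n_cells = 40, seed = 1) {
  if (n_shared_clusters > n_clusters)
    stop("n_shared_clusters must be <= n_clusters")
  need <- n_markers * (n_clusters + (n_clusters - n_shared_clusters))
  if (need > n_genes)
    stop("marker sets exceed the gene universe (need ", need, " genes)")
  genes <- sprintf("gene%03d", seq_len(n_genes))
  with_seed(seed, {
    marker_pool <- sample(genes)
    take <- function(k) {
      m <- marker_pool[seq_len(k)]
      marker_pool <<- marker_pool[-seq_len(k)]
      m
    }
    markers_a <- lapply(seq_len(n_clusters), function(i) take(n_markers))
    markers_b <- lapply(seq_len(n_clusters), function(i) {
      if (i <= n_shared_clusters) markers_a[[i]] else take(n_markers)
    })
    base_profile <- function(markers) {
      prof <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
      names(prof) <- genes
      prof[markers] <- prof[markers] + stats::rlnorm(length(markers), 2.5, 0.3)
      prof
    }
    profiles_a <- lapply(markers_a, base_profile)
    profiles_b <- lapply(seq_len(n_clusters), function(i) {
      if (i <= n_shared_clusters) {
        pa <- log1p(profiles_a[[i]])
        noise <- stats::rnorm(n_genes, 0, stats::sd(pa))
        pb <- planted_cor * pa + sqrt(max(0, 1 - planted_cor^2)) * noise
        prof <- expm1(pmax(pb, 0))
        names(prof) <- genes
        prof[markers_b[[i]]] <- pmax(prof[markers_b[[i]]],
                                     profiles_a[[i]][markers_b[[i]]] *
                                       (if (planted_cor >= 1) 1
                                        else stats::runif(n_markers, 0.7, 1.3)))
        prof
      } else base_profile(markers_b[[i]])
    })
    build <- function(profiles, markers, prefix) {
      cl_names <- paste0(prefix, seq_len(n_clusters))
      cells <- vector("list", n_clusters); names(cells) <- cl_names
      for (i in seq_len(n_clusters)) {
        prof <- profiles[[i]]
        # detection probability saturates with expression (dropout model)
        frac <- ifelse(genes %in% markers[[i]], 0.9,
                       pmin(0.95, prof / (prof + stats::median(prof))))
        on_mat <- matrix(stats::rbinom(n_genes * n_cells, 1, frac),
                         n_genes, n_cells)
        amp <- matrix(stats::rgamma(n_genes * n_cells, shape = 4, rate = 4),
                      n_genes, n_cells)
        cells[[i]] <- on_mat * amp * prof
        dimnames(cells[[i]]) <- list(genes,
                                     paste0(cl_names[i], "_c", seq_len(n_cells)))
      }
      me <- t(vapply(cells, rowMeans, numeric(n_genes)))
      fe <- t(vapply(cells, function(m) rowMeans(m > 0), numeric(n_genes)))
      dimnames(me) <- dimnames(fe) <- list(cl_names, genes)
      atlas_summary(me, fe, n_cells = rep(n_cells, n_clusters), cells = cells)
    }
    atlas_a <- build(profiles_a, markers_a, "A")
    atlas_b <- build(profiles_b, markers_b, "B")
    truth <- if (n_shared_clusters > 0) {
      data.frame(cluster_a = paste0("A", seq_len(n_shared_clusters)),
                 cluster_b = paste0("B", seq_len(n_shared_clusters)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cluster_a = character(0), cluster_b = character(0),
                 stringsAsFactors = FALSE)
    }
    list(atlas_a = atlas_a, atlas_b = atlas_b, truth = truth,
         markers_a = markers_a, markers_b = markers_b)
  })
}

#' Simulate a multi-species ortholog alignment with planted gaps
#'
#' All species share one conserved sequence; requested gap runs are planted
#' as '-' columns in the requested species. Each species carries a genomic
#' anchor (start coordinate and strand) so alignment columns map to genomic
#' positions.
#'
#' @param species Species names.
#' @param length Alignment length in columns.
#' @param gaps data.frame with columns \code{species}, \code{start},
#'   \code{length} (alignment columns, 1-based).
#' @param genomic_start Named (or recycled) per-species genomic start of the
#'   gene span.
#' @param strand Named (or recycled) per-species strand, "+" or "-".
#' @param gene_id Gene identifier carried into GTF output.
#' @param seed Integer seed for the random base sequence.
#' @return An \code{ortholog_alignment}: list(seqs, gene_id, genomic_start,
#'   strand).
#' @export
simulate_alignment <- function(species, length, gaps = NULL,
                               genomic_start = 1001, strand = "+",
                               gene_id = "gene1", seed = 1) {
  stopifnot(length >= 1, !anyDuplicated(species))
  if (!is.null(gaps)) {
    stopifnot(all(c("species", "start", "length") %in% names(gaps)))
    if (!all(gaps$species %in% species)) stop("gap spec names unknown species")
    if (any(gaps$start < 1 | gaps$start + gaps$length - 1 > length))
      stop("gap runs must lie within sequence bounds")
    for (sp in unique(gaps$species)) {
      g <- gaps[gaps$species == sp, , drop = FALSE]
      if (nrow(g) > 1) {
        g <- g[order(g$start), ]
        if (any(g$start[-1] <= (g$start + g$length - 1)[-nrow(g)]))
          stop("overlapping gap specs for species ", sp)
      }
    }
  }
  genomic_start <- rep(genomic_start, length.out = base::length(species))
  strand <- rep(strand, length.out = base::length(species))
  names(genomic_start) <- names(strand) <- species
  with_seed(seed, {
    base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    seqs <- lapply(species, function(sp) {
      s <- base
      if (!is.null(gaps)) {
        g <- gaps[gaps$species == sp, , drop = FALSE]
        for (i in seq_len(nrow(g)))
          s[g$start[i]:(g$start[i] + g$length[i] - 1)] <- "-"
      }
      paste(s, collapse = "")
    })
    names(seqs) <- species
    structure(list(seqs = unlist(seqs), gene_id = gene_id,
                   genomic_start = genomic_start, strand = strand),
              class = "ortholog_alignment")
  })
}

#' Write / read an alignment as FASTA
#'
#' @param aln An \code{ortholog_alignment} (or named character vector).
#' @param file Path to write.
#' @return \code{read_alignment_fasta} returns a named character vector of
#'   aligned sequences.
#' @export
write_alignment_fasta <- function(aln, file) {
  seqs <- if (inherits(aln, "ortholog_alignment")) aln$seqs else aln
  x <- Biostrings::DNAStringSet(gsub("-", "-", seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = file)
  invisible(file)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  stats::setNames(as.character(x), names(x))
}
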