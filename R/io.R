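## TSV input/output for panels, metadata and result tables. Output tables
## carry provenance header comments (package version, seed, input
## checksums) and are read back with comments skipped.

#' Write a table with a provenance header
#'
#' @param df data.frame to write.
#' @param file Output path.
#' @param seed Optional seed recorded in the header.
#' @param inputs Optional named character vector of input paths; their md5
#'   checksums go into the header.
#' @export
write_tsv <- function(df, file, seed = NULL, inputs = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# exprevol ",
                    as.character(utils::packageVersion("exprevol"))), con)
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  if (!is.null(inputs)) {
    sums <- tools::md5sum(inputs)
    writeLines(sprintf("# input %s md5=%s", names(sums), unname(sums)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param file Path.
#' @return data.frame.
#' @export
read_tsv <- function(file) {
  utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write an expression panel to TSV files
#'
#' Emits \code{<prefix>_expression.tsv} (genes x samples, gene ids in the
#' first column), \code{<prefix>_metadata.tsv} and, when ground truth is
#' present, \code{<prefix>_truth.tsv}.
#'
#' @param panel An \code{expression_panel}.
#' @param prefix Path prefix.
#' @return Invisibly, the files written.
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "expression_panel"))
  ef <- paste0(prefix, "_expression.tsv")
  mf <- paste0(prefix, "_metadata.tsv")
  expr <- data.frame(gene = rownames(panel$tpm), panel$tpm,
                     check.names = FALSE)
  write_tsv(expr, ef, seed = panel$seed)
  write_tsv(panel$meta, mf, seed = panel$seed)
  files <- c(ef, mf)
  if (!is.null(panel$truth) && nrow(panel$truth)) {
    tf <- paste0(prefix, "_truth.tsv")
    write_tsv(panel$truth, tf, seed = panel$seed)
    files <- c(files, tf)
  }
  invisible(files)
}

#' Read an expression panel from TSV files
#'
#' @param expr_file Genes x samples table (first column gene ids).
#' @param meta_file Sample metadata (sample, species, tissue, sex,
#'   replicate).
#' @param units Units flag, \code{"TPM"} or \code{"counts"}.
#' @return An \code{expression_panel}.
#' @export
read_panel <- function(expr_file, meta_file, units = "TPM") {
  expr <- read_tsv(expr_file)
  meta <- read_tsv(meta_file)
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr[[1]]
  if (!all(meta$sample %in% colnames(m)))
    stop("metadata samples missing from expression table")
  structure(list(tpm = m[, meta$sample, drop = FALSE], meta = meta,
                 truth = NULL, units = units, seed = NA_integer_),
            class = "expression_panel")
}

#' Read and write atlas summaries as TSV
#'
#' The exchange format for cluster-level single-cell summaries: two
#' cluster x gene tables (mean expression; fraction of cells expressing)
#' with cluster ids in the first column, plus per-cluster cell counts in
#' a \code{n_cells} column of the mean table when present. Exports from
#' loom/H5AD-based toolchains are expected to arrive through this format:
#' split the object by cluster, take \code{rowMeans} of the count matrix
#' and the fraction of nonzero cells per gene, and write the two tables.
#'
#' @param atlas An [atlas_summary()].
#' @param mean_file,fraction_file Paths for the two tables.
#' @return \code{read_atlas_tsv} returns an [atlas_summary()] (without
#'   cell-level matrices, so marker testing needs the original data).
#' @export
write_atlas_tsv <- function(atlas, mean_file, fraction_file) {
  stopifnot(inherits(atlas, "atlas_summary"))
  me <- data.frame(cluster = atlas$clusters, n_cells = atlas$n_cells,
                   atlas$mean_expression, check.names = FALSE)
  fe <- data.frame(cluster = atlas$clusters, atlas$fraction_expressing,
                   check.names = FALSE)
  write_tsv(me, mean_file)
  write_tsv(fe, fraction_file)
  invisible(c(mean_file, fraction_file))
}

#' @rdname write_atlas_tsv
#' @export
read_atlas_tsv <- function(mean_file, fraction_file) {
  me <- read_tsv(mean_file)
  fe <- read_tsv(fraction_file)
  n_cells <- me$n_cells
  gm <- as.matrix(me[, setdiff(names(me), c("cluster", "n_cells")),
                     drop = FALSE])
  gf <- as.matrix(fe[, setdiff(names(fe), "cluster"), drop = FALSE])
  rownames(gm) <- me$cluster; rownames(gf) <- fe$cluster
  atlas_summary(gm, gf[rownames(gm), colnames(gm), drop = FALSE],
                n_cells = n_cells %||% rep(NA_integer_, nrow(gm)))
}

#' Summarise a list of gene fits as a table
#'
#' One row per gene: selected model, parameter estimates, pBIC of the
#' selected candidate, and the shift edges with directions
#' (";"-separated).
#'
#' @param fits List of \code{gene_fit} objects from [fit_gene_models()].
#' @return data.frame.
#' @export
gene_fit_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    if (isTRUE(f$degenerate))
      return(data.frame(gene = f$gene, tissue = f$tissue, model = "unfit",
                        alpha = NA_real_, sigma2 = NA_real_,
                        sigma2_e = NA_real_, logL = NA_real_,
                        pBIC = NA_real_, shifts = "", directions = "",
                        stringsAsFactors = FALSE))
    sel <- f$scores[f$scores$model == f$selected &
                      f$scores$n_shifts == f$n_shifts, , drop = FALSE]
    data.frame(gene = f$gene, tissue = f$tissue, model = f$selected,
               alpha = f$fit$alpha %||% NA_real_,
               sigma2 = f$fit$sigma2, sigma2_e = f$fit$sigma2_e,
               logL = f$fit$logL, pBIC = min(sel$pBIC),
               shifts = paste(f$shift_edge_labels, collapse = ";"),
               directions = paste(f$directions, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene trait matrices for model fitting
#'
#' Extracts, for one tissue, each gene's species x replicate matrix on the
#' requested scale. Sex samples of a sexed tissue enter as additional
#' replicate columns.
#'
#' @param panel An \code{expression_panel}.
#' @param tissue Tissue to extract.
#' @param transform \code{"log2"} for log2(TPM+1) (default) or \code{"raw"}
#'   for raw TPM traits.
#' @return Named list (per gene) of species x replicate matrices.
#' @export
panel_traits <- function(panel, tissue, transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  meta <- panel$meta[panel$meta$tissue == tissue, , drop = FALSE]
  if (!nrow(meta)) stop("no samples for tissue ", tissue)
  species <- sort(unique(meta$species))
  reps <- split(meta$sample, meta$species)
  n_rep <- max(lengths(reps))
  sub <- panel$tpm[, meta$sample, drop = FALSE]
  if (transform == "log2") sub <- log2(sub + 1)
  lapply(stats::setNames(rownames(sub), rownames(sub)), function(g) {
    m <- matrix(NA_real_, length(species), n_rep,
                dimnames = list(species, NULL))
    for (sp in species) m[sp, seq_along(reps[[sp]])] <- sub[g, reps[[sp]]]
    m
  })
}
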