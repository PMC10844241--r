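## Conserved-region trimming of multi-species ortholog alignments.
##
## A region of the alignment is discarded when any species carries a gap
## run strictly longer than max_gap (default 150 bp) inside it; what
## remains is partitioned into maximal conserved blocks that are mapped
## back to per-species genomic coordinates and emitted as trimmed GTF.

aln_matrix <- function(aln) {
  seqs <- if (inherits(aln, "ortholog_alignment")) aln$seqs else aln
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences are not aligned (unequal lengths)")
  do.call(rbind, strsplit(seqs, ""))
}

#' Find alignment blocks conserved across all species
#'
#' Scans every species' row for gap runs strictly longer than
#' \code{max_gap} alignment columns; the union of such runs is excluded and
#' the remaining columns are split into maximal contiguous blocks. A gap
#' run of exactly \code{max_gap} columns does not split a block (the rule
#' is "greater than", strict).
#'
#' @param aln An \code{ortholog_alignment} from [simulate_alignment()], or a
#'   named character vector of equal-length gapped sequences.
#' @param max_gap Longest tolerated per-species gap run, in columns
#'   (default 150).
#' @param species Species that must be present; defaults to all sequences
#'   in the alignment.
#' @return An object of class \code{conserved_blocks}: \code{columns}
#'   (data.frame block, col_start, col_end; 1-based inclusive),
#'   \code{genomic} (long data.frame block, species, start, end, strand,
#'   nongap_len; GTF 1-based inclusive, \code{NA} when a block has no
#'   aligned base in a species), and \code{gene_id}.
#' @export
find_conserved_blocks <- function(aln, max_gap = 150, species = NULL) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  m <- aln_matrix(aln)
  if (!is.null(species)) {
    missing <- setdiff(species, rownames(m))
    if (length(missing)) stop("species missing from alignment: ",
                              paste(missing, collapse = ", "))
    m <- m[species, , drop = FALSE]
  }
  L <- ncol(m)
  empty_cols <- data.frame(block = integer(0), col_start = integer(0),
                           col_end = integer(0))
  if (L == 0)
    return(structure(list(columns = empty_cols,
                          genomic = NULL, gene_id = attr(aln, "gene_id")),
                     class = "conserved_blocks"))
  excluded <- rep(FALSE, L)
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- which(r$values & r$lengths > max_gap)
    for (b in bad) excluded[starts[b]:ends[b]] <- TRUE
  }
  keep_rle <- rle(!excluded)
  ends <- cumsum(keep_rle$lengths)
  starts <- ends - keep_rle$lengths + 1L
  ok <- which(keep_rle$values)
  cols <- if (length(ok)) data.frame(block = seq_along(ok),
                                     col_start = starts[ok],
                                     col_end = ends[ok])
          else empty_cols

  genomic <- NULL
  if (inherits(aln, "ortholog_alignment") && nrow(cols)) {
    rows <- list()
    for (sp in rownames(m)) {
      nongap <- m[sp, ] != "-"
      cum <- cumsum(nongap)              # per-column non-gap rank
      n_tot <- cum[L]
      gstart <- aln$genomic_start[[sp]]
      strand <- aln$strand[[sp]]
      for (b in seq_len(nrow(cols))) {
        span <- cols$col_start[b]:cols$col_end[b]
        n_in <- sum(nongap[span])
        if (n_in == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            block = b, species = sp, start = NA_integer_, end = NA_integer_,
            strand = strand, nongap_len = 0L, stringsAsFactors = FALSE)
          next
        }
        k1 <- cum[span][which(nongap[span])[1]]     # first non-gap rank
        k2 <- k1 + n_in - 1L
        if (strand == "+") {
          g1 <- gstart + k1 - 1L; g2 <- gstart + k2 - 1L
        } else {
          gend <- gstart + n_tot - 1L               # span on the genome
          g1 <- gend - (k2 - 1L); g2 <- gend - (k1 - 1L)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          block = b, species = sp, start = min(g1, g2), end = max(g1, g2),
          strand = strand, nongap_len = n_in, stringsAsFactors = FALSE)
      }
    }
    genomic <- do.call(rbind, rows)
  }
  structure(list(columns = cols, genomic = genomic,
                 gene_id = if (inherits(aln, "ortholog_alignment"))
                   aln$gene_id else NA_character_),
            class = "conserved_blocks")
}

#' Emit trimmed GTF exon records for one species
#'
#' One exon feature per conserved block, GTF2.2 attribute syntax, 1-based
#' inclusive coordinates, strand propagated from the alignment anchors.
#' Blocks with no aligned base in the species are skipped with a warning.
#'
#' @param blocks A \code{conserved_blocks} object carrying genomic anchors.
#' @param species Species to emit records for.
#' @param seqname Sequence (chromosome) name for column 1.
#' @param source Source tag for column 2.
#' @return data.frame with the nine GTF columns.
#' @seealso [write_gtf()]
#' @export
blocks_to_gtf <- function(blocks, species, seqname = "chr1",
                          source = "exprevol") {
  stopifnot(inherits(blocks, "conserved_blocks"))
  if (is.null(blocks$genomic)) stop("blocks carry no genomic anchors")
  g <- blocks$genomic[blocks$genomic$species == species, , drop = FALSE]
  if (!nrow(g)) stop("no anchors for species ", species)
  drop <- is.na(g$start)
  if (any(drop)) {
    warning(sum(drop), " block(s) with zero aligned bases in ", species,
            " skipped")
    g <- g[!drop, , drop = FALSE]
  }
  gid <- blocks$gene_id %||% "gene1"
  data.frame(
    seqname = seqname, source = source, feature = "exon",
    start = g$start, end = g$end, score = ".",
    strand = g$strand, frame = ".",
    attribute = sprintf('gene_id "%s"; transcript_id "%s.t1"; block "%d";',
                        gid, gid, g$block),
    stringsAsFactors = FALSE)
}

#' Write GTF records to a file
#'
#' @param gtf data.frame as produced by [blocks_to_gtf()].
#' @param file Output path.
#' @export
write_gtf <- function(gtf, file) {
  utils::write.table(gtf, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
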