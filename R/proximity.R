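#' Map genes to contact-map bins
#'
#' Each gene is assigned the full run of bins its interval overlaps plus a
#' representative bin, the bin containing the gene midpoint. The
#' representative bin defines the gene's position for genomic distances in
#' the null model. Genes on chromosomes absent from the binning are dropped
#' with a warning.
#'
#' @param genes a \code{gene_table}.
#' @param binning a \code{genome_binning}.
#' @return list of class \code{gene_bin_map}: \code{genes} (possibly
#'   subset), \code{spans} (list of 1-based bin index vectors),
#'   \code{rep_bin} (integer vector), \code{chrom}, and the binning.
#' @export
map_genes_to_bins <- function(genes, binning) {
  stopifnot(inherits(genes, "gene_table"), inherits(binning, "genome_binning"))
  absent <- !(genes$chrom %in% binning$chrom_names)
  if (any(absent)) {
    warning(sum(absent), " gene(s) on chromosomes absent from the binning ",
            "were dropped: ", paste(utils::head(unique(genes$chrom[absent]), 5),
                                    collapse = ", "))
    genes <- genes[!absent, , drop = FALSE]
    class(genes) <- c("gene_table", "data.frame")
  }
  if (!nrow(genes)) stop("no genes left after chromosome filtering")
  len <- binning$chrom_lengths[genes$chrom]
  if (any(genes$start >= len))
    stop("gene(s) start beyond chromosome length: ",
         paste(utils::head(genes$gene_id[genes$start >= len], 5), collapse = ", "))
  # clip ends to the chromosome; zero-length spans after clipping are invalid
  end_c <- pmin(genes$end, len)
  if (any(end_c <= genes$start)) stop("zero-length gene span after clipping")
  bs <- binning$bin_size
  off <- binning$chrom_offset[genes$chrom]
  first <- as.integer(off + floor(genes$start / bs) + 1)
  last <- as.integer(off + floor((end_c - 1) / bs) + 1)
  mid <- floor((genes$start + end_c) / 2)
  rep_bin <- as.integer(off + floor(mid / bs) + 1)
  spans <- mapply(seq.int, first, last, SIMPLIFY = FALSE)
  names(spans) <- genes$gene_id
  structure(list(genes = genes, spans = spans,
                 rep_bin = stats::setNames(rep_bin, genes$gene_id),
                 chrom = stats::setNames(genes$chrom, genes$gene_id),
                 binning = binning),
            class = "gene_bin_map")
}

#' Build the gene proximity matrix W
#'
#' W[i,j] is the contact frequency between genes i and j: the value of the
#' single bin pair when both genes fit in one bin, otherwise the maximum
#' contact frequency over all bin pairs spanned by the two genes
#' (representing the minimum distance between them). The diagonal is zero:
#' self-proximity is excluded throughout.
#'
#' @param cmap a \code{contact_map}.
#' @param gbmap a \code{gene_bin_map} on the same binning.
#' @return symmetric G x G matrix of class \code{gene_proximity} with gene
#'   ids as dimnames and attributes \code{rep_bin}, \code{chrom},
#'   \code{bin_size}.
#' @export
build_gene_proximity <- function(cmap, gbmap) {
  stopifnot(inherits(cmap, "contact_map"), inherits(gbmap, "gene_bin_map"))
  if (cmap$binning$n_bins != gbmap$binning$n_bins)
    stop("contact map and gene-bin map use different binnings")
  ids <- gbmap$genes$gene_id
  G <- length(ids)
  spans <- gbmap$spans
  single <- lengths(spans) == 1L
  M <- cmap$matrix
  W <- matrix(0, G, G, dimnames = list(ids, ids))
  sb <- vapply(spans, `[`, integer(1), 1L)
  # fast path: all single-bin pairs at once
  W[single, single] <- M[sb[single], sb[single], drop = FALSE]
  multi <- which(!single)
  for (i in multi) {
    rows <- M[spans[[i]], , drop = FALSE]
    for (j in seq_len(G)) {
      if (j == i) next
      W[i, j] <- W[j, i] <- max(rows[, spans[[j]]])
    }
  }
  diag(W) <- 0
  structure(W, class = c("gene_proximity", "matrix"),
            rep_bin = gbmap$rep_bin, chrom = gbmap$chrom,
            bin_size = gbmap$binning$bin_size)
}

#' Normalized gene proximity map
#'
#' Divides each observed proximity by its null expectation,
#' \eqn{\tilde W_{ij} = W_{ij} / E_{ij}}. Entries where E is zero are set
#' to zero and flagged via the \code{undefined} attribute.
#'
#' @param W gene proximity matrix.
#' @param E null expected matrix of matching shape and gene order.
#' @return matrix \eqn{\tilde W} with attribute \code{undefined} (logical
#'   matrix, TRUE where E was 0 off the diagonal).
#' @export
normalize_proximity <- function(W, E) {
  stopifnot(all(dim(W) == dim(E)))
  if (!is.null(dimnames(W)) && !is.null(dimnames(E)) &&
      !identical(rownames(W), rownames(E)))
    stop("gene order mismatch between W and E")
  Wn <- unclass(W) / ifelse(E > 0, E, 1)
  Wn[E == 0] <- 0
  undef <- E == 0
  diag(undef) <- FALSE
  attr(Wn, "undefined") <- undef
  Wn
}
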