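#' Genome binning
#'
#' A fixed-width partition of a genome into bins, shared by the contact map
#' and every gene-level object. Bins are numbered 1..N in R (reported as
#' 0-based in serialized COO files); within a chromosome they are consecutive
#' and non-overlapping, and every bin belongs to exactly one chromosome.
#' All internal coordinates are 0-based, half-open.
#'
#' @param chrom_names character vector of chromosome names (ordered).
#' @param chrom_lengths integer vector of chromosome lengths in bp.
#' @param bin_size bin width in bp.
#' @return An object of class \code{genome_binning} with the per-bin
#'   chromosome and start coordinate.
#' @examples
#' b <- genome_binning(c("chr1", "chr2"), c(2500, 1000), bin_size = 1000)
#' b$n_bins  # 3 + 1
#' @export
genome_binning <- function(chrom_names, chrom_lengths, bin_size) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  stopifnot(length(chrom_names) == length(chrom_lengths),
            !anyDuplicated(chrom_names),
            all(chrom_lengths > 0), length(bin_size) == 1L, bin_size > 0)
  nb <- as.integer(ceiling(chrom_lengths / bin_size))
  bin_chrom <- rep(chrom_names, nb)
  bin_start <- unlist(lapply(nb, function(n) (seq_len(n) - 1) * bin_size),
                      use.names = FALSE)
  offset <- c(0L, cumsum(nb))[seq_along(chrom_names)]
  names(offset) <- chrom_names
  structure(list(
    chrom_names = chrom_names,
    chrom_lengths = stats::setNames(chrom_lengths, chrom_names),
    bin_size = bin_size,
    n_bins = sum(nb),
    bins_per_chrom = stats::setNames(nb, chrom_names),
    bin_chrom = bin_chrom,
    bin_start = bin_start,
    chrom_offset = offset
  ), class = "genome_binning")
}

#' @export
print.genome_binning <- function(x, ...) {
  cat("Genome binning:", length(x$chrom_names), "chromosome(s),",
      x$n_bins, "bins of", x$bin_size, "bp\n")
  invisible(x)
}

#' Map a genomic position to its bin index
#'
#' @param binning a \code{genome_binning}.
#' @param chrom chromosome name(s).
#' @param pos 0-based bp position(s).
#' @return 1-based global bin index (vectorized).
#' @export
bin_index <- function(binning, chrom, pos) {
  stopifnot(inherits(binning, "genome_binning"))
  chrom <- as.character(chrom)
  unknown <- setdiff(unique(chrom), binning$chrom_names)
  if (length(unknown))
    stop("chromosome(s) not in binning: ", paste(unknown, collapse = ", "))
  if (any(pos < 0) || any(pos >= binning$chrom_lengths[chrom]))
    stop("position outside chromosome length")
  as.integer(binning$chrom_offset[chrom] + floor(pos / binning$bin_size) + 1)
}

#' Start coordinate (bp) of a bin
#'
#' @param binning a \code{genome_binning}.
#' @param bin 1-based global bin index.
#' @return named list with chrom and 0-based start.
#' @export
bin_coord <- function(binning, bin) {
  stopifnot(inherits(binning, "genome_binning"),
            all(bin >= 1), all(bin <= binning$n_bins))
  list(chrom = binning$bin_chrom[bin], start = binning$bin_start[bin])
}
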