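#' Read a balanced Hi-C contact map
#'
#' Reads a binned, balanced (e.g. ICE-corrected) contact matrix. Two text
#' formats are supported: \code{"dense"}, a whitespace-separated N x N
#' matrix, and \code{"coo"}, a 3-column triplet file (bin_i, bin_j, value)
#' with 0-based bin indices; COO files holding only one triangle are
#' mirrored. Balancing itself is out of scope: inputs are assumed already
#' corrected for uniform coverage.
#'
#' @param path path to the matrix file.
#' @param format \code{"dense"} or \code{"coo"}.
#' @param binning a \code{genome_binning} describing the bins.
#' @param max_dense maximum number of bins accepted for a dense matrix.
#' @param sym_tol absolute tolerance for symmetry of dense input.
#' @return A \code{contact_map}: list with \code{binning} and the symmetric
#'   non-negative \code{matrix}.
#' @export
read_contact_map <- function(path, format = c("dense", "coo"), binning,
                             max_dense = 50000L, sym_tol = 1e-8) {
  format <- match.arg(format)
  stopifnot(file.exists(path), inherits(binning, "genome_binning"))
  n <- binning$n_bins
  if (n > max_dense)
    stop("binning has ", n, " bins, above the dense size cap (", max_dense, ")")
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != n || ncol(m) != n)
      stop("dense matrix is ", nrow(m), "x", ncol(m),
           " but binning has ", n, " bins")
    if (max(abs(m - t(m))) > sym_tol)
      stop("dense matrix asymmetric beyond tolerance ", sym_tol)
    m <- (m + t(m)) / 2
  } else {
    coo <- utils::read.table(path, header = FALSE,
                             col.names = c("i", "j", "x"))
    if (any(coo$i < 0 | coo$i >= n | coo$j < 0 | coo$j >= n))
      stop("COO bin index out of range for ", n, " bins")
    m <- matrix(0, n, n)
    m[cbind(coo$i + 1L, coo$j + 1L)] <- coo$x
    lo <- m[lower.tri(m)]
    up <- t(m)[lower.tri(m)]
    if (all(lo == 0)) {               # upper triangle only: mirror
      m[lower.tri(m)] <- up
    } else if (all(up == 0)) {        # lower triangle only
      m <- t(m); m[lower.tri(m)] <- t(m)[lower.tri(m)]
    } else if (max(abs(lo - up)) > sym_tol) {
      stop("COO entries asymmetric beyond tolerance ", sym_tol)
    }
  }
  if (any(m < 0)) stop("contact map has negative entries")
  contact_map(m, binning)
}

#' Construct a contact map from a matrix
#'
#' @param matrix symmetric non-negative N x N matrix.
#' @param binning matching \code{genome_binning}.
#' @return a \code{contact_map} object.
#' @export
contact_map <- function(matrix, binning) {
  stopifnot(inherits(binning, "genome_binning"),
            is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (nrow(matrix) != binning$n_bins)
    stop("matrix dimension ", nrow(matrix), " does not match binning (",
         binning$n_bins, " bins)")
  if (any(matrix < 0)) stop("contact map has negative entries")
  if (max(abs(matrix - t(matrix))) > 1e-8)
    stop("contact map not symmetric")
  structure(list(binning = binning, matrix = matrix), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("Contact map:", x$binning$n_bins, "bins,",
      length(x$binning$chrom_names), "chromosome(s), total signal",
      format(sum(x$matrix), digits = 4), "\n")
  invisible(x)
}

#' Write a contact map
#'
#' @param cmap a \code{contact_map}.
#' @param path output path.
#' @param format \code{"dense"} or \code{"coo"} (upper triangle incl.
#'   diagonal, 0-based indices, zeros omitted).
#' @export
write_contact_map <- function(cmap, path, format = c("dense", "coo")) {
  format <- match.arg(format)
  stopifnot(inherits(cmap, "contact_map"))
  if (format == "dense") {
    utils::write.table(cmap$matrix, path, row.names = FALSE,
                       col.names = FALSE)
  } else {
    m <- cmap$matrix
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    utils::write.table(
      data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L, x = m[idx]),
      path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a gene table (BED or GTF)
#'
#' BED (>= 4 columns: chrom, start, end, name, [score, strand]) is parsed
#' directly; GTF is imported via \pkg{rtracklayer}, keeping feature type
#' \code{gene} and its \code{gene_id} attribute. Internal coordinates are
#' 0-based half-open (GTF's 1-based inclusive intervals are converted).
#' Strand is retained but never used in computation.
#'
#' @param path input file.
#' @param format \code{"bed"} or \code{"gtf"}.
#' @return data.frame of class \code{gene_table} with columns
#'   \code{gene_id}, \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @export
read_gene_table <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "bed") {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE, fill = TRUE)
    if (ncol(tab) < 4)
      stop("BED gene table needs >= 4 columns (chrom, start, end, name)")
    g <- data.frame(gene_id = as.character(tab[[4]]),
                    chrom = as.character(tab[[1]]),
                    start = as.numeric(tab[[2]]),
                    end = as.numeric(tab[[3]]),
                    strand = if (ncol(tab) >= 6)
                      ifelse(is.na(tab[[6]]) | tab[[6]] == "",
                             "*", as.character(tab[[6]])) else "*",
                    stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & gr$type == "gene"]
    if (!length(gr)) stop("no 'gene' features in GTF")
    if (is.null(gr$gene_id) || anyNA(gr$gene_id))
      stop("GTF gene features missing gene_id attribute")
    g <- data.frame(gene_id = as.character(gr$gene_id),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,  # to 0-based
                    end = as.numeric(GenomicRanges::end(gr)),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  }
  gene_table(g)
}

#' Validate / construct a gene table
#'
#' @param df data.frame with gene_id, chrom, start, end (0-based half-open)
#'   and optionally strand.
#' @return the validated \code{gene_table}.
#' @export
gene_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("gene_id", "chrom", "start", "end") %in% names(df)))
  if (is.null(df$strand)) df$strand <- "*"
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  if (any(df$start >= df$end))
    stop("gene(s) with start >= end: ",
         paste(utils::head(df$gene_id[df$start >= df$end], 5), collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Read an expression profile
#'
#' Tab-separated file with a header line naming at least \code{gene_id}
#' and \code{value}; values are linear-scale, non-negative.
#'
#' @param path input TSV.
#' @return named numeric vector of class \code{expression_profile}.
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "value") %in% names(tab)))
    stop("expression TSV must have columns gene_id and value")
  expression_profile(stats::setNames(tab$value, tab$gene_id))
}

#' Construct an expression profile
#'
#' @param values named non-negative numeric vector (names = gene ids).
#' @return an \code{expression_profile}.
#' @export
expression_profile <- function(values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (anyDuplicated(names(values))) stop("duplicate gene ids in expression")
  if (any(values < 0)) stop("negative expression values")
  structure(values, class = "expression_profile")
}

#' Read domain annotations (TADs or A/B compartments)
#'
#' BED4 file: chrom, start, end, label. Compartment labels must be
#' \code{A} or \code{B}; TAD labels are opaque ids. Intervals on one
#' chromosome must not overlap.
#'
#' @param path input BED.
#' @param kind \code{"tad"} or \code{"compartment"}.
#' @return data.frame of class \code{domain_annotation} with an attribute
#'   \code{kind}.
#' @export
read_domains <- function(path, kind = c("tad", "compartment")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("domain BED needs 4 columns (chrom,start,end,label)")
  domain_annotation(data.frame(chrom = as.character(tab[[1]]),
                               start = as.numeric(tab[[2]]),
                               end = as.numeric(tab[[3]]),
                               label = as.character(tab[[4]]),
                               stringsAsFactors = FALSE), kind)
}

#' Construct a domain annotation
#'
#' @param df data.frame with chrom, start, end, label.
#' @param kind \code{"tad"} or \code{"compartment"}.
#' @return validated \code{domain_annotation}.
#' @export
domain_annotation <- function(df, kind = c("tad", "compartment")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end", "label") %in% names(df)))
  if (any(df$start >= df$end)) stop("domain interval with start >= end")
  if (kind == "compartment" && !all(df$label %in% c("A", "B")))
    stop("compartment labels must be A or B")
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("overlapping domain intervals on ", ch)
  }
  rownames(df) <- NULL
  structure(df, class = c("domain_annotation", "data.frame"), kind = kind)
}
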