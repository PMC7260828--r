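# Chromosome-level reduction of the CGP: inter-chromosomal proximity
# matrix, Frobenius normalization, differential networks, top gene pairs.

#' Reduce the CGP matrix to a chromosome-level proximity matrix
#'
#' Merges rows and columns by chromosome:
#' \eqn{\hat B_{\alpha\beta} = \sum_{i \in \alpha, j \in \beta} B_{ij}}
#' for \eqn{\alpha \neq \beta} (ordered gene pairs), main diagonal zero.
#' The Frobenius-normalized form \eqn{\tilde B = \hat B / \|\hat B\|_F}
#' makes maps from different cell types comparable. Intra-chromosomal
#' sums are computed for the decomposition check but stored separately.
#'
#' @param B a \code{cgp_fit} or CGP matrix with a \code{chrom} attribute
#'   (or supply \code{chrom}).
#' @param chrom per-gene chromosome vector.
#' @return object of class \code{chrom_proximity}: \code{B_hat} (raw),
#'   \code{B_tilde} (Frobenius-normalized; 0 with \code{degenerate = TRUE}
#'   when B_hat is all zero), \code{intra} (per-chromosome intra sums),
#'   \code{gene_counts}.
#' @export
reduce_to_chromosomes <- function(B, chrom = NULL) {
  bw <- bw_from(B)
  Bm <- bw$B
  if (is.null(chrom))
    chrom <- if (!is.null(bw$fit)) bw$fit$gbmap$chrom else attr(B, "chrom")
  if (is.null(chrom)) stop("per-gene chromosomes required")
  chrom <- as.character(chrom)
  stopifnot(length(chrom) == nrow(Bm))
  chroms <- unique(chrom)
  ind <- outer(chrom, chroms, "==") * 1   # genes x chromosomes indicator
  Bh <- t(ind) %*% Bm %*% ind             # block sums over ordered pairs
  dimnames(Bh) <- list(chroms, chroms)
  intra <- diag(Bh)
  diag(Bh) <- 0
  fro <- sqrt(sum(Bh^2))
  degenerate <- fro == 0
  Bt <- if (degenerate) Bh else Bh / fro
  structure(list(B_hat = Bh, B_tilde = Bt, intra = intra,
                 gene_counts = table(factor(chrom, levels = chroms)),
                 frobenius = fro, degenerate = degenerate),
            class = "chrom_proximity")
}

#' @export
print.chrom_proximity <- function(x, ...) {
  cat("Chromosome-level proximity map:", nrow(x$B_hat), "chromosomes,",
      "Frobenius norm", format(x$frobenius, digits = 4),
      if (x$degenerate) "(degenerate: all-zero map)" else "", "\n")
  invisible(x)
}

#' Differential chromosome proximity network
#'
#' Edge-wise difference of two Frobenius-normalized chromosome proximity
#' maps: \eqn{\Delta_{\alpha\beta} = \tilde B_b - \tilde B_a}. Positive
#' values mean the chromosome pair is closer in condition b. All edges are
#' kept in the data; \code{display_threshold} only marks which edges a
#' plot would show.
#'
#' @param a,b \code{chrom_proximity} objects on identical chromosome sets.
#' @param display_threshold |delta| below which an edge is flagged as
#'   hidden in display (data is never dropped).
#' @return object of class \code{chrom_differential}: \code{delta}
#'   (matrix), \code{edges} (data.frame chrom_a, chrom_b, delta, shown),
#'   \code{node_sizes}.
#' @export
differential_map <- function(a, b, display_threshold = 0.05) {
  stopifnot(inherits(a, "chrom_proximity"), inherits(b, "chrom_proximity"))
  if (!identical(rownames(a$B_tilde), rownames(b$B_tilde)))
    stop("chromosome sets differ between conditions")
  delta <- b$B_tilde - a$B_tilde
  chroms <- rownames(delta)
  idx <- which(upper.tri(delta), arr.ind = TRUE)
  edges <- data.frame(chrom_a = chroms[idx[, 1]], chrom_b = chroms[idx[, 2]],
                      delta = delta[idx],
                      shown = abs(delta[idx]) >= display_threshold,
                      stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$delta)), ]
  rownames(edges) <- NULL
  structure(list(delta = delta, edges = edges,
                 node_sizes = b$gene_counts,
                 display_threshold = display_threshold),
            class = "chrom_differential")
}

#' @export
print.chrom_differential <- function(x, ...) {
  cat("Differential chromosome network:", nrow(x$delta), "chromosomes;",
      sum(x$edges$shown), "edge(s) above display threshold",
      x$display_threshold, "\n")
  print(utils::head(x$edges, 5))
  invisible(x)
}

#' Top inter-chromosomal gene pairs
#'
#' The n inter-chromosomal gene pairs with the largest CGP values
#' (spatially closest beyond the null), ties broken lexicographically by
#' gene ids.
#'
#' @param B a \code{cgp_fit} or CGP matrix with \code{chrom} attribute.
#' @param n number of pairs (all available pairs if fewer).
#' @param chrom per-gene chromosomes (override).
#' @return data.frame: gene_i, gene_j, chrom_i, chrom_j, B (sorted
#'   decreasing).
#' @export
top_inter_pairs <- function(B, n = 20L, chrom = NULL) {
  bw <- bw_from(B)
  Bm <- bw$B
  if (is.null(chrom))
    chrom <- if (!is.null(bw$fit)) bw$fit$gbmap$chrom else attr(B, "chrom")
  if (is.null(chrom)) stop("per-gene chromosomes required")
  chrom <- as.character(chrom)
  if (length(unique(chrom)) < 2) stop("need genes on at least 2 chromosomes")
  ids <- rownames(Bm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Bm)))
  inter <- upper.tri(Bm) & outer(chrom, chrom, "!=")
  idx <- which(inter, arr.ind = TRUE)
  gi <- ids[idx[, 1]]; gj <- ids[idx[, 2]]
  ci <- chrom[idx[, 1]]; cj <- chrom[idx[, 2]]
  swap <- gi > gj                       # canonical pair order for ties
  tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
  tmp <- ci[swap]; ci[swap] <- cj[swap]; cj[swap] <- tmp
  val <- Bm[idx]
  ord <- order(-val, gi, gj)
  take <- utils::head(ord, n)
  data.frame(gene_i = gi[take], gene_j = gj[take],
             chrom_i = ci[take], chrom_j = cj[take],
             B = val[take], stringsAsFactors = FALSE)
}
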