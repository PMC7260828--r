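#' Fit the corrected gene proximity model
#'
#' The one-stop fitting function: maps genes to contact-map bins, extracts
#' the gene proximity matrix W, estimates the distance-decay profile
#' f (intra) and the inter-chromosomal background (inter), solves the
#' per-gene visibilities k under the row-sum constraints
#' \eqn{\sum_j E_{ij} = \sum_j W_{ij}}, and returns the null expectation
#' \eqn{E_{ij} = k_i k_j f(d_{ij})} together with the corrected gene
#' proximity (CGP) matrix \eqn{B = W - E}.
#'
#' B is a generalized modularity matrix for the gene proximity network:
#' positive entries mean two genes are spatially closer than their genomic
#' distance and visibilities predict. Genomic distance between genes is
#' measured between their representative (midpoint) bins, in bin units.
#'
#' @param cmap a \code{contact_map} (balanced, e.g. ICE-corrected).
#' @param genes a \code{gene_table}.
#' @param tol relative row-sum tolerance for the visibility solver.
#' @param max_iter visibility solver iteration cap.
#' @return An object of class \code{cgp_fit} with components \code{W},
#'   \code{E}, \code{B}, \code{k}, \code{decay}, \code{visibility} (solver
#'   report), \code{gbmap}, \code{genes}, \code{binning}, \code{call}.
#' @seealso [compute_Q()], [gene_set_tightness()], [reduce_to_chromosomes()]
#' @examples
#' sim <- simulate_contact_map(n_chrom = 2, bins_per_chrom = 30, seed = 1)
#' ge <- simulate_genes_and_expression(sim$truth, genes_per_chrom = 15, seed = 2)
#' fit <- cgp_fit(sim$cmap, ge$genes)
#' fit
#' range(rowSums(residuals(fit)))  # conservation: ~0
#' @export
cgp_fit <- function(cmap, genes, tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(cmap, "contact_map"), inherits(genes, "gene_table"))
  gbmap <- map_genes_to_bins(genes, cmap$binning)
  W <- build_gene_proximity(cmap, gbmap)
  decay <- estimate_f_intra(cmap)
  if (length(cmap$binning$chrom_names) > 1)
    decay$f_inter <- estimate_f_inter(cmap)
  vis <- solve_visibilities(W, decay, tol = tol, max_iter = max_iter)
  E <- build_expected(vis, decay, gbmap$rep_bin, gbmap$chrom)
  B <- compute_cgp(W, E, tol = tol)
  structure(list(W = W, E = E, B = B, k = vis$k, decay = decay,
                 visibility = vis, gbmap = gbmap, genes = gbmap$genes,
                 binning = cmap$binning, tol = tol, call = match.call()),
            class = "cgp_fit")
}

#' @export
print.cgp_fit <- function(x, ...) {
  cat("Corrected gene proximity (CGP) fit\n")
  cat("  genes:", length(x$k), "on", length(unique(x$gbmap$chrom)),
      "chromosome(s); bin size", x$binning$bin_size, "bp\n")
  cat("  visibility solver:", x$visibility$iterations,
      "iterations, max relative row residual",
      format(x$visibility$residual, digits = 3), "\n")
  cat("  f_inter:", format(x$decay$f_inter, digits = 4),
      " f_intra(1):", format(x$decay$f_intra[2], digits = 4), "\n")
  invisible(x)
}

#' @export
summary.cgp_fit <- function(object, ...) {
  B <- unclass(object$B)
  W <- unclass(object$W)
  s <- rowSums(W)
  out <- list(
    n_genes = length(object$k),
    n_chrom = length(unique(object$gbmap$chrom)),
    iterations = object$visibility$iterations,
    residual = object$visibility$residual,
    max_row_residual = max(abs(rowSums(B)) / pmax(s, 1e-12)),
    total_B = sum(B),
    B_quantiles = stats::quantile(B[upper.tri(B)],
                                  c(0, 0.25, 0.5, 0.75, 1)),
    k_summary = summary(object$k),
    f_inter = object$decay$f_inter)
  class(out) <- "summary.cgp_fit"
  out
}

#' @export
print.summary.cgp_fit <- function(x, ...) {
  cat("CGP fit:", x$n_genes, "genes,", x$n_chrom, "chromosome(s)\n")
  cat("Solver:", x$iterations, "iterations; max relative row residual",
      format(x$max_row_residual, digits = 3), "\n")
  cat("Sum of B (should be ~0):", format(x$total_B, digits = 3), "\n")
  cat("Off-diagonal B quantiles:\n")
  print(x$B_quantiles)
  cat("Visibilities k:\n")
  print(x$k_summary)
  invisible(x)
}

#' @export
coef.cgp_fit <- function(object, ...) object$k

#' @export
fitted.cgp_fit <- function(object, ...) object$E

#' Residuals of a CGP fit
#'
#' The residual matrix of the null model is exactly the CGP matrix
#' B = W - E.
#' @param object a \code{cgp_fit}.
#' @param ... unused.
#' @export
residuals.cgp_fit <- function(object, ...) object$B

#' Predict expected contacts for gene pairs
#'
#' @param object a \code{cgp_fit}.
#' @param newdata data.frame with columns \code{gene_i}, \code{gene_j}
#'   naming genes in the fit; if missing, the full E matrix is returned.
#' @param ... unused.
#' @return numeric vector of expected contacts (or E).
#' @export
predict.cgp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$E)
  stopifnot(all(c("gene_i", "gene_j") %in% names(newdata)))
  ids <- names(object$k)
  bad <- setdiff(unique(c(newdata$gene_i, newdata$gene_j)), ids)
  if (length(bad)) stop("unknown gene id(s): ", paste(bad, collapse = ", "))
  object$E[cbind(match(newdata$gene_i, ids), match(newdata$gene_j, ids))]
}

#' Simulate gene proximity matrices from the fitted null
#'
#' Parametric bootstrap: symmetric Poisson draws with mean E (upper
#' triangle sampled, mirrored; diagonal kept zero).
#'
#' @param object a \code{cgp_fit}.
#' @param nsim number of replicate matrices.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of \code{nsim} matrices.
#' @export
simulate.cgp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  E <- unclass(object$E)
  G <- nrow(E)
  ut <- upper.tri(E)
  lambda <- E[ut]
  lapply(seq_len(nsim), function(r) {
    m <- matrix(0, G, G, dimnames = dimnames(E))
    m[ut] <- stats::rpois(length(lambda), lambda)
    m + t(m)
  })
}

#' Plot the fitted distance-decay profile
#'
#' Log-log plot of the smoothed, monotone f_intra against genomic distance
#' (bin units), with the raw per-distance means overlaid and the
#' inter-chromosomal background as a horizontal line.
#'
#' @param x a \code{cgp_fit} or \code{decay_profile}.
#' @param ... passed to \code{plot}.
#' @export
plot.cgp_fit <- function(x, ...) plot(x$decay, ...)

#' @rdname plot.cgp_fit
#' @export
plot.decay_profile <- function(x, ...) {
  d <- seq_len(x$dmax)
  graphics::plot(d, x$f_intra[d + 1L], type = "l", log = "xy",
                 xlab = "genomic distance (bins)",
                 ylab = "mean contact frequency f(d)", ...)
  ok <- !is.na(x$raw) & x$raw > 0
  graphics::points(which(ok) - 1L, x$raw[ok], pch = 16, cex = 0.4,
                   col = "grey50")
  if (!is.na(x$f_inter) && x$f_inter > 0)
    graphics::abline(h = x$f_inter, lty = 2, col = "red")
  invisible(x)
}
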