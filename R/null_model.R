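#' Estimate the intra-chromosomal distance-decay profile
#'
#' For every genomic distance d (in bin units) the raw expectation f(d) is
#' the average contact frequency over all intra-chromosomal bin pairs
#' separated by d, pooled genome-wide. Raw means are then smoothed with
#' log-spaced windows (half-width growing as floor(0.1 d), so short
#' distances keep their raw means) and clamped to
#' be non-increasing by pool-adjacent-violators, reflecting the monotone
#' decay of contact frequency with genomic distance. Distances with no
#' observations inherit the nearest smaller-distance value.
#'
#' @param cmap a \code{contact_map}.
#' @return object of class \code{decay_profile}: \code{f_intra} (numeric,
#'   index t holds f at distance t-1), \code{raw}, \code{counts},
#'   \code{f_inter} (NA until set), \code{dmax}.
#' @export
estimate_f_intra <- function(cmap) {
  stopifnot(inherits(cmap, "contact_map"))
  b <- cmap$binning
  M <- cmap$matrix
  dmax <- max(b$bins_per_chrom) - 1L
  if (dmax < 1) stop("no intra-chromosomal pairs at any distance >= 1")
  sums <- numeric(dmax + 1L)
  counts <- integer(dmax + 1L)
  for (ch in b$chrom_names) {
    nb <- b$bins_per_chrom[[ch]]
    o <- b$chrom_offset[[ch]]
    for (d in 0:(nb - 1L)) {
      i <- o + seq_len(nb - d)
      v <- M[cbind(i, i + d)]
      sums[d + 1L] <- sums[d + 1L] + sum(v)
      counts[d + 1L] <- counts[d + 1L] + length(v)
    }
  }
  raw <- ifelse(counts > 0, sums / counts, NA_real_)
  sm <- smooth_decay(raw)
  # isotonic non-increasing clamp (PAVA on negated values)
  ok <- !is.na(sm)
  if (!any(ok)) stop("decay profile empty")
  iso <- sm
  iso[ok] <- -stats::isoreg(which(ok), -sm[ok])$yf
  # distances never observed inherit the nearest smaller-d value
  for (t in seq_along(iso)) if (is.na(iso[t])) iso[t] <- iso[t - 1L]
  structure(list(f_intra = iso, raw = raw, counts = counts,
                 f_inter = NA_real_, dmax = dmax),
            class = "decay_profile")
}

# log-spaced window smoothing: value at distance d is the mean of raw means
# over distances within floor(0.1*d) of d, so short distances (d < 10) keep
# their raw means and windows widen proportionally at long range. d = 0
# (self-bin contacts, a different regime) never enters a d >= 1 window.
smooth_decay <- function(raw) {
  n <- length(raw)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    d <- t - 1L
    h <- as.integer(floor(0.1 * d))
    w <- max(2L, t - h):min(n, t + h)
    if (d == 0L) w <- 1L
    v <- raw[w]
    if (any(!is.na(v))) out[t] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Estimate the inter-chromosomal background
#'
#' Mean contact frequency over all bin pairs on different chromosomes,
#' each unordered pair counted once.
#'
#' @param cmap a \code{contact_map}.
#' @return non-negative scalar.
#' @export
estimate_f_inter <- function(cmap) {
  stopifnot(inherits(cmap, "contact_map"))
  b <- cmap$binning
  if (length(b$chrom_names) < 2)
    stop("inter-chromosomal background undefined for a single chromosome")
  same <- outer(b$bin_chrom, b$bin_chrom, "==")
  inter <- upper.tri(cmap$matrix) & !same
  fi <- mean(cmap$matrix[inter])
  if (fi == 0) warning("all inter-chromosomal contacts are zero")
  fi
}

#' Evaluate the decay profile
#'
#' @param decay a \code{decay_profile} (with \code{f_inter} set when
#'   inter-chromosomal pairs are queried).
#' @param d integer distances in bin units.
#' @param intra logical, same length or length 1: same-chromosome pair?
#' @return numeric expectations.
#' @export
decay_at <- function(decay, d, intra = TRUE) {
  stopifnot(inherits(decay, "decay_profile"))
  intra <- rep_len(intra, length(d))
  out <- numeric(length(d))
  if (any(intra)) {
    di <- d[intra]
    if (any(di > decay$dmax)) stop("distance beyond decay profile range")
    out[intra] <- decay$f_intra[di + 1L]
  }
  if (any(!intra)) {
    if (is.na(decay$f_inter))
      stop("decay profile has no inter-chromosomal constant")
    out[!intra] <- decay$f_inter
  }
  out
}

# G x G matrix of f(d_ij) from representative bins and chromosomes,
# zero diagonal
decay_matrix <- function(decay, rep_bin, chrom) {
  D <- abs(outer(rep_bin, rep_bin, "-"))
  same <- outer(chrom, chrom, "==")
  Fm <- matrix(decay$f_inter, nrow(D), ncol(D))
  if (any(same)) Fm[same] <- decay$f_intra[D[same] + 1L]
  diag(Fm) <- 0
  Fm
}

#' Solve per-gene visibilities under row-sum constraints
#'
#' Finds k >= 0 such that the null expectation E[i,j] = k_i k_j f(d_ij)
#' reproduces every gene's observed total contacts:
#' sum_j E[i,j] = sum_j W[i,j]. The decay profile is first rescaled once so
#' that, at the initialization k_i = sqrt(sum_j W[i,j]), total expected and
#' observed contacts match (f is only defined up to a constant). Iteration:
#' k_i <- s_i / sum_j k_j f(d_ij), with geometric damping
#' k <- sqrt(k_new * k_old) to prevent oscillation. Genes with zero total
#' contacts get k = 0 and are excluded from the update.
#'
#' @param W gene proximity matrix (a \code{gene_proximity} or plain
#'   symmetric matrix).
#' @param decay \code{decay_profile} with \code{f_inter} set if needed.
#' @param rep_bin,chrom per-gene representative bin and chromosome; default
#'   taken from attributes of \code{W}.
#' @param tol maximum relative row-sum residual accepted.
#' @param max_iter iteration cap; exceeding it raises a condition of class
#'   \code{cgp_convergence_error} carrying the residual trace.
#' @return list of class \code{visibility_vector}: \code{k} (named),
#'   \code{f_scale} (the one-off rescaling applied to f),
#'   \code{iterations}, \code{residual}, \code{trace}.
#' @export
solve_visibilities <- function(W, decay,
                               rep_bin = attr(W, "rep_bin"),
                               chrom = attr(W, "chrom"),
                               tol = 1e-6, max_iter = 1000L) {
  stopifnot(tol > 0, !is.null(rep_bin), !is.null(chrom))
  W <- unclass(W)
  s <- rowSums(W)
  if (all(s == 0)) stop("all genes have zero contacts")
  Fm <- decay_matrix(decay, rep_bin, chrom)
  k <- sqrt(s)
  active <- s > 0
  # one-off normalization of f: match total contacts at the initialization
  tot <- drop(crossprod(k, Fm %*% k))
  if (tot <= 0) stop("null expectation identically zero; cannot rescale f")
  f_scale <- sum(s) / tot
  Fm <- Fm * f_scale
  eps <- 1e-12
  trace <- numeric(0)
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    denom <- drop(Fm %*% k)
    res <- max(abs(k * denom - s)[active] / pmax(s[active], eps))
    trace <- c(trace, res)
    if (res <= tol) break
    it <- it + 1L
    k_new <- k
    k_new[active] <- s[active] / pmax(denom[active], eps)
    k <- sqrt(k_new * k)       # geometric damping
    k[!active] <- 0
  }
  if (res > tol) {
    cond <- structure(
      class = c("cgp_convergence_error", "error", "condition"),
      list(message = sprintf(
        "visibility solver did not reach tol %.1e in %d iterations (residual %.3e)",
        tol, max_iter, res), call = sys.call(-1), trace = trace))
    stop(cond)
  }
  structure(list(k = stats::setNames(k, rownames(W)), f_scale = f_scale,
                 iterations = it, residual = res, trace = trace),
            class = "visibility_vector")
}

#' @export
print.visibility_vector <- function(x, ...) {
  cat("Visibility vector:", length(x$k), "genes,", x$iterations,
      "iterations, residual", format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' Build the null expected matrix E
#'
#' E[i,j] = k_i k_j f(d_ij), using the intra decay for same-chromosome
#' pairs and the inter constant otherwise; zero diagonal. The f rescaling
#' fixed during the visibility solve is applied automatically when
#' \code{k} is a \code{visibility_vector}.
#'
#' @param k a \code{visibility_vector} (or plain non-negative vector, in
#'   which case no rescaling is applied).
#' @param decay \code{decay_profile}.
#' @param rep_bin,chrom per-gene representative bins and chromosomes.
#' @return symmetric matrix of class \code{null_expected}.
#' @export
build_expected <- function(k, decay, rep_bin, chrom) {
  scale <- 1
  if (inherits(k, "visibility_vector")) {
    scale <- k$f_scale
    k <- k$k
  }
  Fm <- decay_matrix(decay, rep_bin, chrom) * scale
  E <- Fm * tcrossprod(k)
  dimnames(E) <- list(names(k), names(k))
  structure(E, class = c("null_expected", "matrix"))
}

#' Corrected gene proximity matrix B = W - E
#'
#' The CGP matrix is the observed gene proximity minus the 1D-distance
#' null expectation: a generalized modularity matrix whose entries measure
#' cell-type-specific 3D proximity. Row sums of B must vanish (the null
#' conserves each gene's total contacts); a violation beyond 10x the
#' solver tolerance signals an unconverged or mismatched E.
#'
#' @param W gene proximity matrix.
#' @param E matching null expected matrix.
#' @param tol solver tolerance used for the integrity check.
#' @return matrix of class \code{cgp_matrix} (gene ids as dimnames,
#'   \code{chrom}/\code{rep_bin} attributes propagated from W).
#' @export
compute_cgp <- function(W, E, tol = 1e-6) {
  if (!all(dim(W) == dim(E))) stop("W and E shapes differ")
  if (!is.null(rownames(W)) && !is.null(rownames(E)) &&
      !identical(rownames(W), rownames(E)))
    stop("gene order mismatch between W and E")
  B <- unclass(W) - unclass(E)
  s <- rowSums(unclass(W))
  rel <- abs(rowSums(B)) / pmax(s, 1e-12)
  if (max(rel[s > 0]) > 10 * tol)
    stop("CGP row sums violate conservation (max relative residual ",
         format(max(rel[s > 0]), digits = 3), "); E unconverged or mismatched?")
  structure(B, class = c("cgp_matrix", "matrix"),
            chrom = attr(W, "chrom"), rep_bin = attr(W, "rep_bin"))
}
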