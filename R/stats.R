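# Expression-aware statistics on the CGP matrix: co-expression, the
# co-regulation objective Q and its permutation nulls, Monte Carlo
# maximization, gene-set tightness, and eigenvector features.

# accept either a cgp_fit or raw matrices for (B, W); the CGP matrix has a
# zero diagonal by convention, enforced here for arbitrary matrix input
bw_from <- function(B, W = NULL) {
  if (inherits(B, "cgp_fit")) return(list(B = unclass(B$B), W = unclass(B$W),
                                          fit = B))
  Bm <- unclass(B)
  diag(Bm) <- 0
  list(B = Bm, W = if (is.null(W)) NULL else unclass(W), fit = NULL)
}

#' Gene co-expression matrix
#'
#' C[i,j] is the product of the log2 expression values of genes i and j;
#' zero-expressed genes get a fixed negative floor, so positive C means
#' "same state" (both active or both inactive) and negative C means
#' opposite states. The diagonal is zeroed for use in correlations.
#'
#' @param expr an \code{expression_profile} (named, linear scale).
#' @param zero_floor log-value assigned to zero expression (negative).
#' @return symmetric matrix of class \code{coexpression} with attribute
#'   \code{log_values}.
#' @export
build_coexpression <- function(expr, zero_floor = -4) {
  stopifnot(is.numeric(expr), !is.null(names(expr)), zero_floor < 0)
  l <- ifelse(expr > 0, log2(expr), zero_floor)
  C <- tcrossprod(l)
  diag(C) <- 0
  dimnames(C) <- list(names(expr), names(expr))
  structure(C, class = c("coexpression", "matrix"),
            log_values = stats::setNames(as.numeric(l), names(expr)))
}

#' Pearson correlation between two gene-pair matrices
#'
#' Correlates the strict upper-triangle entries of A (e.g. the CGP matrix B
#' or the raw proximity W) with a co-expression matrix, optionally per
#' chromosome and optionally restricted to pairs within a genomic distance.
#'
#' @param A symmetric gene x gene matrix with gene ids as dimnames;
#'   \code{chrom}/\code{rep_bin} attributes (as on \code{cgp_matrix} /
#'   \code{gene_proximity}) are used for per-chromosome and distance masks,
#'   or supply \code{chrom}/\code{rep_bin} explicitly.
#' @param Cm matching matrix (same gene order).
#' @param per_chromosome if TRUE, return one r per chromosome computed over
#'   same-chromosome pairs.
#' @param max_distance optional distance mask (bin units); pairs farther
#'   apart, and inter-chromosomal pairs, are excluded.
#' @param chrom,rep_bin per-gene metadata overriding the attributes of A.
#' @return a single r, or a named vector per chromosome; NA where fewer
#'   than 3 pairs remain.
#' @export
matrix_correlation <- function(A, Cm, per_chromosome = FALSE,
                               max_distance = NULL,
                               chrom = attr(A, "chrom"),
                               rep_bin = attr(A, "rep_bin")) {
  A <- unclass(A); Cm <- unclass(Cm)
  stopifnot(all(dim(A) == dim(Cm)))
  if (!is.null(rownames(A)) && !is.null(rownames(Cm)) &&
      !identical(rownames(A), rownames(Cm)))
    stop("gene order mismatch between matrices")
  ut <- upper.tri(A)
  keep <- ut
  if (!is.null(max_distance)) {
    if (is.null(chrom) || is.null(rep_bin))
      stop("distance mask needs chrom and rep_bin")
    same <- outer(chrom, chrom, "==")
    D <- abs(outer(rep_bin, rep_bin, "-"))
    keep <- keep & same & D <= max_distance
  }
  safe_cor <- function(m) if (sum(m) < 3) NA_real_ else
    stats::cor(A[m], Cm[m])
  if (!per_chromosome) return(safe_cor(keep))
  if (is.null(chrom)) stop("per-chromosome correlation needs chrom")
  vapply(unique(chrom), function(ch) {
    onchr <- chrom == ch
    safe_cor(keep & outer(onchr, onchr, "&"))
  }, numeric(1))
}

#' Binarize expression into ON/OFF states
#'
#' Fits a two-component Gaussian mixture to the log2 expression values
#' (zeros floored); the cluster with the higher mean is ON (+1), the other
#' OFF (-1). Degenerate fits (one empty component, or fewer than two
#' distinct values) fall back to a median split with a warning.
#'
#' @param expr an \code{expression_profile}.
#' @param zero_floor log-value for zero expression.
#' @param seed optional integer seed (the GMM fit is deterministic given
#'   the data, but a seed keeps the call reproducible by convention).
#' @return named vector of +1/-1 of class \code{expression_states}, with
#'   attributes \code{on_fraction}, \code{means} and \code{method}.
#' @export
binarize_expression <- function(expr, zero_floor = -4, seed = NULL) {
  stopifnot(is.numeric(expr), !is.null(names(expr)))
  if (!is.null(seed)) set.seed(seed)
  l <- ifelse(expr > 0, log2(expr), zero_floor)
  x <- NULL
  method <- "gmm"
  if (length(unique(l)) >= 2) {
    fit <- tryCatch(
      local({
        # Mclust resolves mclustBIC in the calling frame
        mclustBIC <- mclust::mclustBIC
        mclust::Mclust(l, G = 2, verbose = FALSE)
      }),
      error = function(e) NULL)
    if (!is.null(fit) && length(unique(fit$classification)) == 2) {
      mu <- fit$parameters$mean
      on_cluster <- which.max(mu)
      x <- ifelse(fit$classification == on_cluster, 1, -1)
      means <- sort(mu)
    }
  }
  if (is.null(x)) {
    warning("degenerate expression distribution; falling back to median split")
    method <- "median"
    x <- ifelse(l > stats::median(l), 1, -1)
    means <- c(low = min(l), high = max(l))
  }
  structure(stats::setNames(as.numeric(x), names(expr)),
            class = "expression_states",
            on_fraction = mean(x == 1), means = means, method = method)
}

#' Co-regulation objective Q
#'
#' \deqn{Q = \frac{1}{\sum_{ij} W_{ij}} \sum_{ij} B_{ij} x_i x_j}
#' with both (i,j) and (j,i) counted and the diagonal excluded. Q measures
#' how strongly same-state (ON/ON or OFF/OFF) genes sit closer in 3D than
#' the distance null predicts; it is 0 in expectation when states are
#' placed at random, and invariant under a global sign flip of x.
#'
#' @param B a \code{cgp_fit}, or the CGP matrix.
#' @param W gene proximity matrix (ignored when B is a fit).
#' @param x vector of +1/-1 expression states, in matrix gene order (a
#'   named \code{expression_states} is matched by name when dimnames exist).
#' @return scalar Q.
#' @export
compute_Q <- function(B, W = NULL, x) {
  bw <- bw_from(B, W)
  if (is.null(bw$W)) stop("W required")
  x <- align_states(x, rownames(bw$B))
  sw <- sum(bw$W)
  if (sw <= 0) stop("sum of W must be positive")
  as.numeric(crossprod(x, bw$B %*% x)) / sw
}

align_states <- function(x, ids) {
  xv <- as.numeric(x)
  if (!is.null(names(x)) && !is.null(ids)) {
    if (!all(ids %in% names(x))) stop("states missing for some genes")
    xv <- as.numeric(x[ids])
  }
  if (!all(xv %in% c(-1, 1))) stop("states must be +1/-1")
  xv
}

#' Permutation test for Q
#'
#' Generates an ensemble of randomized gene configurations in which the
#' spatial locations of genes are shuffled (equivalently, the ON/OFF
#' labels are reassigned to matrix positions) and recomputes Q on each.
#' Schemes: \code{global} shuffles across all genes; \code{within_compartment}
#' shuffles separately inside A and B compartments;
#' \code{within_tad} shuffles separately inside each TAD;
#' \code{permuted_tad} first permutes the TAD blocks along each chromosome
#' (preserving the block-size multiset) and then shuffles genes within the
#' permuted blocks. Genes not covered by a TAD become singleton blocks
#' (with a warning).
#'
#' @param fit a \code{cgp_fit} (needed for gene coordinates under domain
#'   schemes; for \code{global} a \code{cgp_matrix} plus \code{W} works too).
#' @param x expression states (+1/-1).
#' @param scheme randomization scheme.
#' @param domains a \code{domain_annotation} (compartments or TADs) for the
#'   domain-preserving schemes.
#' @param n number of randomizations (>= 100).
#' @param seed integer seed.
#' @param W proximity matrix when \code{fit} is a plain matrix.
#' @return object of class \code{q_result}: \code{Q}, \code{null} (n
#'   values), \code{z}, \code{p} (empirical, (r+1)/(n+1)), \code{scheme}.
#' @export
q_permutation_test <- function(fit, x,
                               scheme = c("global", "within_compartment",
                                          "within_tad", "permuted_tad"),
                               domains = NULL, n = 1000L, seed = NULL,
                               W = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 100)
  bw <- bw_from(fit, W)
  B <- bw$B
  if (is.null(bw$W)) stop("W required")
  sw <- sum(bw$W)
  x <- align_states(x, rownames(B))
  G <- length(x)
  if (!is.null(seed)) set.seed(seed)
  blocks <- permutation_blocks(scheme, bw$fit, domains, G)
  q_of <- function(xv) as.numeric(crossprod(xv, B %*% xv)) / sw
  Q_emp <- q_of(x)
  null <- vapply(seq_len(n), function(r) {
    q_of(permute_states(x, scheme, blocks, G))
  }, numeric(1))
  sdn <- stats::sd(null)
  z <- if (sdn > 0) (Q_emp - mean(null)) / sdn else 0
  p <- (sum(null >= Q_emp) + 1) / (n + 1)
  structure(list(Q = Q_emp, null = null, z = z, p = p, scheme = scheme,
                 n = n), class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat("Q =", format(x$Q, digits = 4), " [", x$scheme, "null, n =", x$n,
      "]  z =", format(x$z, digits = 3), " p =", format(x$p, digits = 3), "\n")
  invisible(x)
}

# resolve the block structure a scheme shuffles within
permutation_blocks <- function(scheme, fit, domains, G) {
  if (scheme == "global") return(NULL)
  if (is.null(fit)) stop("domain schemes need a cgp_fit")
  genes <- fit$genes
  if (scheme == "within_compartment") {
    if (is.null(domains) || attr(domains, "kind") != "compartment")
      stop("within_compartment needs a compartment domain_annotation")
    lab <- domain_of(genes, domains)
    lab[is.na(lab)] <- "unassigned"
    return(list(groups = split(seq_len(G), lab)))
  }
  if (is.null(domains) || attr(domains, "kind") != "tad")
    stop("TAD schemes need a TAD domain_annotation")
  tad <- domain_of(genes, domains)
  if (anyNA(tad)) {
    warning(sum(is.na(tad)), " gene(s) outside any TAD; using singleton blocks")
    tad[is.na(tad)] <- paste0(".singleton", which(is.na(tad)))
  }
  if (scheme == "within_tad") return(list(groups = split(seq_len(G), tad)))
  # permuted_tad: per chromosome, blocks ordered along the chromosome
  pos <- fit$gbmap$rep_bin
  by_chrom <- lapply(split(seq_len(G), genes$chrom), function(idx) {
    idx <- idx[order(pos[idx])]
    bl <- split(idx, factor(tad[idx], levels = unique(tad[idx])))
    list(slots = idx, blocks = unname(bl))
  })
  list(by_chrom = by_chrom)
}

# midpoint-based domain membership; returns label (or TAD id) per gene
domain_of <- function(genes, domains) {
  mid <- floor((genes$start + genes$end) / 2)
  out <- rep(NA_character_, nrow(genes))
  for (r in seq_len(nrow(domains))) {
    hit <- genes$chrom == domains$chrom[r] &
      mid >= domains$start[r] & mid < domains$end[r]
    out[hit] <- domains$label[r]
  }
  out
}

permute_states <- function(x, scheme, blocks, G) {
  if (scheme == "global") return(x[sample.int(G)])
  if (scheme %in% c("within_compartment", "within_tad")) {
    xp <- x
    for (g in blocks$groups) xp[g] <- x[g[sample.int(length(g))]]
    return(xp)
  }
  # permuted_tad
  xp <- x
  for (ch in blocks$by_chrom) {
    bl <- ch$blocks[sample.int(length(ch$blocks))]
    donors <- unlist(lapply(bl, function(b) b[sample.int(length(b))]),
                     use.names = FALSE)
    xp[ch$slots] <- x[donors]
  }
  xp
}

#' Monte Carlo maximization of Q
#'
#' Hill climbing over the placement of expression states: each step picks a
#' random ON gene and a random OFF gene and swaps their locations in the
#' network; the swap is kept only if Q increases. The ON count is
#' preserved and the accepted-Q trajectory is non-decreasing.
#'
#' @param B a \code{cgp_fit} or CGP matrix.
#' @param W proximity matrix when B is a matrix.
#' @param x0 starting states (+1/-1).
#' @param n_steps number of proposed swaps (>= 1).
#' @param seed integer seed.
#' @return list of class \code{q_mc}: \code{x_best}, \code{trajectory}
#'   (Q after each accepted swap, starting value first), \code{Q_final},
#'   \code{n_accepted}.
#' @export
monte_carlo_maximize_Q <- function(B, W = NULL, x0, n_steps, seed = NULL) {
  stopifnot(n_steps >= 1)
  bw <- bw_from(B, W)
  Bm <- bw$B
  if (is.null(bw$W)) stop("W required")
  sw <- sum(bw$W)
  x <- align_states(x0, rownames(Bm))
  ids <- rownames(Bm)
  dimnames(Bm) <- NULL          # keep the hot loop free of name propagation
  if (!is.null(seed)) set.seed(seed)
  g <- as.numeric(Bm %*% x)
  qt <- as.numeric(crossprod(x, g))       # Q * sum(W)
  traj <- qt / sw
  n_acc <- 0L
  on <- which(x == 1)
  off <- which(x == -1)
  if (length(on) && length(off)) {
    for (step in seq_len(n_steps)) {
      i <- on[sample.int(length(on), 1L)]
      j <- off[sample.int(length(off), 1L)]
      dq <- -4 * x[i] * g[i] - 4 * x[j] * g[j] - 8 * Bm[i, j]
      if (dq > 0) {
        g <- g - 2 * x[i] * Bm[, i] - 2 * x[j] * Bm[, j]
        x[i] <- -1; x[j] <- 1
        on[on == i] <- j
        off[off == j] <- i
        qt <- qt + dq
        n_acc <- n_acc + 1L
        traj <- c(traj, qt / sw)
      }
    }
  }
  names(x) <- ids
  structure(list(x_best = x, trajectory = traj, Q_final = qt / sw,
                 n_accepted = n_acc), class = "q_mc")
}

#' Gene-set tightness
#'
#' The raw tightness of a gene set p is \eqn{b_p = \sum_{i,j \in p} B_{ij}}
#' (ordered pairs, zero diagonal). Its null distribution comes from
#' size-matched gene sets drawn uniformly at random without replacement
#' from all genes; the normalized tightness is the z-score
#' \eqn{T_p = (b_p - \mu_p)/\sigma_p}. High T means the set is spatially
#' tighter than random same-size sets.
#'
#' @param B a \code{cgp_fit} or CGP matrix.
#' @param gene_set character vector of gene ids (or integer indices).
#' @param n_rand number of random sets (ignored when exhaustive).
#' @param seed integer seed.
#' @param exhaustive enumerate all same-size subsets instead of sampling
#'   (population SD used); only for small instances.
#' @return object of class \code{tightness_result}: \code{n_p}, \code{b},
#'   \code{mu}, \code{sigma}, \code{T}, \code{n_rand}, \code{null} (the
#'   null sample), \code{degenerate}, \code{exhaustive}.
#' @export
gene_set_tightness <- function(B, gene_set, n_rand = 5000L, seed = NULL,
                               exhaustive = FALSE) {
  bw <- bw_from(B)
  Bm <- bw$B
  G <- nrow(Bm)
  idx <- set_indices(gene_set, rownames(Bm))
  if (length(idx) < 2) stop("gene set must contain at least 2 genes")
  b <- sum(Bm[idx, idx])
  if (exhaustive) {
    combos <- utils::combn(G, length(idx))
    null <- apply(combos, 2, function(s) sum(Bm[s, s]))
    mu <- mean(null)
    sigma <- sqrt(mean((null - mu)^2))   # population SD: full enumeration
    n_used <- ncol(combos)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_rand), function(r) {
      s <- sample.int(G, length(idx))
      sum(Bm[s, s])
    }, numeric(1))
    mu <- mean(null)
    sigma <- stats::sd(null)
    n_used <- n_rand
  }
  degenerate <- !is.finite(sigma) || sigma == 0
  T_p <- if (degenerate) 0 else (b - mu) / sigma
  structure(list(n_p = length(idx), b = b, mu = mu, sigma = sigma, T = T_p,
                 n_rand = n_used, null = null, degenerate = degenerate,
                 exhaustive = exhaustive),
            class = "tightness_result")
}

#' @export
print.tightness_result <- function(x, ...) {
  cat("Gene-set tightness: n =", x$n_p, " b =", format(x$b, digits = 4),
      " T =", format(x$T, digits = 4),
      if (x$degenerate) "(degenerate null)" else "", "\n")
  invisible(x)
}

set_indices <- function(gene_set, ids) {
  if (is.numeric(gene_set)) {
    if (any(gene_set < 1 | gene_set > length(ids)))
      stop("gene index out of range")
    return(unique(as.integer(gene_set)))
  }
  if (is.null(ids)) stop("matrix has no gene ids; pass integer indices")
  bad <- setdiff(gene_set, ids)
  if (length(bad))
    stop("unknown gene id(s): ", paste(utils::head(bad, 10), collapse = ", "))
  match(unique(gene_set), ids)
}

#' Tightness change between two conditions
#'
#' For each named gene set, computes the tightness T in two CGP matrices
#' (e.g. two cell lines) over their shared gene universe and reports
#' \eqn{\Delta T = T_b - T_a}. Positive values mean the set is tighter in
#' condition b. The same random null sets are used in both conditions, so
#' identical inputs give exactly zero change.
#'
#' @param B_a,B_b CGP matrices (or \code{cgp_fit}s) with gene ids.
#' @param gene_sets named list of gene id vectors.
#' @param n_rand random sets per null.
#' @param seed integer seed.
#' @return data.frame: set, n_shared, T_a, T_b, delta_T (NA rows for sets
#'   with fewer than 2 shared genes).
#' @export
tightness_change <- function(B_a, B_b, gene_sets, n_rand = 5000L,
                             seed = NULL) {
  Ba <- bw_from(B_a)$B
  Bb <- bw_from(B_b)$B
  shared <- intersect(rownames(Ba), rownames(Bb))
  if (!length(shared)) stop("no shared genes between conditions")
  if (length(shared) < nrow(Ba) || length(shared) < nrow(Bb))
    message("using ", length(shared), " shared genes")
  Ba <- Ba[shared, shared]
  Bb <- Bb[shared, shared]
  G <- length(shared)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(names(gene_sets), function(nm) {
    idx <- match(intersect(gene_sets[[nm]], shared), shared)
    if (length(idx) < 2)
      return(data.frame(set = nm, n_shared = length(idx), T_a = NA_real_,
                        T_b = NA_real_, delta_T = NA_real_))
    nulls <- replicate(n_rand, sample.int(G, length(idx)), simplify = FALSE)
    t_of <- function(Bm) {
      b <- sum(Bm[idx, idx])
      nv <- vapply(nulls, function(s) sum(Bm[s, s]), numeric(1))
      sdn <- stats::sd(nv)
      if (sdn == 0) 0 else (b - mean(nv)) / sdn
    }
    ta <- t_of(Ba); tb <- t_of(Bb)
    data.frame(set = nm, n_shared = length(idx), T_a = ta, T_b = tb,
               delta_T = tb - ta)
  })
  do.call(rbind, res)
}

#' Leading eigenvectors of the CGP matrix
#'
#' Eigenpairs of the symmetric CGP matrix ordered by algebraically largest
#' eigenvalue; the per-gene components of the leading eigenvectors serve
#' as features (e.g. for compartment classification). Vectors are
#' unit-norm with a deterministic sign: the largest-magnitude component is
#' positive.
#'
#' @param B a \code{cgp_fit} or CGP matrix.
#' @param n_vec number of leading eigenvectors (<= number of genes).
#' @return list of class \code{cgp_eigen}: \code{values} (length n_vec),
#'   \code{vectors} (genes x n_vec, gene ids as rownames).
#' @export
leading_eigenvectors <- function(B, n_vec = 50L) {
  Bm <- bw_from(B)$B
  stopifnot(n_vec >= 1, n_vec <= nrow(Bm))
  if (max(abs(Bm - t(Bm))) > 1e-8) stop("B must be symmetric")
  e <- eigen((Bm + t(Bm)) / 2, symmetric = TRUE)
  vals <- e$values[seq_len(n_vec)]
  vecs <- e$vectors[, seq_len(n_vec), drop = FALSE]
  for (m in seq_len(n_vec)) {
    top <- which.max(abs(vecs[, m]))
    if (vecs[top, m] < 0) vecs[, m] <- -vecs[, m]
  }
  rownames(vecs) <- rownames(Bm)
  structure(list(values = vals, vectors = vecs), class = "cgp_eigen")
}
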