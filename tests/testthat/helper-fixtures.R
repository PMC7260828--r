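# Shared fixtures and independent oracles. Oracles here deliberately avoid
# the code paths they check: brute-force loops, enumeration, closed forms.

# small symmetric non-negative contact matrix on a given binning
random_contact_map <- function(binning, seed = 1, scale = 10) {
  set.seed(seed)
  n <- binning$n_bins
  m <- matrix(stats::runif(n * n, 0, scale), n, n)
  m <- (m + t(m)) / 2
  contact_map(m, binning)
}

# one single-bin gene per bin of a binning
genes_per_bin <- function(binning, prefix = "g") {
  n <- binning$n_bins
  start <- binning$bin_start
  gene_table(data.frame(
    gene_id = sprintf("%s%03d", prefix, seq_len(n)),
    chrom = binning$bin_chrom,
    start = start, end = start + binning$bin_size,
    strand = "*", stringsAsFactors = FALSE))
}

# the 4-gene worked example: two tight pairs, repulsive cross entries,
# total proximity 16; Q = 0.5 at x = (+,+,-,-)
toy4 <- function() {
  B <- matrix(-0.5, 4, 4)
  B[1, 2] <- B[2, 1] <- 1
  B[3, 4] <- B[4, 3] <- 1
  diag(B) <- 0
  W <- matrix(16 / 12, 4, 4)
  diag(W) <- 0
  ids <- paste0("t", 1:4)
  dimnames(B) <- dimnames(W) <- list(ids, ids)
  list(B = B, W = W, ids = ids)
}

# oracle: pool-adjacent-violators for a non-increasing fit (unweighted)
pava_nonincreasing <- function(y) {
  vals <- as.list(y)
  wts <- as.list(rep(1, length(y)))
  i <- 1
  while (i < length(vals)) {
    if (vals[[i]] < vals[[i + 1]] - 1e-15) {
      pooled <- (vals[[i]] * wts[[i]] + vals[[i + 1]] * wts[[i + 1]]) /
        (wts[[i]] + wts[[i + 1]])
      vals[[i]] <- pooled
      wts[[i]] <- wts[[i]] + wts[[i + 1]]
      vals[[i + 1]] <- NULL
      wts[[i + 1]] <- NULL
      if (i > 1) i <- i - 1
    } else {
      i <- i + 1
    }
  }
  unlist(mapply(function(v, w) rep(v, w), vals, wts, SIMPLIFY = FALSE))
}

# oracle: brute-force Q by double loop over ordered pairs, diagonal excluded
q_bruteforce <- function(B, W, x) {
  G <- length(x)
  acc <- 0
  for (i in seq_len(G)) for (j in seq_len(G)) {
    if (i != j) acc <- acc + B[i, j] * x[i] * x[j]
  }
  acc / sum(W)
}

# oracle: exhaustive maximum of Q over all ON/OFF assignments with the
# given ON count
q_exhaustive_max <- function(B, W, n_on) {
  G <- nrow(B)
  best <- -Inf
  combos <- utils::combn(G, n_on)
  for (c in seq_len(ncol(combos))) {
    x <- rep(-1, G)
    x[combos[, c]] <- 1
    best <- max(best, q_bruteforce(B, W, x))
  }
  best
}

# oracle: brute-force nonlinear solve of the visibility equations
# sum_{j != i} k_i k_j F[i,j] = s_i by minimizing squared residuals over
# log k from several starts (independent of the fixed-point iteration)
solve_k_bruteforce <- function(Fm, s) {
  obj <- function(logk) {
    k <- exp(logk)
    sum((k * drop(Fm %*% k) - s)^2)
  }
  grad <- function(logk) {
    k <- exp(logk)
    fk <- drop(Fm %*% k)
    r <- k * fk - s
    2 * k * (r * fk + drop(Fm %*% (r * k)))
  }
  best <- NULL
  for (start in list(log(sqrt(s)), rep(0, length(s)), log(sqrt(s)) + 0.5)) {
    o <- stats::optim(start, obj, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16))
    o <- stats::optim(o$par, obj, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16))
    if (is.null(best) || o$value < best$value) best <- o
  }
  unname(exp(best$par))
}

# tiny fitted instance reused across tests
tiny_fit <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      st <- simulate_cgp_study("tiny", seed = 404)
      memo <<- list(study = st, fit = cgp_fit(st$cmap, st$genes))
    }
    memo
  }
})
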