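# Co-expression, Q, permutation nulls, Monte Carlo, tightness, eigenvectors

test_that("co-expression products follow the sign conventions", {
  expr <- expression_profile(c(a = 4, b = 8, z1 = 0, z2 = 0))
  C <- build_coexpression(expr, zero_floor = -4)
  expect_equal(C["a", "b"], 6)          # log2(4) * log2(8) = 2 * 3
  expect_equal(C["z1", "z2"], 16)       # both inactive: (-4)^2 > 0
  expect_equal(C["a", "z1"], -8)        # opposite states: 2 * (-4) < 0
  expect_true(all(diag(C) == 0))
  l <- attr(C, "log_values")
  expect_equal(unname(l[c("a", "z1")]), c(2, -4))
})

test_that("matrix correlation matches a flat-vector Pearson oracle", {
  set.seed(21)
  ids <- paste0("g", 1:4)
  A <- matrix(rnorm(16), 4, 4); A <- A + t(A); diag(A) <- 0
  Cm <- matrix(rnorm(16), 4, 4); Cm <- Cm + t(Cm); diag(Cm) <- 0
  dimnames(A) <- dimnames(Cm) <- list(ids, ids)
  ut <- upper.tri(A)
  expect_equal(matrix_correlation(A, Cm), cor(A[ut], Cm[ut]))
  expect_equal(matrix_correlation(A, A), 1)
  expect_equal(matrix_correlation(A, -A), -1)
  # per-chromosome split and distance mask
  chrom <- c("chr1", "chr1", "chr1", "chr2")
  rep_bin <- c(1L, 2L, 9L, 20L)
  r <- matrix_correlation(A, Cm, per_chromosome = TRUE, chrom = chrom,
                          rep_bin = rep_bin)
  on1 <- 1:3
  expect_equal(unname(r["chr1"]),
               cor(A[on1, on1][upper.tri(A[on1, on1])],
                   Cm[on1, on1][upper.tri(Cm[on1, on1])]))
  expect_true(is.na(r["chr2"]))          # a single gene has no pairs
  # masking to d <= 1 keeps only the (1,2) pair: fewer than 3 -> NA
  expect_true(is.na(matrix_correlation(A, Cm, max_distance = 1,
                                       chrom = chrom, rep_bin = rep_bin)))
})

test_that("GMM binarization recovers well-separated states", {
  set.seed(31)
  n <- 250
  lv <- c(rnorm(n, -2, 0.5), rnorm(n, 3, 0.5))
  expr <- expression_profile(stats::setNames(2^lv, sprintf("g%03d", 1:(2 * n))))
  x <- binarize_expression(expr, seed = 1)
  truth <- rep(c(-1, 1), each = n)
  expect_gte(mean(x == truth), 0.99)
  expect_equal(attr(x, "method"), "gmm")
  # two point masses: a zero-variance mixture is degenerate, but the
  # split must still be correct via the fallback
  expr2 <- expression_profile(stats::setNames(
    c(rep(2^-4, 50), rep(2^3, 50)), paste0("h", 1:100)))
  x2 <- suppressWarnings(binarize_expression(expr2))
  expect_true(all(x2[51:100] == 1) && all(x2[1:50] == -1))
  # degenerate: identical values fall back deterministically
  expr3 <- expression_profile(stats::setNames(rep(2, 10), paste0("i", 1:10)))
  expect_warning(x3 <- binarize_expression(expr3), "degenerate")
  expect_equal(attr(x3, "method"), "median")
})

test_that("Q matches hand evaluation and its identities", {
  toy <- toy4()
  x <- c(1, 1, -1, -1)
  expect_equal(compute_Q(toy$B, toy$W, x), 0.5)
  expect_equal(compute_Q(toy$B, toy$W, x), q_bruteforce(toy$B, toy$W, x))
  # global flip invariance, for several random states
  set.seed(5)
  for (r in 1:5) {
    xr <- sample(c(-1, 1), 4, replace = TRUE)
    expect_identical(compute_Q(toy$B, toy$W, xr),
                     compute_Q(toy$B, toy$W, -xr))
  }
  # zero row sums + constant x => Q = 0
  B0 <- matrix(c(0, 1, -1, 0,
                 1, 0, 0, -1,
                 -1, 0, 0, 1,
                 0, -1, 1, 0), 4, 4)
  expect_equal(compute_Q(B0, toy$W, rep(1, 4)), 0)
  expect_error(compute_Q(toy$B, matrix(0, 4, 4), x), "positive")
})

test_that("permutation nulls are centred and schemes respect domains", {
  tf <- tiny_fit()
  st <- tf$study
  x <- binarize_expression(st$expr, seed = 2)
  qr <- q_permutation_test(tf$fit, x, "global", n = 400, seed = 7)
  expect_length(qr$null, 400)
  expect_lte(abs(mean(qr$null)), 3 * sd(qr$null) / sqrt(400))
  expect_gt(qr$p, 0)
  expect_lte(qr$p, 1)
  # constant states: every Q (empirical and null) equals sum(B)/sum(W) ~ 0
  xc <- rep(1, length(x))
  names(xc) <- names(x)
  qc <- q_permutation_test(tf$fit, xc, "global", n = 100, seed = 1)
  expect_equal(qc$Q, sum(tf$fit$B) / sum(tf$fit$W))
  expect_equal(var(qc$null), 0)
  expect_equal(qc$p, 1)
  # within-TAD shuffle keeps the multiset of states inside every TAD
  qt <- q_permutation_test(tf$fit, x, "within_tad", domains = st$tads,
                           n = 100, seed = 3)
  expect_s3_class(qt, "q_result")
  blocks <- cgpmap:::permutation_blocks("within_tad", tf$fit, st$tads,
                                        length(x))
  set.seed(8)
  xp <- cgpmap:::permute_states(as.numeric(x), "within_tad", blocks,
                                length(x))
  for (g in blocks$groups)
    expect_equal(sort(xp[g]), sort(as.numeric(x)[g]))
  # permuted-TAD shuffle preserves the per-chromosome state multiset
  pb <- cgpmap:::permutation_blocks("permuted_tad", tf$fit, st$tads,
                                    length(x))
  xq <- cgpmap:::permute_states(as.numeric(x), "permuted_tad", pb, length(x))
  for (ch in pb$by_chrom)
    expect_equal(sort(xq[ch$slots]), sort(as.numeric(x)[ch$slots]))
  # requesting a domain scheme without domains fails loudly
  expect_error(q_permutation_test(tf$fit, x, "within_tad", n = 100),
               "TAD")
})

test_that("Monte Carlo is monotone, conserves ON count, reaches small optima", {
  toy <- toy4()
  x0 <- c(1, -1, 1, -1)
  mc <- monte_carlo_maximize_Q(toy$B, toy$W, x0, n_steps = 200, seed = 3)
  expect_true(all(diff(mc$trajectory) >= 0))
  expect_equal(mc$Q_final, 0.5)
  expect_equal(sum(mc$x_best == 1), sum(x0 == 1))
  expect_equal(mc$Q_final, q_exhaustive_max(toy$B, toy$W, 2))
  # 6-gene two-block instance: exhaustive optimum reached from a poor start
  ids <- paste0("s", 1:6)
  B6 <- matrix(-0.5, 6, 6)
  B6[1:3, 1:3] <- 1
  B6[4:6, 4:6] <- 1
  diag(B6) <- 0
  dimnames(B6) <- list(ids, ids)
  W6 <- matrix(1, 6, 6); diag(W6) <- 0; dimnames(W6) <- dimnames(B6)
  x6 <- c(1, -1, 1, -1, 1, -1)
  opt <- q_exhaustive_max(B6, W6, 3)
  for (seed in 1:3) {
    mc6 <- monte_carlo_maximize_Q(B6, W6, x6, n_steps = 300, seed = seed)
    expect_true(all(diff(mc6$trajectory) >= 0))
    expect_equal(mc6$Q_final, opt)
  }
  # starting at the optimum: no accepted swaps
  xopt <- c(1, 1, 1, -1, -1, -1)
  mc_opt <- monte_carlo_maximize_Q(B6, W6, xopt, n_steps = 200, seed = 1)
  expect_equal(mc_opt$n_accepted, 0L)
  expect_identical(unname(mc_opt$x_best), xopt)
})

test_that("incremental Q updates agree with direct recomputation", {
  tf <- tiny_fit()
  x <- binarize_expression(tf$study$expr, seed = 2)
  mc <- monte_carlo_maximize_Q(tf$fit, x0 = x, n_steps = 500, seed = 11)
  expect_equal(mc$Q_final,
               compute_Q(tf$fit, x = mc$x_best), tolerance = 1e-10)
  expect_gte(mc$Q_final, compute_Q(tf$fit, x = x))
})

test_that("tightness matches an exhaustive null on a 5-gene instance", {
  set.seed(41)
  ids <- paste0("p", 1:5)
  B <- matrix(rnorm(25), 5, 5); B <- B + t(B); diag(B) <- 0
  dimnames(B) <- list(ids, ids)
  res <- gene_set_tightness(B, c("p1", "p2"), exhaustive = TRUE)
  combos <- utils::combn(5, 2)
  null <- apply(combos, 2, function(s) sum(B[s, s]))
  mu <- mean(null)
  sigma <- sqrt(mean((null - mu)^2))
  expect_equal(res$b, B[1, 2] * 2)
  expect_equal(res$T, (res$b - mu) / sigma)
  expect_error(gene_set_tightness(B, c("p1", "nope")), "unknown gene")
  # degenerate: all-zero matrix
  Bz <- matrix(0, 5, 5, dimnames = list(ids, ids))
  rz <- gene_set_tightness(Bz, c("p1", "p2"), n_rand = 50, seed = 1)
  expect_true(rz$degenerate)
  expect_equal(rz$T, 0)
})

test_that("the whole-gene set has near-zero raw tightness on a fit", {
  tf <- tiny_fit()
  res <- gene_set_tightness(tf$fit, rownames(tf$fit$B), n_rand = 100,
                            seed = 1)
  expect_lt(abs(res$b) / sum(tf$fit$W), 1e-6)
})

test_that("tightness change is zero for identical conditions and antisymmetric", {
  tf <- tiny_fit()
  B <- tf$fit$B
  sets <- list(mod = tf$study$module_genes[[1]],
               rand = rownames(B)[5:14])
  same <- tightness_change(B, B, sets, n_rand = 200, seed = 3)
  expect_equal(same$delta_T, c(0, 0))
  # swapping conditions flips the sign (same seed, same nulls)
  B2 <- unclass(B)                  # a structurally different condition
  idx <- match(sets$mod[1:2], rownames(B2))
  B2[idx[1], idx[2]] <- B2[idx[2], idx[1]] <- B2[idx[1], idx[2]] + 5
  ab <- tightness_change(B, B2, sets, n_rand = 200, seed = 3)
  ba <- tightness_change(B2, B, sets, n_rand = 200, seed = 3)
  expect_equal(ab$delta_T, -ba$delta_T, tolerance = 1e-12)
})

test_that("eigenvectors are ordered, sign-fixed, and reconstruct B", {
  B2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  e <- leading_eigenvectors(B2, n_vec = 2)
  expect_equal(e$values, c(1, -1))
  expect_equal(e$vectors[, 1], c(a = 1, b = 1) / sqrt(2))
  # spectral reconstruction with all vectors
  set.seed(51)
  ids <- paste0("e", 1:8)
  B8 <- matrix(rnorm(64), 8, 8); B8 <- B8 + t(B8); diag(B8) <- 0
  dimnames(B8) <- list(ids, ids)
  full <- leading_eigenvectors(B8, n_vec = 8)
  rec <- full$vectors %*% diag(full$values) %*% t(full$vectors)
  expect_equal(rec, B8, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(full$values) <= 1e-12))
  for (m in 1:8) {
    v <- full$vectors[, m]
    expect_gt(v[which.max(abs(v))], 0)
  }
})
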