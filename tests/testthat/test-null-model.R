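# Distance-decay estimation, visibility solver, E and B

test_that("raw f(1) is the mean over offset-1 intra pairs", {
  b <- genome_binning("chr1", 4000, 1000)
  m <- matrix(0, 4, 4)
  m[cbind(1:3, 2:4)] <- c(4, 2, 6)
  m <- m + t(m)
  decay <- estimate_f_intra(contact_map(m, b))
  expect_equal(decay$raw[2], 4)   # mean(4, 2, 6), window of 1 at short range
})

test_that("a constant map yields a constant decay profile", {
  b <- genome_binning("chr1", 6000, 1000)
  m <- matrix(3.5, 6, 6)
  decay <- estimate_f_intra(contact_map(m, b))
  expect_true(all(abs(decay$f_intra - 3.5) < 1e-12))
})

test_that("isotonic clamp agrees with a pool-adjacent-violators oracle", {
  # craft a map whose raw offset means are exactly 5, 4, 4.5 for d = 1..3;
  # a high diagonal keeps d = 0 out of the pooled blocks
  b <- genome_binning("chr1", 4000, 1000)
  m <- matrix(0, 4, 4)
  m[cbind(1:3, 2:4)] <- 5
  m[cbind(1:2, 3:4)] <- 4
  m[1, 4] <- 4.5
  m <- m + t(m)
  diag(m) <- 6
  decay <- estimate_f_intra(contact_map(m, b))
  expect_equal(decay$raw[2:4], c(5, 4, 4.5))
  oracle <- pava_nonincreasing(c(5, 4, 4.5))
  expect_equal(decay$f_intra[2:4], oracle)           # 5, 4.25, 4.25
  expect_true(all(diff(decay$f_intra) <= 1e-12))
  # larger random instance against the oracle (short range: no smoothing)
  b2 <- genome_binning("chr1", 9000, 1000)
  set.seed(12)
  m2 <- matrix(stats::runif(81, 0, 10), 9, 9)
  m2 <- (m2 + t(m2)) / 2
  diag(m2) <- 20
  d2 <- estimate_f_intra(contact_map(m2, b2))
  expect_equal(d2$f_intra[2:9], pava_nonincreasing(d2$raw[2:9]),
               tolerance = 1e-10)
})

test_that("f_inter averages unordered inter-chromosomal pairs", {
  b <- genome_binning(c("chr1", "chr2"), c(2000, 2000), 1000)
  m <- matrix(0, 4, 4)
  m[1:2, 3:4] <- matrix(c(1, 3, 5, 7), 2, 2)
  m <- m + t(m) - diag(diag(m))
  expect_equal(estimate_f_inter(contact_map(m, b)), 4)
  expect_error(estimate_f_inter(random_contact_map(
    genome_binning("chr1", 3000, 1000), 1)), "single chromosome")
  z <- contact_map(diag(0, 4), b)
  expect_warning(fz <- estimate_f_inter(z), "zero")
  expect_equal(fz, 0)
})

test_that("two inter-chromosomal genes give the closed-form fixed point", {
  W <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  decay <- structure(list(f_intra = c(1, 1), raw = c(1, 1),
                          counts = c(1L, 1L), f_inter = 1, dmax = 1L),
                     class = "decay_profile")
  vis <- solve_visibilities(W, decay, rep_bin = c(1L, 5L),
                            chrom = c("chr1", "chr2"))
  expect_equal(unname(vis$k), c(2, 2), tolerance = 1e-6)
  E <- build_expected(vis, decay, c(1L, 5L), c("chr1", "chr2"))
  expect_equal(E[1, 2], 4, tolerance = 1e-6)
  B <- compute_cgp(W, E)
  expect_equal(B[1, 2], 0, tolerance = 1e-6)
})

test_that("symmetric three-gene instance converges to E = W, B = 0", {
  ids <- c("a", "b", "c")
  W <- matrix(2, 3, 3, dimnames = list(ids, ids))
  diag(W) <- 0
  decay <- structure(list(f_intra = c(1, 1), raw = c(1, 1),
                          counts = c(1L, 1L), f_inter = 1, dmax = 1L),
                     class = "decay_profile")
  chrom <- c("c1", "c2", "c3")
  vis <- solve_visibilities(W, decay, rep_bin = c(1L, 2L, 3L), chrom = chrom)
  expect_equal(max(vis$k) - min(vis$k), 0, tolerance = 1e-6)
  E <- build_expected(vis, decay, c(1L, 2L, 3L), chrom)
  expect_equal(unclass(E), unclass(W), tolerance = 1e-5)
  expect_equal(max(abs(compute_cgp(W, E))), 0, tolerance = 1e-5)
})

test_that("zero-coverage genes get k = 0 without disturbing the others", {
  ids <- c("a", "b", "z")
  W <- matrix(0, 3, 3, dimnames = list(ids, ids))
  W[1, 2] <- W[2, 1] <- 4
  decay <- structure(list(f_intra = c(1, 1), raw = c(1, 1),
                          counts = c(1L, 1L), f_inter = 1, dmax = 1L),
                     class = "decay_profile")
  chrom <- c("c1", "c2", "c3")
  vis <- solve_visibilities(W, decay, rep_bin = 1:3, chrom = chrom)
  expect_equal(unname(vis$k["z"]), 0)
  expect_equal(unname(vis$k[c("a", "b")]), c(2, 2), tolerance = 1e-6)
  E <- build_expected(vis, decay, 1:3, chrom)
  expect_true(all(E[3, ] == 0) && all(E[, 3] == 0))
})

test_that("fixed point matches a brute-force nonlinear solve on small instances", {
  for (seed in c(2, 5)) {
    set.seed(seed)
    G <- 8
    ids <- sprintf("g%d", 1:G)
    chrom <- rep(c("chr1", "chr2"), each = G / 2)
    rep_bin <- c(1:4, 11:14)
    W <- matrix(stats::runif(G * G, 1, 10), G, G)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    dimnames(W) <- list(ids, ids)
    decay <- structure(list(f_intra = 5 / (1:10), raw = 5 / (1:10),
                            counts = rep(1L, 10), f_inter = 0.8, dmax = 9L),
                       class = "decay_profile")
    vis <- solve_visibilities(W, decay, rep_bin, chrom, tol = 1e-9)
    # oracle works on the same rescaled kernel the solver fixed
    Fm <- cgpmap:::decay_matrix(decay, rep_bin, chrom) * vis$f_scale
    k_oracle <- solve_k_bruteforce(Fm, rowSums(W))
    expect_equal(unname(vis$k), k_oracle, tolerance = 1e-6)
  }
})

test_that("conservation and scale covariance hold on a fitted instance", {
  tf <- tiny_fit()
  fit <- tf$fit
  s <- rowSums(unclass(fit$W))
  expect_lt(max(abs(rowSums(unclass(fit$E)) - s) / pmax(s, 1e-12)), 1e-6)
  expect_lt(abs(sum(fit$B)) / sum(fit$W), 1e-6)
  # scaling W by c scales E and B by c
  cm2 <- tf$study$cmap
  cm2$matrix <- cm2$matrix * 3
  fit2 <- cgp_fit(cm2, tf$study$genes)
  expect_equal(unclass(fit2$E), 3 * unclass(fit$E), tolerance = 1e-6)
  expect_equal(unclass(fit2$B), 3 * unclass(fit$B), tolerance = 1e-6)
  expect_equal(unname(fit2$k / fit$k), rep(sqrt(3), length(fit$k)),
               tolerance = 1e-4)
})

test_that("compute_cgp rejects a mismatched expectation", {
  tf <- tiny_fit()
  E_bad <- unclass(tf$fit$E) * 1.5
  expect_error(compute_cgp(tf$fit$W, E_bad), "conservation")
})

test_that("fit methods expose the model components coherently", {
  tf <- tiny_fit()
  fit <- tf$fit
  expect_identical(coef(fit), fit$k)
  expect_identical(residuals(fit), fit$B)
  expect_identical(fitted(fit), fit$E)
  expect_equal(unclass(fit$B), unclass(fit$W) - unclass(fit$E))
  pairs <- data.frame(gene_i = names(fit$k)[1:3], gene_j = names(fit$k)[4:6])
  expect_equal(predict(fit, pairs),
               fit$E[cbind(1:3, 4:6)])
  expect_output(print(fit), "CGP")
  expect_output(print(summary(fit)), "row residual")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(sims[[1]], t(sims[[1]]))
  expect_identical(simulate(fit, seed = 9)[[1]], simulate(fit, seed = 9)[[1]])
})
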