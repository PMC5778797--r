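scan_rows <- function(p, pos = seq_along(p) * 1e4) {
  data.frame(snp_id = paste0("s", seq_along(p)), chromosome = "1",
             position_bp = pos, pvalue = p, stringsAsFactors = FALSE)
}

test_that("region SNP selection follows the p < 0.001 / top-10 / top-40 rules", {
  set.seed(1)
  # 25 SNPs below the cut among 200 -> exactly those 25
  p <- runif(200, 0.01, 1); p[sample(200, 25)] <- runif(25, 0, 9e-4)
  sel <- select_region_snps(scan_rows(p))
  expect_identical(nrow(sel), 25L)
  expect_true(all(sel$pvalue < 0.001))
  # 6 below the cut -> the 10 smallest
  p2 <- runif(200, 0.01, 1); p2[1:6] <- 1e-5
  sel2 <- select_region_snps(scan_rows(p2))
  expect_identical(nrow(sel2), 10L)
  expect_true(all(sort(p2)[1:10] %in% sel2$pvalue))
  # 60 below the cut -> the 40 smallest
  p3 <- runif(200, 0.01, 1); p3[1:60] <- runif(60, 0, 9e-4)
  sel3 <- select_region_snps(scan_rows(p3))
  expect_identical(nrow(sel3), 40L)
  expect_equal(sort(sel3$pvalue), sort(p3)[1:40])
  # region with fewer than 10 SNPs in total -> all, flagged
  sel4 <- select_region_snps(scan_rows(runif(4)))
  expect_identical(nrow(sel4), 4L)
  expect_true(attr(sel4, "short"))
  expect_error(select_region_snps(scan_rows(NA_real_)), "finite")
})

test_that("loading rows square-sum to FLK and zero deviation gives zero loadings", {
  x <- sim_freq_table(n_pops = 6, n_snps = 400, seed = 71)
  scan <- run_flk_scan(x$ft, x$F)
  P <- attr(scan, "freq")
  W <- flk_loadings(P, scan$p0, x$F)
  expect_lt(max(abs(rowSums(W^2) - scan$flk)), 1e-8)
  # p = p0 at a SNP -> zero loading row
  P2 <- cbind(rep(0.4, 6))
  rownames(P2) <- rownames(x$F)
  W2 <- flk_loadings(P2, 0.4, x$F)
  expect_lt(max(abs(W2)), 1e-12)
  # F = I: Gram matrix of W equals Gram matrix of standardised deviations
  FI <- diag(6); dimnames(FI) <- dimnames(x$F)
  W3 <- flk_loadings(P, scan$p0, FI)
  C <- sweep(P, 2, scan$p0) / rep(sqrt(scan$p0 * (1 - scan$p0)), each = 6)
  expect_matrix_equal(tcrossprod(W3), crossprod(C), tol = 1e-8)
})

test_that("loading correlation is the cosine similarity with a stabilising ridge", {
  set.seed(5)
  W <- matrix(rnorm(50), 10, 5)
  W[3, ] <- W[1, ] * 2          # duplicated profile
  W[4, ] <- 0                   # zero row excluded
  rownames(W) <- paste0("s", 1:10)
  R <- loading_correlation(W)
  expect_identical(attr(R, "excluded"), "s4")
  expect_equal(R["s1", "s3"], 1)
  # brute-force pairwise cosine loop
  keep <- setdiff(rownames(W), "s4")
  for (a in keep) for (b in keep) {
    if (a == b) next
    cosab <- sum(W[a, ] * W[b, ]) / sqrt(sum(W[a, ]^2) * sum(W[b, ]^2))
    expect_equal(R[a, b], cosab, tolerance = 1e-12)
  }
  expect_equal(unname(diag(R)), rep(1 + 1e-6, 9))
  # orthogonal rows -> zero entry
  W5 <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(loading_correlation(W5)["a", "b"], 0)
})

test_that("causal posterior: exact enumeration on identity-correlation cases", {
  R <- diag(10); dimnames(R) <- list(paste0("s", 1:10), paste0("s", 1:10))
  # all scores null -> posterior favours the empty configuration
  cp0 <- causal_posterior(rep(0.1, 10), R, gamma = 0.01, lambda = 5)
  expect_identical(cp0$method, "exact")
  expect_lt(cp0$posterior_mean, 0.2)
  # one strong score -> about one variant
  z1 <- c(6, rep(0.1, 9))
  cp1 <- causal_posterior(z1, R, gamma = 0.01, lambda = 5)
  expect_gt(cp1$posterior_mean, 0.9)
  expect_lt(cp1$posterior_mean, 1.3)
  expect_gt(cp1$inclusion[1], 0.9)
  # two strong scores at uncorrelated SNPs -> about two
  z2 <- c(6, 6, rep(0.1, 8))
  cp2 <- causal_posterior(z2, R, gamma = 0.01, lambda = 5)
  expect_gt(cp2$posterior_mean, 1.8)
  expect_lt(cp2$posterior_mean, 2.4)
  # posterior over counts sums to one
  expect_equal(sum(cp2$count_probs), 1, tolerance = 1e-8)
})

test_that("posterior mean grows with the number of planted independent signals", {
  R <- diag(12)
  means <- sapply(1:3, function(k) {
    z <- c(rep(6, k), rep(0.05, 12 - k))
    causal_posterior(z, R, gamma = 0.01, lambda = 5)$posterior_mean
  })
  expect_true(all(diff(means) > 0))
})

test_that("permuting SNPs permutes inclusion probabilities, not the mean", {
  set.seed(9)
  A <- matrix(rnorm(36), 6)
  R <- cov2cor(crossprod(A) + diag(6))
  z <- c(4, 0.3, 3.5, 0.2, 0.1, 1)
  cp <- causal_posterior(z, R, gamma = 0.05, lambda = 4)
  perm <- c(3, 1, 6, 2, 5, 4)
  cp_p <- causal_posterior(z[perm], R[perm, perm], gamma = 0.05, lambda = 4)
  expect_equal(cp_p$posterior_mean, cp$posterior_mean, tolerance = 1e-10)
  expect_equal(unname(cp_p$inclusion), unname(cp$inclusion[perm]),
               tolerance = 1e-10)
})

test_that("Monte-Carlo search agrees with exact enumeration on small cases", {
  set.seed(31)
  for (case in 1:5) {
    m <- sample(8:12, 1)
    A <- matrix(rnorm(m * m), m)
    R <- cov2cor(crossprod(A) + diag(m))
    z <- rnorm(m); z[sample(m, 2)] <- c(5, -4.5)
    ex <- causal_posterior(z, R, m_max = 6, gamma = 0.02, lambda = 5)
    mc <- causal_posterior(z, R, m_max = 6, gamma = 0.02, lambda = 5,
                           enum_limit = 1, n_sweeps = 4e4, seed = case)
    expect_identical(mc$method, "monte_carlo")
    expect_lt(abs(mc$posterior_mean - ex$posterior_mean), 0.1)
  }
})

test_that("heterogeneity report separates one from two selected variants", {
  # one selected variant: posterior concentrates near 1; two variants in
  # different populations: near (or above) 2 with two high inclusions
  x <- sim_freq_table(n_pops = 6, n_snps = 300, seed = 81)
  single <- inject_selection(x$freq, list(list(loci = 150, populations = "pop2",
                                               target = 1)))
  scan1 <- run_flk_scan(frequency_table(single$freq), x$F)
  regions <- data.frame(region_id = "region_001", chromosome = "1",
                        start_bp = 130 * 1e4, end_bp = 170 * 1e4,
                        stringsAsFactors = FALSE)
  rep1 <- heterogeneity_report(scan1, regions, x$F, seed = 5)
  expect_false(rep1$heterogeneous)
  double <- inject_selection(x$freq,
                             list(list(loci = 145, populations = "pop2", target = 1),
                                  list(loci = 155, populations = "pop5", target = 1)))
  scan2 <- run_flk_scan(frequency_table(double$freq), x$F)
  rep2 <- heterogeneity_report(scan2, regions, x$F, seed = 5)
  expect_true(rep2$heterogeneous)
  # single-SNP region: posterior over {0, 1} only
  r1 <- data.frame(region_id = "r", chromosome = "1",
                   start_bp = 150e4, end_bp = 150e4)
  scan3 <- scan1[scan1$position_bp == 150e4, ]
  attr(scan3, "freq") <- attr(scan1, "freq")[, scan1$position_bp == 150e4,
                                             drop = FALSE]
  rep3 <- heterogeneity_report(scan3, r1, x$F, seed = 5)
  expect_identical(rep3$n_snps_used, 1L)
  post <- attr(rep3, "posteriors")[[1]]
  expect_identical(sum(post$count_probs > 1e-12 &
                         seq_along(post$count_probs) > 2), 0L)
})
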