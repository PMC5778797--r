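test_that("PLINK bed/bim/fam round-trip is the identity", {
  G <- toy_table()
  prefix <- file.path(tempdir(), "rt")
  write_plink(G, prefix)
  G2 <- read_plink(prefix)
  expect_identical(G2$calls, G$calls)
  expect_identical(G2$samples, G$samples)
  expect_identical(G2$snps, G$snps)
  # a missing call survives the 2-bit encoding, others intact
  expect_true(is.na(G2$calls[2, 4]))
  expect_identical(sum(is.na(G2$calls)), 2L)
})

test_that("bed reader rejects bad magic, individual-major mode and size mismatch", {
  G <- toy_table()
  prefix <- file.path(tempdir(), "bad")
  write_plink(G, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 1e4)
  writeBin(c(as.raw(0), raw[-1]), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
  raw[3] <- as.raw(0)
  writeBin(raw, paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "mode")
  raw[3] <- as.raw(1)
  writeBin(raw[-length(raw)], paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "size")
})

test_that("fixture-dialect TSV round-trip is the identity", {
  G <- toy_table()
  path <- tempfile(fileext = ".tsv")
  write_geno_tsv(G, path)
  G2 <- read_geno_tsv(path)
  expect_identical(G2$calls, G$calls)
  expect_identical(G2$samples, G$samples)
  expect_equal(G2$snps, G$snps)
})

test_that("genotype_table validates calls, duplicates and position order", {
  expect_error(genotype_table(matrix(3L, 1, 1),
                              data.frame(sample_id = "s", population_id = "p"),
                              data.frame(snp_id = "r", chromosome = "1",
                                         position_bp = 1, allele_A = "A",
                                         allele_B = "B")),
               "0, 1, 2")
  expect_error(genotype_table(matrix(0L, 1, 2),
                              data.frame(sample_id = "s", population_id = "p"),
                              data.frame(snp_id = c("r1", "r2"), chromosome = "1",
                                         position_bp = c(5, 5), allele_A = "A",
                                         allele_B = "B")),
               "increasing")
})

test_that("allele frequencies match a per-cell counting oracle", {
  # worked example: one population, calls {0, 1, 2} at a SNP
  G1 <- genotype_table(matrix(c(0L, 1L, 2L), 3, 1),
                       data.frame(sample_id = paste0("s", 1:3),
                                  population_id = "P"),
                       data.frame(snp_id = "r", chromosome = "1",
                                  position_bp = 1, allele_A = "A",
                                  allele_B = "B"))
  ft1 <- allele_frequencies(G1)
  expect_equal(unname(ft1$freq["P", 1]), 0.5)
  expect_equal(unname(ft1$n_obs["P", 1]), 6L)

  # all-missing SNP flagged undefined
  G1$calls[, 1] <- NA_integer_
  expect_true(is.na(allele_frequencies(G1)$freq["P", 1]))

  # random tables against the brute-force loop (property, 100 cases)
  for (case in 1:100) {
    set.seed(case)
    n <- sample(5:20, 1); S <- sample(5:30, 1)
    calls <- matrix(sample(c(0:2, NA), n * S, replace = TRUE), n, S)
    pops <- sample(c("X", "Y"), n, replace = TRUE)
    G <- genotype_table(calls,
                        data.frame(sample_id = paste0("s", 1:n),
                                   population_id = pops),
                        data.frame(snp_id = paste0("r", 1:S), chromosome = "1",
                                   position_bp = 1:S, allele_A = "A",
                                   allele_B = "B"))
    ft <- allele_frequencies(G)
    for (p in unique(pops)) for (s in sample(S, 3)) {
      cc <- calls[pops == p, s]
      n_ok <- sum(!is.na(cc))
      expect_equal(unname(ft$n_obs[p, s]), 2L * n_ok)
      if (n_ok == 0) expect_true(is.na(ft$freq[p, s]))
      else expect_equal(unname(ft$freq[p, s]), sum(cc, na.rm = TRUE) / (2 * n_ok))
    }
  }
})

# independent enumeration oracle: unnormalised multinomial weight of each
# heterozygote count given the allele counts, built from choose() products
hwe_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  w <- sapply(hets, function(h) {
    naa <- (nA - h) / 2
    choose(n, naa) * choose(n - naa, h) * 2^h
  })
  probs <- w / sum(w)
  obs <- probs[hets == nAB]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

test_that("exact HWE test matches enumeration and behaves at the extremes", {
  expect_equal(hwe_test(25, 50, 25), 1.0)
  expect_equal(hwe_test(3, 4, 3), hwe_oracle(3, 4, 3), tolerance = 1e-10)
  expect_lt(hwe_test(50, 0, 50), 1e-20)
  expect_true(is.na(hwe_test(0, 0, 0)))
  expect_error(hwe_test(-1, 2, 3), "negative")
})

test_that("HWE p-values are near-uniform under the null", {
  set.seed(7)
  reps <- 10000
  p <- runif(reps, 0.2, 0.8)
  g <- rbinom(reps * 100, 2, rep(p, each = 100))
  dim(g) <- c(100, reps)
  pv <- hwe_test(colSums(g == 0), colSums(g == 1), colSums(g == 2))
  # discrete test: compare mean and sub-uniform tail rather than exact KS
  expect_gt(mean(pv), 0.45)
  expect_lt(mean(pv < 0.05), 0.06)
})

test_that("q-values match the step-up oracle and Storey behaves", {
  expect_equal(fdr_qvalues(0.05, "BH"), 0.05)
  expect_equal(as.numeric(fdr_qvalues(0.05, "storey")), 0.05)
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03, 0.04, 1.0), "BH"),
               c(0.05, 0.05, 0.05, 0.05, 1.0))
  expect_equal(fdr_qvalues(rep(0.2, 10), "BH"), rep(0.2, 10))
  expect_length(fdr_qvalues(numeric(0)), 0)
  # step-up oracle on random vectors; Storey never exceeds BH
  for (case in 1:20) {
    set.seed(case)
    p <- runif(50)^2
    q <- fdr_qvalues(p, "BH")
    m <- length(p)
    ord <- order(p)
    oracle <- p[ord] * m / seq_len(m)
    oracle <- rev(cummin(rev(oracle)))
    expect_equal(q[ord], pmin(1, oracle))
    expect_true(all(as.numeric(fdr_qvalues(p, "storey")) <= q + 1e-12))
    # monotone in sorted p order
    expect_true(!is.unsorted(q[ord]))
  }
})

test_that("qc_filter applies the documented rules and is idempotent", {
  set.seed(11)
  G <- hwe_table(100, 50, seed = 3)
  # make SNP 1 monomorphic, SNP 2 missing in 2 of 100 samples
  G$calls[, 1] <- 0L
  G$calls[1:2, 2] <- NA_integer_
  out <- qc_filter(G)
  expect_true(all(c("snp1", "snp2") %in% out$report$removed_snps$snp_id))
  rs <- out$report$removed_snps
  expect_identical(rs$reason[rs$snp_id == "snp1"], "MAF")
  expect_identical(rs$reason[rs$snp_id == "snp2"], "SNP_MISSING")
  # every removed item appears exactly once
  expect_identical(anyDuplicated(rs$snp_id), 0L)
  # already-clean table: identical output, empty report; idempotence
  again <- qc_filter(out$genotypes)
  expect_identical(again$genotypes$calls, out$genotypes$calls)
  expect_identical(nrow(again$report$removed_snps), 0L)
  expect_identical(nrow(again$report$removed_samples), 0L)
})

test_that("qc_filter removes samples above the missing-call threshold", {
  G <- hwe_table(50, 40, seed = 5)
  G$calls[1, 1:10] <- NA_integer_   # 25% missing
  out <- qc_filter(G)
  expect_identical(out$report$removed_samples$sample_id, G$samples$sample_id[1])
  expect_identical(out$report$removed_samples$reason, "IND_MISSING")
})

test_that("GRM matches the direct VanRaden formula", {
  # two identical samples: off-diagonal equals both diagonals
  calls <- rbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, 0L))
  G <- genotype_table(calls,
                      data.frame(sample_id = paste0("s", 1:3),
                                 population_id = "P"),
                      data.frame(snp_id = paste0("r", 1:4), chromosome = "1",
                                 position_bp = 1:4, allele_A = "A",
                                 allele_B = "B"))
  K <- compute_grm(G)
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])
  # brute-force formula oracle
  p <- colMeans(calls) / 2
  poly <- p > 0 & p < 1
  Z <- sweep(calls[, poly], 2, 2 * p[poly])
  expect_matrix_equal(unclass(K), Z %*% t(Z) / (2 * sum(p[poly] * (1 - p[poly]))))
  G$calls[] <- 1L   # every sample heterozygous: no polymorphic information
  G$calls[, ] <- 0L
  expect_error(compute_grm(G), "polymorphic")
})

test_that("GRM diagonal is near 1 and off-diagonal near 0 for unrelated HWE samples", {
  G <- hwe_table(200, 5000, seed = 9)
  K <- compute_grm(G)
  expect_lt(abs(mean(diag(K)) - 1), 0.05)
  off <- K[upper.tri(K)]
  # sample-centred Z makes E[off-diagonal] = -1/(n-1), not exactly 0
  expect_lt(abs(mean(off) + 1 / (nrow(K) - 1)), 0.003)
  expect_lt(abs(mean(off)), 0.01)
})

test_that("relatedness filter needs 3 samples and removes planted duplicates", {
  G <- hwe_table(60, 800, seed = 21)
  sp <- spike_related_pairs(G, list(list(kinship = 0.5, count = 3)), seed = 4)
  K <- compute_grm(sp$genotypes)
  expect_error(relatedness_filter(K[1:2, 1:2]), "3 samples")
  out <- relatedness_filter(K)
  expect_identical(length(out$removed), 3L)
  # exactly one member of each planted pair removed
  for (i in seq_len(nrow(sp$truth)))
    expect_identical(sum(c(sp$truth$sample_a[i], sp$truth$sample_b[i]) %in%
                           out$removed), 1L)
})

test_that("LD decay: identical SNP pair gives r2 = 1; independent SNPs sit at the sampling floor", {
  calls <- cbind(rep(c(0L, 1L, 2L), 10), rep(c(0L, 1L, 2L), 10))
  G <- genotype_table(calls,
                      data.frame(sample_id = paste0("s", 1:30),
                                 population_id = "P"),
                      data.frame(snp_id = c("a", "b"), chromosome = "1",
                                 position_bp = c(1000L, 26000L),
                                 allele_A = "A", allele_B = "B"))
  ld <- ld_decay(G, max_dist_bp = 1e5, bin_bp = 5e4)
  expect_equal(ld$mean_r2[1], 1)
  expect_identical(ld$n_pairs[1], 1L)

  n <- 100
  G2 <- hwe_table(n, 80, seed = 31)
  ld2 <- ld_decay(G2, max_dist_bp = 2e5, bin_bp = 2e5)
  # E[r2] ~ 1/n for independent SNPs; generous 3-SE-style band
  expect_lt(abs(ld2$mean_r2[1] - 1 / n), 3 * (2 / n) / sqrt(ld2$n_pairs[1]) + 0.01)
})
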