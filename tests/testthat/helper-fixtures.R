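# Shared fixture builders; everything is generated in code.

# small genotype table with mixed calls and both populations
toy_table <- function() {
  calls <- rbind(c(0L, 1L, 2L, 0L, 1L, 2L),
                 c(1L, 1L, 0L, NA, 2L, 0L),
                 c(2L, 0L, 1L, 2L, 0L, 1L),
                 c(0L, 2L, 2L, 1L, NA, 0L))
  genotype_table(
    calls,
    samples = data.frame(sample_id = paste0("s", 1:4),
                         population_id = c("A", "A", "B", "B")),
    snps = data.frame(snp_id = paste0("rs", 1:6), chromosome = "1",
                      position_bp = c(100L, 200L, 350L, 500L, 900L, 1500L),
                      allele_A = "A", allele_B = "C")
  )
}

# genotypes under HWE with independent SNPs, one population
hwe_table <- function(n, S, seed, pops = "pop1") {
  set.seed(seed)
  p <- runif(S, 0.1, 0.9)
  freq <- matrix(p, length(pops), S, byrow = TRUE,
                 dimnames = list(pops, NULL))
  simulate_genotypes(freq, n_per_pop = n, seed = seed + 1)
}

# frequency table wrapped around simulated drift frequencies
sim_freq_table <- function(n_pops = 8, n_snps = 2000, seed = 1,
                           total_drift = 0.2, ...) {
  tree <- sim_population_tree(n_pops, total_drift, seed = seed)
  fr <- simulate_frequencies(tree, n_snps, seed = seed + 1, ...)
  list(ft = frequency_table(fr$freq), F = fr$F, tree = tree, p0 = fr$p0,
       freq = fr$freq)
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
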