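#' Per-population allele frequencies
#'
#' @param G a [genotype_table()].
#' @param grouping named character vector mapping sample id to population;
#'   defaults to the table's own population labels.
#' @return An object of class `frequency_table`: a list with `freq`
#'   (population x SNP matrix of allele-B frequencies, `NA` where a
#'   population has no genotyped sample), `n_obs` (non-missing allele
#'   counts, 2 per genotyped sample), `snps` (the SNP map) and
#'   `populations`.
#' @export
allele_frequencies <- function(G, grouping = NULL) {
  if (is.null(grouping)) {
    grouping <- G$samples$population_id
    names(grouping) <- G$samples$sample_id
  }
  pop <- as.character(grouping[G$samples$sample_id])
  if (anyNA(pop)) stop("grouping must cover all samples")
  pops <- sort(unique(pop))
  ok <- !is.na(G$calls)
  freq <- matrix(NA_real_, length(pops), ncol(G$calls),
                 dimnames = list(pops, G$snps$snp_id))
  n_obs <- matrix(0L, length(pops), ncol(G$calls),
                  dimnames = list(pops, G$snps$snp_id))
  for (p in pops) {
    rows <- pop == p
    cnt <- colSums(ok[rows, , drop = FALSE])
    s <- colSums(G$calls[rows, , drop = FALSE], na.rm = TRUE)
    n_obs[p, ] <- 2L * as.integer(cnt)
    freq[p, ] <- ifelse(cnt > 0, s / (2 * cnt), NA_real_)
  }
  structure(list(freq = freq, n_obs = n_obs, snps = G$snps,
                 populations = pops),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("frequency_table:", length(x$populations), "populations x",
      ncol(x$freq), "SNPs\n")
  invisible(x)
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Full-enumeration exact test on the heterozygote count conditional on the
#' allele counts (no mid-p correction): the p-value is the total probability
#' of all heterozygote counts at most as probable as the observed one.  A
#' chi-squared (1 df) approximation is available via `method = "chisq"`.
#'
#' @param nAA,nAB,nBB genotype counts (vectors recycle together).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return p-values in `(0, 1]`; `NA` where the total count is zero.
#' @export
hwe_test <- function(nAA, nAB, nBB, method = c("exact", "chisq")) {
  method <- match.arg(method)
  k <- max(length(nAA), length(nAB), length(nBB))
  nAA <- rep_len(as.integer(nAA), k)
  nAB <- rep_len(as.integer(nAB), k)
  nBB <- rep_len(as.integer(nBB), k)
  if (any(c(nAA, nAB, nBB) < 0, na.rm = TRUE)) stop("negative genotype count")
  vapply(seq_len(k), function(i) {
    n <- nAA[i] + nAB[i] + nBB[i]
    if (is.na(n) || n == 0L) return(NA_real_)
    if (method == "chisq") {
      p <- (2 * nAA[i] + nAB[i]) / (2 * n)
      e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
      if (any(e == 0)) return(1)
      x2 <- sum((c(nAA[i], nAB[i], nBB[i]) - e)^2 / e)
      return(stats::pchisq(x2, 1, lower.tail = FALSE))
    }
    .hwe_exact(nAA[i], nAB[i], nBB[i])
  }, numeric(1))
}

# conditional distribution of the het count given allele counts:
# P(nAB | n, nA) = n! / (nAA! nAB! nBB!) * 2^nAB / [C(2n, nA)]
.hwe_exact <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2L * nAA + nAB
  nB <- 2L * n - nA
  hets <- seq.int(nA %% 2L, min(nA, nB), by = 2L)
  lp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((nB - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2L * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(nAB, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' False-discovery-rate q-values
#'
#' Benjamini-Hochberg step-up q-values, or Storey q-values with the
#' smoother estimate of the null proportion pi0 (pi0(lambda) =
#' mean(p > lambda) / (1 - lambda) on a lambda grid, smoothed by a cubic
#' spline and evaluated at the largest lambda, capped to (0, 1]).
#'
#' @param p vector of p-values in \[0, 1\].
#' @param method `"storey"` (default) or `"BH"`.
#' @return q-values of the same length; `attr(, "pi0")` for Storey.
#' @export
fdr_qvalues <- function(p, method = c("storey", "BH")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q_bh <- stats::p.adjust(p, method = "BH")
  if (method == "BH") return(q_bh)
  pi0 <- .storey_pi0(p[!is.na(p)])
  q <- pi0 * q_bh
  attr(q, "pi0") <- pi0
  q
}

.storey_pi0 <- function(p) {
  lambda <- seq(0.05, 0.95, by = 0.05)
  if (length(p) < 20 || max(p) < max(lambda)) {
    # too little tail information for the smoother; conservative null
    return(1)
  }
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  if (!is.finite(pi0) || pi0 <= 0) return(1)
  min(pi0, 1)
}

#' Quality-control filter chain
#'
#' Applies, in a fixed order, (1) removal of samples whose missing call rate
#' exceeds `ind_miss_max`; (2) removal of SNPs with overall minor allele
#' frequency of zero (or below `maf_min` when positive); (3) removal of SNPs
#' whose missing call rate exceeds `snp_miss_max`; (4) removal of SNPs out
#' of Hardy-Weinberg equilibrium (q-value below `hwe_fdr`) in one or more
#' populations.  Each removed item is reported once with its first failing
#' rule (SNPs: MAF, SNP_MISSING, HWE; samples: IND_MISSING).
#'
#' @param G a [genotype_table()].
#' @param maf_min minor-allele-frequency threshold; the default 0 removes
#'   only monomorphic SNPs.
#' @param snp_miss_max maximum SNP missing call rate (default 0.01).
#' @param ind_miss_max maximum individual missing call rate (default 0.05).
#' @param hwe_fdr FDR level of the per-population HWE screen (default 0.05).
#' @param hwe_method passed to [hwe_test()].
#' @param qvalue_method passed to [fdr_qvalues()].
#' @return A list with `genotypes` (the filtered table) and `report` (a
#'   `qc_report`: data.frames `removed_snps` and `removed_samples` with a
#'   `reason` column, plus the thresholds used).
#' @export
qc_filter <- function(G, maf_min = 0, snp_miss_max = 0.01,
                      ind_miss_max = 0.05, hwe_fdr = 0.05,
                      hwe_method = "exact", qvalue_method = "storey") {
  stopifnot(maf_min >= 0, maf_min <= 1, snp_miss_max >= 0, snp_miss_max <= 1,
            ind_miss_max >= 0, ind_miss_max <= 1, hwe_fdr >= 0, hwe_fdr <= 1)
  removed_samples <- data.frame(sample_id = character(), reason = character(),
                                stringsAsFactors = FALSE)
  # 1. sample missingness
  ind_miss <- rowMeans(is.na(G$calls))
  drop_s <- ind_miss > ind_miss_max
  if (any(drop_s)) {
    removed_samples <- data.frame(sample_id = G$samples$sample_id[drop_s],
                                  reason = "IND_MISSING",
                                  stringsAsFactors = FALSE)
    G <- G[!drop_s, ]
  }
  m <- ncol(G$calls)
  reason <- rep(NA_character_, m)
  # 2. MAF
  fr <- colMeans(G$calls, na.rm = TRUE) / 2
  maf <- pmin(fr, 1 - fr)
  maf[is.nan(maf)] <- 0          # all-missing SNP: treat as monomorphic
  fail_maf <- maf == 0 | maf < maf_min
  reason[fail_maf] <- "MAF"
  # 3. SNP missingness
  snp_miss <- colMeans(is.na(G$calls))
  fail_miss <- snp_miss > snp_miss_max
  reason[is.na(reason) & fail_miss] <- "SNP_MISSING"
  # 4. HWE within each population, q-value screen
  pops <- unique(G$samples$population_id)
  fail_hwe <- rep(FALSE, m)
  for (p in pops) {
    rows <- G$samples$population_id == p
    cc <- G$calls[rows, , drop = FALSE]
    nAA <- colSums(cc == 0L, na.rm = TRUE)
    nAB <- colSums(cc == 1L, na.rm = TRUE)
    nBB <- colSums(cc == 2L, na.rm = TRUE)
    pv <- hwe_test(nAA, nAB, nBB, method = hwe_method)
    qv <- rep(NA_real_, m)
    ok <- !is.na(pv)
    qv[ok] <- fdr_qvalues(pv[ok], method = qvalue_method)
    fail_hwe <- fail_hwe | (!is.na(qv) & qv < hwe_fdr)
  }
  reason[is.na(reason) & fail_hwe] <- "HWE"
  removed_snps <- data.frame(snp_id = G$snps$snp_id[!is.na(reason)],
                             reason = reason[!is.na(reason)],
                             stringsAsFactors = FALSE)
  keep <- is.na(reason)
  if (!any(keep)) warning("all SNPs removed by QC")
  G <- G[, keep]
  report <- structure(
    list(removed_snps = removed_snps, removed_samples = removed_samples,
         thresholds = list(maf_min = maf_min, snp_miss_max = snp_miss_max,
                           ind_miss_max = ind_miss_max, hwe_fdr = hwe_fdr)),
    class = "qc_report")
  list(genotypes = G, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", nrow(x$removed_snps), "SNPs and",
      nrow(x$removed_samples), "samples removed\n")
  if (nrow(x$removed_snps))
    print(table(x$removed_snps$reason))
  if (nrow(x$removed_samples))
    print(table(x$removed_samples$reason))
  invisible(x)
}

#' Genomic relationship matrix
#'
#' VanRaden method 1: `G_rel = Z Z' / (2 * sum p (1 - p))` with
#' `Z = calls - 2p` per SNP and missing calls imputed to the SNP mean `2p`.
#' Monomorphic SNPs carry no information and are excluded from the
#' denominator (their Z column is zero).
#'
#' @param G a [genotype_table()].
#' @return Symmetric sample x sample matrix of class `grm`.
#' @export
compute_grm <- function(G) {
  if (nrow(G$calls) < 2) stop("need at least two samples")
  p <- colMeans(G$calls, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNP: GRM undefined")
  Z <- sweep(G$calls[, poly, drop = FALSE], 2, 2 * p[poly])
  Z[is.na(Z)] <- 0
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(Z) / denom
  K <- (K + t(K)) / 2
  dimnames(K) <- list(G$samples$sample_id, G$samples$sample_id)
  class(K) <- c("grm", "matrix")
  K
}

#' Mixture-model relatedness filter
#'
#' Off-diagonal GRM coefficients are modelled as a two-component normal
#' mixture (EM via mclust); the major component (larger mixing weight)
#' represents unrelated pairs.  A pair is flagged related when it lies above
#' the major-component mean and its local false-discovery rate (posterior
#' probability of the major component) keeps the overall FDR of the flagged
#' set below `fdr`.  One member of each flagged pair is then removed
#' greedily: repeatedly drop the sample in the most flagged pairs (ties
#' broken by the lexicographically smallest sample id) until no flagged pair
#' survives intact.
#'
#' @param grm a [compute_grm()] matrix.
#' @param fdr target false-discovery rate for declaring pairs related
#'   (default 0.05).
#' @param fallback_threshold fixed coefficient cut-off used (with a warning)
#'   when the mixture fit degenerates.
#' @return A list with `kept`, `removed`, `flagged_pairs` and `mixture_fit`
#'   (the mclust model or `NULL` on fallback).
#' @export
relatedness_filter <- function(grm, fdr = 0.05, fallback_threshold = 0.2) {
  n <- nrow(grm)
  if (n < 3) stop("relatedness filter needs at least 3 samples")
  ids <- rownames(grm)
  ut <- upper.tri(grm)
  coefs <- grm[ut]
  idx <- which(ut, arr.ind = TRUE)
  # model selection between one and two components: with no related pairs
  # the coefficient distribution is a single bulk and nothing is flagged
  fit <- tryCatch(
    Mclust(coefs, G = 1:2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  one_component <- !is.null(fit) && fit$G == 1
  flagged <- NULL
  major_ok <- FALSE
  if (!is.null(fit) && !one_component) {
    major <- which.max(fit$parameters$pro)
    sig <- fit$parameters$variance$sigmasq
    sig_major <- if (length(sig) > 1) sig[major] else sig
    # only the major (unrelated) component must be non-degenerate: a
    # near-point-mass minor component is a legitimate tight related cluster
    major_ok <- is.finite(sig_major) && sig_major > 1e-12 &&
      all(is.finite(fit$parameters$mean))
  }
  if (one_component) {
    flagged <- integer(0)
  } else if (major_ok) {
    mu_major <- fit$parameters$mean[major]
    lfdr <- fit$z[, major]                  # P(unrelated | coef)
    # related pairs must sit clearly above the unrelated bulk, not merely
    # in a spurious upper-tail component of a small sample
    cand <- which(coefs > mu_major + 3 * sqrt(sig_major))
    cand <- cand[order(lfdr[cand])]
    # largest prefix whose mean local FDR stays below the target
    cum <- cumsum(lfdr[cand]) / seq_along(cand)
    k <- if (length(cand)) max(0L, which(cum < fdr)) else 0L
    if (length(k) == 0L || is.infinite(k)) k <- 0L
    flagged <- cand[seq_len(k)]
  } else {
    warning("mixture fit degenerate; falling back to fixed threshold ",
            fallback_threshold)
    fit <- NULL
    flagged <- which(coefs > fallback_threshold)
  }
  pairs <- data.frame(a = ids[idx[flagged, 1]], b = ids[idx[flagged, 2]],
                      coef = coefs[flagged], stringsAsFactors = FALSE)
  removed <- character(0)
  live <- pairs
  while (nrow(live)) {
    cnt <- sort(table(c(live$a, live$b)), decreasing = TRUE)
    top <- cnt[cnt == max(cnt)]
    victim <- sort(names(top))[1]
    removed <- c(removed, victim)
    live <- live[live$a != victim & live$b != victim, , drop = FALSE]
  }
  list(kept = setdiff(ids, removed), removed = removed,
       flagged_pairs = pairs, mixture_fit = fit)
}

#' Linkage-disequilibrium decay
#'
#' Composite r-squared between SNP pairs from the genotype correlation (no
#' phasing), binned by physical distance and averaged over chromosomes.
#'
#' @param G a [genotype_table()].
#' @param population optional population label; default uses all samples.
#' @param max_dist_bp largest pair distance considered (default 5 Mb).
#' @param bin_bp distance bin width (default 50 kb).
#' @return data.frame with `dist_lo`, `dist_hi`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(G, population = NULL, max_dist_bp = 5e6, bin_bp = 5e4) {
  if (!is.null(population))
    G <- G[G$samples$population_id == population, ]
  nb <- ceiling(max_dist_bp / bin_bp)
  sums <- numeric(nb); cnts <- integer(nb)
  for (chr in unique(G$snps$chromosome)) {
    j <- which(G$snps$chromosome == chr)
    if (length(j) < 2) next
    pos <- G$snps$position_bp[j]
    X <- G$calls[, j, drop = FALSE]
    sdx <- apply(X, 2, stats::sd, na.rm = TRUE)
    for (a in seq_along(j)[-length(j)]) {
      bmax <- which(pos - pos[a] <= max_dist_bp)
      bmax <- bmax[bmax > a]
      if (!length(bmax)) next
      if (is.na(sdx[a]) || sdx[a] == 0) next
      for (b in bmax) {
        if (is.na(sdx[b]) || sdx[b] == 0) next
        r <- stats::cor(X[, a], X[, b], use = "pairwise.complete.obs")
        if (is.na(r)) next
        bin <- min(nb, 1L + (pos[b] - pos[a]) %/% bin_bp)
        sums[bin] <- sums[bin] + r * r
        cnts[bin] <- cnts[bin] + 1L
      }
    }
  }
  if (!sum(cnts)) stop("no SNP pair within max_dist_bp")
  data.frame(dist_lo = (seq_len(nb) - 1) * bin_bp,
             dist_hi = seq_len(nb) * bin_bp,
             mean_r2 = ifelse(cnts > 0, sums / cnts, NA_real_),
             n_pairs = cnts)
}

#' Construct a frequency table from a plain matrix
#'
#' Wraps a population x SNP frequency matrix (e.g. simulated true
#' frequencies) in the container produced by [allele_frequencies()] so it
#' can be fed to the scans directly.
#'
#' @param freq population x SNP matrix with population rownames.
#' @param snps optional SNP map (`snp_id`, `chromosome`, `position_bp`);
#'   defaults to a single-chromosome 10 kb grid.
#' @param n_obs optional matrix of non-missing allele counts (default:
#'   treated as population frequencies known exactly, `Inf`).
#' @return A `frequency_table`.
#' @export
frequency_table <- function(freq, snps = NULL, n_obs = NULL) {
  freq <- as.matrix(freq)
  if (is.null(rownames(freq))) stop("freq must have population rownames")
  if (is.null(snps))
    snps <- data.frame(snp_id = paste0("snp", seq_len(ncol(freq))),
                       chromosome = "1",
                       position_bp = seq_len(ncol(freq)) * 1e4,
                       allele_A = "A", allele_B = "B",
                       stringsAsFactors = FALSE)
  if (is.null(n_obs)) n_obs <- matrix(Inf, nrow(freq), ncol(freq))
  colnames(freq) <- snps$snp_id
  dimnames(n_obs) <- dimnames(freq)
  structure(list(freq = freq, n_obs = n_obs, snps = snps,
                 populations = rownames(freq)),
            class = "frequency_table")
}

#' Relatedness filtering within each population
#'
#' Convenience wrapper applying [compute_grm()] and [relatedness_filter()]
#' separately to every population (kinship coefficients are only
#' comparable within a breed: across-breed pairs reflect population
#' structure, not recent pedigree relationships).
#'
#' @param G a [genotype_table()].
#' @param fdr per-population relatedness FDR (default 0.05).
#' @return list with `kept`, `removed` (sample ids across all
#'   populations) and per-population `detail`.
#' @export
relatedness_filter_by_pop <- function(G, fdr = 0.05) {
  removed <- character(0)
  detail <- list()
  for (p in unique(G$samples$population_id)) {
    Gp <- G[G$samples$population_id == p, ]
    if (nrow(Gp$calls) < 3) next
    out <- tryCatch(relatedness_filter(compute_grm(Gp), fdr = fdr),
                    error = function(e) NULL)
    if (is.null(out)) next
    removed <- c(removed, out$removed)
    detail[[p]] <- out
  }
  list(kept = setdiff(G$samples$sample_id, removed), removed = removed,
       detail = detail)
}
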