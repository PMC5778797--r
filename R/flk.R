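#' Estimate the ancestral allele frequency of a SNP
#'
#' Generalised-least-squares estimate under the drift model:
#' `p0 = (1' F^-1 p) / (1' F^-1 1)`, clamped to \[0, 1\].  A 1e-8 ridge is
#' added to F when it is numerically singular.
#'
#' @param p vector of population allele frequencies (length = nrow(F)).
#' @param F population kinship matrix from [kinship_from_tree()].
#' @return Scalar ancestral frequency estimate.
#' @export
estimate_ancestral_freq <- function(p, F) {
  w <- .flk_weights(F)
  min(1, max(0, sum(w * p)))
}

.flk_weights <- function(F) {
  Fi <- .safe_solve(F)
  w <- Fi %*% rep(1, nrow(F))
  as.vector(w / sum(w))
}

.safe_solve <- function(F) {
  out <- tryCatch(solve(F), error = function(e) NULL)
  if (is.null(out)) {
    message("kinship matrix numerically singular; adding 1e-8 ridge")
    out <- solve(F + diag(1e-8, nrow(F)))
  }
  out
}

#' Ancestral minor-allele-frequency filter
#'
#' Keeps SNPs whose estimated ancestral minor allele frequency is at least
#' `threshold` (the scan default removes ancestral MAF below 5%).
#'
#' @param p0 vector of ancestral frequency estimates.
#' @param threshold minimum ancestral MAF (default 0.05).
#' @return Logical vector: `TRUE` for retained SNPs.
#' @export
ancestral_maf_filter <- function(p0, threshold = 0.05) {
  !is.na(p0) & pmin(p0, 1 - p0) >= threshold
}

#' FLK statistic for one SNP
#'
#' Quadratic form of the population frequency deviations against the drift
#' covariance: `flk = (p - p0 1)' [p0 (1 - p0) F]^-1 (p - p0 1)`, chi-squared
#' with `n_pops - 1` degrees of freedom under neutrality (one degree is
#' spent estimating the ancestral frequency).
#'
#' @param p vector of population allele frequencies.
#' @param p0 ancestral frequency in (0, 1).
#' @param F population kinship matrix.
#' @return list with `flk` and `p_value`.
#' @export
flk_statistic <- function(p, p0, F) {
  if (length(p) < 2) stop("need at least two populations")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly in (0, 1)")
  Fi <- .safe_solve(F)
  d <- p - p0
  flk <- as.numeric(t(d) %*% Fi %*% d) / (p0 * (1 - p0))
  list(flk = flk,
       p_value = stats::pchisq(flk, df = length(p) - 1, lower.tail = FALSE))
}

#' FLK genome scan
#'
#' Per-SNP FLK with GLS ancestral-frequency estimation, the ancestral-MAF
#' filter, chi-squared p-values (df = populations - 1) and q-values.
#'
#' @param x a [genotype_table()] or `frequency_table`.
#' @param F population kinship matrix; its row names select (and order) the
#'   scanned populations, so leave-one-out scans just pass a reduced F.
#' @param fdr significance level on q-values (default 0.01).
#' @param maf_threshold ancestral-MAF filter level (default 0.05).
#' @param qvalue_method `"storey"` or `"BH"`.
#' @param keep_freqs retain the population frequency matrix in the result
#'   (needed by [heterogeneity_report()]; default TRUE).
#' @param sampling_correction add the binomial sampling term to the drift
#'   covariance (`F_ii + (1 - F_ii) / (2 n_i)`, with `2 n_i` the
#'   population's mean non-missing allele count); on by default and a
#'   no-op when frequencies are exact (`n_obs` infinite).
#' @return Object of class `flk_scan`: a data.frame with columns `snp_id`,
#'   `chromosome`, `position_bp`, `p0`, `flk`, `pvalue`, `qvalue`,
#'   `significant`, plus attributes `F`, `df`, `freq`, `dropped_snps`.
#' @export
run_flk_scan <- function(x, F, fdr = 0.01, maf_threshold = 0.05,
                         qvalue_method = "storey", keep_freqs = TRUE,
                         sampling_correction = TRUE) {
  ft <- if (inherits(x, "genotype_table")) allele_frequencies(x) else x
  pops <- rownames(F)
  if (!all(pops %in% rownames(ft$freq)))
    stop("population in F absent from data: ",
         paste(setdiff(pops, rownames(ft$freq)), collapse = ", "))
  P <- ft$freq[pops, , drop = FALSE]
  if (sampling_correction) {
    n_all <- rowMeans(ft$n_obs[pops, , drop = FALSE], na.rm = TRUE)
    extra <- (1 - diag(F)) / n_all
    extra[!is.finite(extra)] <- 0
    F <- F + diag(extra, nrow(F))
  }
  defined <- colSums(is.na(P)) == 0
  w <- .flk_weights(F)
  p0 <- as.vector(crossprod(w, P))
  p0 <- pmin(1, pmax(0, p0))
  keep <- defined & ancestral_maf_filter(p0, maf_threshold)
  dropped <- ft$snps$snp_id[!keep]
  P <- P[, keep, drop = FALSE]
  p0 <- p0[keep]
  Fi <- .safe_solve(F)
  C <- sweep(P, 2, p0)
  flk <- colSums(C * (Fi %*% C)) / (p0 * (1 - p0))
  pval <- stats::pchisq(flk, df = length(pops) - 1, lower.tail = FALSE)
  qval <- fdr_qvalues(pval, method = qvalue_method)
  res <- data.frame(ft$snps[keep, c("snp_id", "chromosome", "position_bp")],
                    p0 = p0, flk = flk, pvalue = pval,
                    qvalue = as.numeric(qval),
                    significant = as.numeric(qval) < fdr,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("flk_scan", "data.frame"),
            F = F, df = length(pops) - 1, fdr = fdr,
            freq = if (keep_freqs) P else NULL, dropped_snps = dropped)
}

#' @export
print.flk_scan <- function(x, ...) {
  cat("FLK scan:", nrow(x), "SNPs,", attr(x, "df") + 1, "populations,",
      sum(x$significant), "significant at FDR", attr(x, "fdr"), "\n")
  print.data.frame(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
summary.flk_scan <- function(object, ...) {
  cat("FLK scan over", attr(object, "df") + 1, "populations (df =",
      attr(object, "df"), ")\n")
  cat("SNPs scanned:", nrow(object),
      " dropped (undefined/ancestral MAF):", length(attr(object, "dropped_snps")), "\n")
  cat(sprintf("mean FLK: %.3f (null expectation %d)\n",
              mean(object$flk), attr(object, "df")))
  cat("significant SNPs at FDR", attr(object, "fdr"), ":",
      sum(object$significant), "\n")
  invisible(object)
}

#' Manhattan-style plot of a scan
#'
#' @param x an `flk_scan` or `hapflk_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.flk_scan <- function(x, ...) {
  chr <- factor(x$chromosome, levels = unique(x$chromosome))
  offs <- c(0, cumsum(tapply(x$position_bp, chr, max)))
  gx <- x$position_bp + offs[as.integer(chr)]
  graphics::plot(gx, -log10(x$pvalue), pch = 20, cex = 0.4,
                 col = c("grey30", "steelblue")[1 + as.integer(chr) %% 2],
                 xlab = "genome position", ylab = "-log10 p", ...)
  if (any(x$significant))
    graphics::points(gx[x$significant], -log10(x$pvalue[x$significant]),
                     pch = 20, cex = 0.6, col = "firebrick")
  invisible(x)
}

#' Export a scan result as TSV
#'
#' Fixed column order: snp_id, chrom, pos, p0, flk, pvalue, qvalue,
#' significant (0/1); hapFLK scans add hapflk_raw, scale, dof.
#'
#' @param scan an `flk_scan` or `hapflk_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  d <- as.data.frame(scan)
  d$significant <- as.integer(d$significant)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
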