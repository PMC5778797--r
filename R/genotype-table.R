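#' Construct a genotype table
#'
#' The universal input container of the package: a sample-by-SNP matrix of
#' allele-B dosages (0, 1, 2 or `NA` for a missing call) together with a
#' sample sheet (sample id, population label) and a SNP map (id, chromosome,
#' 1-based physical position, alleles).
#'
#' @param calls integer matrix, samples in rows, SNPs in columns; entries
#'   0/1/2/`NA` counting copies of `allele_B`.
#' @param samples data.frame with columns `sample_id`, `population_id`.
#' @param snps data.frame with columns `snp_id`, `chromosome`, `position_bp`,
#'   `allele_A`, `allele_B`; positions must be strictly increasing within
#'   each chromosome.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(calls, samples, snps) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(
    all(c("sample_id", "population_id") %in% names(samples)),
    all(c("snp_id", "chromosome", "position_bp", "allele_A", "allele_B") %in% names(snps)),
    nrow(calls) == nrow(samples),
    ncol(calls) == nrow(snps)
  )
  samples$sample_id <- as.character(samples$sample_id)
  samples$population_id <- as.character(samples$population_id)
  snps$snp_id <- as.character(snps$snp_id)
  snps$chromosome <- as.character(snps$chromosome)
  snps$position_bp <- as.integer(snps$position_bp)
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample ids")
  for (chr in unique(snps$chromosome)) {
    pos <- snps$position_bp[snps$chromosome == chr]
    if (any(diff(pos) <= 0))
      stop("positions must be strictly increasing within chromosome ", chr)
  }
  dimnames(calls) <- list(samples$sample_id, snps$snp_id)
  structure(list(calls = calls, samples = samples, snps = snps),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$calls), "samples x", ncol(x$calls), "SNPs\n")
  cat("populations:", paste(sort(unique(x$samples$population_id)), collapse = ", "), "\n")
  cat("chromosomes:", paste(unique(x$snps$chromosome), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing call rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' Subset a genotype table
#'
#' @param x a `genotype_table`.
#' @param i sample index (logical, integer or sample id).
#' @param j SNP index (logical, integer or SNP id).
#' @param ... ignored.
#' @return The subsetted `genotype_table`.
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$snps$snp_id)
  genotype_table(x$calls[i, j, drop = FALSE],
                 x$samples[i, , drop = FALSE],
                 x$snps[j, , drop = FALSE])
}

#' Read a genotype table from the plain-text fixture dialect
#'
#' A TSV with columns `snp_id`, `chrom`, `pos`, `A`, `B` followed by one
#' column per sample, one SNP per row.  Sample column headers are either a
#' bare sample id or `sample_id:population_id`; bare ids fall in population
#' `"pop1"`.  Missing calls are written as `NA`.
#'
#' @param path file path.
#' @return A `genotype_table`.
#' @export
read_geno_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("snp_id", "chrom", "pos", "A", "B")
  if (!all(fixed %in% names(d)[1:5]))
    stop("malformed fixture file: expected columns snp_id, chrom, pos, A, B")
  sample_cols <- names(d)[-(1:5)]
  parts <- strsplit(sample_cols, ":", fixed = TRUE)
  samples <- data.frame(
    sample_id = vapply(parts, `[`, "", 1L),
    population_id = vapply(parts, function(p) if (length(p) > 1) p[2] else "pop1", ""),
    stringsAsFactors = FALSE
  )
  calls <- t(as.matrix(d[, -(1:5), drop = FALSE]))
  snps <- data.frame(snp_id = d$snp_id, chromosome = as.character(d$chrom),
                     position_bp = d$pos, allele_A = d$A, allele_B = d$B,
                     stringsAsFactors = FALSE)
  genotype_table(calls, samples, snps)
}

#' Write a genotype table in the plain-text fixture dialect
#'
#' @param G a `genotype_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geno_tsv <- function(G, path) {
  hdr <- ifelse(G$samples$population_id == "pop1" &
                  !grepl(":", G$samples$sample_id),
                G$samples$sample_id,
                paste0(G$samples$sample_id, ":", G$samples$population_id))
  d <- data.frame(snp_id = G$snps$snp_id, chrom = G$snps$chromosome,
                  pos = G$snps$position_bp, A = G$snps$allele_A,
                  B = G$snps$allele_B, stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(t(G$calls)))
  names(d) <- c("snp_id", "chrom", "pos", "A", "B", hdr)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
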