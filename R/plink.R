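# PLINK binary (.bed/.bim/.fam) IO.  The bed payload is SNP-major: three
# header bytes 0x6C 0x1B 0x01, then ceiling(n_samples / 4) bytes per SNP,
# two bits per sample (little-endian within each byte):
#   00 = hom A1A1, 01 = missing, 10 = het, 11 = hom A2A2.
# A1 maps to allele_A and A2 to allele_B, so the stored 2-bit code converts
# to the allele-B dosage as 00 -> 0, 10 -> 1, 11 -> 2, 01 -> NA.
# The FAM family-ID column carries the population label.

.bed_code_to_dosage <- c(0L, NA_integer_, 1L, 2L)   # index by code + 1

#' Read a PLINK bed/bim/fam file set
#'
#' @param bed_path path to the `.bed` file (or a prefix if `bim_path` and
#'   `fam_path` are missing).
#' @param bim_path,fam_path paths to the map and sample files; default to
#'   `bed_path` with the extension swapped.
#' @return A [genotype_table()] with the FAM family id as `population_id`.
#' @export
read_plink <- function(bed_path, bim_path = NULL, fam_path = NULL) {
  if (is.null(bim_path) && !grepl("\\.bed$", bed_path)) {
    bim_path <- paste0(bed_path, ".bim")
    fam_path <- paste0(bed_path, ".fam")
    bed_path <- paste0(bed_path, ".bed")
  }
  if (is.null(bim_path)) bim_path <- sub("\\.bed$", ".bim", bed_path)
  if (is.null(fam_path)) fam_path <- sub("\\.bed$", ".fam", bed_path)
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("file not found: ", f)

  fam <- utils::read.table(fam_path, stringsAsFactors = FALSE)
  bim <- utils::read.table(bim_path, stringsAsFactors = FALSE)
  if (ncol(bim) != 6) stop("malformed bim file: expected 6 columns")
  n <- nrow(fam); m <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B))
    stop("not a PLINK bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("unsupported bed mode byte (only SNP-major 0x01 is supported)")
  bpp <- ceiling(n / 4)
  if (length(raw) - 3L != bpp * m)
    stop("bed payload size does not match bim/fam dimensions")

  payload <- raw[-(1:3)]
  # unpack all 2-bit fields at once: byte -> 4 codes, little-endian
  b <- as.integer(payload)
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
  dim(codes) <- c(4L * bpp, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  calls <- .bed_code_to_dosage[codes + 1L]
  dim(calls) <- c(n, m)

  genotype_table(
    calls,
    samples = data.frame(sample_id = as.character(fam[[2]]),
                         population_id = as.character(fam[[1]]),
                         stringsAsFactors = FALSE),
    snps = data.frame(snp_id = as.character(bim[[2]]),
                      chromosome = as.character(bim[[1]]),
                      position_bp = as.integer(bim[[4]]),
                      allele_A = as.character(bim[[5]]),
                      allele_B = as.character(bim[[6]]),
                      stringsAsFactors = FALSE)
  )
}

#' Write a genotype table as PLINK bed/bim/fam
#'
#' @param G a [genotype_table()].
#' @param prefix output path prefix; `<prefix>.bed/.bim/.fam` are written.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  n <- nrow(G$calls); m <- ncol(G$calls)
  fam <- data.frame(G$samples$population_id, G$samples$sample_id,
                    0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(G$snps$chromosome, G$snps$snp_id, 0L,
                    G$snps$position_bp, G$snps$allele_A, G$snps$allele_B)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  # dosage -> 2-bit code: 0 -> 00, 1 -> 10, 2 -> 11, NA -> 01
  code <- matrix(1L, n, m)
  code[!is.na(G$calls) & G$calls == 0L] <- 0L
  code[!is.na(G$calls) & G$calls == 1L] <- 2L
  code[!is.na(G$calls) & G$calls == 2L] <- 3L
  bpp <- ceiling(n / 4)
  pad <- matrix(0L, 4L * bpp - n, m)
  code <- rbind(code, pad)
  dim(code) <- c(4L, bpp * m)
  bytes <- as.raw(code[1, ] + 4L * code[2, ] + 16L * code[3, ] + 64L * code[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}
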