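#' Build selection-signature regions from significant SNPs
#'
#' Chain-merges significant SNPs: consecutive significant SNPs on the same
#' chromosome at most `gap_bp` apart join one region.  Region boundaries
#' are the span of member SNPs (closed, 1-based), not extended by the gap.
#' Regions with fewer than `min_snps` members are kept but flagged below
#' the gene-annotation threshold (the single-SNP scan rule uses 10, the
#' haplotype scan rule 5).
#'
#' @param scan a scan data.frame (e.g. [run_flk_scan()] output) with
#'   columns `chromosome`, `position_bp`, `snp_id`, `pvalue` and
#'   `significant`, sorted by (chromosome, position); or any data.frame of
#'   significant SNPs if `significant` is absent.
#' @param gap_bp maximum within-region gap (default 1 Mb).
#' @param min_snps minimum members for gene annotation (default 10).
#' @return data.frame of class `selection_signatures`: `region_id`,
#'   `chromosome`, `start_bp`, `end_bp`, `n_significant`, `best_snp`,
#'   `best_pos`, `best_p`, `annotatable`, plus a list column `member_snps`.
#' @export
build_regions <- function(scan, gap_bp = 1e6, min_snps = 10) {
  d <- as.data.frame(scan)
  if ("significant" %in% names(d)) d <- d[as.logical(d$significant), , drop = FALSE]
  if (!nrow(d))
    return(structure(data.frame(region_id = character(), chromosome = character(),
                                start_bp = integer(), end_bp = integer(),
                                n_significant = integer(), best_snp = character(),
                                best_pos = integer(), best_p = numeric(),
                                annotatable = logical()),
                     class = c("selection_signatures", "data.frame")))
  for (chr in unique(d$chromosome)) {
    pos <- d$position_bp[d$chromosome == chr]
    if (is.unsorted(pos, strictly = TRUE))
      stop("SNPs must be sorted by position within chromosome")
  }
  new_region <- c(TRUE, d$chromosome[-1] != d$chromosome[-nrow(d)] |
                    diff(d$position_bp) > gap_bp)
  grp <- cumsum(new_region)
  out <- lapply(split(seq_len(nrow(d)), grp), function(ix) {
    dd <- d[ix, , drop = FALSE]
    best <- if ("pvalue" %in% names(dd)) {
      # smallest p, ties broken by smaller position
      dd[order(dd$pvalue, dd$position_bp), , drop = FALSE][1, ]
    } else dd[1, ]
    data.frame(chromosome = dd$chromosome[1],
               start_bp = min(dd$position_bp), end_bp = max(dd$position_bp),
               n_significant = nrow(dd), best_snp = best$snp_id,
               best_pos = best$position_bp,
               best_p = if ("pvalue" %in% names(dd)) best$pvalue else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- cbind(region_id = sprintf("region_%03d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  res$annotatable <- res$n_significant >= min_snps
  res$member_snps <- lapply(split(d$snp_id, grp), identity)
  rownames(res) <- NULL
  structure(res, class = c("selection_signatures", "data.frame"),
            gap_bp = gap_bp, min_snps = min_snps)
}

#' @export
print.selection_signatures <- function(x, ...) {
  cat("selection signatures:", nrow(x), "regions (gap",
      attr(x, "gap_bp"), "bp )\n")
  print.data.frame(x[, setdiff(names(x), "member_snps")])
  invisible(x)
}

#' Read gene records from a GFF3 file
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default `"gene"`).
#' @param id_attr attribute keys tried in order for the gene id
#'   (default `ID` then `Name`).
#' @return data.frame `gene_id`, `chromosome`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates).
#' @export
read_gene_set <- function(path, feature = "gene", id_attr = c("ID", "Name")) {
  g <- ape::read.gff(path)
  g <- g[g$type == feature, , drop = FALSE]
  ids <- rep(NA_character_, nrow(g))
  for (key in id_attr) {
    pat <- paste0("(^|;)\\s*", key, "=([^;]+)")
    m <- regmatches(g$attributes, regexec(pat, g$attributes))
    val <- vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
    ids[is.na(ids)] <- val[is.na(ids)]
  }
  data.frame(gene_id = ids, chromosome = as.character(g$seqid),
             start = g$start, end = g$end, strand = as.character(g$strand),
             stringsAsFactors = FALSE)
}

#' Rank genes in a region by distance to the best SNP
#'
#' Genes whose interval overlaps the region span are listed with the
#' distance from the gene midpoint to the best SNP and ranked ascending
#' (ties broken by smaller gene id); the closest gene is the best gene.
#'
#' @param region one row of a [build_regions()] result (or any list with
#'   `chromosome`, `start_bp`, `end_bp`, `best_pos`).
#' @param genes a gene set from [read_gene_set()].
#' @return data.frame `gene_id`, `midpoint_bp`, `distance_to_best`, `rank`,
#'   ordered by rank; zero rows when no gene overlaps.
#' @export
annotate_genes <- function(region, genes) {
  g <- genes[genes$chromosome == region$chromosome &
               genes$start <= region$end_bp &
               genes$end >= region$start_bp, , drop = FALSE]
  if (!nrow(g))
    return(data.frame(gene_id = character(), midpoint_bp = numeric(),
                      distance_to_best = numeric(), rank = integer()))
  mid <- (g$start + g$end) / 2
  dist <- abs(mid - region$best_pos)
  ord <- order(dist, g$gene_id)
  data.frame(gene_id = g$gene_id[ord], midpoint_bp = mid[ord],
             distance_to_best = dist[ord], rank = seq_along(ord),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare two region sets
#'
#' Classifies every region as shared (any bp overlap with a region of the
#' other set on the same chromosome) or private, and reports merged-span
#' summary statistics per set (count, mean length) for size comparisons
#' between scans.
#'
#' @param set_a,set_b [build_regions()] results (or data.frames with
#'   `chromosome`, `start_bp`, `end_bp`).
#' @return list with `a` and `b` (the inputs plus a `status` column of
#'   `"shared"`/`"a_only"` resp. `"b_only"`) and `summary` (per-set count
#'   and mean merged-span length).
#' @export
compare_region_sets <- function(set_a, set_b) {
  overlap_any <- function(x, other) {
    vapply(seq_len(nrow(x)), function(i) {
      any(other$chromosome == x$chromosome[i] &
            other$start_bp <= x$end_bp[i] &
            other$end_bp >= x$start_bp[i])
    }, logical(1))
  }
  a <- as.data.frame(set_a); b <- as.data.frame(set_b)
  a$status <- ifelse(nrow(b) > 0 & overlap_any(a, b), "shared", "a_only")
  b$status <- ifelse(nrow(a) > 0 & overlap_any(b, a), "shared", "b_only")
  span <- function(x) {
    if (!nrow(x)) return(c(n = 0, mean_length = NA_real_))
    lens <- unlist(lapply(split(x, x$chromosome), function(xx) {
      xx <- xx[order(xx$start_bp), ]
      merged <- list()
      cur <- c(xx$start_bp[1], xx$end_bp[1])
      for (i in seq_len(nrow(xx))[-1]) {
        if (xx$start_bp[i] <= cur[2]) cur[2] <- max(cur[2], xx$end_bp[i])
        else { merged <- c(merged, list(cur)); cur <- c(xx$start_bp[i], xx$end_bp[i]) }
      }
      merged <- c(merged, list(cur))
      vapply(merged, function(m) m[2] - m[1] + 1, numeric(1))
    }))
    c(n = length(lens), mean_length = mean(lens))
  }
  list(a = a, b = b,
       summary = rbind(a = span(a), b = span(b)))
}

#' Write regions as BED-like and annotated TSV
#'
#' @param regions a [build_regions()] result.
#' @param path output TSV path (BED-style half-open start).
#' @return `path`, invisibly.
#' @export
write_regions_tsv <- function(regions, path) {
  d <- as.data.frame(regions)
  out <- data.frame(chrom = d$chromosome, start = d$start_bp - 1L,
                    end = d$end_bp, n_snps = d$n_significant,
                    best_snp = d$best_snp, best_p = d$best_p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
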