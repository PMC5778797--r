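#' Reynolds distance between two populations
#'
#' Coancestry distance from allele frequencies, summed over usable loci:
#' `D = sum_l sum_u (p_au - p_bu)^2 / (2 * sum_l (1 - sum_u p_au p_bu))`
#' with `u` running over the two alleles.  Approximately linear in
#' divergence time under pure drift.  The 1983 sample-size-corrected
#' estimator is available when allele counts are present.
#'
#' @param freqs a `frequency_table` from [allele_frequencies()].
#' @param pop_a,pop_b population labels.
#' @param snp_subset optional indices or SNP ids restricting the loci.
#' @param corrected use the sample-size-corrected estimator (default FALSE).
#' @return Non-negative scalar distance.
#' @export
reynolds_distance <- function(freqs, pop_a, pop_b, snp_subset = NULL,
                              corrected = FALSE) {
  pa <- freqs$freq[pop_a, ]
  pb <- freqs$freq[pop_b, ]
  na <- freqs$n_obs[pop_a, ] / 2               # diploid sample sizes
  nb <- freqs$n_obs[pop_b, ] / 2
  if (!is.null(snp_subset)) {
    pa <- pa[snp_subset]; pb <- pb[snp_subset]
    na <- na[snp_subset]; nb <- nb[snp_subset]
  }
  use <- !is.na(pa) & !is.na(pb)
  if (!any(use)) stop("no usable locus for Reynolds distance")
  pa <- pa[use]; pb <- pb[use]; na <- na[use]; nb <- nb[use]
  if (!corrected) {
    num <- sum((pa - pb)^2) * 2                # both alleles
    den <- 2 * sum(1 - (pa * pb + (1 - pa) * (1 - pb)))
    if (den <= 0) return(0)
    return(num / den)
  }
  ha <- 2 * na / (2 * na - 1) * (1 - pa^2 - (1 - pa)^2)
  hb <- 2 * nb / (2 * nb - 1) * (1 - pb^2 - (1 - pb)^2)
  ss <- 2 * (pa - pb)^2                        # sum over both alleles
  al <- ss / 2 - (na + nb) * (na * ha + nb * hb) / (4 * na * nb * (na + nb - 1))
  bl <- ss / 2 + (4 * na * nb - na - nb) * (na * ha + nb * hb) /
    (4 * na * nb * (na + nb - 1))
  den <- sum(bl)
  if (den <= 0) return(0)
  max(0, sum(al) / den)
}

#' Reynolds distance matrix over all populations
#'
#' @inheritParams reynolds_distance
#' @return Symmetric zero-diagonal matrix of class `dist_matrix`.
#' @export
build_distance_matrix <- function(freqs, snp_subset = NULL, corrected = FALSE) {
  pops <- freqs$populations
  D <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops))
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <-
        reynolds_distance(freqs, pops[i], pops[j], snp_subset, corrected)
    }
  class(D) <- c("dist_matrix", "matrix")
  D
}

#' Neighbour-joining population tree rooted on an outgroup
#'
#' Builds the NJ topology from a Reynolds distance matrix, clamps negative
#' branch lengths to zero (shifting the deficit onto the sibling branch),
#' roots the tree at the midpoint of the outgroup's branch, and provides the
#' outgroup-pruned ingroup tree used for the kinship matrix F.
#'
#' @param D distance matrix (populations in rows/columns).
#' @param outgroup label of the outgroup population.
#' @return An object of class `population_tree`: list with `tree` (rooted
#'   `phylo` including the outgroup), `ingroup` (rooted `phylo` without it)
#'   and `outgroup`.
#' @export
nj_tree <- function(D, outgroup) {
  if (!all(is.finite(D))) stop("non-finite distances")
  if (nrow(D) < 3) stop("need at least 3 populations")
  if (!outgroup %in% rownames(D)) stop("outgroup not in distance matrix")
  tr <- ape::nj(stats::as.dist(D))
  tr <- .clamp_negative_edges(tr)
  tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  tr <- .clamp_negative_edges(tr)
  # midpoint-root on the outgroup branch: split its terminal edge evenly
  # between the outgroup edge and the ingroup side of the root
  og_tip <- which(tr$tip.label == outgroup)
  root_node <- ape::Ntip(tr) + 1L
  og_edge <- which(tr$edge[, 1] == root_node & tr$edge[, 2] == og_tip)
  sib_edge <- which(tr$edge[, 1] == root_node & tr$edge[, 2] != og_tip)
  if (length(og_edge) == 1 && length(sib_edge) == 1) {
    tot <- tr$edge.length[og_edge] + tr$edge.length[sib_edge]
    tr$edge.length[og_edge] <- tot / 2
    tr$edge.length[sib_edge] <- tot / 2
  }
  ingroup <- ape::drop.tip(tr, outgroup)
  ingroup$root.edge <- NULL
  structure(list(tree = tr, ingroup = ingroup, outgroup = outgroup),
            class = "population_tree")
}

.clamp_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs))
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' @export
print.population_tree <- function(x, ...) {
  cat("population_tree rooted on outgroup", x$outgroup, "with",
      ape::Ntip(x$ingroup), "ingroup populations\n")
  cat(ape::write.tree(x$tree), "\n")
  invisible(x)
}

#' Population kinship matrix F from a rooted tree
#'
#' `F[i, j]` is the drift shared on the root-to-i and root-to-j paths, i.e.
#' the root-to-MRCA(i, j) path length; `F[i, i]` is the root-to-leaf path
#' length.  Branch lengths are on the Reynolds (drift) scale.
#'
#' @param tree a rooted `phylo`, or a `population_tree` (its outgroup-pruned
#'   ingroup tree is used).
#' @return Symmetric positive semidefinite matrix of class `kinship_f`.
#' @export
kinship_from_tree <- function(tree) {
  if (inherits(tree, "population_tree")) tree <- tree$ingroup
  if (!inherits(tree, "phylo")) stop("tree must be a phylo or population_tree")
  if (!ape::is.rooted(tree) && is.null(tree$root.edge))
    stop("tree must be rooted")
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)   # distance from root
  mr <- ape::mrca(tree)
  F <- matrix(depth[mr], ntip, ntip)
  diag(F) <- depth[seq_len(ntip)]
  dimnames(F) <- list(tree$tip.label, tree$tip.label)
  class(F) <- c("kinship_f", "matrix")
  F
}

#' Re-fit branch lengths of a fixed topology to local distances
#'
#' Keeps the global tree's topology and re-estimates every branch length by
#' non-negative least squares of the leaf-to-leaf path lengths against a
#' local (regional) Reynolds distance matrix.  A binary root makes the two
#' root-child branches jointly identified only through their sum; the fitted
#' sum is split in the same proportion as in the global tree so that
#' identical input distances reproduce the global fit exactly.
#'
#' @param global_tree rooted `phylo` (or `population_tree`) whose topology
#'   is retained.
#' @param local_D distance matrix over the same leaf labels.
#' @return A `phylo` with re-fitted branch lengths; attribute
#'   `rank_deficient` flags an under-determined design beyond the root pair.
#' @export
fit_local_tree <- function(global_tree, local_D) {
  if (inherits(global_tree, "population_tree")) global_tree <- global_tree$ingroup
  tr <- global_tree
  tips <- tr$tip.label
  if (!all(tips %in% rownames(local_D)))
    stop("local_D must cover all tree leaves")
  local_D <- local_D[tips, tips]
  ntip <- length(tips)
  nedge <- nrow(tr$edge)
  # edge sets on each root-to-leaf path
  paths <- lapply(seq_len(ntip), function(tip) {
    e <- integer(0)
    node <- tip
    repeat {
      row <- which(tr$edge[, 2] == node)
      if (!length(row)) break
      e <- c(e, row)
      node <- tr$edge[row, 1]
    }
    e
  })
  pairs <- utils::combn(ntip, 2)
  X <- matrix(0, ncol(pairs), nedge)
  d <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    on_path <- union(setdiff(paths[[i]], paths[[j]]),
                     setdiff(paths[[j]], paths[[i]]))
    X[k, on_path] <- 1
    d[k] <- local_D[i, j]
  }
  root <- ape::Ntip(tr) + 1L
  root_edges <- which(tr$edge[, 1] == root)
  merged <- NULL
  if (length(root_edges) == 2) {
    # merge the two root-child columns (identical across all leaf pairs)
    merged <- root_edges
    X2 <- X[, -merged[2], drop = FALSE]
    fit <- pracma::lsqnonneg(X2, d)
    bl <- numeric(nedge)
    bl[-merged[2]] <- fit$x
    tot <- bl[merged[1]]
    g1 <- tr$edge.length[merged[1]]; g2 <- tr$edge.length[merged[2]]
    w <- if (g1 + g2 > 0) g1 / (g1 + g2) else 0.5
    bl[merged[1]] <- tot * w
    bl[merged[2]] <- tot * (1 - w)
    rank_ok <- qr(X2)$rank == ncol(X2)
  } else {
    fit <- pracma::lsqnonneg(X, d)
    bl <- fit$x
    rank_ok <- qr(X)$rank == ncol(X)
  }
  tr$edge.length <- bl
  attr(tr, "rank_deficient") <- !rank_ok
  tr
}

#' Estimate the population kinship matrix F from allele frequencies
#'
#' Pipeline convenience tying the pieces together: Reynolds distances,
#' neighbour-joining, outgroup rooting, outgroup pruning and the path-sum
#' kinship matrix.  The pairwise Reynolds distance estimates the *average*
#' of the two populations' drift from their common ancestor, i.e. half the
#' additive tree distance `F_ii + F_jj - 2 F_ij`, so distances are doubled
#' before tree fitting to put branch lengths on the drift scale that the
#' FLK covariance `p0 (1 - p0) F` requires.
#'
#' @param freqs a `frequency_table` covering ingroup populations and the
#'   outgroup.
#' @param outgroup population label used for rooting, then pruned.
#' @param snp_subset optional SNP subset (regional kinship).
#' @return list-free `kinship_f` matrix over the ingroup populations, with
#'   the rooted `population_tree` in attribute `tree`.
#' @export
estimate_kinship <- function(freqs, outgroup, snp_subset = NULL) {
  D <- build_distance_matrix(freqs, snp_subset = snp_subset)
  pt <- nj_tree(2 * unclass(D), outgroup)
  F <- kinship_from_tree(pt)
  attr(F, "tree") <- pt
  F
}
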