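# Synthetic drift/sweep data with known truth: populations drift along a
# rooted tree with branch lengths on the Reynolds (drift) scale; sweeps are
# instantaneous frequency displacements in the target populations, so the
# truth table is exact.  Defaults reflect a dense-array livestock-breed
# panel: 8 populations, total drift 0.2, ~20 diploid samples per breed.

#' Random rooted population tree with a given total drift
#'
#' @param n_pops number of leaf populations.
#' @param total_drift sum of all branch lengths (drift units, default 0.2).
#' @param seed RNG seed.
#' @return Rooted `phylo` with tips `pop1..popN`.
#' @export
sim_population_tree <- function(n_pops, total_drift = 0.2, seed = 1) {
  set.seed(seed)
  tr <- ape::rtree(n_pops, rooted = TRUE, tip.label = paste0("pop", seq_len(n_pops)))
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * total_drift
  tr
}

# vectorised truncated-normal on [0, 1] by inverse-CDF
.rtrunc01 <- function(mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  x <- stats::qnorm(stats::runif(length(mean), lo, hi), mean, sd)
  out <- pmin(1, pmax(0, x))
  out[sd == 0] <- mean[sd == 0]
  out
}

#' Simulate neutral allele frequencies drifting along a tree
#'
#' Ancestral frequencies `p0` are drawn per SNP and propagated from the
#' root to every leaf.  The `truncated_normal` engine draws each child as
#' `Normal(parent, p0 (1 - p0) * branch_length)` truncated to \[0, 1\]
#' (the Gaussian drift approximation underlying FLK, with the variance tied
#' to the ancestral heterozygosity).  The `wright_fisher` engine iterates
#' binomial resampling in a population of `Ne` diploids for
#' `round(2 Ne * branch_length)` generations.
#'
#' @param tree rooted `phylo` with drift-scale branch lengths.
#' @param n_snps number of SNPs.
#' @param p0 either a length-2 vector `c(lo, hi)` for uniform ancestral
#'   frequencies (default `c(0.1, 0.9)`, emulating the intermediate-frequency
#'   ascertainment of genotyping arrays) or a function `(n) -> p0`.
#' @param engine `"truncated_normal"` (default) or `"wright_fisher"`.
#' @param Ne diploid effective size per branch for the Wright-Fisher
#'   engine (default 100).
#' @param seed RNG seed.
#' @return list: `freq` (population x SNP), `p0`, `tree`,
#'   `F` (the true kinship matrix of the tree).
#' @export
simulate_frequencies <- function(tree, n_snps, p0 = c(0.1, 0.9),
                                 engine = c("truncated_normal", "wright_fisher"),
                                 Ne = 100, seed = 1) {
  engine <- match.arg(engine)
  if (any(tree$edge.length < 0)) stop("negative branch length")
  set.seed(seed)
  p0v <- if (is.function(p0)) p0(n_snps) else stats::runif(n_snps, p0[1], p0[2])
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  node_freq <- matrix(NA_real_, nnode, n_snps)
  root <- ntip + 1L
  node_freq[root, ] <- p0v
  # preorder traversal: parents of reorder(tree)$edge come before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    len <- ord$edge.length[e]
    parent_p <- node_freq[par, ]
    if (len == 0) {
      node_freq[child, ] <- parent_p
    } else if (engine == "truncated_normal") {
      node_freq[child, ] <- .rtrunc01(parent_p, sqrt(p0v * (1 - p0v) * len))
    } else {
      gen <- max(1L, round(2 * Ne * len))
      x <- parent_p
      for (g in seq_len(gen))
        x <- stats::rbinom(n_snps, 2 * Ne, x) / (2 * Ne)
      node_freq[child, ] <- x
    }
  }
  freq <- node_freq[seq_len(ntip), , drop = FALSE]
  rownames(freq) <- tree$tip.label
  list(freq = freq, p0 = p0v, tree = tree, F = kinship_from_tree(tree))
}

#' Inject selection events into a frequency matrix
#'
#' A sweep event displaces the frequency at the event loci toward `target`
#' in the target populations (instantaneous displacement: the scan
#' statistics respond to the final frequency pattern and the truth stays
#' exact).  An optional `ld_profile` gives per-locus hitchhiking weights in
#' \[0, 1\]: the core locus (weight 1) is fully swept while flanking loci
#' move only part of the way, mimicking the decay of association with the
#' selected haplotype.  An introgression event copies the donor
#' population's local frequency profile into the recipient over a window.
#' Allelic heterogeneity is two sweep events at nearby loci in different
#' populations.
#'
#' @param freq population x SNP frequency matrix.
#' @param events list of events; a sweep is
#'   `list(type = "sweep", loci, populations, target)` (`type` may be
#'   omitted) with optional `ld_profile` (weights recycled over `loci`),
#'   an introgression is `list(type = "introgression", loci, donor,
#'   recipient)`.
#' @return list: `freq` (modified matrix) and `truth` (data.frame `locus`,
#'   `population`, `target`).
#' @export
inject_selection <- function(freq, events) {
  truth <- data.frame(locus = integer(), population = character(),
                      target = numeric(), stringsAsFactors = FALSE)
  seen <- list()
  for (ev in events) {
    type <- if (is.null(ev$type)) "sweep" else ev$type
    if (any(ev$loci < 1 | ev$loci > ncol(freq))) stop("event locus out of range")
    if (type == "sweep") {
      if (ev$target < 0 || ev$target > 1) stop("target frequency outside [0, 1]")
      wts <- if (is.null(ev$ld_profile)) rep(1, length(ev$loci))
             else rep_len(ev$ld_profile, length(ev$loci))
      if (any(wts < 0 | wts > 1)) stop("ld_profile weights outside [0, 1]")
      for (pop in ev$populations) for (i in seq_along(ev$loci)) {
        l <- ev$loci[i]
        new_p <- freq[pop, l] + (ev$target - freq[pop, l]) * wts[i]
        key <- paste(pop, l)
        if (!is.null(seen[[key]]) && abs(seen[[key]] - new_p) > 1e-12)
          stop("contradictory selection events at locus ", l, " in ", pop)
        seen[[key]] <- new_p
        freq[pop, l] <- new_p
        truth <- rbind(truth, data.frame(locus = l, population = pop,
                                         target = new_p))
      }
    } else if (type == "introgression") {
      freq[ev$recipient, ev$loci] <- freq[ev$donor, ev$loci]
      truth <- rbind(truth,
                     data.frame(locus = ev$loci, population = ev$recipient,
                                target = freq[ev$donor, ev$loci]))
    } else stop("unknown event type: ", type)
  }
  list(freq = freq, truth = truth)
}

#' Sample diploid genotypes from population frequencies
#'
#' Calls are independent `Binomial(2, p)` draws per individual.
#'
#' @param freq population x SNP frequency matrix (rownames = populations).
#' @param n_per_pop samples per population (scalar or named vector).
#' @param spacing_bp physical spacing between adjacent SNPs (default 10 kb,
#'   single chromosome).
#' @param seed RNG seed.
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(freq, n_per_pop = 20, spacing_bp = 1e4,
                               seed = 1) {
  if (any(freq < 0 | freq > 1)) stop("frequencies outside [0, 1]")
  set.seed(seed)
  pops <- rownames(freq)
  S <- ncol(freq)
  if (length(n_per_pop) == 1) n_per_pop <- stats::setNames(rep(n_per_pop, length(pops)), pops)
  calls <- do.call(rbind, lapply(pops, function(p) {
    matrix(stats::rbinom(n_per_pop[p] * S, 2, rep(freq[p, ], each = n_per_pop[p])),
           n_per_pop[p], S)
  }))
  samples <- data.frame(
    sample_id = unlist(lapply(pops, function(p) paste0(p, "_", seq_len(n_per_pop[p])))),
    population_id = rep(pops, n_per_pop[pops]),
    stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = paste0("snp", seq_len(S)), chromosome = "1",
                     position_bp = seq_len(S) * spacing_bp,
                     allele_A = "A", allele_B = "B", stringsAsFactors = FALSE)
  genotype_table(calls, samples, snps)
}

#' Simulate mosaic haplotypes from K founders
#'
#' K founder haplotypes are drawn per SNP from a shared base frequency;
#' founder weights drift along the tree on the logit scale (keeping the
#' simplex valid without rejection); each haplotype is a mosaic that
#' re-draws its founder with probability `switch_rate` per SNP interval,
#' and copies the founder allele with a small emission error.
#'
#' @param tree rooted `phylo` over the populations.
#' @param n_snps number of SNPs.
#' @param K number of founder haplotypes (at least 2).
#' @param n_hap_per_pop haplotypes per population (default 40, i.e. 20
#'   diploids).
#' @param switch_rate per-interval founder re-draw probability
#'   (default 0.02).
#' @param noise allele copy-error rate (default 0.02).
#' @param weight_sd drift scale of the founder log-weights per unit branch
#'   length (default 3).
#' @param seed RNG seed.
#' @return list: `haplotypes` (n x S, 0/1), `populations`, `founders`
#'   (K x S), `founder_paths` (n x S founder index), `weights`
#'   (population x K), `snps`, `tree`.
#' @export
simulate_haplotypes <- function(tree, n_snps, K = 3, n_hap_per_pop = 40,
                                switch_rate = 0.02, noise = 0.02,
                                weight_sd = 3, seed = 1) {
  if (K < 2) stop("need at least 2 founders")
  if (switch_rate <= 0 || switch_rate >= 1) stop("switch rate outside (0, 1)")
  set.seed(seed)
  base <- stats::runif(n_snps, 0.1, 0.9)
  founders <- matrix(stats::rbinom(K * n_snps, 1, rep(base, each = K)), K, n_snps)
  # founder weights per population: logistic-normal drift along the tree
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  logw <- matrix(NA_real_, nnode, K)
  logw[ntip + 1L, ] <- 0
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    logw[child, ] <- logw[par, ] +
      stats::rnorm(K, 0, weight_sd * sqrt(ord$edge.length[e]))
  }
  W <- exp(logw[seq_len(ntip), , drop = FALSE])
  W <- W / rowSums(W)
  rownames(W) <- tree$tip.label
  pops <- rep(tree$tip.label, each = n_hap_per_pop)
  n <- length(pops)
  haps <- matrix(0L, n, n_snps)
  paths <- matrix(0L, n, n_snps)
  for (i in seq_len(n)) {
    w <- W[pops[i], ]
    f <- sample.int(K, 1, prob = w)
    jump <- stats::runif(n_snps) < switch_rate
    jump[1] <- FALSE
    for (s in seq_len(n_snps)) {
      if (jump[s]) f <- sample.int(K, 1, prob = w)
      paths[i, s] <- f
    }
    haps[i, ] <- founders[cbind(paths[i, ], seq_len(n_snps))]
  }
  flip <- matrix(stats::runif(n * n_snps) < noise, n, n_snps)
  haps[flip] <- 1L - haps[flip]
  snps <- data.frame(snp_id = paste0("snp", seq_len(n_snps)), chromosome = "1",
                     position_bp = seq_len(n_snps) * 1e4,
                     allele_A = "A", allele_B = "B", stringsAsFactors = FALSE)
  list(haplotypes = haps, populations = pops, founders = founders,
       founder_paths = paths, weights = W, snps = snps, tree = tree)
}

#' Fix one founder haplotype in a population over a window
#'
#' Models a hard sweep on the haplotype scale: a fraction of the
#' population's haplotypes is replaced by the chosen founder's segment
#' across the window.
#'
#' @param sim a [simulate_haplotypes()] result.
#' @param population target population label.
#' @param founder founder index driven to high frequency.
#' @param window SNP index range (integer vector).
#' @param fraction fraction of haplotypes swept (default 1).
#' @param seed RNG seed for choosing the swept haplotypes.
#' @return The modified simulation, with a `sweep_truth` entry.
#' @export
fix_founder_window <- function(sim, population, founder, window,
                               fraction = 1, seed = 1) {
  set.seed(seed)
  rows <- which(sim$populations == population)
  rows <- sample(rows, max(1, round(fraction * length(rows))))
  for (i in rows) {
    sim$haplotypes[i, window] <- sim$founders[founder, window]
    sim$founder_paths[i, window] <- founder
  }
  sim$sweep_truth <- rbind(sim$sweep_truth,
                           data.frame(population = population,
                                      founder = founder,
                                      start = min(window), end = max(window)))
  sim
}

#' Spike related sample pairs into a genotype table
#'
#' Kinship-1/2 pairs are made by duplicating a sample's genotype onto
#' another sample; kinship-1/4 pairs by gene-dropping two individuals from
#' one shared parent (the other parental allele is drawn from the
#' population frequency).
#'
#' @param G a [genotype_table()].
#' @param pairs list of `list(kinship = 0.5 or 0.25, count = k)`.
#' @param seed RNG seed.
#' @return list: `genotypes` (modified table) and `truth` (data.frame
#'   `sample_a`, `sample_b`, `kinship`).
#' @export
spike_related_pairs <- function(G, pairs, seed = 1) {
  set.seed(seed)
  truth <- data.frame(sample_a = character(), sample_b = character(),
                      kinship = numeric(), stringsAsFactors = FALSE)
  total <- sum(vapply(pairs, function(p) p$count, numeric(1))) * 2
  if (total > nrow(G$calls)) stop("not enough samples to build related pairs")
  if (!total) return(list(genotypes = G, truth = truth))
  pool <- sample(nrow(G$calls), total)
  freq <- colMeans(G$calls, na.rm = TRUE) / 2
  k <- 1L
  for (p in pairs) {
    for (r in seq_len(p$count)) {
      a <- pool[k]; b <- pool[k + 1L]; k <- k + 2L
      if (p$kinship >= 0.5) {
        G$calls[b, ] <- G$calls[a, ]
      } else {
        # shared parent = sample a's genotype; both a and b become children
        parent <- G$calls[a, ]
        drop_allele <- function() {
          from_par <- ifelse(is.na(parent), stats::rbinom(length(parent), 1, freq),
                             ifelse(parent == 1L, stats::rbinom(length(parent), 1, 0.5),
                                    parent %/% 2L))
          from_par + stats::rbinom(length(parent), 1, freq)
        }
        G$calls[a, ] <- drop_allele()
        G$calls[b, ] <- drop_allele()
      }
      truth <- rbind(truth, data.frame(sample_a = G$samples$sample_id[a],
                                       sample_b = G$samples$sample_id[b],
                                       kinship = p$kinship))
    }
  }
  list(genotypes = G, truth = truth)
}

#' Simulate a complete dataset with truth tables
#'
#' Convenience wrapper: tree, neutral frequencies, optional selection
#' events, genotype sampling and optional related-pair spikes, with every
#' latent quantity recorded.
#'
#' @param n_pops,total_drift,n_snps,p0,engine,Ne as in the component
#'   generators.
#' @param n_per_pop diploid samples per population (default 20).
#' @param spacing_bp SNP spacing (default 10 kb).
#' @param selection_events passed to [inject_selection()].
#' @param related_pairs passed to [spike_related_pairs()].
#' @param seed RNG seed (mandatory; all stages derive from it).
#' @return list: `genotypes`, `truth` (list with `tree`, `F`, `p0`,
#'   `freq`, `selection`, `related_pairs`).
#' @export
simulate_dataset <- function(seed, n_pops = 8, total_drift = 0.2,
                             n_snps = 5000, n_per_pop = 20, p0 = c(0.1, 0.9),
                             engine = "truncated_normal", Ne = 100,
                             spacing_bp = 1e4, selection_events = list(),
                             related_pairs = list()) {
  tree <- sim_population_tree(n_pops, total_drift, seed = seed)
  fr <- simulate_frequencies(tree, n_snps, p0 = p0, engine = engine,
                             Ne = Ne, seed = seed + 1)
  sel <- inject_selection(fr$freq, selection_events)
  G <- simulate_genotypes(sel$freq, n_per_pop = n_per_pop,
                          spacing_bp = spacing_bp, seed = seed + 2)
  rel <- spike_related_pairs(G, related_pairs, seed = seed + 3)
  list(genotypes = rel$genotypes,
       truth = list(tree = tree, F = fr$F, p0 = fr$p0, freq = sel$freq,
                    selection = sel$truth, related_pairs = rel$truth))
}
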