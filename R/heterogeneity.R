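#' Select the SNP set of a region for the causal-count analysis
#'
#' All SNPs with p below `p_cut` (default 0.001); if fewer than `n_min`
#' (default 10) qualify, the `n_min` smallest-p SNPs are taken; if more
#' than `n_max` (default 40) qualify, only the `n_max` smallest-p SNPs are
#' kept.  Ties at a cut are broken by smaller position.  A region with
#' fewer than `n_min` SNPs in total contributes all of them, flagged.
#'
#' @param region_scan scan rows (data.frame with `snp_id`, `position_bp`,
#'   `pvalue`) restricted to one region.
#' @param p_cut,n_min,n_max selection thresholds.
#' @return The selected rows, ordered by position; attribute `short` is
#'   TRUE when the region had fewer than `n_min` SNPs in total.
#' @export
select_region_snps <- function(region_scan, p_cut = 0.001, n_min = 10,
                               n_max = 40) {
  d <- as.data.frame(region_scan)
  if (!nrow(d) || all(!is.finite(d$pvalue)))
    stop("region must contain at least one SNP with a finite p-value")
  d <- d[is.finite(d$pvalue), , drop = FALSE]
  ord <- order(d$pvalue, d$position_bp)
  n_hit <- sum(d$pvalue < p_cut)
  n_take <- min(max(n_hit, n_min), n_max, nrow(d))
  sel <- d[ord[seq_len(n_take)], , drop = FALSE]
  sel <- sel[order(sel$position_bp), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "short") <- nrow(d) < n_min
  sel
}

#' Loadings of FLK signals on orthogonal drift components
#'
#' With the eigendecomposition `F = U L U'`, the loading row of SNP s is
#' `w_s = L^(-1/2) U' (p_s - p0_s 1) / sqrt(p0_s (1 - p0_s))`, so that
#' `||w_s||^2` equals the SNP's FLK statistic exactly.  Eigenvalues below
#' 1e-10 are dropped (rank reduction).
#'
#' @param P population x SNP frequency matrix.
#' @param p0 per-SNP ancestral frequencies in (0, 1).
#' @param F population kinship matrix.
#' @return SNP x component loading matrix `W`; SNPs with `p0` at 0 or 1
#'   are excluded (attribute `excluded`).
#' @export
flk_loadings <- function(P, p0, F) {
  ok <- is.finite(p0) & p0 > 0 & p0 < 1
  eg <- eigen((F + t(F)) / 2, symmetric = TRUE)
  keep <- eg$values > 1e-10
  U <- eg$vectors[, keep, drop = FALSE]
  L <- eg$values[keep]
  C <- sweep(P[, ok, drop = FALSE], 2, p0[ok])
  W <- t((1 / sqrt(L)) * (t(U) %*% C)) / sqrt(p0[ok] * (1 - p0[ok]))
  rownames(W) <- colnames(P)[ok]
  attr(W, "excluded") <- colnames(P)[!ok]
  W
}

#' Eigen-decomposition-based SNP correlation matrix
#'
#' Cosine similarity of FLK loading rows; captures correlation between the
#' per-SNP tests induced jointly by linkage and the shared drift history of
#' the populations.  A 1e-6 ridge is added to the diagonal so downstream
#' inversions are defined.
#'
#' @param W loading matrix from [flk_loadings()].
#' @return SNP x SNP correlation matrix; zero-norm rows are excluded
#'   (attribute `excluded`).
#' @export
loading_correlation <- function(W) {
  nrm <- sqrt(rowSums(W^2))
  keep <- nrm > 0
  Wn <- W[keep, , drop = FALSE] / nrm[keep]
  R <- tcrossprod(Wn)
  R <- (R + t(R)) / 2
  diag(R) <- diag(R) + 1e-6
  attr(R, "excluded") <- rownames(W)[!keep]
  R
}

# orient score signs to agree with the correlation matrix inside each
# correlated block; the PC1 seed only orients the dominant block
.relax_signs <- function(sgn, R, mag) {
  for (it in 1:10) {
    new <- sgn
    for (s in seq_along(sgn)) {
      tot <- sum(R[s, -s] * sgn[-s] * mag[-s])
      if (tot != 0) new[s] <- sign(tot)
    }
    if (all(new == sgn)) break
    sgn <- new
  }
  sgn
}

# log-density of N(0, Sigma) at z, via Cholesky
.lmvn <- function(z, Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  u <- backsolve(ch, z, transpose = TRUE)
  -sum(log(diag(ch))) - 0.5 * sum(u^2) - 0.5 * length(z) * log(2 * pi)
}

#' Posterior on the number of independent selected variants
#'
#' Fine-mapping model for signed association scores `z` with test
#' correlation `R`: a causal configuration `c` (subset of SNPs, at most
#' `m_max` members) has likelihood `N(z; 0, R + lambda^2 R diag(c) R)` and
#' prior `gamma^|c| (1-gamma)^(m-|c|)`.  The posterior over configurations
#' is obtained by exact enumeration when the configuration count is at most
#' `enum_limit`, otherwise by a seeded Metropolis sampler with add/drop/swap
#' moves (likelihoods cached per configuration).
#'
#' @param z signed per-SNP scores (`sqrt(FLK)` with a consistent sign).
#' @param R SNP correlation matrix from [loading_correlation()].
#' @param m_max maximum number of causal variants (default 10).
#' @param gamma per-SNP prior inclusion probability (default 0.01).
#' @param lambda prior effect scale / non-centrality (default 5.2).
#' @param enum_limit configuration-count bound for exact enumeration
#'   (default 5e4, roughly 14 SNPs at `m_max = 10`; larger sets switch to
#'   the sampler).
#' @param n_sweeps Metropolis iterations (default 1e5).
#' @param seed RNG seed for the sampler.
#' @return Object of class `causal_posterior`: list with `count_probs`
#'   (posterior over 0..m_max variants), `posterior_mean`, `inclusion`
#'   (per-SNP marginal inclusion probabilities), `method` (`"exact"` or
#'   `"monte_carlo"`).
#' @export
causal_posterior <- function(z, R, m_max = 10, gamma = 0.01, lambda = 5.2,
                             enum_limit = 5e4, n_sweeps = 1e5, seed = 1) {
  m <- length(z)
  stopifnot(nrow(R) == m, ncol(R) == m)
  m_max <- min(m_max, m)
  ev_min <- min(eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) stop("R is not positive semidefinite")
  loglik <- function(sel) {
    D <- numeric(m); D[sel] <- lambda^2
    .lmvn(z, R + R %*% (D * R))          # R diag(D) R == R %*% (D * R)
  }
  logprior_k <- function(k) k * log(gamma) + (m - k) * log(1 - gamma)
  n_conf <- sum(choose(m, 0:m_max))
  if (n_conf <= enum_limit) {
    confs <- vector("list", n_conf)
    lp <- numeric(n_conf); ks <- integer(n_conf)
    incl_num <- numeric(m)
    i <- 0L
    for (k in 0:m_max) {
      sets <- if (k == 0) list(integer(0)) else
        asplit(utils::combn(m, k), 2)
      for (sel in sets) {
        i <- i + 1L
        confs[[i]] <- sel
        lp[i] <- loglik(sel) + logprior_k(length(sel))
        ks[i] <- length(sel)
      }
    }
    w <- exp(lp - max(lp)); w <- w / sum(w)
    for (i in seq_along(confs)) incl_num[confs[[i]]] <-
        incl_num[confs[[i]]] + w[i]
    count_probs <- vapply(0:m_max, function(k) sum(w[ks == k]), numeric(1))
    method <- "exact"
  } else {
    set.seed(seed)
    cache <- new.env(hash = TRUE, parent = emptyenv())
    pad <- rep(FALSE, 8 * ceiling(m / 8) - m)
    post_un <- function(msk) {
      key <- paste(as.integer(packBits(c(msk, pad), "raw")), collapse = ",")
      v <- cache[[key]]
      if (is.null(v)) {
        v <- loglik(which(msk)) + logprior_k(sum(msk))
        cache[[key]] <- v
      }
      v
    }
    msk <- rep(FALSE, m)
    cur <- post_un(msk)
    counts <- numeric(m_max + 1)
    incl_num <- numeric(m)
    burn <- n_sweeps %/% 10
    n_tot <- n_sweeps + burn
    # symmetric proposals: single-bit flip (2/3) or swap (1/3)
    flips <- sample.int(m, n_tot, replace = TRUE)
    us <- stats::runif(n_tot)
    las <- log(stats::runif(n_tot))
    for (it in seq_len(n_tot)) {
      prop <- msk
      if (us[it] < 2 / 3) {
        j <- flips[it]
        prop[j] <- !prop[j]
      } else {
        on <- which(msk)
        if (length(on) && length(on) < m) {
          off <- which(!msk)
          prop[on[1L + (flips[it] %% length(on))]] <- FALSE
          prop[off[1L + (flips[it] %% length(off))]] <- TRUE
        }
      }
      if (sum(prop) <= m_max) {
        lp_prop <- post_un(prop)
        if (las[it] < lp_prop - cur) {
          msk <- prop; cur <- lp_prop
        }
      }
      if (it > burn) {
        k <- sum(msk)
        counts[k + 1L] <- counts[k + 1L] + 1
        incl_num[msk] <- incl_num[msk] + 1
      }
    }
    count_probs <- counts / n_sweeps
    incl_num <- incl_num / n_sweeps
    w <- NULL
    method <- "monte_carlo"
  }
  structure(list(count_probs = stats::setNames(count_probs, 0:m_max),
                 posterior_mean = sum((0:m_max) * count_probs),
                 inclusion = stats::setNames(incl_num, rownames(R)),
                 method = method, gamma = gamma, lambda = lambda,
                 m_max = m_max),
            class = "causal_posterior")
}

#' @export
print.causal_posterior <- function(x, ...) {
  cat(sprintf("causal_posterior (%s): posterior mean %.3f variants\n",
              x$method, x$posterior_mean))
  print(round(x$count_probs, 4))
  invisible(x)
}

#' Allelic-heterogeneity report over selection signatures
#'
#' For every region: selects the SNP set, builds the loading-based test
#' correlation matrix, signs the scores by their projection on the first
#' principal loading component, runs [causal_posterior()] and reports the
#' posterior mean number of independent selected variants.  A region is
#' called heterogeneous when the posterior mean is at least `het_mean` or
#' at least two SNPs have marginal inclusion probability above 0.5.
#'
#' @param scan an [run_flk_scan()] result with retained frequencies
#'   (`keep_freqs = TRUE`).
#' @param score how per-SNP signed score magnitudes are built.
#'   `"chi_norm"` (default) uses `sqrt(FLK / df)`: the score ratios between
#'   SNPs then equal the loading-norm ratios, which is what the cosine
#'   correlation matrix describes, and the null mean square is 1.
#'   `"zscore"` maps the FLK p-value to a standard-normal magnitude
#'   (exactly calibrated marginally, but ratio-inconsistent with the
#'   cosine matrix for strong signals).  `"sqrt_flk"` is the raw
#'   `sqrt(FLK)` magnitude.  Signs start from the projection on the first
#'   principal loading component and are then relaxed to agree with the
#'   correlation matrix within each correlated block (the first component
#'   orients only the dominant block).
#' @param regions a [build_regions()] result on the same scan.
#' @param F population kinship matrix used in the scan.
#' @param m_max,gamma,lambda,seed passed to [causal_posterior()].
#' @param het_mean posterior-mean threshold for the heterogeneity flag
#'   (default 2: more than one independent variant).
#' @return data.frame, one row per region: `region_id`, `n_snps_used`,
#'   `posterior_mean`, `n_incl_05`, `heterogeneous`; attribute
#'   `posteriors` holds the full `causal_posterior` objects.
#' @export
heterogeneity_report <- function(scan, regions, F, m_max = 10, gamma = 0.05,
                                 lambda = 2, het_mean = 2, seed = 1,
                                 score = c("chi_norm", "zscore", "sqrt_flk")) {
  score <- match.arg(score)
  P <- attr(scan, "freq")
  if (is.null(P)) stop("scan must be run with keep_freqs = TRUE")
  posts <- vector("list", nrow(regions))
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    in_reg <- scan$chromosome == reg$chromosome &
      scan$position_bp >= reg$start_bp & scan$position_bp <= reg$end_bp
    sel <- select_region_snps(scan[in_reg, , drop = FALSE])
    j <- match(sel$snp_id, scan$snp_id)
    W <- flk_loadings(P[, j, drop = FALSE], scan$p0[j], F)
    R <- loading_correlation(W)
    used <- rownames(R)
    ju <- match(used, scan$snp_id)
    # consistent orientation: sign of the projection on the first PC of W
    Wu <- W[used, , drop = FALSE]
    v1 <- svd(Wu, nu = 0, nv = 1)$v[, 1]
    sgn <- sign(Wu %*% v1)
    sgn[sgn == 0] <- 1
    mag <- switch(score,
      chi_norm = sqrt(scan$flk[ju] / attr(scan, "df")),
      zscore = stats::qnorm(pmax(scan$pvalue[ju], 1e-300) / 2,
                            lower.tail = FALSE),
      sqrt_flk = sqrt(scan$flk[ju]))
    sgn <- .relax_signs(as.vector(sgn), R, mag)
    z <- sgn * mag
    cp <- causal_posterior(z, R, m_max = m_max, gamma = gamma,
                           lambda = lambda, seed = seed + i)
    posts[[i]] <<- cp
    data.frame(region_id = reg$region_id, n_snps_used = length(used),
               posterior_mean = cp$posterior_mean,
               n_incl_05 = sum(cp$inclusion > 0.5),
               heterogeneous = cp$posterior_mean >= het_mean |
                 sum(cp$inclusion > 0.5) >= 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "posteriors") <- posts
  out
}
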