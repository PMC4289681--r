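## Haplotype coding shared by the EM estimator and the pair simulator:
## row 1 = AB (alt allele at both sites), 2 = Ab, 3 = aB, 4 = ab.
HAP_ALLELES <- matrix(c(1L, 1L, 0L, 0L,   # allele at site 1
                        1L, 0L, 1L, 0L),  # allele at site 2
                      nrow = 4, dimnames = list(c("AB", "Ab", "aB", "ab"),
                                                c("site1", "site2")))

## Ordered haplotype pairs consistent with each two-SNP genotype class.
## Haplotypes are coded 1..4 = AB, Ab, aB, ab (see HAP_ALLELES). The list is
## indexed by 3*g1 + g2 + 1 and each element is a 2-column matrix of
## (h1, h2) index pairs.
consistent_pairs <- local({
  out <- vector("list", 9)
  for (g1 in 0:2) for (g2 in 0:2) {
    pp <- which(outer(HAP_ALLELES[, 1], HAP_ALLELES[, 1], "+") == g1 &
                outer(HAP_ALLELES[, 2], HAP_ALLELES[, 2], "+") == g2,
                arr.ind = TRUE)
    colnames(pp) <- c("h1", "h2")
    out[[3 * g1 + g2 + 1]] <- pp
  }
  out
})

## One EM run from starting value p0 (4 x K). alphas: n x K for the retained
## individuals; cls: per-individual genotype-class index (1..9).
## Returns p, logLik trace, iteration count and convergence flag.
em_pair_haplotypes <- function(p0, alphas, cls, tol, max_iter) {
  K <- ncol(alphas)
  p <- p0
  trace <- numeric(0)
  converged <- FALSE
  by_class <- split(seq_along(cls), cls)
  for (iter in seq_len(max_iter)) {
    A <- p %*% t(alphas)                        # a(j, i) = sum_k p_jk alpha_ik
    L <- numeric(length(cls))
    B <- matrix(0, 4, length(cls))
    for (cname in names(by_class)) {
      pp <- consistent_pairs[[as.integer(cname)]]
      ii <- by_class[[cname]]
      Ai <- A[, ii, drop = FALSE]
      Li <- rep(0, length(ii))
      Bi <- matrix(0, 4, length(ii))
      for (r in seq_len(nrow(pp))) {
        h1 <- pp[r, 1]; h2 <- pp[r, 2]
        Li <- Li + Ai[h1, ] * Ai[h2, ]
        Bi[h1, ] <- Bi[h1, ] + Ai[h2, ]
        Bi[h2, ] <- Bi[h2, ] + Ai[h1, ]
      }
      L[ii] <- Li
      B[, ii] <- Bi
    }
    trace <- c(trace, sum(log(L)))
    # M-step: expected (haplotype, ancestry) counts normalized per ancestry
    N <- p * (sweep(B, 2, L, "/") %*% alphas)
    p_new <- sweep(N, 2, colSums(N), "/")
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  # log-likelihood at the final parameter value
  A <- p %*% t(alphas)
  L <- numeric(length(cls))
  for (cname in names(by_class)) {
    pp <- consistent_pairs[[as.integer(cname)]]
    ii <- by_class[[cname]]
    Ai <- A[, ii, drop = FALSE]
    Li <- rep(0, length(ii))
    for (r in seq_len(nrow(pp)))
      Li <- Li + Ai[pp[r, 1], ] * Ai[pp[r, 2], ]
    L[ii] <- Li
  }
  trace <- c(trace, sum(log(L)))
  list(p = p, logLik = trace[length(trace)], trace = trace,
       n_iterations = length(trace) - 1L, converged = converged)
}

## Likelihood of a 4 x K haplotype-frequency matrix for genotype classes cls
## (ordered-pair enumeration, same convention as the EM).
pair_haplotype_loglik <- function(p, alphas, cls) {
  A <- p %*% t(alphas)
  L <- numeric(length(cls))
  for (i in seq_along(cls)) {
    pp <- consistent_pairs[[cls[i]]]
    L[i] <- sum(A[pp[, 1], i] * A[pp[, 2], i])
  }
  sum(log(L))
}

#' Ancestry-specific haplotype frequencies for one SNP pair by EM
#'
#' Estimates the 4 x K matrix of haplotype frequencies `p_jk` (haplotypes
#' AB, Ab, aB, ab; ancestries k = 1..K) from unphased two-SNP genotypes of
#' admixed individuals with known admixture proportions. The likelihood sums
#' over the haplotype pairs consistent with each genotype and over the
#' (unobserved) ancestry of each haplotype, assuming one ancestry per
#' haplotype across both loci and conditionally independent haplotype
#' ancestries given the admixture proportions:
#' `L(p) = prod_i sum_{h in h(G_i)} sum_{k1,k2} p_{h1 k1} p_{h2 k2}
#'  alpha_{i k1} alpha_{i k2}`.
#' EM iterates the standard ratio-of-expected-counts update until no
#' parameter moves by more than `tol`; the best of `n_starts` uniform-random
#' starts is returned. Ancestries with total admixture weight
#' `sum_i alpha_ik <= 0.5` among retained individuals carry essentially no
#' data and are flagged unresolved.
#'
#' @param genotype_pairs n x 2 matrix (or [geno_matrix()] with 2 sites) of
#'   genotypes in `{0, 1, 2, NA}`; individuals missing either site are
#'   dropped.
#' @param alphas An [admix_props()] matrix with one row per individual.
#' @param tol Convergence tolerance on the parameter max-change.
#' @param n_starts Number of random restarts.
#' @param max_iter Iteration cap per start.
#' @param seed Optional integer seed for the random starts.
#' @return Object of class `pair_haplotypes`: list with `p` (4 x K),
#'   `logLik`, `trace` (log-likelihood per iteration of the best start),
#'   `n_iterations`, `converged`, `n_used`, `resolved` (per-ancestry flag).
#' @export
estimate_pair_haplotype_frequencies <- function(genotype_pairs, alphas,
                                                tol = 1e-6, n_starts = 5,
                                                max_iter = 5000,
                                                seed = NULL) {
  if (inherits(genotype_pairs, "geno_matrix"))
    genotype_pairs <- genotype_pairs$genotypes
  g <- as.matrix(genotype_pairs)
  if (ncol(g) != 2) stop("genotype_pairs must have exactly 2 sites")
  if (nrow(g) != nrow(alphas))
    stop("genotype rows and admixture rows must match")
  ok <- !is.na(g[, 1]) & !is.na(g[, 2])
  if (!any(ok)) stop("no individuals with complete genotypes at both sites")
  g <- g[ok, , drop = FALSE]
  am <- unclass(alphas)[ok, , drop = FALSE]
  K <- ncol(am)
  resolved <- colSums(am) > 0.5
  cls <- as.integer(3 * g[, 1] + g[, 2] + 1)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- matrix(stats::runif(4 * K), 4, K)
    p0 <- sweep(p0, 2, colSums(p0), "/")
    fit <- em_pair_haplotypes(p0, am, cls, tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  dimnames(best$p) <- list(rownames(HAP_ALLELES), colnames(alphas))
  names(resolved) <- colnames(alphas)
  structure(list(p = best$p, logLik = best$logLik, trace = best$trace,
                 n_iterations = best$n_iterations, converged = best$converged,
                 n_used = nrow(g), resolved = resolved),
            class = "pair_haplotypes")
}

#' @export
print.pair_haplotypes <- function(x, ...) {
  cat("pair_haplotypes: n =", x$n_used, "individuals,",
      ncol(x$p), "ancestries\n")
  print(round(x$p, 4))
  r2 <- vapply(seq_len(ncol(x$p)), function(k)
    r_squared_from_haplotypes(x$p[, k]), numeric(1))
  cat("  r^2:", paste(format(round(r2, 4)), collapse = ", "),
      if (!all(x$resolved)) paste0(" (unresolved: ",
        paste(names(x$resolved)[!x$resolved], collapse = ", "), ")") else "",
      "\n")
  cat(sprintf("  logLik = %.4f after %d iterations (%s)\n", x$logLik,
              x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Squared correlation r2 from two-locus haplotype frequencies
#'
#' `D = p_AB - p_A p_B` with `p_A = p_AB + p_Ab`, `p_B = p_AB + p_aB`, and
#' `r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`. Undefined (returned as `NA`)
#' when either locus is monomorphic in the population described by the
#' frequency vector.
#'
#' @param p_column Numeric vector of 4 haplotype frequencies in the order
#'   AB, Ab, aB, ab, summing to 1.
#' @return A single r-squared value, or `NA` if undefined.
#' @export
r_squared_from_haplotypes <- function(p_column) {
  stopifnot(length(p_column) == 4)
  if (abs(sum(p_column) - 1) > 1e-6) stop("haplotype frequencies must sum to 1")
  pA <- p_column[1] + p_column[2]
  pB <- p_column[1] + p_column[3]
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den <= 0) return(NA_real_)
  D <- p_column[1] - pA * pB
  unname(D^2 / den)
}

#' Per-ancestry and naive LD-decay curves
#'
#' Samples SNP pairs within chromosomes, bins them by physical distance, and
#' reports per-bin mean r-squared both naively (squared dosage correlation,
#' which mixes ancestries) and per ancestral population (from the EM
#' haplotype-frequency fit of each pair). Sites are first screened at
#' `maf_min` (a 5% cutoff is conventional for array data).
#'
#' @param gm A [geno_matrix()].
#' @param alphas An [admix_props()] matrix aligned with `gm`'s individuals.
#' @param distance_bins Increasing vector of bp bin edges.
#' @param maf_min Minor-allele-frequency screen applied before pairing.
#' @param max_pairs_per_bin Pairs are sampled uniformly without replacement
#'   up to this many per distance bin.
#' @param tol,n_starts Passed to [estimate_pair_haplotype_frequencies()].
#' @param seed Optional integer seed (pair sampling and EM starts).
#' @return Object of class `ld_decay`: list with `pairs` (one row per
#'   sampled pair: positions, distance, bin, naive r2, one r2 column per
#'   ancestry) and `bins` (per-bin means and pair counts; empty bins are
#'   absent).
#' @export
ld_decay_curve <- function(gm, alphas, distance_bins, maf_min = 0.05,
                           max_pairs_per_bin = 100, tol = 1e-6, n_starts = 5,
                           seed = NULL) {
  stopifnot(inherits(gm, "geno_matrix"), nrow(alphas) == n_individuals(gm))
  if (!is.null(seed)) set.seed(seed)
  keep <- site_maf(gm) >= maf_min & !is.na(site_maf(gm))
  gm2 <- gm[, keep]
  ## candidate within-chromosome pairs and their distances
  cand <- NULL
  for (chr in unique(gm2$sites$chrom)) {
    idx <- which(gm2$sites$chrom == chr)
    if (length(idx) < 2) next
    pr <- t(utils::combn(idx, 2))
    cand <- rbind(cand, pr)
  }
  if (is.null(cand))
    return(structure(list(pairs = NULL, bins = NULL), class = "ld_decay"))
  d <- abs(gm2$sites$pos[cand[, 2]] - gm2$sites$pos[cand[, 1]])
  bin <- findInterval(d, distance_bins, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin < length(distance_bins)
  cand <- cand[inside, , drop = FALSE]; d <- d[inside]; bin <- bin[inside]
  sel <- unlist(lapply(unique(bin), function(b) {
    ib <- which(bin == b)
    if (length(ib) > max_pairs_per_bin)
      ib <- sample(ib, max_pairs_per_bin)
    ib
  }))
  if (length(sel) == 0)
    return(structure(list(pairs = NULL, bins = NULL), class = "ld_decay"))
  labels <- colnames(alphas)
  rows <- vector("list", length(sel))
  for (q in seq_along(sel)) {
    i <- sel[q]
    gp <- gm2$genotypes[, cand[i, ], drop = FALSE]
    fit <- estimate_pair_haplotype_frequencies(gp, alphas, tol = tol,
                                               n_starts = n_starts)
    r2k <- vapply(seq_along(labels), function(k)
      if (fit$resolved[k]) r_squared_from_haplotypes(fit$p[, k]) else NA_real_,
      numeric(1))
    names(r2k) <- paste0("r2_", labels)
    rows[[q]] <- data.frame(
      chrom = gm2$sites$chrom[cand[i, 1]],
      pos1 = gm2$sites$pos[cand[i, 1]], pos2 = gm2$sites$pos[cand[i, 2]],
      distance = d[i], bin = bin[i],
      r2_naive = genotype_r2(gp[, 1], gp[, 2]),
      as.list(r2k), converged = fit$converged,
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  agg <- lapply(split(pairs, pairs$bin), function(df) {
    means <- colMeans(df[, c("r2_naive", paste0("r2_", labels)),
                         drop = FALSE], na.rm = TRUE)
    data.frame(bin = df$bin[1],
               lower = distance_bins[df$bin[1]],
               upper = distance_bins[df$bin[1] + 1],
               n_pairs = nrow(df), as.list(means))
  })
  bins <- do.call(rbind, agg)
  rownames(bins) <- NULL
  structure(list(pairs = pairs, bins = bins), class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  if (is.null(x$bins)) {
    cat("ld_decay: no pairs sampled\n")
    return(invisible(x))
  }
  cat("ld_decay:", nrow(x$pairs), "pairs in", nrow(x$bins), "distance bins\n")
  print(x$bins, row.names = FALSE)
  invisible(x)
}
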