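#' Per-population allele frequencies
#'
#' Alternate-allele frequency per site and population, computed as allele
#' count over twice the number of non-missing individuals. Sites with no
#' non-missing call in a population get `NA` there (no information for that
#' population).
#'
#' @param gm A [geno_matrix()].
#' @param groups Named character/factor vector mapping every individual id
#'   (names) to a population, or an unnamed vector in `gm` row order.
#' @return List with matrices `freq` and `n` (non-missing individuals),
#'   sites in rows and one column per population.
#' @export
population_allele_frequencies <- function(gm, groups) {
  stopifnot(inherits(gm, "geno_matrix"))
  ids <- rownames(gm$genotypes)
  if (!is.null(names(groups))) {
    if (!all(ids %in% names(groups)))
      stop("every individual must be mapped to a population")
    groups <- groups[ids]
  } else if (length(groups) != length(ids)) {
    stop("groups must name every individual")
  }
  groups <- as.character(groups)
  pops <- unique(groups)
  S <- n_sites(gm)
  freq <- matrix(NA_real_, S, length(pops), dimnames = list(NULL, pops))
  nmat <- matrix(0L, S, length(pops), dimnames = list(NULL, pops))
  for (p in pops) {
    g <- gm$genotypes[groups == p, , drop = FALSE]
    if (nrow(g) == 0) stop("empty population: ", p)
    nn <- colSums(!is.na(g))
    cnt <- colSums(g, na.rm = TRUE)
    freq[, p] <- ifelse(nn > 0, cnt / (2 * nn), NA_real_)
    nmat[, p] <- nn
  }
  list(freq = freq, n = nmat)
}

#' Four-population D statistic from allele frequencies
#'
#' For the tree `(((H1, H2), H3), H4)` with H4 the outgroup,
#' `D = sum_i (f_iH3 - f_iH4)(f_iH1 - f_iH2) /
#'      sum_i (f_iH3 + f_iH4 - 2 f_iH3 f_iH4)(f_iH1 + f_iH2 - 2 f_iH1 f_iH2)`.
#' Only sites with information (a non-missing frequency) in all four
#' populations enter; sites contributing a zero denominator term alongside a
#' zero numerator term (all four populations monomorphic) are dropped from
#' both sums and from the site count M. The statistic is free of allele
#' polarization: substituting `f -> 1 - f` at a site in all populations
#' leaves it unchanged, and swapping H1 with H2 (or H3 with H4) flips its
#' sign.
#'
#' @param freqs Matrix or data frame with 4 columns of per-site allele
#'   frequencies in the order H1, H2, H3, H4.
#' @return List with `D`, per-site contributions `num` and `den`, and the
#'   index `included` of the sites used (M = `length(included)`).
#' @export
d_statistic <- function(freqs) {
  f <- as.matrix(freqs)
  if (ncol(f) != 4) stop("freqs must have 4 columns (H1, H2, H3, H4)")
  complete <- rowSums(is.na(f)) == 0
  num <- (f[, 3] - f[, 4]) * (f[, 1] - f[, 2])
  den <- (f[, 3] + f[, 4] - 2 * f[, 3] * f[, 4]) *
         (f[, 1] + f[, 2] - 2 * f[, 1] * f[, 2])
  inc <- which(complete & den != 0)
  if (length(inc) == 0 || sum(den[inc]) == 0)
    stop("no informative sites: denominator sum is zero")
  list(D = sum(num[inc]) / sum(den[inc]),
       num = num[inc], den = den[inc], included = inc)
}

#' Weighted delete-m block jackknife for a ratio-of-sums statistic
#'
#' Standard error of `theta = sum(num) / sum(den)` over genomic blocks of
#' unequal SNP counts, using the delete-m-for-unequal-m jackknife: with `g`
#' blocks, `n` total sites, `m_j` sites in block `j` and `h_j = n / m_j`,
#' the pseudo-values are `tau_j = h_j theta - (h_j - 1) theta_(-j)`, the
#' bias-corrected estimate is
#' `theta_J = g theta - sum_j (1 - m_j / n) theta_(-j)`, and
#' `Var = (1/g) sum_j (tau_j - theta_J)^2 / (h_j - 1)`.
#' With equal block sizes this reduces exactly to the classic delete-m
#' jackknife, and with one site per block to the delete-1 jackknife.
#'
#' @param num,den Per-site numerator and denominator contributions.
#' @param block_ids Block assignment per site (any vector; empty blocks
#'   simply never occur).
#' @return List with `theta`, `theta_jack` (bias-corrected), `SE`, `Z`
#'   (`NA` when SE is 0), `n_blocks`, `m` (per-block site counts).
#' @export
block_jackknife <- function(num, den, block_ids) {
  stopifnot(length(num) == length(den), length(num) == length(block_ids))
  bid <- as.character(block_ids)
  m <- tapply(rep(1, length(bid)), bid, sum)
  g <- length(m)
  if (g < 2) stop("need at least 2 non-empty blocks")
  n <- length(num)
  theta <- sum(num) / sum(den)
  bnum <- tapply(num, bid, sum)[names(m)]
  bden <- tapply(den, bid, sum)[names(m)]
  theta_loo <- (sum(num) - bnum) / (sum(den) - bden)
  h <- n / m
  tau <- h * theta - (h - 1) * theta_loo
  theta_jack <- g * theta - sum((1 - m / n) * theta_loo)
  var_jack <- sum((tau - theta_jack)^2 / (h - 1)) / g
  se <- sqrt(var_jack)
  list(theta = theta, theta_jack = theta_jack, SE = se,
       Z = if (se > 0) theta / se else NA_real_,
       n_blocks = g, m = m)
}

## Block ids from positions: fixed windows of block_size_bp anchored at each
## chromosome's first site.
genomic_blocks <- function(chrom, pos, block_size_bp = 5e6) {
  anchor <- tapply(pos, chrom, min)[as.character(chrom)]
  paste0(chrom, ":", floor((pos - anchor) / block_size_bp))
}

#' D statistic with block-jackknife Z score
#'
#' Computes the four-population [d_statistic()] and its standard error and Z
#' score from a weighted delete-m jackknife over contiguous genomic windows
#' (5 Mb by default), weighting blocks by their SNP counts.
#'
#' @inheritParams d_statistic
#' @param chrom,pos Site coordinates aligned with `freqs` rows.
#' @param block_size_bp Jackknife block width in bp.
#' @return Object of class `dstat`: list with `D`, `SE`, `Z`, `n_sites`,
#'   `n_blocks`, `m` (per-block SNP counts).
#' @export
dstat <- function(freqs, chrom, pos, block_size_bp = 5e6) {
  ds <- d_statistic(freqs)
  blocks <- genomic_blocks(chrom[ds$included], pos[ds$included],
                           block_size_bp)
  jk <- block_jackknife(ds$num, ds$den, blocks)
  structure(list(D = ds$D, SE = jk$SE, Z = jk$Z,
                 n_sites = length(ds$included), n_blocks = jk$n_blocks,
                 m = jk$m),
            class = "dstat")
}

#' @export
print.dstat <- function(x, ...) {
  cat(sprintf("dstat: D = %.5f  SE = %.5f  Z = %.3f  (M = %d sites, %d blocks)\n",
              x$D, x$SE, if (is.na(x$Z)) NA else x$Z, x$n_sites, x$n_blocks))
  invisible(x)
}

#' Weir-Cockerham fixation index for two populations
#'
#' Multi-site ratio-of-sums estimator of FST from the 1984 variance
#' components: per site, `a` (between populations), `b` (between
#' individuals within populations) and `c` (within individuals) are
#' computed from sample sizes, allele frequencies and observed heterozygote
#' frequencies, and `FST = sum(a) / sum(a + b + c)`.
#'
#' @param gm A [geno_matrix()].
#' @param groups Mapping of individuals to exactly two populations (as in
#'   [population_allele_frequencies()]).
#' @return List with `fst`, per-site components `a`, `b`, `c`, and
#'   `n_sites` actually used. `fst` is `NA` (flagged by `defined = FALSE`)
#'   when every site is monomorphic.
#' @export
weir_cockerham_fst <- function(gm, groups) {
  pf <- population_allele_frequencies(gm, groups)
  if (ncol(pf$freq) != 2) stop("exactly two populations required")
  ids <- rownames(gm$genotypes)
  grp <- if (!is.null(names(groups))) as.character(groups[ids])
         else as.character(groups)
  pops <- colnames(pf$freq)
  het <- sapply(pops, function(p) {
    g <- gm$genotypes[grp == p, , drop = FALSE]
    colMeans(g == 1, na.rm = TRUE)
  })
  n1 <- pf$n[, 1]; n2 <- pf$n[, 2]
  p1 <- pf$freq[, 1]; p2 <- pf$freq[, 2]
  usable <- n1 > 1 & n2 > 1 & !is.na(p1) & !is.na(p2)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * het[, 1] + n2 * het[, 2]) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- usable & pbar > 0 & pbar < 1
  if (!any(poly))
    return(list(fst = NA_real_, defined = FALSE, a = a, b = b, c = cc,
                n_sites = 0L))
  tot <- sum(a[poly] + b[poly] + cc[poly])
  list(fst = sum(a[poly]) / tot, defined = TRUE,
       a = a[poly], b = b[poly], c = cc[poly], n_sites = sum(poly))
}
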