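#' Genotype probabilities under an inbreeding coefficient
#'
#' With allele frequency `f_star` (for an admixed individual, the
#' ancestry-weighted frequency `f* = sum_k alpha_k f_k`) and inbreeding
#' coefficient `F`, the genotype is drawn from the usual identity-by-descent
#' mixture: with probability `F` a single allele is drawn and duplicated,
#' otherwise the two alleles are independent. The three probabilities are
#' `(1-f*)^2 (1-F) + (1-f*) F`, `2 f* (1-f*) (1-F)` and
#' `f*^2 (1-F) + f* F` for genotypes 0, 1, 2; they sum to 1.
#'
#' @param g Genotype, 0, 1 or 2 (vectorized).
#' @param f_star Allele frequency strictly inside `(0, 1)`.
#' @param F Inbreeding coefficient in `[0, 1]`.
#' @return Probability of the genotype(s).
#' @export
genotype_prob_F <- function(g, f_star, F) {
  if (any(f_star <= 0 | f_star >= 1))
    stop("f_star must lie strictly inside (0, 1)")
  stopifnot(all(F >= 0), all(F <= 1), all(g %in% 0:2))
  q <- 1 - f_star
  ifelse(g == 0, q^2 * (1 - F) + q * F,
  ifelse(g == 1, 2 * f_star * q * (1 - F),
                 f_star^2 * (1 - F) + f_star * F))
}

## Composite log-likelihood of F over sites (vectorized over a grid of F).
inbreeding_loglik <- function(F_grid, g, f_star) {
  q <- 1 - f_star
  vapply(F_grid, function(F)
    sum(log(ifelse(g == 0, q^2 * (1 - F) + q * F,
            ifelse(g == 1, 2 * f_star * q * (1 - F),
                           f_star^2 * (1 - F) + f_star * F)))),
    numeric(1))
}

#' Maximum-likelihood inbreeding coefficient of one individual
#'
#' Maximizes the composite likelihood `prod_s Pr(g_s | F)` over `F` in
#' `[0, 1]`, with the per-site allele frequency taken as the
#' ancestry-weighted mixture `f*_s = sum_k alpha_k f_sk`. Ignoring the
#' admixture (using pooled cohort frequencies for `f*`) inflates `F`
#' because admixture itself produces an excess of homozygotes relative to
#' Hardy-Weinberg at pooled frequencies. Sites with a missing genotype, or
#' with `f*` within `f_eps` of 0 or 1 (near-monomorphic, where the
#' log-likelihood degenerates), are dropped. The optimum is located on a
#' 101-point grid and refined by [stats::optimize()] between the grid
#' neighbors of the best point.
#'
#' @param genotypes Numeric vector of one individual's genotypes
#'   (`{0, 1, 2, NA}`).
#' @param alphas The individual's ancestry proportions (length-K vector
#'   summing to 1).
#' @param ancestral_freqs S x K matrix of per-ancestry allele frequencies
#'   (rows follow `genotypes`).
#' @param f_eps Boundary guard on `f*`.
#' @param min_sites Minimum usable sites (error below this).
#' @param id Individual label carried into the result.
#' @return Object of class `inbreeding_ml`: list with `id`, `F_hat`,
#'   `logLik`, `n_sites`.
#' @export
estimate_inbreeding <- function(genotypes, alphas, ancestral_freqs,
                                f_eps = 0.005, min_sites = 50, id = NULL) {
  fr <- as.matrix(ancestral_freqs)
  alphas <- as.numeric(alphas)
  if (length(genotypes) != nrow(fr))
    stop("genotypes and ancestral_freqs rows must match")
  if (length(alphas) != ncol(fr))
    stop("alphas length must match ancestral_freqs columns")
  if (abs(sum(alphas) - 1) > 1e-6) stop("alphas must sum to 1")
  f_star <- drop(fr %*% alphas)
  use <- !is.na(genotypes) & f_star >= f_eps & f_star <= 1 - f_eps
  if (sum(use) < min_sites)
    stop("only ", sum(use), " usable sites (need ", min_sites, ")")
  g <- genotypes[use]; fs <- f_star[use]
  grid <- seq(0, 1, length.out = 101)
  ll <- inbreeding_loglik(grid, g, fs)
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(function(F) inbreeding_loglik(F, g, fs),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  # the refined interior optimum can only beat the grid; keep whichever wins
  if (opt$objective >= ll[i]) {
    F_hat <- opt$maximum; logL <- opt$objective
  } else {
    F_hat <- grid[i]; logL <- ll[i]
  }
  structure(list(id = id %||% "ind", F_hat = unname(F_hat),
                 logLik = unname(logL), n_sites = sum(use)),
            class = "inbreeding_ml")
}

#' @export
print.inbreeding_ml <- function(x, ...) {
  cat(sprintf("inbreeding_ml: %s  F = %.5f  (logLik %.3f over %d sites)\n",
              x$id, x$F_hat, x$logLik, x$n_sites))
  invisible(x)
}

#' Inbreeding coefficients for every individual of a cohort
#'
#' Convenience wrapper calling [estimate_inbreeding()] per individual of a
#' genotype matrix with its admixture-proportion matrix and a shared
#' ancestral-frequency table.
#'
#' @param gm A [geno_matrix()].
#' @param alphas An [admix_props()] matrix aligned with `gm`.
#' @param ancestral_freqs S x K matrix of per-ancestry allele frequencies.
#' @inheritParams estimate_inbreeding
#' @return Data frame with columns `id`, `F_hat`, `logLik`, `n_sites`.
#' @export
estimate_inbreeding_all <- function(gm, alphas, ancestral_freqs,
                                    f_eps = 0.005, min_sites = 50) {
  stopifnot(inherits(gm, "geno_matrix"), nrow(alphas) == n_individuals(gm))
  rows <- lapply(seq_len(n_individuals(gm)), function(i) {
    est <- estimate_inbreeding(gm$genotypes[i, ], unclass(alphas)[i, ],
                               ancestral_freqs, f_eps = f_eps,
                               min_sites = min_sites,
                               id = rownames(gm$genotypes)[i])
    data.frame(id = est$id, F_hat = est$F_hat, logLik = est$logLik,
               n_sites = est$n_sites, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
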