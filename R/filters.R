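#' Site quality-control filter
#'
#' Retains sites with minor allele frequency at least `maf_min` and missing
#' fraction at most `miss_max`. MAF and missingness are computed from
#' non-missing genotypes only. The SNP-array default (MAF below 5% and/or
#' more than 1% missingness removed) corresponds to
#' `maf_min = 0.05, miss_max = 0.01`.
#'
#' @param gm A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency, in `[0, 0.5]`.
#' @param miss_max Maximum missing-genotype fraction, in `[0, 1]`.
#' @return A [geno_matrix()] with the failing sites removed; a warning is
#'   issued (not an error) when no site survives.
#' @export
filter_sites <- function(gm, maf_min = 0.05, miss_max = 0.01) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1)
  maf <- site_maf(gm)
  miss <- site_missingness(gm)
  keep <- !is.na(maf) & maf >= maf_min & miss <= miss_max
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("all sites removed by filter_sites")
  gm[, keep]
}

#' Individual quality-control filter
#'
#' Removes individuals whose missing-genotype fraction exceeds `miss_max`,
#' assessed only at sites with minor allele frequency above `maf_floor`
#' (rare sites are uninformative about call quality). The SNP-array default
#' (more than 2% missingness among MAF > 1% sites) corresponds to
#' `miss_max = 0.02, maf_floor = 0.01`.
#'
#' @inheritParams filter_sites
#' @param maf_floor Sites with MAF at or below this are excluded from the
#'   missingness assessment.
#' @return A [geno_matrix()] with the failing individuals removed.
#' @export
filter_individuals <- function(gm, miss_max = 0.02, maf_floor = 0.01) {
  stopifnot(miss_max >= 0, miss_max <= 1, maf_floor >= 0, maf_floor <= 0.5)
  maf <- site_maf(gm)
  assess <- !is.na(maf) & maf > maf_floor
  if (!any(assess)) {
    warning("no sites above maf_floor; all individuals retained")
    return(gm)
  }
  miss <- rowMeans(is.na(gm$genotypes[, assess, drop = FALSE]))
  keep <- miss <= miss_max
  if (!any(keep)) warning("all individuals removed by filter_individuals")
  gm[keep, ]
}

## Squared Pearson correlation of genotype dosages (composite LD),
## pairwise-complete over missing calls.
genotype_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  vx <- stats::var(x[ok]); vy <- stats::var(y[ok])
  if (vx == 0 || vy == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Windowed LD pruning
#'
#' Scans each chromosome left to right in windows of `window` SNPs advanced
#' by `step` SNPs. Within a window, every pair of still-retained SNPs with
#' squared dosage correlation (composite LD) above `r2_max` loses its
#' later-positioned member. The output is deterministic and a subset of the
#' input columns in the original order. The SNP-array default corresponds to
#' `r2_max = 0.3, window = 50, step = 5`.
#'
#' @inheritParams filter_sites
#' @param r2_max Retain no within-window pair with r-squared above this.
#' @param window Window width in SNPs (must exceed `step` and be at least 2).
#' @param step Window advance in SNPs.
#' @return A pruned [geno_matrix()].
#' @export
ld_prune <- function(gm, r2_max = 0.3, window = 50, step = 5) {
  if (window < 2) stop("window must span at least 2 SNPs")
  stopifnot(step >= 1, window > step)
  keep <- rep(TRUE, n_sites(gm))
  for (chr in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == chr)
    nc <- length(idx)
    if (nc < 2) next
    starts <- seq(1L, nc, by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, nc)]
      if (length(win) < 2) next
      for (a in seq_len(length(win) - 1L)) {
        ia <- win[a]
        if (!keep[ia]) next
        for (b in (a + 1L):length(win)) {
          ib <- win[b]
          if (!keep[ib]) next
          r2 <- genotype_r2(gm$genotypes[, ia], gm$genotypes[, ib])
          if (!is.na(r2) && r2 > r2_max) keep[ib] <- FALSE
        }
      }
      if (s + window - 1L >= nc) break
    }
  }
  gm[, keep]
}
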