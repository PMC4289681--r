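#' Transition rates of the two-state ancestry-tract Markov process
#'
#' Ancestry along an admixed chromosome is approximated by a two-state
#' Markov chain over base pairs with per-bp rates
#' `lambda1 = (1 - m) r (t - 1)` (admixed to unadmixed) and
#' `lambda2 = m r (t - 1)` (unadmixed to admixed), where `m` is the
#' admixture proportion, `r` the recombination rate per bp (Morgans) and
#' `t > 1` the admixture time in generations. The stationary probability of
#' the unadmixed state is `pi2 = 1 - m`.
#'
#' @param m Admixture proportion in `[0, 1]`.
#' @param r Recombination rate, Morgans per bp.
#' @param t Admixture time in generations (`t > 1`).
#' @return List with `lambda1`, `lambda2`, `pi2`.
#' @export
tract_rates <- function(m, r, t) {
  if (t <= 1) stop("admixture time t must exceed 1 generation")
  stopifnot(m >= 0, m <= 1, r > 0)
  list(lambda1 = (1 - m) * r * (t - 1),
       lambda2 = m * r * (t - 1),
       pi2 = 1 - m)
}

#' Probability of observing no admixture tract of a given length
#'
#' Under the two-state Markov tract model, a site initiates a run of at
#' least `k` admixed sites with probability
#' `R = pi2 * lambda2 * (1 - lambda1)^(k-1)`; for small `R` and a genome of
#' `S` sites the number of such runs is approximately Poisson and the
#' probability of seeing none is `exp(-R * S)`. A length threshold in cM is
#' converted to sites by `k = round((L / 100) / r)` (one bp = one Markov
#' site at the uniform rate `r`). The power term is evaluated in log space
#' so genome-scale `k` does not underflow.
#'
#' @inheritParams tract_rates
#' @param S Genome size in bp.
#' @param length_cM Tract length threshold in centimorgans.
#' @return Probability of observing no admixed tract of at least
#'   `length_cM` in a genome of `S` sites.
#' @seealso [prob_at_least_one_tract()] for the complement.
#' @export
prob_no_tract_at_least <- function(m, r, t, S, length_cM) {
  rates <- tract_rates(m, r, t)
  stopifnot(S > 0, length_cM > 0)
  k <- round((length_cM / 100) / r)
  if (k < 1) stop("length threshold below one site at this rate")
  if (m == 0 || m == 1) return(1)
  logR <- log(rates$pi2) + log(rates$lambda2) +
    (k - 1) * log1p(-rates$lambda1)
  exp(-exp(logR) * S)
}

#' @rdname prob_no_tract_at_least
#' @export
prob_at_least_one_tract <- function(m, r, t, S, length_cM) {
  1 - prob_no_tract_at_least(m, r, t, S, length_cM)
}

#' Bin tract lengths into fixed-width cM bins
#'
#' Summarizes a tract-length distribution in `[i*bin, (i+1)*bin)` cM bins
#' (5 cM is the conventional width), optionally restricted to one ancestry
#' and stratified by population.
#'
#' @param ts A [tract_set()].
#' @param bin_cM Bin width in centimorgans.
#' @param ancestry Optional ancestry label to restrict to.
#' @param groups Optional named vector mapping individual ids to
#'   populations; when supplied, distributions are per population.
#' @return Data frame with columns `population`, `bin_low`, `bin_high`,
#'   `count`, `freq`; frequencies sum to 1 within each population.
#' @export
bin_tract_lengths <- function(ts, bin_cM = 5, ancestry = NULL,
                              groups = NULL) {
  if (bin_cM <= 0) stop("bin_cM must be positive")
  tr <- as.data.frame(ts)
  if (nrow(tr) == 0) stop("empty tract set")
  if (!is.null(ancestry)) tr <- tr[tr$ancestry %in% ancestry, , drop = FALSE]
  if (nrow(tr) == 0) stop("no tracts left after ancestry filter")
  pop <- if (is.null(groups)) rep("all", nrow(tr))
         else as.character(groups[tr$individual])
  bin <- floor(tr$length_cM / bin_cM)
  out <- lapply(split(seq_len(nrow(tr)), pop), function(idx) {
    tb <- table(bin[idx])
    b <- as.integer(names(tb))
    data.frame(population = pop[idx[1]],
               bin_low = b * bin_cM, bin_high = (b + 1) * bin_cM,
               count = as.integer(tb),
               freq = as.integer(tb) / length(idx),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match individuals across two cohorts by ancestry proportion
#'
#' Minimum-cost one-to-one matching: after discarding individuals below
#' `min_prop`, the smaller cohort is fully matched into the larger one so
#' that the total absolute difference in ancestry proportion is minimal.
#' For a one-dimensional cost an optimal matching preserves sorted order,
#' so the optimum is found by dynamic programming over the two sorted lists
#' (`O(nA * nB)`); the result is deterministic (on ties the earlier
#' candidate in sorted order is skipped). Used to compare tract-length
#' distributions between populations while controlling for
#' population-level differences in admixture.
#'
#' @param props_A,props_B Numeric vectors of ancestry proportions.
#' @param min_prop Minimum proportion for inclusion.
#' @return List with `pairs` (data frame: `index_A`, `index_B`, `prop_A`,
#'   `prop_B`, `diff`, indices referring to the original vectors) and
#'   `total_diff`.
#' @export
match_by_ancestry <- function(props_A, props_B, min_prop = 0.05) {
  ia <- which(props_A >= min_prop)
  ib <- which(props_B >= min_prop)
  if (length(ia) == 0 || length(ib) == 0)
    stop("one side is empty after filtering at min_prop")
  swapped <- length(ia) > length(ib)
  if (swapped) { tmp <- ia; ia <- ib; ib <- tmp
                 x <- props_B; y <- props_A } else { x <- props_A; y <- props_B }
  sa <- ia[order(x[ia])]; sb <- ib[order(y[ib])]
  n <- length(sa); m <- length(sb)
  # f[i+1, j+1]: minimal cost of matching the first i of sa into first j of sb
  f <- matrix(Inf, n + 1, m + 1)
  f[1, ] <- 0
  for (i in seq_len(n)) for (j in i:m)
    f[i + 1, j + 1] <- min(f[i + 1, j],
                           f[i, j] + abs(x[sa[i]] - y[sb[j]]))
  # backtrack
  pa <- integer(n); i <- n; j <- m
  while (i >= 1) {
    if (f[i + 1, j + 1] == f[i + 1, j]) { j <- j - 1 }
    else { pa[i] <- sb[j]; i <- i - 1; j <- j - 1 }
  }
  idx_small <- sa; idx_big <- pa
  if (swapped) {
    index_A <- idx_big; index_B <- idx_small
  } else {
    index_A <- idx_small; index_B <- idx_big
  }
  pairs <- data.frame(index_A = index_A, index_B = index_B,
                      prop_A = props_A[index_A], prop_B = props_B[index_B],
                      diff = abs(props_A[index_A] - props_B[index_B]))
  pairs <- pairs[order(pairs$index_A), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, total_diff = sum(pairs$diff))
}
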