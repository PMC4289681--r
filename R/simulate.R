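#' Draw admixture proportions from a point-mass/beta mixture
#'
#' Each individual's ancestry-1 proportion is 0 with probability `p0`, 1
#' with probability `p1`, and otherwise a `Beta(a, b)` draw. This is the
#' distribution family the admixture-correction machinery fits: cohorts of
#' recently admixed individuals typically contain both unadmixed individuals
#' (an atom at 0) and fully migrant individuals (an atom at 1).
#'
#' @param n Number of individuals.
#' @param p0,p1 Atom probabilities at 0 and 1 (`p0 + p1 <= 1`).
#' @param a,b Beta shape parameters for the interior component.
#' @param labels Ancestry labels for the two columns.
#' @param seed Optional integer seed.
#' @return An [admix_props()] matrix with columns `(alpha, 1 - alpha)`.
#' @export
draw_admixture_proportions <- function(n, p0 = 0, a = 1, b = 1, p1 = 0,
                                       labels = c("EUR", "INUIT"),
                                       seed = NULL) {
  stopifnot(n >= 1, p0 >= 0, p1 >= 0, p0 + p1 <= 1, a > 0, b > 0)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  alpha <- numeric(n)
  interior <- u >= p0 & u < 1 - p1
  alpha[u < p0] <- 0
  alpha[u >= 1 - p1] <- 1
  alpha[interior] <- stats::rbeta(sum(interior), a, b)
  admix_props(cbind(alpha, 1 - alpha), labels = labels)
}

#' Simulate allele frequencies drifting on a rooted 4-leaf tree
#'
#' Frequencies evolve from a shared ancestral frequency along the fixed
#' topology `(((H1, H2), H3), H4)` by successive Balding-Nichols draws: a
#' branch with drift parameter `c` replaces frequency `f` by a
#' `Beta(f(1-c)/c, (1-f)(1-c)/c)` draw (mean `f`, variance `c f(1-f)`).
#' `c = 0` means no drift on that branch.
#'
#' @param n_sites Number of independent sites.
#' @param drift Named numeric vector of per-branch drift parameters in
#'   `[0, 1)`: `n1` (root to the H1/H2/H3 ancestor), `n2` (to the H1/H2
#'   ancestor), `H1`, `H2`, `H3`, `H4` (terminal branches).
#' @param root_freq Function of `n` returning ancestral frequencies, or a
#'   numeric vector of length `n_sites`; default `Unif(0.05, 0.95)`.
#' @param seed Optional integer seed.
#' @return List with matrix `leaves` (`n_sites` x 4, columns H1..H4) and
#'   vector `root` of ancestral frequencies.
#' @export
simulate_ancestral_frequencies <- function(n_sites,
                                           drift = c(n1 = 0.02, n2 = 0.02,
                                                     H1 = 0.05, H2 = 0.05,
                                                     H3 = 0.05, H4 = 0.05),
                                           root_freq = NULL, seed = NULL) {
  stopifnot(n_sites >= 1)
  need <- c("n1", "n2", "H1", "H2", "H3", "H4")
  if (!all(need %in% names(drift)))
    stop("drift needs entries: ", paste(need, collapse = ", "))
  if (any(drift < 0) || any(drift >= 1))
    stop("drift parameters must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  f0 <- if (is.null(root_freq)) stats::runif(n_sites, 0.05, 0.95)
        else if (is.function(root_freq)) root_freq(n_sites)
        else rep_len(root_freq, n_sites)
  bn <- function(f, c) {
    if (c < 1e-12) return(f)
    f <- pmin(pmax(f, 1e-9), 1 - 1e-9)
    out <- stats::rbeta(length(f), f * (1 - c) / c, (1 - f) * (1 - c) / c)
    pmin(pmax(out, 1e-9), 1 - 1e-9)
  }
  f_n1 <- bn(f0, drift[["n1"]])
  f_n2 <- bn(f_n1, drift[["n2"]])
  leaves <- cbind(H1 = bn(f_n2, drift[["H1"]]),
                  H2 = bn(f_n2, drift[["H2"]]),
                  H3 = bn(f_n1, drift[["H3"]]),
                  H4 = bn(f0, drift[["H4"]]))
  list(leaves = leaves, root = f0)
}

#' Simulate genotypes of admixed, possibly inbred individuals
#'
#' For individual `i` at site `s`: with probability `F_i` one (ancestry,
#' allele) pair is drawn -- ancestry `k` with probability `alpha_ik`, allele
#' with probability `f_sk` -- and duplicated (identity by descent);
#' otherwise the two gene copies are drawn independently. The expected
#' genotype mean is `2 f*_s` with `f*_s = sum_k alpha_ik f_sk`. Inbreeding
#' is applied independently per site, matching the composite likelihood of
#' the inbreeding estimator (not contiguous runs of homozygosity).
#'
#' @param alphas An [admix_props()] matrix (`n` x `K`).
#' @param freqs Numeric `S` x `K` matrix of per-ancestry allele frequencies.
#' @param F_true Per-individual inbreeding coefficients in `[0, 1]`
#'   (recycled).
#' @param sites Optional site table; default: one chromosome, positions
#'   `1e4 * (1:S)`.
#' @param seed Optional integer seed.
#' @return A [geno_matrix()].
#' @export
simulate_admixed_genotypes <- function(alphas, freqs, F_true = 0,
                                       sites = NULL, seed = NULL) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != ncol(alphas))
    stop("freqs must have one column per ancestry")
  if (any(freqs < 0) || any(freqs > 1)) stop("frequencies must be in [0, 1]")
  n <- nrow(alphas); S <- nrow(freqs); K <- ncol(freqs)
  F_true <- rep_len(F_true, n)
  stopifnot(all(F_true >= 0), all(F_true <= 1))
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(NA_integer_, n, S)
  for (i in seq_len(n)) {
    k1 <- sample.int(K, S, replace = TRUE, prob = alphas[i, ])
    k2 <- sample.int(K, S, replace = TRUE, prob = alphas[i, ])
    a1 <- stats::rbinom(S, 1, freqs[cbind(seq_len(S), k1)])
    a2 <- stats::rbinom(S, 1, freqs[cbind(seq_len(S), k2)])
    ibd <- stats::runif(S) < F_true[i]
    a2[ibd] <- a1[ibd]
    g[i, ] <- a1 + a2
  }
  if (is.null(sites))
    sites <- data.frame(chrom = "chr1", pos = 10000L * seq_len(S),
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
  geno_matrix(g, sites = sites, individual_ids = rownames(alphas))
}

#' Simulate two-SNP genotypes of admixed individuals
#'
#' Each individual receives two haplotypes drawn independently: the
#' haplotype's ancestry `k` with probability `alpha_ik`, then the haplotype
#' (`AB`, `Ab`, `aB`, `ab`) from that ancestry's frequency column. The
#' ancestry is shared by the two loci of a haplotype (loci assumed tightly
#' linked). Phase is discarded: genotypes are per-site allele sums. All
#' `n_pairs` pairs share the haplotype-frequency matrix.
#'
#' @param alphas An [admix_props()] matrix.
#' @param pair_hap_freqs 4 x K matrix of haplotype frequencies (rows AB, Ab,
#'   aB, ab), each column summing to 1.
#' @param n_pairs Number of independent SNP pairs (2 sites each).
#' @param seed Optional integer seed.
#' @return A [geno_matrix()] with `2 * n_pairs` sites; sites `2j - 1` and
#'   `2j` form pair `j`.
#' @export
simulate_admixed_genotype_pairs <- function(alphas, pair_hap_freqs,
                                            n_pairs = 1, seed = NULL) {
  p <- as.matrix(pair_hap_freqs)
  if (nrow(p) != 4 || ncol(p) != ncol(alphas))
    stop("pair_hap_freqs must be 4 x K")
  if (any(abs(colSums(p) - 1) > 1e-8))
    stop("each ancestry's haplotype frequencies must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(alphas); K <- ncol(alphas)
  g <- matrix(NA_integer_, n, 2L * n_pairs)
  for (i in seq_len(n)) {
    k <- matrix(sample.int(K, 2L * n_pairs, replace = TRUE,
                           prob = alphas[i, ]), ncol = 2)
    hap <- matrix(0L, n_pairs, 2)
    for (h in 1:2)
      hap[, h] <- vapply(k[, h], function(kk)
        sample.int(4L, 1L, prob = p[, kk]), integer(1))
    g[i, seq(1, 2 * n_pairs, by = 2)] <-
      HAP_ALLELES[hap[, 1], 1] + HAP_ALLELES[hap[, 2], 1]
    g[i, seq(2, 2 * n_pairs, by = 2)] <-
      HAP_ALLELES[hap[, 1], 2] + HAP_ALLELES[hap[, 2], 2]
  }
  pos <- as.integer(t(cbind(2e6 * seq_len(n_pairs),
                            2e6 * seq_len(n_pairs) + 1000)))
  sites <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
  geno_matrix(g, sites = sites, individual_ids = rownames(alphas))
}

#' Simulate ancestry tracts along haplotypes by a two-state Markov process
#'
#' Ancestry along a haplotype alternates between the admixed and unadmixed
#' state with per-base-pair exit probabilities `lambda1 = (1-m) r (t-1)`
#' (leaving the admixed state) and `lambda2 = m r (t-1)` (entering it),
#' where `m` is the admixture proportion, `r` the recombination rate per bp
#' and `t` the admixture time in generations. The initial state is admixed
#' with the stationary probability `m`; run lengths are geometric. Tracts
#' are emitted with bp lengths and `cM = bp * r * 100`.
#'
#' @param m Admixture proportion in `[0, 1]`.
#' @param r Recombination rate, Morgans per bp.
#' @param t Admixture time in generations (`t > 1`).
#' @param chrom_lengths_bp Named or unnamed vector of chromosome lengths.
#' @param n_individuals Number of diploid individuals (2 haplotypes each).
#' @param seed Optional integer seed.
#' @return A [tract_set()] containing the admixed-ancestry (`"ADMIXED"`) and
#'   unadmixed (`"UNADMIXED"`) tracts.
#' @export
simulate_ancestry_tracts <- function(m, r, t, chrom_lengths_bp,
                                     n_individuals = 1, seed = NULL) {
  if (t <= 1) stop("admixture time t must exceed 1 generation")
  stopifnot(m >= 0, m <= 1, r > 0)
  if (!is.null(seed)) set.seed(seed)
  rates <- tract_rates(m, r, t)
  chroms <- chrom_lengths_bp
  if (is.null(names(chroms))) names(chroms) <- paste0("chr", seq_along(chroms))
  acc <- list(chrom = list(), start = list(), end = list(),
              individual = list(), haplotype = list(), ancestry = list())
  states <- c("ADMIXED", "UNADMIXED")
  for (i in seq_len(n_individuals)) {
    for (hap in 1:2) {
      for (ci in seq_along(chroms)) {
        L <- chroms[[ci]]
        pos <- 0
        state <- if (stats::runif(1) < m) 1L else 2L  # 1 = admixed
        starts <- ends <- numeric(0)
        anc <- integer(0)
        while (pos < L) {
          lambda <- if (state == 1L) rates$lambda1 else rates$lambda2
          len <- if (lambda <= 0) L - pos
                 else min(stats::rgeom(1, lambda) + 1, L - pos)
          starts <- c(starts, pos); ends <- c(ends, pos + len)
          anc <- c(anc, state)
          pos <- pos + len
          state <- 3L - state
        }
        j <- length(acc$chrom) + 1L
        acc$chrom[[j]] <- rep(names(chroms)[ci], length(starts))
        acc$start[[j]] <- starts
        acc$end[[j]] <- ends
        acc$individual[[j]] <- rep(paste0("ind", i), length(starts))
        acc$haplotype[[j]] <- rep(hap, length(starts))
        acc$ancestry[[j]] <- states[anc]
      }
    }
  }
  tracts <- data.frame(chrom = unlist(acc$chrom),
                       start = unlist(acc$start), end = unlist(acc$end),
                       individual = unlist(acc$individual),
                       haplotype = unlist(acc$haplotype),
                       ancestry = unlist(acc$ancestry),
                       stringsAsFactors = FALSE)
  tract_set(tracts, rate_morgans_per_bp = r)
}
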