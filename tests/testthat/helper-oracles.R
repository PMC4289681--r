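# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: plain loops, direct formula transcription.

# Tiny geno_matrix builder: g is individuals x sites.
toy_gm <- function(g, chrom = NULL, pos = NULL) {
  g <- as.matrix(g)
  S <- ncol(g)
  geno_matrix(g, sites = data.frame(
    chrom = chrom %||% rep("chr1", S),
    pos = pos %||% (1000L * seq_len(S)),
    ref = "A", alt = "G", stringsAsFactors = FALSE))
}

# Single-pass windowed LD pruning, nested loops, no shortcuts.
ld_prune_reference <- function(g, chrom, r2_max, window, step) {
  keep <- rep(TRUE, ncol(g))
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    for (s in seq(1, length(idx), by = step)) {
      win <- idx[s:min(s + window - 1, length(idx))]
      for (a in seq_along(win)) for (b in seq_along(win)) {
        if (a >= b) next
        if (!keep[win[a]] || !keep[win[b]]) next
        x <- g[, win[a]]; y <- g[, win[b]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 2 || var(x[ok]) == 0 || var(y[ok]) == 0) next
        if (cor(x[ok], y[ok])^2 > r2_max) keep[win[b]] <- FALSE
      }
      if (s + window - 1 >= length(idx)) break
    }
  }
  which(keep)
}

# Classic unweighted delete-m jackknife for a ratio-of-sums statistic with
# equal-size blocks (reduces to delete-1 when each block has one site).
jackknife_equal_m_reference <- function(num, den, block_ids) {
  blocks <- unique(block_ids)
  g <- length(blocks)
  theta <- sum(num) / sum(den)
  loo <- sapply(blocks, function(b) {
    keep <- block_ids != b
    sum(num[keep]) / sum(den[keep])
  })
  pseudo <- g * theta - (g - 1) * loo
  se <- sqrt(sum((pseudo - mean(pseudo))^2) / (g * (g - 1)))
  list(theta = theta, SE = se)
}

# Independent K = 1 likelihood for a two-SNP genotype sample: direct sum over
# ordered haplotype pairs consistent with each genotype (p in order AB, Ab,
# aB, ab; allele coding: AB carries the counted allele at both sites).
k1_pair_loglik <- function(p, g1, g2) {
  x1 <- c(1, 1, 0, 0); x2 <- c(1, 0, 1, 0)
  ll <- 0
  for (i in seq_along(g1)) {
    li <- 0
    for (h1 in 1:4) for (h2 in 1:4)
      if (x1[h1] + x1[h2] == g1[i] && x2[h1] + x2[h2] == g2[i])
        li <- li + p[h1] * p[h2]
    ll <- ll + log(li)
  }
  ll
}

# Brute-force maximization of k1_pair_loglik: exhaustive simplex grid
# (resolution `res`) followed by a generic simplex-parameterized optimizer
# polish from the best grid point. Fully independent of the EM.
k1_grid_max_loglik <- function(g1, g2, res = 0.005) {
  steps <- round(1 / res)
  grid <- expand.grid(i = 0:steps, j = 0:steps)
  # tabulate genotype classes once; class likelihood is a polynomial in p
  cls <- table(factor(3 * g1 + g2 + 1, levels = 1:9))
  x1 <- c(1, 1, 0, 0); x2 <- c(1, 0, 1, 0)
  class_pairs <- lapply(1:9, function(cl) {
    gg1 <- (cl - 1) %/% 3; gg2 <- (cl - 1) %% 3
    pp <- NULL
    for (h1 in 1:4) for (h2 in 1:4)
      if (x1[h1] + x1[h2] == gg1 && x2[h1] + x2[h2] == gg2)
        pp <- rbind(pp, c(h1, h2))
    pp
  })
  best_ll <- -Inf; best_p <- NULL
  for (i in 0:steps) {
    jmax <- steps - i
    for (j in 0:jmax) {
      k <- 0:(steps - i - j)
      p1 <- i * res; p2 <- j * res; p3 <- k * res; p4 <- 1 - p1 - p2 - p3
      P <- cbind(p1, p2, p3, pmax(p4, 0))
      ll <- rep(0, nrow(P))
      for (cl in which(cls > 0)) {
        pp <- class_pairs[[cl]]
        lc <- rep(0, nrow(P))
        for (r in seq_len(nrow(pp)))
          lc <- lc + P[, pp[r, 1]] * P[, pp[r, 2]]
        ll <- ll + cls[cl] * log(lc)
      }
      m <- which.max(ll)
      if (ll[m] > best_ll) { best_ll <- ll[m]; best_p <- P[m, ] }
    }
  }
  # polish with a generic optimizer in softmax coordinates
  obj <- function(z) {
    p <- exp(c(z, 0)); p <- p / sum(p)
    -k1_pair_loglik(p, g1, g2)
  }
  z0 <- log(pmax(best_p, 1e-6) / pmax(best_p[4], 1e-6))[1:3]
  opt <- optim(z0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  max(best_ll, -opt$value)
}

# Classical two-locus composite EM for unphased genotypes in ONE population
# (no admixture): cubic-EM on the double-heterozygote phase split.
classic_two_locus_em <- function(g1, g2, tol = 1e-10, max_iter = 10000) {
  n <- length(g1)
  p <- rep(0.25, 4)  # AB, Ab, aB, ab
  # counts of fully determined haplotypes per genotype category
  for (iter in seq_len(max_iter)) {
    cnt <- numeric(4)
    for (i in seq_len(n)) {
      a <- g1[i]; b <- g2[i]
      if (a == 1 && b == 1) {
        # AB/ab vs Ab/aB
        w1 <- p[1] * p[4]; w2 <- p[2] * p[3]
        if (w1 + w2 == 0) { w1 <- w2 <- 0.5 } else {
          w1 <- w1 / (p[1] * p[4] + p[2] * p[3]) }
        w2 <- 1 - w1
        cnt <- cnt + c(w1, w2, w2, w1)
      } else {
        # unambiguous: haplotypes are (ceil splits)
        h1 <- c(ifelse(a >= 1, 1, 0), ifelse(b >= 1, 1, 0))
        h2 <- c(a - h1[1], b - h1[2])
        idx <- function(x) 4 - (x[1] * 2 + x[2])  # (1,1)->1,(1,0)->2,(0,1)->3,(0,0)->4
        cnt[idx(h1)] <- cnt[idx(h1)] + 1
        cnt[idx(h2)] <- cnt[idx(h2)] + 1
      }
    }
    p_new <- cnt / (2 * n)
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  p
}

# Infinite-sample-size Weir-Cockerham variance components from true
# frequencies of two equally weighted populations under HWE.
wc_realized_theta <- function(f1, f2) {
  pbar <- (f1 + f2) / 2
  s2 <- ((f1 - pbar)^2 + (f2 - pbar)^2)
  hbar <- f1 * (1 - f1) + f2 * (1 - f2)
  a <- s2
  b <- pbar * (1 - pbar) - s2 / 2 - hbar / 2
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  sum(a[poly]) / sum((a + b + cc)[poly])
}

# Hand-rolled 4-choose-2-style exhaustive assignment: minimum total
# |difference| over all one-to-one matchings of equally sized lists.
exhaustive_match_total <- function(a, b) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  min(vapply(perms(seq_along(b)), function(s) sum(abs(a - b[s])), numeric(1)))
}
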