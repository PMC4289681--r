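test_that("r2 from haplotype frequencies evaluates the D-prime-free formula", {
  expect_equal(r_squared_from_haplotypes(c(.5, 0, 0, .5)), 1)
  expect_equal(r_squared_from_haplotypes(c(.25, .25, .25, .25)), 0)
  expect_equal(r_squared_from_haplotypes(c(.4, .2, .1, .3)),
               0.1^2 / (0.6 * 0.4 * 0.5 * 0.5))
  expect_true(is.na(r_squared_from_haplotypes(c(0, 0, .5, .5))))  # locus 1 fixed
  expect_error(r_squared_from_haplotypes(c(.5, .5, .5, .5)), "sum to 1")
})

test_that("fully determined haplotypes are recovered exactly", {
  # unadmixed cohort, only (0,0) and (2,2) genotype pairs: every haplotype
  # is observable, so p_ab and p_AB are the sample fractions and r2 = 1
  g <- rbind(matrix(0L, 30, 2), matrix(2L, 20, 2))
  al <- admix_props(matrix(1, 50, 1), labels = "POP")
  fit <- estimate_pair_haplotype_frequencies(g, al, seed = 31)
  expect_equal(unname(fit$p["ab", 1]), 0.6, tolerance = 1e-6)
  expect_equal(unname(fit$p["AB", 1]), 0.4, tolerance = 1e-6)
  expect_equal(r_squared_from_haplotypes(fit$p[, 1]), 1, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("missing genotypes drop individuals and empty input errors", {
  g <- rbind(c(0L, NA), c(1L, 1L), c(2L, 2L))
  al <- admix_props(matrix(1, 3, 1), labels = "POP")
  fit <- estimate_pair_haplotype_frequencies(g, al, seed = 32)
  expect_equal(fit$n_used, 2)
  g_allmiss <- matrix(NA_integer_, 3, 2)
  expect_error(estimate_pair_haplotype_frequencies(g_allmiss, al),
               "no individuals")
})

test_that("K=1 EM attains the brute-force grid maximum of the likelihood", {
  set.seed(33)
  for (rep in 1:3) {
    p_true <- as.numeric(rmultinom(1, 40, c(.3, .2, .2, .3))) / 40
    al <- admix_props(matrix(1, 20, 1), labels = "POP")
    g <- simulate_admixed_genotype_pairs(al, matrix(p_true, 4, 1))
    fit <- estimate_pair_haplotype_frequencies(g$genotypes, al, tol = 1e-9,
                                               n_starts = 5, seed = rep)
    oracle <- k1_grid_max_loglik(g$genotypes[, 1], g$genotypes[, 2])
    expect_lt(abs(fit$logLik - oracle), 1e-4)
  }
})

test_that("K=1 EM agrees with the classical two-locus genotype EM", {
  set.seed(34)
  for (rep in 1:5) {
    p_true <- as.numeric(rmultinom(1, 60, runif(4, .1, 1)))
    p_true <- p_true / sum(p_true)
    al <- admix_props(matrix(1, 100, 1), labels = "POP")
    g <- simulate_admixed_genotype_pairs(al, matrix(p_true, 4, 1))
    fit <- estimate_pair_haplotype_frequencies(g$genotypes, al, tol = 1e-10,
                                               n_starts = 5, seed = rep)
    ref <- classic_two_locus_em(g$genotypes[, 1], g$genotypes[, 2])
    expect_lt(max(abs(fit$p[, 1] - ref)), 1e-6)
  }
})

test_that("EM log-likelihood never decreases and columns stay stochastic", {
  set.seed(35)
  for (rep in 1:20) {
    n <- 30
    al <- draw_admixture_proportions(n, a = 1, b = 1)
    p <- matrix(runif(8), 4, 2)
    p <- sweep(p, 2, colSums(p), "/")
    g <- simulate_admixed_genotype_pairs(al, p, n_pairs = 1)
    fit <- estimate_pair_haplotype_frequencies(g$genotypes, al, n_starts = 2,
                                               seed = rep)
    expect_true(all(diff(fit$trace) >= -1e-8))
    expect_equal(unname(colSums(fit$p)), c(1, 1), tolerance = 1e-12)
    expect_true(all(fit$p >= 0))
  }
})

test_that("ancestries with negligible admixture weight are flagged unresolved", {
  al <- admix_props(cbind(rep(0.999, 20), rep(0.001, 20)),
                    labels = c("A", "B"), tol = 1e-2)
  g <- matrix(sample(0:2, 40, replace = TRUE), 20, 2)
  fit <- estimate_pair_haplotype_frequencies(g, al, seed = 36)
  expect_true(fit$resolved["A"])
  expect_false(fit$resolved["B"])
})

test_that("K=2 haplotype frequencies are recovered from an admixed cohort", {
  # ancestry 1 in strong LD (r2 = 0.9), ancestry 2 at equilibrium
  D <- sqrt(0.9 * 0.25 * 0.25)
  p1 <- c(.25 + D, .25 - D, .25 - D, .25 + D)
  p <- cbind(p1, rep(.25, 4))
  al <- draw_admixture_proportions(1000, a = 2, b = 2, seed = 37)
  g <- simulate_admixed_genotype_pairs(al, p, n_pairs = 1, seed = 38)
  fit <- estimate_pair_haplotype_frequencies(g$genotypes, al, seed = 39)
  expect_lt(max(abs(fit$p - p)), 0.05)
})

test_that("unadmixed-subset estimates match the inferred ancestral component", {
  D <- 0.15
  p1 <- c(.25 + D, .25 - D, .25 - D, .25 + D)
  p <- cbind(p1, rep(.25, 4))
  al <- draw_admixture_proportions(1500, p0 = 0.4, a = 2, b = 2, seed = 40)
  g <- simulate_admixed_genotype_pairs(al, p, n_pairs = 1, seed = 41)
  full <- estimate_pair_haplotype_frequencies(g$genotypes, al, seed = 42)
  sub <- al[, "EUR"] < 1e-9  # unadmixed in ancestry 2 (INUIT)
  al_sub <- admix_props(matrix(1, sum(sub), 1), labels = "INUIT")
  direct <- estimate_pair_haplotype_frequencies(g$genotypes[sub, ], al_sub,
                                                seed = 43)
  expect_lt(max(abs(full$p[, "INUIT"] - direct$p[, 1])), 0.05)
})

test_that("LD decay binning reports naive and per-ancestry curves", {
  set.seed(44)
  n <- 400
  al <- admix_props(matrix(1, n, 1), labels = "POP")
  # 12 sites on one chromosome, weak decaying LD via a latent haplotype
  S <- 12
  hap1 <- matrix(rbinom(n * S, 1, 0.5), n, S)
  hap2 <- matrix(rbinom(n * S, 1, 0.5), n, S)
  g <- hap1 + hap2
  gm <- toy_gm(g, pos = as.integer(seq(1e5, 12e5, length.out = S)))
  ld <- ld_decay_curve(gm, al, distance_bins = c(0, 5e5, 15e5),
                       max_pairs_per_bin = 10, seed = 45)
  expect_true(all(ld$bins$n_pairs <= 10))
  expect_true(all(ld$bins$r2_naive >= 0 & ld$bins$r2_naive <= 1))
  expect_true(all(!is.na(ld$pairs$r2_POP)))
  # no candidate pairs: empty result
  ld0 <- ld_decay_curve(gm[, 1], al, distance_bins = c(0, 1e5))
  expect_null(ld0$bins)
})

test_that("for an unadmixed cohort the EM curve equals the classical haplotype EM", {
  set.seed(46)
  n <- 1000
  al <- admix_props(matrix(1, n, 1), labels = "POP")
  diffs <- replicate(10, {
    p_true <- as.numeric(rmultinom(1, 50, runif(4, .2, 1)))
    p_true <- p_true / sum(p_true)
    g <- simulate_admixed_genotype_pairs(al, matrix(p_true, 4, 1))
    fit <- estimate_pair_haplotype_frequencies(g$genotypes, al, n_starts = 3)
    ref <- classic_two_locus_em(g$genotypes[, 1], g$genotypes[, 2])
    r2_em <- r_squared_from_haplotypes(fit$p[, 1])
    r2_ref <- r_squared_from_haplotypes(ref)
    abs(r2_em - r2_ref)
  })
  expect_lt(mean(diffs, na.rm = TRUE), 0.01)
})
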