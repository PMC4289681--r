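test_that("generators are bit-reproducible under a fixed seed", {
  a1 <- draw_admixture_proportions(50, p0 = .2, a = 2, b = 5, p1 = .1, seed = 9)
  a2 <- draw_admixture_proportions(50, p0 = .2, a = 2, b = 5, p1 = .1, seed = 9)
  expect_identical(a1, a2)
  f1 <- simulate_ancestral_frequencies(20, seed = 9)
  f2 <- simulate_ancestral_frequencies(20, seed = 9)
  expect_identical(f1, f2)
  t1 <- simulate_ancestry_tracts(.05, 1.3e-8, 25, 1e8, 2, seed = 9)
  t2 <- simulate_ancestry_tracts(.05, 1.3e-8, 25, 1e8, 2, seed = 9)
  expect_identical(t1, t2)
})

test_that("admixture proportions follow the point-mass/beta mixture", {
  expect_true(all(draw_admixture_proportions(20, p0 = 1, seed = 1)[, 1] == 0))
  # uniform interior: mean ~ 0.5 within 3 SE (SE for Unif(0,1) = 1/sqrt(12n))
  a <- draw_admixture_proportions(10000, a = 1, b = 1, seed = 2)[, 1]
  expect_lt(abs(mean(a) - 0.5), 3 / sqrt(12 * 10000))
  # atom at zero: binomial SE
  a2 <- draw_admixture_proportions(10000, p0 = .3, a = 2, b = 5, p1 = .1,
                                   seed = 3)[, 1]
  expect_lt(abs(mean(a2 == 0) - 0.3), 3 * sqrt(.3 * .7 / 10000))
  expect_lt(abs(mean(a2 == 1) - 0.1), 3 * sqrt(.1 * .9 / 10000))
  expect_error(draw_admixture_proportions(10, p0 = .6, p1 = .5))
})

test_that("frequency drift on the 4-leaf tree has the Balding-Nichols moments", {
  # no drift: leaves equal the root
  f0 <- simulate_ancestral_frequencies(50, drift = c(n1 = 0, n2 = 0, H1 = 0,
                                                     H2 = 0, H3 = 0, H4 = 0),
                                       seed = 4)
  expect_equal(f0$leaves[, "H1"], f0$root, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(f0$leaves[, "H4"], f0$root, tolerance = 1e-12,
               ignore_attr = TRUE)
  # symmetric drift to H1/H2: E[f_H1 - f_H2] = 0 within 3 SE
  fs <- simulate_ancestral_frequencies(20000, seed = 5)
  d <- fs$leaves[, "H1"] - fs$leaves[, "H2"]
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("drifted population pair reproduces the implied Weir-Cockerham FST", {
  set.seed(6)
  cc <- 0.12
  fs <- simulate_ancestral_frequencies(
    5000, drift = c(n1 = 0, n2 = 0, H1 = cc, H2 = cc, H3 = 0, H4 = 0))
  n <- 250
  g <- rbind(
    sapply(fs$leaves[, "H1"], function(f) rbinom(n, 2, f)),
    sapply(fs$leaves[, "H2"], function(f) rbinom(n, 2, f)))
  gm <- toy_gm(g, chrom = rep("chr1", 5000), pos = 1000L * seq_len(5000))
  fst <- weir_cockerham_fst(gm, rep(c("A", "B"), each = n))
  realized <- wc_realized_theta(fs$leaves[, "H1"], fs$leaves[, "H2"])
  expect_lt(abs(fst$fst - realized), 0.01)
  expect_lt(abs(realized - cc), 0.03)  # drift parameter sets the scale
})

test_that("admixed genotype simulation matches its stated moments", {
  al <- admix_props(matrix(c(1, 0), 1, 2))
  # zero frequencies -> all genotypes zero
  g0 <- simulate_admixed_genotypes(al, matrix(0, 100, 2), seed = 7)
  expect_true(all(g0$genotypes == 0))
  # full IBD: no heterozygotes
  g1 <- simulate_admixed_genotypes(al, matrix(0.5, 2000, 2), F_true = 1,
                                   seed = 8)
  expect_equal(sum(g1$genotypes == 1), 0)
  # HWE at F = 0 in one ancestry: frequencies within 3 multinomial SE
  S <- 10000
  g2 <- simulate_admixed_genotypes(al, matrix(0.3, S, 2), F_true = 0,
                                   seed = 9)
  obs <- tabulate(g2$genotypes[1, ] + 1L, 3) / S
  hwe <- c(.49, .42, .09)
  for (j in 1:3)
    expect_lt(abs(obs[j] - hwe[j]), 3 * sqrt(hwe[j] * (1 - hwe[j]) / S))
  # chi-square goodness of fit against binomial(2, f) sampling
  expect_gt(chisq.test(tabulate(g2$genotypes[1, ] + 1L, 3),
                       p = hwe)$p.value, 0.01)
})

test_that("two-SNP pair simulation reproduces haplotype frequencies", {
  al1 <- admix_props(matrix(1, 3, 1), labels = "POP")
  pAB <- matrix(c(1, 0, 0, 0), 4, 1)
  g <- simulate_admixed_genotype_pairs(al1, pAB, n_pairs = 5, seed = 10)
  expect_true(all(g$genotypes == 2))
  # unadmixed cohort, known p: empirical haplotype counts within 3 SE.
  # With p_Ab = p_aB = 0 every haplotype is identifiable from the genotypes.
  p <- matrix(c(.6, 0, 0, .4), 4, 1)
  n <- 4000
  al <- admix_props(matrix(1, n, 1), labels = "POP")
  gp <- simulate_admixed_genotype_pairs(al, p, n_pairs = 1, seed = 11)
  n_AB <- sum(gp$genotypes[, 1]) # copies of the alt-alt haplotype
  expect_lt(abs(n_AB / (2 * n) - 0.6), 3 * sqrt(.6 * .4 / (2 * n)))
  expect_error(simulate_admixed_genotype_pairs(al, matrix(c(.5, .2, .2, .2))),
               "sum to 1")
})

test_that("admixture of strong-LD and no-LD ancestries gives intermediate naive r2", {
  p <- cbind(c(.5, 0, 0, .5), c(.25, .25, .25, .25))  # r2 = 1 and r2 = 0
  al <- admix_props(matrix(0.5, 600, 2))
  g <- simulate_admixed_genotype_pairs(al, p, n_pairs = 20, seed = 12)
  r2 <- sapply(seq_len(20), function(j)
    cor(g$genotypes[, 2 * j - 1], g$genotypes[, 2 * j])^2)
  expect_gt(mean(r2), 0.05)
  expect_lt(mean(r2), 0.95)
})

test_that("ancestry tracts have geometric lengths and stationary admixed mass", {
  m <- 0.05; r <- 1.3e-8; t <- 25
  expect_equal(nrow(subset(simulate_ancestry_tracts(0, r, t, 1e8, 5, seed = 13),
                           ancestry == "ADMIXED")), 0)
  ts <- simulate_ancestry_tracts(m, r, t, 7e10, n_individuals = 5, seed = 14)
  adm <- ts[ts$ancestry == "ADMIXED" & ts$end < 7e10, ]
  expect_gt(nrow(adm), 5000)
  mean_len <- 1 / ((1 - m) * r * (t - 1))
  expect_lt(abs(mean(adm$length_bp) - mean_len),
            3 * sd(adm$length_bp) / sqrt(nrow(adm)))
  # stationary admixed fraction across haplotypes
  ts2 <- simulate_ancestry_tracts(m, r, t, 2e8, n_individuals = 500, seed = 15)
  hap <- paste(ts2$individual, ts2$haplotype)
  frac <- tapply(ts2$length_bp * (ts2$ancestry == "ADMIXED"), hap, sum) / 2e8
  expect_lt(abs(mean(frac) - m), 3 * sd(frac) / sqrt(length(frac)))
})
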