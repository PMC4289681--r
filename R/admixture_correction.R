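#' Fit a point-mass/beta mixture to admixture proportions
#'
#' Model-based ancestry estimates of a recently admixed cohort typically
#' pile up at exactly 0 (unadmixed individuals) and 1 (migrants), with a
#' continuous spread in between. The fitted model puts probability `p0` at
#' 0, `p1` at 1, and a `Beta(a, b)` density on the interior. Point masses
#' are assigned empirically (fraction of values within `eps` of the
#' boundary, since ancestry software emits near-zero rather than exact-zero
#' values); the beta shapes are maximum-likelihood estimates on the interior
#' values, computed by [MASS::fitdistr()] from a moment-matching start.
#'
#' @param alphas Numeric vector of per-individual ancestry proportions in
#'   `[0, 1]` (e.g. one column of an [admix_props()] matrix), `n >= 3`.
#' @param eps Boundary threshold for point-mass assignment.
#' @return Object of class `admix_dist`: list with `p0`, `p1`, `shape1`,
#'   `shape2` (NA when there is no interior mass), `interior_mass`, `n`,
#'   `empirical_mean`, `model_mean`, `logLik`.
#' @export
fit_admixture_distribution <- function(alphas, eps = 1e-3) {
  alphas <- as.numeric(alphas)
  if (length(alphas) < 3) stop("need at least 3 values")
  if (any(!is.finite(alphas)) || any(alphas < 0) || any(alphas > 1))
    stop("admixture proportions must lie in [0, 1]")
  n <- length(alphas)
  at0 <- alphas <= eps
  at1 <- alphas >= 1 - eps
  interior <- alphas[!at0 & !at1]
  p0 <- mean(at0); p1 <- mean(at1)
  w_int <- 1 - p0 - p1
  shape <- c(NA_real_, NA_real_)
  ll <- n * (p0 * log(max(p0, 1e-300)) + p1 * log(max(p1, 1e-300)))
  if (w_int > 0) {
    if (length(interior) < 2)
      stop("interior mass present but fewer than 2 interior points")
    mu <- mean(interior); v <- stats::var(interior)
    v <- min(v, mu * (1 - mu) * 0.99)          # keep moment start feasible
    common <- mu * (1 - mu) / v - 1
    start <- list(shape1 = max(mu * common, 1e-2),
                  shape2 = max((1 - mu) * common, 1e-2))
    fit <- tryCatch(
      suppressWarnings(MASS::fitdistr(interior, stats::dbeta, start = start,
                                      lower = c(1e-6, 1e-6))),
      error = function(e)
        stop("degenerate beta fit (n_interior = ", length(interior),
             ", mean = ", format(mu), ", var = ", format(v), "): ",
             conditionMessage(e)))
    shape <- unname(fit$estimate)
    ll <- ll + n * w_int * log(w_int) + as.numeric(fit$loglik)
  }
  model_mean <- p1 + if (w_int > 0) w_int * shape[1] / (shape[1] + shape[2]) else 0
  structure(list(p0 = p0, p1 = p1, shape1 = shape[1], shape2 = shape[2],
                 interior_mass = w_int, n = n,
                 empirical_mean = mean(alphas), model_mean = model_mean,
                 logLik = ll),
            class = "admix_dist")
}

#' @export
print.admix_dist <- function(x, ...) {
  cat("admix_dist (point-mass/beta mixture), n =", x$n, "\n")
  cat(sprintf("  p0 = %.4f  p1 = %.4f  interior = %.4f\n",
              x$p0, x$p1, x$interior_mass))
  if (x$interior_mass > 0)
    cat(sprintf("  beta shapes: a = %.3f  b = %.3f\n", x$shape1, x$shape2))
  cat(sprintf("  mean: empirical %.4f, model %.4f\n",
              x$empirical_mean, x$model_mean))
  invisible(x)
}

#' Discretize a fitted admixture distribution into equal-width bins
#'
#' Splits `[0, 1]` into `B` equal-width bins. Each bin's mass is the
#' interior beta mass it contains, plus the point mass at 0 (first bin) or 1
#' (last bin). The representative proportion `alpha_b` is the
#' probability-weighted mean of the bin's content; empty bins keep zero mass
#' and their midpoint as representative.
#'
#' @param dist An `admix_dist` from [fit_admixture_distribution()].
#' @param B Number of bins (at least 2); 10 is the conventional choice.
#' @return Data frame with columns `lower`, `upper`, `alpha` (representative
#'   proportion) and `prob`, with `sum(prob) == 1`.
#' @export
discretize_distribution <- function(dist, B = 10) {
  stopifnot(inherits(dist, "admix_dist"))
  if (B < 2) stop("B must be at least 2")
  edges <- seq(0, 1, length.out = B + 1)
  lower <- edges[-(B + 1)]; upper <- edges[-1]
  mass <- numeric(B); moment <- numeric(B)
  if (dist$interior_mass > 0) {
    a <- dist$shape1; b <- dist$shape2
    cdf <- stats::pbeta(edges, a, b)
    mass <- dist$interior_mass * diff(cdf)
    # int_l^u x dBeta(a,b) = mean * [P(u; a+1, b) - P(l; a+1, b)]
    cdf1 <- stats::pbeta(edges, a + 1, b)
    moment <- dist$interior_mass * (a / (a + b)) * diff(cdf1)
  }
  mass[1] <- mass[1] + dist$p0                 # alpha = 0 adds no moment
  mass[B] <- mass[B] + dist$p1
  moment[B] <- moment[B] + dist$p1
  alpha <- ifelse(mass > 0, moment / mass, (lower + upper) / 2)
  data.frame(lower = lower, upper = upper, alpha = alpha,
             prob = mass / sum(mass))
}

#' Admixture-corrected allele frequencies
#'
#' Removes the contribution of admixture from an observed cohort allele
#' frequency. Under the mixture model, the observed frequency decomposes as
#' `f_G = E[alpha] f_D + (1 - E[alpha]) f'_G`, where `f_D` is the reference
#' (donor-population) frequency and `alpha` the donor-ancestry proportion.
#' With the fitted distribution discretized into bins `(alpha_b, Pr_b)`, the
#' corrected frequency is the ratio of bin-averaged sums
#' `sum_b Pr_b (f_G - alpha_b f_D) / sum_b Pr_b (1 - alpha_b)`,
#' which is exactly unbiased when the decomposition holds. Bins with
#' `alpha_b = 1` carry no information about the corrected frequency and are
#' excluded (their weight renormalizes away in the ratio). Raw values can
#' leave `[0, 1]` when `f_G` and `f_D` are noisy; they are clamped and
#' flagged.
#'
#' @param f_G Observed admixed-cohort allele frequencies (vectorized).
#' @param f_D Reference donor-population allele frequencies.
#' @param bins Data frame from [discretize_distribution()] (columns `alpha`,
#'   `prob`).
#' @return Data frame of class `corrected_freqs` with columns `f_G`, `f_D`,
#'   `f_corrected`, `clamped`.
#' @export
corrected_allele_frequency <- function(f_G, f_D, bins) {
  stopifnot(all(f_G >= 0 & f_G <= 1, na.rm = TRUE),
            all(f_D >= 0 & f_D <= 1, na.rm = TRUE),
            all(c("alpha", "prob") %in% names(bins)))
  keep <- bins$alpha < 1 - 1e-9
  if (!any(keep))
    stop("all bins have alpha = 1: corrected frequency is undefined")
  a <- bins$alpha[keep]; w <- bins$prob[keep]
  den <- sum(w * (1 - a))
  raw <- (sum(w) * f_G - sum(w * a) * f_D) / den
  clamped <- raw < 0 | raw > 1
  out <- data.frame(f_G = f_G, f_D = f_D,
                    f_corrected = pmin(pmax(raw, 0), 1),
                    clamped = clamped)
  class(out) <- c("corrected_freqs", "data.frame")
  out
}
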