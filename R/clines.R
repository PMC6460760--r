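# Genomic clines: per-locus multinomial regression of genotype (AA/Aa/aa)
# on the genome-wide hybrid index, tested against neutral admixture
# expectations by parametric bootstrap.

# Negative log-likelihood and gradient of the 3-category multinomial logistic
# model with linear predictors in h:
#   log P(Aa)/P(AA) = b0 + b1 h ;  log P(aa)/P(AA) = c0 + c1 h
# theta = (b0, b1, c0, c1); g in {0,1,2}; all vectors non-missing.
.mn_nll <- function(theta, g, h) {
  e1 <- theta[1] + theta[2] * h
  e2 <- theta[3] + theta[4] * h
  m <- pmax(e1, pmax(e2, 0))
  lse <- m + log(exp(-m) + exp(e1 - m) + exp(e2 - m))
  -sum(ifelse(g == 1L, e1, ifelse(g == 2L, e2, 0)) - lse)
}

.mn_grad <- function(theta, g, h) {
  e1 <- theta[1] + theta[2] * h
  e2 <- theta[3] + theta[4] * h
  m <- pmax(e1, pmax(e2, 0))
  d <- exp(-m) + exp(e1 - m) + exp(e2 - m)
  p1 <- exp(e1 - m) / d
  p2 <- exp(e2 - m) / d
  r1 <- (g == 1L) - p1
  r2 <- (g == 2L) - p2
  -c(sum(r1), sum(r1 * h), sum(r2), sum(r2 * h))
}

#' Log-likelihood of a locus under neutral admixture
#'
#' Under neutral introgression an individual with hybrid index h draws its
#' two alleles at a locus independently with B-allele probability
#' q = h p_B + (1 - h) p_A, so its genotype is Binomial(2, q). Genotype
#' probabilities of exactly 0 at an observed genotype are floored at 1e-12
#' (with a warning) so the sum stays finite.
#'
#' @param g Polarized calls at one locus (0/1/2, NA skipped).
#' @param h Per-sample hybrid indices, same length as \code{g}.
#' @param pa,pb Scalar B-polarized parental allele frequencies of the locus.
#' @return Scalar log-likelihood.
#' @export
neutral_loglik <- function(g, h, pa, pb) {
  keep <- !is.na(g)
  g <- as.integer(g[keep]); h <- h[keep]
  q <- h * pb + (1 - h) * pa
  pr <- stats::dbinom(g, 2, q)
  if (any(pr == 0)) {
    warning(sum(pr == 0), " genotype(s) impossible under the neutral model;",
            " probability floored at 1e-12")
    pr <- pmax(pr, 1e-12)
  }
  sum(log(pr))
}

#' Fit a per-locus genomic cline by multinomial regression
#'
#' Three-category multinomial logistic model of genotype (AA, Aa, aa)
#' against the genome-wide hybrid index, with linear predictors in h,
#' fitted by maximum likelihood (L-BFGS-B with analytic gradient,
#' coefficients bounded at |coef| <= 30 to tame complete separation; a fit
#' on the bound is flagged \code{clipped}). Restarts from a second starting
#' point when the first does not converge.
#'
#' @param g Polarized calls at one locus (NA allowed, dropped).
#' @param h Per-sample hybrid indices.
#' @param max_coef Coefficient bound.
#' @return List of class \code{cline_fit}: \code{coef} (b0, b1, c0, c1),
#'   \code{loglik}, \code{converged}, \code{clipped}, \code{n}.
#' @export
fit_multinomial_cline <- function(g, h, max_coef = 30) {
  keep <- !is.na(g)
  g <- as.integer(g[keep]); h <- h[keep]
  if (length(g) < 3) stop("need at least 3 non-missing calls to fit a cline")
  if (stats::sd(h) == 0) stop("hybrid index must vary across samples")

  nll <- function(theta) .mn_nll(theta, g, h)
  grad <- function(theta) .mn_grad(theta, g, h)
  starts <- list(rep(0, 4), c(0, 2, -2, 4))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, nll, grad, method = "L-BFGS-B",
                      lower = -max_coef, upper = max_coef,
                      control = list(factr = 1e4, maxit = 200))
    if (is.null(best) || o$value < best$value) best <- o
    if (best$convergence == 0) break
  }
  structure(list(coef = best$par, loglik = -best$value,
                 converged = best$convergence == 0,
                 clipped = any(abs(best$par) >= max_coef - 1e-6),
                 n = length(g)),
            class = "cline_fit")
}

# Fitted P(AA), P(Aa), P(aa) at hybrid indices h.
.mn_probs <- function(coef, h) {
  e1 <- exp(coef[1] + coef[2] * h)
  e2 <- exp(coef[3] + coef[4] * h)
  d <- 1 + e1 + e2
  cbind(AA = 1 / d, Aa = e1 / d, aa = e2 / d)
}

#' Test one locus for departure from neutral introgression
#'
#' The observed likelihood-ratio statistic LR = 2 (lnL_fit - lnL_neutral)
#' compares the fitted multinomial cline with the neutral Binomial(2, q)
#' model (negative values, which can arise because the two families are not
#' nested, are clamped to 0). Its null distribution is obtained by
#' parametric bootstrap: genotypes are simulated from the neutral model at
#' each sample's hybrid index, the cline refitted, and LR recomputed;
#' p_raw = (1 + #\{LR_sim >= LR_obs\}) / (n_sims + 1), so p is never 0.
#' The same simulations yield the genotype deviation summary: each genotype
#' class is marked "+" when the observed count exceeds the 97.5th percentile
#' of its simulated neutral distribution, "-" below the 2.5th, blank
#' otherwise — e.g. \code{"AA Aa- aa+"} reads as a heterozygote deficit with
#' homozygote-aa excess.
#'
#' @param g Polarized calls at one locus for the admixed individuals.
#' @param h Their hybrid indices.
#' @param pa,pb Scalar B-polarized parental allele frequencies of the locus.
#' @param n_sims Number of parametric-bootstrap replicates (>= 100).
#' @param seed Mandatory RNG seed.
#' @param max_coef Passed to \code{\link{fit_multinomial_cline}}.
#' @return List of class \code{cline_test}: \code{fit}, \code{lnl_neutral},
#'   \code{lr}, \code{p_raw}, \code{deviation}, \code{counts} (observed
#'   genotype counts), \code{n_sims}, \code{low_confidence} (TRUE when over
#'   5\% of bootstrap refits failed to converge).
#' @export
cline_test <- function(g, h, pa, pb, n_sims = 1000, seed, max_coef = 30) {
  if (missing(seed)) stop("seed is mandatory for cline_test")
  stopifnot(n_sims >= 100)
  keep <- !is.na(g)
  g <- as.integer(g[keep]); h <- h[keep]

  fit <- fit_multinomial_cline(g, h, max_coef = max_coef)
  lnl0 <- neutral_loglik(g, h, pa, pb)
  lr_obs <- max(0, 2 * (fit$loglik - lnl0))

  q <- pmin(pmax(h * pb + (1 - h) * pa, 0), 1)
  n <- length(g)
  obs_counts <- tabulate(g + 1L, nbins = 3L)

  set.seed(seed)
  lr_sim <- numeric(n_sims)
  count_sim <- matrix(0L, n_sims, 3)
  n_fail <- 0L
  for (s in seq_len(n_sims)) {
    gs <- stats::rbinom(n, 2, q)
    fs <- fit_multinomial_cline(gs, h, max_coef = max_coef)
    if (!fs$converged) n_fail <- n_fail + 1L
    lr_sim[s] <- max(0, 2 * (fs$loglik - neutral_loglik(gs, h, pa, pb)))
    count_sim[s, ] <- tabulate(gs + 1L, nbins = 3L)
  }
  p_raw <- (1 + sum(lr_sim >= lr_obs)) / (n_sims + 1)

  marks <- vapply(1:3, function(k) {
    qs <- stats::quantile(count_sim[, k], c(0.025, 0.975), names = FALSE)
    if (obs_counts[k] > qs[2]) "+"
    else if (obs_counts[k] < qs[1]) "-"
    else ""
  }, character(1))
  deviation <- paste0(c("AA", "Aa", "aa"), marks, collapse = " ")

  low_conf <- n_fail > 0.05 * n_sims
  if (low_conf)
    warning(n_fail, " of ", n_sims, " bootstrap refits did not converge;",
            " p-value is low-confidence")
  structure(list(fit = fit, lnl_neutral = lnl0, lr = lr_obs, p_raw = p_raw,
                 deviation = deviation, counts = obs_counts,
                 n_sims = n_sims, low_confidence = low_conf),
            class = "cline_test")
}

#' Benjamini-Yekutieli adjusted significance level (Narum formulation)
#'
#' For a family of k tests the nominal level alpha is divided by the k-th
#' harmonic number: alpha / sum(1/i, i = 1..k). Valid under arbitrary
#' dependence among tests.
#'
#' @param k Number of tests in the family (>= 1).
#' @param alpha Nominal significance level.
#' @return Adjusted alpha.
#' @export
by_alpha <- function(k, alpha = 0.05) {
  if (k < 1) stop("k must be >= 1")
  alpha / sum(1 / seq_len(k))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH adjustment; \code{NA} inputs are excluded from the
#' ranking (the effective family size is the number of non-missing
#' p-values) and propagated as \code{NA} in place.
#'
#' @param p Vector of p-values in [0, 1] (NA allowed).
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Run genomic-cline tests over a diagnostic-locus set
#'
#' Fits and bootstrap-tests every locus of a polarized matrix on the
#' admixed individuals (parental groups contribute only through the allele
#' frequencies already baked into the matrix), then applies both
#' significance conventions side by side: the B-Y adjusted alpha for the
#' family of tested loci, and BH-adjusted p-values.
#'
#' @param pol A \code{\link{polarize}}d matrix.
#' @param ancestry Output of \code{\link{estimate_ancestry}} covering the
#'   samples to test.
#' @param sample_ids Samples to include (default: the ADMIXED_CANDIDATE
#'   group of \code{pol}, or all samples when no groups are assigned).
#' @param diff Optional \code{\link{allele_freq_differential}} table used to
#'   report each locus's delta.
#' @param n_sims Bootstrap replicates per locus.
#' @param seed Mandatory base seed; locus l uses \code{seed + l}.
#' @param alpha Nominal significance level.
#' @return Data frame of class \code{cline_table}: \code{locus_id},
#'   \code{delta}, \code{lr}, \code{p_raw}, \code{alpha_by}, \code{p_bh},
#'   \code{significant_by}, \code{significant_bh}, \code{deviation},
#'   \code{converged}, \code{low_confidence}.
#' @export
cline_scan <- function(pol, ancestry, sample_ids = NULL, diff = NULL,
                       n_sims = 1000, seed, alpha = 0.05) {
  if (missing(seed)) stop("seed is mandatory for cline_scan")
  stopifnot(inherits(pol, "polarized_matrix"))
  if (is.null(sample_ids)) {
    sample_ids <- group_samples(pol, "ADMIXED_CANDIDATE")
    if (!length(sample_ids)) sample_ids <- rownames(pol$calls)
  }
  h <- ancestry$h[match(sample_ids, ancestry$sample_id)]
  if (anyNA(h)) stop("hybrid index undefined for some samples in cline_scan")

  loci <- pol$bfreqs$locus_id
  rows <- vector("list", length(loci))
  for (l in seq_along(loci)) {
    g <- pol$calls[sample_ids, loci[l]]
    res <- tryCatch(
      suppressWarnings(
        cline_test(g, h, pol$bfreqs$p_a[l], pol$bfreqs$p_b[l],
                   n_sims = n_sims, seed = seed + l)),
      error = function(e) NULL)
    rows[[l]] <- if (is.null(res)) {
      data.frame(locus_id = loci[l], lr = NA_real_, p_raw = NA_real_,
                 deviation = NA_character_, converged = FALSE,
                 low_confidence = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(locus_id = loci[l], lr = res$lr, p_raw = res$p_raw,
                 deviation = res$deviation, converged = res$fit$converged,
                 low_confidence = res$low_confidence,
                 stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)

  k <- sum(!is.na(tab$p_raw))
  a_by <- by_alpha(max(k, 1), alpha)
  tab$alpha_by <- a_by
  tab$p_bh <- bh_adjust(tab$p_raw)
  tab$significant_by <- !is.na(tab$p_raw) & tab$p_raw < a_by
  tab$significant_bh <- !is.na(tab$p_bh) & tab$p_bh < alpha
  tab$delta <- if (!is.null(diff))
    diff$delta[match(tab$locus_id, diff$locus_id)] else NA_real_
  tab <- tab[, c("locus_id", "delta", "lr", "p_raw", "alpha_by", "p_bh",
                 "significant_by", "significant_bh", "deviation",
                 "converged", "low_confidence")]
  class(tab) <- c("cline_table", "data.frame")
  tab
}
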