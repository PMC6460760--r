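#' Polarize genotypes to counts of the B-associated allele
#'
#' At each locus of the diagnostic set, the B-associated allele is the allele
#' with the higher frequency in the PARENTAL_B group. Calls are recoded so
#' that 0 = homozygous for A-associated alleles (genotype AA), 1 =
#' interspecific heterozygote (Aa) and 2 = homozygous for B-associated
#' alleles (aa). The returned object also carries the B-polarized parental
#' allele frequencies used by the likelihood models downstream.
#'
#' @param gm A \code{genotype_matrix}.
#' @param freqs Parental allele frequencies from
#'   \code{\link{estimate_parental_freqs}} (alt-allele scale).
#' @param locus_set Character vector of locus ids to keep (typically a
#'   delta-selected diagnostic set).
#' @return An object of class \code{polarized_matrix}: a
#'   \code{genotype_matrix} restricted to \code{locus_set} whose calls count
#'   the B-associated allele, with element \code{bfreqs} (columns
#'   \code{locus_id}, \code{p_a}, \code{p_b}, \code{flipped}) holding the
#'   frequency of the B-associated allele in each parental group.
#' @export
polarize <- function(gm, freqs, locus_set) {
  stopifnot(inherits(gm, "genotype_matrix"))
  idx <- match(locus_set, freqs$locus_id)
  if (anyNA(idx)) stop("locus_set contains loci absent from freqs")
  pa <- freqs$p_a[idx]
  pb <- freqs$p_b[idx]
  if (anyNA(pa) || anyNA(pb))
    stop("cannot polarize loci with undefined parental frequencies")
  if (any(pa == pb))
    stop("cannot polarize loci with p_a == p_b: ",
         paste(locus_set[pa == pb], collapse = ", "))

  out <- subset_genotypes(gm, loci = locus_set)
  # B-associated allele: the allele commoner in PARENTAL_B. If that is the
  # ref allele, flip codes 0 <-> 2 and mirror the frequencies.
  flip <- pb < pa
  calls <- out$calls
  calls[, flip] <- 2L - calls[, flip, drop = FALSE]
  out$calls <- calls
  bf <- data.frame(locus_id = locus_set,
                   p_a = ifelse(flip, 1 - pa, pa),
                   p_b = ifelse(flip, 1 - pb, pb),
                   flipped = flip, stringsAsFactors = FALSE)
  out$bfreqs <- bf
  class(out) <- c("polarized_matrix", class(out))
  out
}

# Per-individual log-likelihood of hybrid index h given polarized calls g
# (0/1/2 counts of the B allele) and B-polarized parental frequencies.
# q_l = h p_B,l + (1-h) p_A,l; genotype ~ Binomial(2, q_l).
.h_loglik <- function(h, g, pa, pb) {
  q <- h * pb + (1 - h) * pa
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  sum(g * log(q) + (2 - g) * log1p(-q)) + sum(log(ifelse(g == 1L, 2, 1)))
}

#' Maximum-likelihood hybrid index of one individual
#'
#' The hybrid index h is the proportion of the genome derived from the
#' B-type parental population. Each locus contributes a Binomial(2, q)
#' genotype likelihood with q = h p_B + (1 - h) p_A, where p_A and p_B are
#' the B-polarized parental allele frequencies; loci are treated as
#' independent and parental frequencies as known. When every usable locus
#' carries a fixed difference (p_A = 0, p_B = 1) the MLE has the closed form
#' (count of B alleles) / (2 x loci) and is returned exactly; otherwise the
#' likelihood is maximized numerically on [0, 1] to absolute tolerance 1e-6,
#' from three starting points (0.1, 0.5, 0.9) as a guard against numerical
#' flatness. A 2-log-likelihood-unit support interval is returned alongside.
#'
#' @param g Integer vector of polarized calls (0/1/2, NA allowed).
#' @param pa,pb B-polarized parental allele frequencies, same length as
#'   \code{g}.
#' @return List with \code{h}, \code{lo}, \code{hi} (support interval),
#'   \code{n_loci} (non-missing loci used) and \code{loglik}; \code{h} is
#'   \code{NA} when every call is missing.
#' @export
ml_hybrid_index <- function(g, pa, pb) {
  keep <- !is.na(g)
  g <- as.integer(g[keep]); pa <- pa[keep]; pb <- pb[keep]
  n <- length(g)
  if (n == 0)
    return(list(h = NA_real_, lo = NA_real_, hi = NA_real_,
                n_loci = 0L, loglik = NA_real_))

  if (all(pa == 0 & pb == 1)) {
    h <- sum(g) / (2 * n)
  } else {
    fits <- vapply(c(0.1, 0.5, 0.9), function(h0) {
      o <- stats::optim(h0, function(h) -.h_loglik(h, g, pa, pb),
                        method = "L-BFGS-B", lower = 0, upper = 1,
                        control = list(factr = 10))
      c(o$par, -o$value)
    }, numeric(2))
    # boundary candidates: optim can stall just inside the box
    cand <- c(fits[1, ], 0, 1)
    ll <- c(fits[2, ], .h_loglik(0, g, pa, pb), .h_loglik(1, g, pa, pb))
    h <- cand[which.max(ll)]
  }
  llmax <- .h_loglik(h, g, pa, pb)

  drop2 <- function(x) .h_loglik(x, g, pa, pb) - (llmax - 2)
  lo <- if (drop2(0) >= 0) 0 else
    stats::uniroot(drop2, c(0, h), tol = 1e-8)$root
  hi <- if (drop2(1) >= 0) 1 else
    stats::uniroot(drop2, c(h, 1), tol = 1e-8)$root
  list(h = h, lo = lo, hi = hi, n_loci = n, loglik = llmax)
}

#' Interspecific heterozygosity of one individual
#'
#' The proportion of non-missing diagnostic loci at which the individual
#' carries one A-associated and one B-associated allele (polarized call 1).
#' Near 1 for F1 hybrids at fixed loci; decays with backcrossing.
#'
#' @param g Integer vector of polarized calls (0/1/2, NA allowed).
#' @return Proportion in [0, 1], or \code{NA} if every call is missing.
#' @export
interspecific_heterozygosity <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) return(NA_real_)
  mean(g == 1L)
}

#' Hybrid classification thresholds
#'
#' The rule set partitions the (h, H) unit square: pure parentals sit at
#' h = 0 or 1 exactly; F1-like individuals have interspecific heterozygosity
#' of at least 85%; the remainder split into backcross classes (h at or
#' beyond 0.25 / 0.75, tie resolving to the backcross) and multi-generation
#' hybrids in between.
#'
#' @param f1_h_lo,f1_h_hi Hybrid-index window for the F1 class.
#' @param f1_het_min Minimum interspecific heterozygosity for F1.
#' @param backcross_a_h_max,backcross_b_h_min Hybrid-index bounds for the
#'   two backcross classes.
#' @param het_max Heterozygosity ceiling for non-F1 hybrid classes.
#' @return A list of class \code{class_thresholds}.
#' @export
class_thresholds <- function(f1_h_lo = 0.25, f1_h_hi = 0.75,
                             f1_het_min = 0.85,
                             backcross_a_h_max = 0.25,
                             backcross_b_h_min = 0.75,
                             het_max = 0.85) {
  structure(list(f1_h_lo = f1_h_lo, f1_h_hi = f1_h_hi,
                 f1_het_min = f1_het_min,
                 backcross_a_h_max = backcross_a_h_max,
                 backcross_b_h_min = backcross_b_h_min,
                 het_max = het_max),
            class = "class_thresholds")
}

#' Assign a hybrid class from hybrid index and heterozygosity
#'
#' Total function on the unit square: every (h, H) maps to exactly one of
#' PURE_A, BACKCROSS_A, MULTIGEN, F1, BACKCROSS_B, PURE_B. High-H
#' individuals outside the F1 hybrid-index window are still reported as F1
#' (the heterozygosity criterion is primary) with \code{boundary = TRUE}.
#'
#' @param h Hybrid index in [0, 1].
#' @param het Interspecific heterozygosity in [0, 1].
#' @param thresholds A \code{\link{class_thresholds}} object.
#' @return Character class label with attribute \code{boundary}.
#' @export
classify_hybrid <- function(h, het, thresholds = class_thresholds()) {
  stopifnot(h >= 0, h <= 1, het >= 0, het <= 1)
  t <- thresholds
  boundary <- FALSE
  cls <- if (h == 0) "PURE_A"
  else if (h == 1) "PURE_B"
  else if (het >= t$f1_het_min) {
    boundary <- h < t$f1_h_lo || h > t$f1_h_hi
    "F1"
  }
  else if (h <= t$backcross_a_h_max) "BACKCROSS_A"
  else if (h >= t$backcross_b_h_min) "BACKCROSS_B"
  else "MULTIGEN"
  structure(cls, boundary = boundary)
}

#' Estimate ancestry for every individual in a polarized matrix
#'
#' Convenience wrapper running \code{\link{ml_hybrid_index}},
#' \code{\link{interspecific_heterozygosity}} and
#' \code{\link{classify_hybrid}} over rows.
#'
#' @param pol A \code{\link{polarize}}d matrix.
#' @param sample_ids Samples to estimate (default: all rows).
#' @param thresholds A \code{\link{class_thresholds}} object.
#' @return Data frame: \code{sample_id}, \code{h}, \code{h_support_lo},
#'   \code{h_support_hi}, \code{het}, \code{n_loci_used},
#'   \code{hybrid_class}, \code{boundary}.
#' @export
estimate_ancestry <- function(pol, sample_ids = NULL,
                              thresholds = class_thresholds()) {
  stopifnot(inherits(pol, "polarized_matrix"))
  if (is.null(sample_ids)) sample_ids <- rownames(pol$calls)
  pa <- pol$bfreqs$p_a
  pb <- pol$bfreqs$p_b
  rows <- lapply(sample_ids, function(sid) {
    g <- pol$calls[sid, ]
    fit <- ml_hybrid_index(g, pa, pb)
    het <- interspecific_heterozygosity(g)
    if (is.na(fit$h)) {
      cls <- NA_character_; bnd <- NA
    } else {
      cl <- classify_hybrid(fit$h, het, thresholds)
      cls <- as.character(cl); bnd <- attr(cl, "boundary")
    }
    data.frame(sample_id = sid, h = fit$h, h_support_lo = fit$lo,
               h_support_hi = fit$hi, het = het, n_loci_used = fit$n_loci,
               hybrid_class = cls, boundary = bnd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Triangle plot of hybrid index against interspecific heterozygosity
#'
#' Classic hybrid-zone diagnostic: F1s sit at the apex (h = 0.5, H = 1),
#' parentals at the base corners, backcrosses along the sides. The dashed
#' lines mark the admissible region H <= 2 min(h, 1 - h) expected at fixed
#' loci.
#'
#' @param ancestry Output of \code{\link{estimate_ancestry}}.
#' @param ... Passed to \code{plot}.
#' @return \code{ancestry}, invisibly.
#' @export
plot_triangle <- function(ancestry, ...) {
  cls <- factor(ancestry$hybrid_class,
                levels = c("PURE_A", "BACKCROSS_A", "MULTIGEN",
                           "F1", "BACKCROSS_B", "PURE_B"))
  plot(ancestry$h, ancestry$het, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "hybrid index (h)", ylab = "interspecific heterozygosity (H)",
       pch = 19, col = as.integer(cls), ...)
  graphics::segments(0, 0, 0.5, 1, lty = 2)
  graphics::segments(0.5, 1, 1, 0, lty = 2)
  graphics::legend("topright", legend = levels(cls), col = seq_len(6),
                   pch = 19, cex = 0.7, bty = "n")
  invisible(ancestry)
}
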