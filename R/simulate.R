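# Synthetic hybrid-zone generator. Emulates the data structure the analysis
# assumes -- two parental populations with a mixture of fixed and strongly
# differentiated loci among mostly weakly differentiated ones, admixed
# individuals of known pedigree, missing genotypes, plumage scores monotone
# in ancestry, and a latitudinal replacement zone -- with ground truth
# recorded for every downstream stage. Loci are independent (no linkage, no
# mutation), matching the assumptions of every downstream model.

#' Simulation configuration
#'
#' @param n_loci Total loci.
#' @param frac_fixed Fraction of loci fixed between the parental
#'   populations (true delta = 1).
#' @param frac_strong Fraction of loci strongly differentiated (true delta
#'   drawn from [0.8, 0.98)); default 0.08, capped at \code{1 - frac_fixed}.
#' @param diff_beta_params Beta shape pair for the allele frequencies of
#'   the remaining, weakly differentiated loci (drawn i.i.d. per side).
#'   The default Beta(0.5, 0.5) gives the U-shaped frequency spectrum
#'   typical of SNP panels, with most loci near fixation on both sides.
#' @param n_parental_A,n_parental_B Parental reference sample sizes.
#' @param class_counts Named integer vector of admixed-group pedigree
#'   classes: \code{PURE_A}, \code{PURE_B}, \code{F1}, \code{F2},
#'   \code{BC1_A}, \code{BC1_B}, \code{BC2_A}, \code{BC2_B}, or
#'   \code{MULTIGEN_<k>} for k successive hybrid x hybrid generations.
#' @param missing_rate Per-call missing probability, in [0, 0.5].
#' @param distorted_loci Named numeric vector: names are locus indices,
#'   values transmission biases b in [-0.5, 0.5] (the B-origin allele of a
#'   heterozygous parent is transmitted with probability 1/2 + b).
#' @param plumage_noise_sd Gaussian noise sd on the latent trait value.
#' @param n_missing_rump Individuals whose rump score is set missing.
#' @param lat_range Latitude range (south, north) in decimal degrees;
#'   A-type individuals sit at the northern end.
#' @param lon_range Longitude range; intermediates are placed in the middle
#'   third (the simulated contact zone).
#' @param seed Mandatory RNG seed.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_loci = 600, frac_fixed = 0.04, frac_strong = NULL,
                       diff_beta_params = c(0.5, 0.5),
                       n_parental_A = 40, n_parental_B = 21,
                       class_counts = c(PURE_A = 2, PURE_B = 2, F1 = 3,
                                        F2 = 3, BC1_A = 3, BC1_B = 3),
                       missing_rate = 0.05, distorted_loci = NULL,
                       plumage_noise_sd = 0.1, n_missing_rump = 0,
                       lat_range = c(-31, -26), lon_range = c(149.5, 152.5),
                       seed) {
  if (missing(seed)) stop("seed is mandatory in sim_config")
  if (is.null(frac_strong)) frac_strong <- min(0.08, 1 - frac_fixed)
  stopifnot(frac_fixed >= 0, frac_fixed <= 1, frac_strong >= 0,
            frac_fixed + frac_strong <= 1,
            missing_rate >= 0, missing_rate <= 0.5,
            n_loci >= 1, length(class_counts) >= 1)
  if (!is.null(distorted_loci))
    stopifnot(all(abs(distorted_loci) <= 0.5), !is.null(names(distorted_loci)))
  structure(list(n_loci = n_loci, frac_fixed = frac_fixed,
                 frac_strong = frac_strong,
                 diff_beta_params = diff_beta_params,
                 n_parental_A = n_parental_A, n_parental_B = n_parental_B,
                 class_counts = class_counts, missing_rate = missing_rate,
                 distorted_loci = distorted_loci,
                 plumage_noise_sd = plumage_noise_sd,
                 n_missing_rump = n_missing_rump,
                 lat_range = lat_range, lon_range = lon_range, seed = seed),
            class = "sim_config")
}

#' Simulate true parental allele frequencies
#'
#' Fixed loci get (p_A, p_B) = (0, 1) on the alt-allele scale; strongly
#' differentiated loci get a true delta drawn uniformly from [0.8, 0.98)
#' with random side assignment; the remainder draw both frequencies i.i.d.
#' from the configured Beta, so they are mostly weakly differentiated.
#'
#' @param config A \code{\link{sim_config}} (its seed is used).
#' @return Data frame: \code{locus_id}, \code{p_a}, \code{p_b},
#'   \code{delta_true}, \code{locus_class} (fixed/strong/weak).
#' @export
simulate_parental_freqs <- function(config) {
  set.seed(config$seed)
  .sim_freqs(config)
}

.sim_freqs <- function(config) {
  n <- config$n_loci
  n_fixed <- round(config$frac_fixed * n)
  n_strong <- round(config$frac_strong * n)
  n_weak <- n - n_fixed - n_strong
  cls <- c(rep("fixed", n_fixed), rep("strong", n_strong),
           rep("weak", n_weak))
  pa <- pb <- numeric(n)
  pa[cls == "fixed"] <- 0
  pb[cls == "fixed"] <- 1
  if (n_strong > 0) {
    d <- stats::runif(n_strong, 0.8, 0.98)
    lo <- stats::runif(n_strong, 0, 1 - d)
    swap <- stats::runif(n_strong) < 0.5
    pa[cls == "strong"] <- ifelse(swap, lo + d, lo)
    pb[cls == "strong"] <- ifelse(swap, lo, lo + d)
  }
  if (n_weak > 0) {
    sh <- config$diff_beta_params
    wa <- stats::rbeta(n_weak, sh[1], sh[2])
    wb <- stats::rbeta(n_weak, sh[1], sh[2])
    # "weak" means delta < 0.8 by construction: redraw the occasional pair
    # the U-shaped spectrum throws beyond it
    for (it in 1:100) {
      bad <- abs(wa - wb) >= 0.8
      if (!any(bad)) break
      wa[bad] <- stats::rbeta(sum(bad), sh[1], sh[2])
      wb[bad] <- stats::rbeta(sum(bad), sh[1], sh[2])
    }
    pa[cls == "weak"] <- wa
    pb[cls == "weak"] <- wb
  }
  data.frame(locus_id = sprintf("L%04d", seq_len(n)), p_a = pa, p_b = pb,
             delta_true = abs(pa - pb), locus_class = cls,
             stringsAsFactors = FALSE)
}

# An individual is a pair of haplotypes: alleles (alt counts, 0/1) and
# ancestry origins (TRUE = B-origin), each a 2 x n_loci matrix.
.new_parental <- function(freqs, side) {
  p <- if (side == "A") freqs$p_a else freqs$p_b
  n <- length(p)
  list(a = matrix(stats::rbinom(2 * n, 1, rep(p, each = 2)), nrow = 2),
       o = matrix(side == "B", nrow = 2, ncol = n))
}

.gamete <- function(ind, bias) {
  # One meiosis: haplotype chosen per locus with probability 1/2; at
  # origin-heterozygous loci the B-origin haplotype wins with prob 1/2 + b.
  n <- ncol(ind$a)
  idx <- integer(n)
  het <- ind$o[1, ] != ind$o[2, ]
  u <- stats::runif(n)
  idx[!het] <- ifelse(u[!het] < 0.5, 1L, 2L)
  b_row <- ifelse(ind$o[1, ], 1L, 2L)  # which haplotype is B-origin
  take_b <- u < 0.5 + bias
  idx[het] <- ifelse(take_b[het], b_row[het], 3L - b_row[het])
  list(a = ind$a[cbind(idx, seq_len(n))], o = ind$o[cbind(idx, seq_len(n))])
}

#' Cross two individuals
#'
#' Each gamete carries one of the parent's two alleles per locus with
#' probability 1/2, independently across loci (free recombination, no
#' linkage). At a distorted locus, a parent heterozygous for ancestry
#' origin transmits its B-origin allele with probability 1/2 + b.
#'
#' @param parent1,parent2 Individuals as built by the simulator (lists with
#'   haplotype allele and origin matrices).
#' @param bias Numeric vector of per-locus transmission biases (0 =
#'   Mendelian).
#' @param seed Optional seed for a reproducible single cross.
#' @return An offspring individual.
#' @export
breed <- function(parent1, parent2, bias = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(parent1$a)
  stopifnot(ncol(parent2$a) == n)
  bias <- rep_len(bias, n)
  g1 <- .gamete(parent1, bias)
  g2 <- .gamete(parent2, bias)
  list(a = rbind(g1$a, g2$a), o = rbind(g1$o, g2$o))
}

.bias_vector <- function(config) {
  b <- rep(0, config$n_loci)
  if (!is.null(config$distorted_loci))
    b[as.integer(names(config$distorted_loci))] <- config$distorted_loci
  b
}

# Build one individual of a pedigree class by its recipe.
.make_class <- function(cls, freqs, bias) {
  pa <- function() .new_parental(freqs, "A")
  pb <- function() .new_parental(freqs, "B")
  f1 <- function() breed(pa(), pb(), bias)
  multigen <- function(k) {
    gen <- function(i) {
      if (i <= 1) f1() else breed(gen(i - 1), gen(i - 1), bias)
    }
    gen(k)
  }
  if (grepl("^MULTIGEN_\\d+$", cls))
    return(multigen(as.integer(sub("MULTIGEN_", "", cls))))
  switch(cls,
         PURE_A = pa(), PURE_B = pb(), F1 = f1(),
         F2 = breed(f1(), f1(), bias),
         BC1_A = breed(f1(), pa(), bias),
         BC1_B = breed(f1(), pb(), bias),
         BC2_A = breed(breed(f1(), pa(), bias), pa(), bias),
         BC2_B = breed(breed(f1(), pb(), bias), pb(), bias),
         stop("unknown pedigree class: ", cls))
}

#' Sample parental genotypes under Hardy-Weinberg
#'
#' @param freqs Output of \code{\link{simulate_parental_freqs}}.
#' @param n Number of individuals.
#' @param side \code{"A"} or \code{"B"}.
#' @param missing_rate Per-call missing probability.
#' @param seed Optional seed.
#' @return Integer matrix n x loci of calls (0/1/2, NA for missing).
#' @export
sample_parental_genotypes <- function(freqs, n, side = c("A", "B"),
                                      missing_rate = 0, seed = NULL) {
  side <- match.arg(side)
  if (!is.null(seed)) set.seed(seed)
  p <- if (side == "A") freqs$p_a else freqs$p_b
  calls <- matrix(stats::rbinom(n * length(p), 2, rep(p, each = n)),
                  nrow = n, dimnames = list(NULL, freqs$locus_id))
  if (missing_rate > 0)
    calls[matrix(stats::runif(length(calls)) < missing_rate,
                 nrow = n)] <- NA_integer_
  calls
}

#' Simulate the admixed-group individuals of requested pedigree classes
#'
#' @param config A \code{\link{sim_config}} (its seed is used).
#' @param freqs Optional precomputed true frequencies (so the call can be
#'   embedded in a larger deterministic simulation); default draws them.
#' @return List: \code{calls} (individuals x loci, with missing data),
#'   \code{truth} (data frame: \code{sample_id}, \code{class},
#'   \code{ancestry_true} = realized B-origin fraction,
#'   \code{het_true} = realized origin-heterozygous fraction).
#' @export
simulate_class_sample <- function(config, freqs = NULL) {
  set.seed(config$seed)
  if (is.null(freqs)) freqs <- .sim_freqs(config)
  .sim_classes(config, freqs)
}

.sim_classes <- function(config, freqs) {
  bias <- .bias_vector(config)
  counts <- config$class_counts
  total <- sum(counts)
  calls <- matrix(NA_integer_, total, config$n_loci,
                  dimnames = list(NULL, freqs$locus_id))
  truth <- data.frame(sample_id = character(total), class = character(total),
                      ancestry_true = numeric(total),
                      het_true = numeric(total), stringsAsFactors = FALSE)
  i <- 0
  for (cls in names(counts)) {
    for (k in seq_len(counts[[cls]])) {
      i <- i + 1
      ind <- .make_class(cls, freqs, bias)
      calls[i, ] <- ind$a[1, ] + ind$a[2, ]
      truth$sample_id[i] <- sprintf("HZ%03d", i)
      truth$class[i] <- cls
      truth$ancestry_true[i] <- mean(ind$o)
      truth$het_true[i] <- mean(ind$o[1, ] != ind$o[2, ])
    }
  }
  rownames(calls) <- truth$sample_id
  if (config$missing_rate > 0)
    calls[matrix(stats::runif(length(calls)) < config$missing_rate,
                 nrow = total)] <- NA_integer_
  list(calls = calls, truth = truth)
}

#' Simulate plumage scores monotone in ancestry
#'
#' Each trait's latent value is the individual's true ancestry fraction
#' plus Gaussian noise, clipped to [0, 1], scaled by the trait maximum and
#' rounded to an integer score. The cheek patch receives extra noise at low
#' ancestry (sd multiplied by 1 + 2 (1 - ancestry)), emulating the
#' polymorphism of that trait in the A-type parental population. With zero
#' noise the scores are an exact deterministic function of ancestry.
#'
#' @param truth Truth table with \code{sample_id} and \code{ancestry_true}.
#' @param config A \code{\link{sim_config}}.
#' @param seed Optional seed (default derives from the config seed).
#' @return Plumage record data frame (scores plus \code{ancestry_true}).
#' @export
simulate_plumage <- function(truth, config, seed = config$seed + 1) {
  set.seed(seed)
  .sim_plumage(truth, config)
}

.sim_plumage <- function(truth, config) {
  n <- nrow(truth)
  anc <- truth$ancestry_true
  sd0 <- config$plumage_noise_sd
  rec <- data.frame(sample_id = truth$sample_id, stringsAsFactors = FALSE)
  for (tr in names(.PLUMAGE_TRAITS)) {
    sd_tr <- if (tr == "cheek_patch") sd0 * (1 + 2 * (1 - anc)) else sd0
    latent <- anc + if (sd0 > 0) stats::rnorm(n, 0, sd_tr) else 0
    latent <- pmin(pmax(latent, 0), 1)
    rec[[tr]] <- as.integer(round(latent * .PLUMAGE_TRAITS[[tr]]))
  }
  if (config$n_missing_rump > 0) {
    drop <- sample.int(n, min(config$n_missing_rump, n))
    rec$rump[drop] <- NA_integer_
  }
  rec$ancestry_true <- anc
  rec
}

#' Simulate hybrid-zone geography
#'
#' Latitude is a monotone map from ancestry (A-type at the northern end of
#' \code{lat_range}) plus Gaussian noise; intermediate individuals
#' (ancestry in (0.2, 0.8)) get longitudes inside the middle third of
#' \code{lon_range} (the contact zone), others anywhere in the range.
#'
#' @param truth Truth table with \code{ancestry_true}.
#' @param config A \code{\link{sim_config}}.
#' @param lat_noise_sd Latitude noise, degrees.
#' @param seed Optional seed (default derives from the config seed).
#' @return Data frame: \code{sample_id}, \code{latitude}, \code{longitude}.
#' @export
simulate_zone_geography <- function(truth, config, lat_noise_sd = 0.2,
                                    seed = config$seed + 2) {
  set.seed(seed)
  .sim_geography(truth, config, lat_noise_sd)
}

.sim_geography <- function(truth, config, lat_noise_sd = 0.2) {
  anc <- truth$ancestry_true
  south <- config$lat_range[1]; north <- config$lat_range[2]
  lat <- north - anc * (north - south) +
    stats::rnorm(length(anc), 0, lat_noise_sd)
  lat <- pmin(pmax(lat, south), north)
  lon_lo <- config$lon_range[1]; lon_hi <- config$lon_range[2]
  third <- (lon_hi - lon_lo) / 3
  mid <- anc > 0.2 & anc < 0.8
  lon <- ifelse(mid,
                stats::runif(length(anc), lon_lo + third, lon_hi - third),
                stats::runif(length(anc), lon_lo, lon_hi))
  data.frame(sample_id = truth$sample_id, latitude = lat, longitude = lon,
             stringsAsFactors = FALSE)
}

#' Simulate a complete hybrid-zone dataset
#'
#' Deterministic in the config (seed included): true parental frequencies,
#' parental reference samples, admixed individuals of the requested
#' pedigree classes, plumage scores and coordinates, all with ground truth.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{hz_sim}: \code{gm} (a
#'   \code{genotype_matrix} with groups assigned), \code{truth} (all
#'   individuals; parental reference samples have ancestry 0 or 1),
#'   \code{plumage} (records with coordinates merged in), \code{freqs_true},
#'   \code{fixed_ids}, \code{strong_ids} (true delta >= 0.8, including
#'   fixed).
#' @export
simulate_hybridzone <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  freqs <- .sim_freqs(config)

  a_calls <- sample_parental_genotypes(freqs, config$n_parental_A, "A",
                                       config$missing_rate)
  b_calls <- sample_parental_genotypes(freqs, config$n_parental_B, "B",
                                       config$missing_rate)
  rownames(a_calls) <- sprintf("PA%03d", seq_len(config$n_parental_A))
  rownames(b_calls) <- sprintf("PB%03d", seq_len(config$n_parental_B))
  adm <- .sim_classes(config, freqs)

  calls <- rbind(a_calls, b_calls, adm$calls)
  samples <- data.frame(
    sample_id = rownames(calls),
    group = c(rep("PARENTAL_A", config$n_parental_A),
              rep("PARENTAL_B", config$n_parental_B),
              rep("ADMIXED_CANDIDATE", nrow(adm$calls))),
    stringsAsFactors = FALSE)

  truth <- rbind(
    data.frame(sample_id = rownames(a_calls), class = "PURE_A",
               ancestry_true = 0, het_true = 0, stringsAsFactors = FALSE),
    data.frame(sample_id = rownames(b_calls), class = "PURE_B",
               ancestry_true = 1, het_true = 0, stringsAsFactors = FALSE),
    adm$truth)
  truth$group <- samples$group

  plumage <- .sim_plumage(truth, config)
  geo <- .sim_geography(truth, config)
  plumage <- merge(plumage, geo, by = "sample_id", sort = FALSE)
  samples$latitude <- geo$latitude[match(samples$sample_id, geo$sample_id)]
  samples$longitude <- geo$longitude[match(samples$sample_id, geo$sample_id)]

  gm <- genotype_matrix(calls, samples = samples)
  structure(list(gm = gm, truth = truth, plumage = plumage,
                 freqs_true = freqs,
                 fixed_ids = freqs$locus_id[freqs$locus_class == "fixed"],
                 strong_ids = freqs$locus_id[freqs$delta_true >= 0.8],
                 config = config),
            class = "hz_sim")
}
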