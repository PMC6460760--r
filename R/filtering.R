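#' Filtering parameters for SNP loci
#'
#' Defaults mirror a standard RADseq genotype-export filter: per-call read
#' depth of at least 20, locus called in at least 80% of individuals, minor
#' allele frequency at least 0.05, and presence of the locus in all three
#' groups (both parental populations and the admixed candidates).
#'
#' @param min_depth Minimum per-call read depth; calls below it are masked to
#'   missing before the other filters run (only when depth data exist).
#' @param min_call_fraction Minimum fraction of individuals with a
#'   non-missing call, in (0, 1].
#' @param min_maf Minimum minor allele frequency over all non-missing calls
#'   (parental and admixed together), in [0, 0.5).
#' @param require_group_presence Require at least one non-missing call in
#'   each of the three groups.
#' @return A list of class \code{filter_params}.
#' @export
filter_params <- function(min_depth = 20, min_call_fraction = 0.80,
                          min_maf = 0.05, require_group_presence = TRUE) {
  stopifnot(min_call_fraction > 0, min_call_fraction <= 1,
            min_maf >= 0, min_maf < 0.5, min_depth >= 0)
  structure(list(min_depth = min_depth,
                 min_call_fraction = min_call_fraction,
                 min_maf = min_maf,
                 require_group_presence = require_group_presence),
            class = "filter_params")
}

#' Filter SNP loci by depth, call rate, MAF and group presence
#'
#' Filters are applied in a fixed order: depth masking, then call fraction,
#' then minor allele frequency, then group presence. Depth masking precedes
#' the call-rate filter because masked calls count as missing there. The
#' attached report gives per-filter removal counts in that order, so the
#' counts are interpretable as sequential removals.
#'
#' @param gm A \code{genotype_matrix}; groups must be assigned when
#'   \code{require_group_presence} is \code{TRUE}.
#' @param params A \code{\link{filter_params}} object.
#' @return The filtered \code{genotype_matrix} with a data-frame attribute
#'   \code{"filter_report"} (columns \code{filter}, \code{removed},
#'   \code{retained}).
#' @export
filter_loci <- function(gm, params = filter_params()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  depth <- gm$depth

  if (params$min_depth > 0) {
    if (is.null(depth)) {
      warning("depth filter requested but no depth data; skipping")
    } else {
      low <- !is.na(depth) & depth < params$min_depth
      calls[low] <- NA_integer_
      depth[low] <- 0L
    }
  }

  report <- data.frame(filter = character(0), removed = integer(0),
                       retained = integer(0), stringsAsFactors = FALSE)
  keep <- rep(TRUE, ncol(calls))
  note <- function(name, pass) {
    removed <- sum(keep & !pass)
    keep <<- keep & pass
    report <<- rbind(report, data.frame(filter = name, removed = removed,
                                        retained = sum(keep)))
  }

  call_frac <- colMeans(!is.na(calls))
  note("call_fraction", call_frac >= params$min_call_fraction)

  alt <- colSums(calls, na.rm = TRUE)
  tot <- 2 * colSums(!is.na(calls))
  p <- ifelse(tot > 0, alt / tot, NA_real_)
  maf <- pmin(p, 1 - p)
  note("maf", !is.na(maf) & maf >= params$min_maf)

  if (params$require_group_presence) {
    grp <- gm$samples$group
    if (all(is.na(grp)))
      stop("group presence filter requires assigned groups")
    present <- rep(TRUE, ncol(calls))
    for (g in .GROUPS) {
      rows <- which(!is.na(grp) & grp == g)
      present <- present & (colSums(!is.na(calls[rows, , drop = FALSE])) >= 1)
    }
    note("group_presence", present)
  }

  if (!any(keep)) stop("no loci survive filtering")
  out <- gm
  out$calls <- calls
  out$depth <- depth
  out <- subset_genotypes(out, loci = which(keep))
  attr(out, "filter_report") <- report
  out
}

#' Estimate parental allele frequencies per locus
#'
#' Frequencies of the alternate allele are computed separately in the
#' PARENTAL_A and PARENTAL_B groups as (sum of alt-allele counts) /
#' (2 x non-missing samples); admixed candidates never contribute. A group
#' with zero non-missing calls at a locus yields \code{NA} there and the
#' locus is excluded from downstream delta ranking.
#'
#' @param gm A \code{genotype_matrix} with groups assigned.
#' @return A data frame of class \code{allele_freq_table} with columns
#'   \code{locus_id}, \code{p_a}, \code{p_b}, \code{n_a}, \code{n_b}
#'   (n = allele copies used, i.e. 2 x individuals).
#' @export
estimate_parental_freqs <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  a_ids <- group_samples(gm, "PARENTAL_A")
  b_ids <- group_samples(gm, "PARENTAL_B")
  if (!length(a_ids) || !length(b_ids))
    stop("need at least one sample in each parental group")
  one <- function(ids) {
    sub <- gm$calls[ids, , drop = FALSE]
    n <- 2L * colSums(!is.na(sub))
    p <- ifelse(n > 0, colSums(sub, na.rm = TRUE) / n, NA_real_)
    list(p = p, n = n)
  }
  fa <- one(a_ids)
  fb <- one(b_ids)
  structure(data.frame(locus_id = colnames(gm$calls),
                       p_a = unname(fa$p), p_b = unname(fb$p),
                       n_a = unname(fa$n), n_b = unname(fb$n),
                       stringsAsFactors = FALSE),
            class = c("allele_freq_table", "data.frame"))
}

#' Interspecies allele-frequency differential (delta)
#'
#' For a biallelic locus the Gregorius-Roberds differential
#' (half the summed absolute frequency differences over alleles) reduces to
#' \code{|p_a - p_b|}. Delta ranges from 0 to 1; 1 marks a fixed difference.
#' The \code{fixed} column uses exact semantics on the counted frequencies:
#' a locus is fixed iff the observed parental allele sets are disjoint
#' (each group carries only one allele and they differ), with no floating
#' tolerance.
#'
#' @param freqs An \code{\link{estimate_parental_freqs}} table.
#' @return A data frame with columns \code{locus_id}, \code{delta},
#'   \code{fixed}. Undefined parental frequencies propagate as \code{NA}.
#' @export
allele_freq_differential <- function(freqs) {
  stopifnot(is.data.frame(freqs), all(c("p_a", "p_b") %in% colnames(freqs)))
  delta <- abs(freqs$p_a - freqs$p_b)
  fixed <- !is.na(freqs$p_a) & !is.na(freqs$p_b) &
    ((freqs$p_a == 0 & freqs$p_b == 1) | (freqs$p_a == 1 & freqs$p_b == 0))
  data.frame(locus_id = freqs$locus_id, delta = delta, fixed = fixed,
             stringsAsFactors = FALSE)
}

#' Select strongly differentiated (diagnostic) loci
#'
#' \code{threshold = 1} selects loci with fixed differences using the exact
#' disjoint-allele-set semantics of \code{\link{allele_freq_differential}};
#' any lower threshold selects loci with \code{delta >= threshold}.
#'
#' @param diff An \code{\link{allele_freq_differential}} table.
#' @param threshold Delta threshold in (0, 1].
#' @return Character vector of selected locus ids (possibly empty, with a
#'   warning).
#' @export
select_differentiated <- function(diff, threshold = 1) {
  stopifnot(threshold > 0, threshold <= 1)
  sel <- if (threshold == 1) diff$fixed
         else !is.na(diff$delta) & diff$delta >= threshold
  ids <- diff$locus_id[sel]
  if (!length(ids))
    warning("no loci reach delta >= ", threshold)
  ids
}

#' Write a filter report as TSV
#' @param gm A filtered \code{genotype_matrix} carrying a
#'   \code{"filter_report"} attribute.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_filter_report <- function(gm, path) {
  rep <- attr(gm, "filter_report")
  if (is.null(rep)) stop("no filter report attached")
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
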