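# Pairwise Weir-Cockerham F_ST and exploratory genotype PCA.

#' Pairwise Weir-Cockerham F_ST between two groups
#'
#' Per-locus variance components from the two-population, two-allele
#' Weir-Cockerham (1984) formulation: a (among populations), b (among
#' individuals within populations) and c (within individuals), with
#' per-locus theta = a / (a + b + c) and the mean over loci taken as the
#' ratio of sums, sum(a) / sum(a + b + c). A locus contributes only when
#' both groups have at least two individuals with non-missing calls there.
#' Small negative estimates are possible and reported unclamped.
#'
#' @param gm A \code{genotype_matrix} (polarization is irrelevant: theta is
#'   invariant to allele relabeling).
#' @param group1,group2 Group labels or explicit character vectors of
#'   sample ids.
#' @return List of class \code{fst_result}: \code{pair},
#'   \code{per_locus_theta} (named, NA where non-contributing),
#'   \code{mean_fst}, \code{n_loci}.
#' @export
weir_cockerham_fst <- function(gm, group1, group2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ids <- function(g) {
    if (length(g) == 1 && g %in% .GROUPS) group_samples(gm, g) else g
  }
  ids1 <- ids(group1); ids2 <- ids(group2)
  if (!length(ids1) || !length(ids2)) stop("empty group in weir_cockerham_fst")

  g1 <- gm$calls[ids1, , drop = FALSE]
  g2 <- gm$calls[ids2, , drop = FALSE]
  r <- 2  # populations

  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- ifelse(n1 > 0, colSums(g1, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, colSums(g2, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, colSums(g1 == 1L, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, colSums(g2 == 1L, na.rm = TRUE) / n2, NA_real_)

  usable <- n1 >= 2 & n2 >= 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  denom <- a + b + cc
  theta <- ifelse(usable & denom != 0, a / denom, NA_real_)
  names(theta) <- colnames(gm$calls)
  contrib <- usable & !is.na(denom) & denom != 0
  if (!any(contrib)) stop("no contributing loci for F_ST")
  mean_fst <- sum(a[contrib]) / sum(denom[contrib])

  structure(list(pair = c(if (length(group1) == 1) group1 else "set1",
                          if (length(group2) == 1) group2 else "set2"),
                 per_locus_theta = theta, mean_fst = mean_fst,
                 n_loci = sum(contrib)),
            class = "fst_result")
}

#' Mean pairwise F_ST between all three groups
#'
#' @param gm A \code{genotype_matrix} with groups assigned.
#' @return Data frame with columns \code{group1}, \code{group2},
#'   \code{n_loci}, \code{mean_fst}.
#' @export
pairwise_fst <- function(gm) {
  pairs <- utils::combn(.GROUPS, 2)
  rows <- apply(pairs, 2, function(pr) {
    res <- weir_cockerham_fst(gm, pr[1], pr[2])
    data.frame(group1 = pr[1], group2 = pr[2], n_loci = res$n_loci,
               mean_fst = res$mean_fst, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genotype PCA with mean imputation of missing calls
#'
#' Loci are mean-centered; missing calls are imputed to the locus mean (so
#' they contribute nothing to that locus's variance but heavily-missing
#' individuals shrink towards the origin, a known qualitative artefact of
#' this policy). Scores come from the singular value decomposition of the
#' centered matrix.
#'
#' @param gm A \code{genotype_matrix} with at least 2 samples and 2 loci.
#' @return List of class \code{pca_result}: \code{scores} (samples x
#'   components), \code{explained_fraction}, \code{loadings}.
#' @export
genotype_pca <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"),
            nrow(gm$calls) >= 2, ncol(gm$calls) >= 2)
  x <- gm$calls
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, colMeans(x))
  if (all(x == 0)) stop("constant genotype matrix: no variance for PCA")
  sv <- svd(x)
  ncomp <- sum(sv$d > sv$d[1] * 1e-12)
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  rownames(scores) <- rownames(gm$calls)
  colnames(scores) <- paste0("PC", seq_len(ncomp))
  ev <- sv$d^2
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  rownames(loadings) <- colnames(gm$calls)
  colnames(loadings) <- colnames(scores)
  structure(list(scores = scores,
                 explained_fraction = (ev / sum(ev))[seq_len(ncomp)],
                 loadings = loadings),
            class = "pca_result")
}
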