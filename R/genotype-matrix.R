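# Group labels used throughout: the two parental reference populations and the
# putatively admixed individuals sampled in or near the contact zone.
.GROUPS <- c("PARENTAL_A", "PARENTAL_B", "ADMIXED_CANDIDATE")

# Case-insensitive aliases accepted in metadata files.
.GROUP_ALIASES <- c(
  parental_a = "PARENTAL_A", a = "PARENTAL_A", p_a = "PARENTAL_A",
  parental_b = "PARENTAL_B", b = "PARENTAL_B", p_b = "PARENTAL_B",
  admixed_candidate = "ADMIXED_CANDIDATE", hybrid = "ADMIXED_CANDIDATE",
  admixed = "ADMIXED_CANDIDATE"
)

#' Construct a genotype matrix
#'
#' The central container of the package: an individuals x loci matrix of
#' biallelic genotype calls coded as the count of the alternate allele
#' (0, 1, 2), with \code{NA} for missing calls, plus per-sample metadata
#' (group assignment, coordinates, sex) and per-locus allele labels.
#' Genotypes are stored unpolarized; recoding to counts of the
#' B-associated allele happens in \code{\link{polarize}}.
#'
#' @param calls Integer matrix, samples x loci, values in \{0, 1, 2, NA\}.
#'   Row names are sample ids, column names locus ids (supplied names win
#'   over \code{samples}/\code{loci} arguments when both are present).
#' @param samples Optional data frame with columns \code{sample_id} and
#'   optionally \code{group}, \code{latitude}, \code{longitude}, \code{sex}.
#' @param loci Optional data frame with columns \code{locus_id},
#'   \code{ref_allele}, \code{alt_allele}.
#' @param depth Optional non-negative integer matrix of per-call read depths,
#'   same dimensions as \code{calls}. A depth of 0 must coincide with a
#'   missing call.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(calls, samples = NULL, loci = NULL, depth = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype calls must be 0, 1, 2 or NA; found ",
         paste(unique(bad[!bad %in% 0:2]), collapse = ", "))
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- if (!is.null(samples)) as.character(samples$sample_id)
                       else paste0("S", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- if (!is.null(loci)) as.character(loci$locus_id)
                       else paste0("L", seq_len(ncol(calls)))
  }
  if (anyDuplicated(rownames(calls)))
    stop("duplicate sample_id in genotype matrix")
  if (anyDuplicated(colnames(calls)))
    stop("duplicate locus_id in genotype matrix")

  if (is.null(samples)) {
    samples <- data.frame(sample_id = rownames(calls),
                          stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  for (col in c("group", "latitude", "longitude", "sex")) {
    if (is.null(samples[[col]])) samples[[col]] <- NA
  }
  if (!all(rownames(calls) == samples$sample_id))
    stop("sample order in `samples` must match rows of `calls`")
  known <- samples$group[!is.na(samples$group)]
  if (length(known) && !all(known %in% .GROUPS))
    stop("unknown group label(s): ",
         paste(setdiff(known, .GROUPS), collapse = ", "))

  if (is.null(loci)) {
    loci <- data.frame(locus_id = colnames(calls),
                       ref_allele = "0", alt_allele = "1",
                       stringsAsFactors = FALSE)
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  loci$locus_id <- as.character(loci$locus_id)
  if (!all(colnames(calls) == loci$locus_id))
    stop("locus order in `loci` must match columns of `calls`")
  if (any(loci$ref_allele == loci$alt_allele))
    stop("ref_allele and alt_allele must differ at every locus")

  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!all(dim(depth) == dim(calls)))
      stop("depth matrix dimensions must match calls")
    if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
    zero_called <- !is.na(depth) & depth == 0 & !is.na(calls)
    if (any(zero_called))
      stop("depth = 0 with a non-missing genotype call")
    dimnames(depth) <- dimnames(calls)
  }

  structure(list(calls = calls, samples = samples, loci = loci, depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  grp <- table(factor(x$samples$group, levels = .GROUPS), useNA = "ifany")
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "loci\n")
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  cat("  missing calls:",
      sprintf("%.1f%%", 100 * mean(is.na(x$calls))), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param gm A \code{genotype_matrix}.
#' @param samples,loci Character vectors of ids (or logical/integer indices)
#'   to keep; \code{NULL} keeps everything.
#' @return A \code{genotype_matrix}.
#' @export
subset_genotypes <- function(gm, samples = NULL, loci = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ri <- if (is.null(samples)) seq_len(nrow(gm$calls)) else samples
  ci <- if (is.null(loci)) seq_len(ncol(gm$calls)) else loci
  if (is.character(ri)) ri <- match(ri, rownames(gm$calls))
  if (is.character(ci)) ci <- match(ci, colnames(gm$calls))
  if (anyNA(ri)) stop("unknown sample id in subset")
  if (anyNA(ci)) stop("unknown locus id in subset")
  genotype_matrix(gm$calls[ri, ci, drop = FALSE],
                  samples = gm$samples[ri, , drop = FALSE],
                  loci = gm$loci[ci, , drop = FALSE],
                  depth = if (!is.null(gm$depth)) gm$depth[ri, ci, drop = FALSE])
}

#' Sample ids belonging to a group
#' @param gm A \code{genotype_matrix}.
#' @param group One of \code{"PARENTAL_A"}, \code{"PARENTAL_B"},
#'   \code{"ADMIXED_CANDIDATE"}.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(gm, group) {
  group <- match.arg(group, .GROUPS)
  gm$samples$sample_id[!is.na(gm$samples$group) & gm$samples$group == group]
}

#' Read genotypes from a VCF file
#'
#' Keeps biallelic SNP records only: records with more than one ALT allele or
#' with non-single-nucleotide REF/ALT are dropped and the dropped count is
#' reported via \code{message()}. The genotype code is the count of the
#' (single) ALT allele; \code{./.} becomes \code{NA}. Per-call \code{DP} is
#' attached as the depth matrix when present.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return A \code{genotype_matrix}.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  n_drop <- sum(!snp)
  if (n_drop > 0)
    message("read_vcf: dropped ", n_drop, " non-biallelic-SNP record(s)")
  if (!any(snp)) stop("empty dataset: no usable biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  # count ALT alleles in a diploid GT string, phased or not
  code <- function(g) {
    out <- rep(NA_integer_, length(g))
    ok <- !is.na(g) & !g %in% c("./.", ".|.", ".")
    alleles <- strsplit(gsub("|", "/", g[ok], fixed = TRUE), "/", fixed = TRUE)
    out[ok] <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
    out
  }
  calls <- apply(gt, 2, code)
  if (is.null(dim(calls)))
    calls <- matrix(calls, nrow = sum(snp), dimnames = list(NULL, colnames(gt)))
  calls <- t(calls)  # samples x loci

  ids <- fix[snp, "ID"]
  nohit <- is.na(ids) | ids == "."
  ids[nohit] <- paste0(fix[snp, "CHROM"][nohit], "_", fix[snp, "POS"][nohit])
  colnames(calls) <- ids
  loci <- data.frame(locus_id = ids, ref_allele = ref[snp],
                     alt_allele = alt[snp], stringsAsFactors = FALSE)

  depth <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    dp <- t(dp[snp, , drop = FALSE])
    if (any(!is.na(dp))) {          # DP declared but never emitted: skip
      dp[is.na(dp) & is.na(calls)] <- 0
      colnames(dp) <- ids
      depth <- dp
    }
  }
  genotype_matrix(calls, loci = loci, depth = depth)
}

#' Read genotypes from a TSV matrix
#'
#' Dialect: header row of locus ids, first column \code{sample_id}, cells in
#' \{0, 1, 2, NA\}.
#'
#' @param path Path to a tab-separated genotype table.
#' @return A \code{genotype_matrix}.
#' @export
read_genotype_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read genotype TSV: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(tab) == 0) stop("empty dataset: ", path, " has a header but no rows")
  if (ncol(tab) < 2) stop("empty dataset: ", path, " has no locus columns")
  ids <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  ok <- is.na(vals) | vals %in% c("0", "1", "2", "NA", "")
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop("invalid genotype cell '", vals[idx[1], idx[2]], "' for sample '",
         ids[idx[1]], "' at locus '", colnames(vals)[idx[2]], "'")
  }
  vals[vals %in% c("NA", "")] <- NA
  calls <- matrix(as.integer(vals), nrow = nrow(vals),
                  dimnames = list(ids, colnames(vals)))
  genotype_matrix(calls)
}

#' Write a genotype matrix as TSV
#'
#' Inverse of \code{\link{read_genotype_tsv}}; missing calls are written as
#' \code{NA}, never as a numeric code.
#'
#' @param gm A \code{genotype_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_genotype_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  tab <- data.frame(sample_id = rownames(gm$calls), gm$calls,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Attach sample metadata from a TSV file
#'
#' Expects columns \code{sample_id} and \code{group}; \code{latitude},
#' \code{longitude} and \code{sex} are optional. Group labels are matched
#' case-insensitively against \code{PARENTAL_A}, \code{PARENTAL_B},
#' \code{ADMIXED_CANDIDATE} and the aliases \code{A}, \code{B} and
#' \code{hybrid}/\code{admixed}. Every sample in the matrix must be covered.
#'
#' @param path Path to the metadata TSV.
#' @param gm A \code{genotype_matrix}.
#' @return \code{gm} with groups, coordinates and sex filled in.
#' @export
read_sample_metadata <- function(path, gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!file.exists(path)) stop("cannot read metadata: ", path)
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(meta)))
    stop("metadata must contain sample_id and group columns")
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  grp <- .GROUP_ALIASES[tolower(trimws(meta$group))]
  if (anyNA(grp))
    stop("unknown group label(s): ",
         paste(unique(meta$group[is.na(grp)]), collapse = ", "))
  missing <- setdiff(rownames(gm$calls), meta$sample_id)
  if (length(missing))
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))

  idx <- match(rownames(gm$calls), meta$sample_id)
  gm$samples$group <- unname(grp[idx])
  for (col in c("latitude", "longitude")) {
    gm$samples[[col]] <- if (col %in% colnames(meta))
      as.numeric(meta[[col]][idx]) else NA_real_
  }
  gm$samples$sex <- if ("sex" %in% colnames(meta)) {
    sx <- toupper(trimws(as.character(meta$sex[idx])))
    sx[!sx %in% c("M", "F")] <- "U"
    sx
  } else NA_character_
  gm
}

#' Write sample metadata as TSV
#' @param gm A \code{genotype_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sample_metadata <- function(gm, path) {
  utils::write.table(gm$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
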