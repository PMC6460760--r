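# Small in-code fixtures shared across test files.

# A genotype matrix from a plain integer matrix, with optional group labels.
toy_gm <- function(calls, groups = NULL, depth = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  samples <- data.frame(sample_id = rownames(calls),
                        stringsAsFactors = FALSE)
  if (!is.null(groups)) samples$group <- groups
  genotype_matrix(calls, samples = samples, depth = depth)
}

# Write a minimal VCF with given calls (samples x loci) and optional DP.
write_toy_vcf <- function(path, calls, extra_records = character(0),
                          dp = NULL) {
  n_s <- nrow(calls); n_l <- ncol(calls)
  gt_of <- function(x) c(`0` = "0/0", `1` = "0/1", `2` = "1/1")[as.character(x)]
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(calls)), collapse = "\t"))
  recs <- vapply(seq_len(n_l), function(l) {
    cells <- vapply(seq_len(n_s), function(s) {
      g <- if (is.na(calls[s, l])) "./." else gt_of(calls[s, l])
      if (is.null(dp)) g else paste0(g, ":", dp[s, l])
    }, character(1))
    paste(c("chr1", l * 100, colnames(calls)[l], "A", "T", ".", "PASS", ".",
            if (is.null(dp)) "GT" else "GT:DP", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs, extra_records), path)
  path
}

# Plumage record data frame from a matrix of ancestral proportions.
toy_plumage <- function(props, lat = NULL, lon = NULL) {
  maxima <- c(head = 4, cheek_patch = 2, chest = 4,
              upper_abdomen = 4, lower_abdomen = 4, rump = 4)
  rec <- data.frame(sample_id = paste0("P", seq_len(nrow(props))),
                    stringsAsFactors = FALSE)
  for (i in seq_along(maxima))
    rec[[names(maxima)[i]]] <- as.integer(round(props[, i] * maxima[i]))
  if (!is.null(lat)) rec$latitude <- lat
  if (!is.null(lon)) rec$longitude <- lon
  rec
}
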