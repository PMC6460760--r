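# Plumage-score analysis: trait proportions, plumage hybrid index, scaled
# PCA with and without the rump trait, and geographic zone profiling.

# Trait maxima of the six scored plumage characters. All traits run 0-4
# except the cheek patch (0-2); rump may be unscorable from photographs.
.PLUMAGE_TRAITS <- c(head = 4, cheek_patch = 2, chest = 4,
                     upper_abdomen = 4, lower_abdomen = 4, rump = 4)

#' Read plumage score records from TSV
#'
#' Columns: \code{sample_id}, the six trait scores (\code{head},
#' \code{cheek_patch}, \code{chest}, \code{upper_abdomen},
#' \code{lower_abdomen}, \code{rump}; \code{NA} allowed for rump only),
#' and optional \code{latitude}, \code{longitude}.
#'
#' @param path Path to the TSV.
#' @return Data frame of validated plumage records.
#' @export
read_plumage_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read plumage TSV: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", names(.PLUMAGE_TRAITS))
  if (!all(need %in% colnames(tab)))
    stop("plumage TSV must contain columns: ", paste(need, collapse = ", "))
  validate_plumage(tab)
  tab
}

#' Validate plumage scores against trait ranges
#'
#' @param records Data frame with the six trait columns.
#' @return \code{records}, invisibly; out-of-range or illegally missing
#'   scores raise an error naming the trait.
#' @export
validate_plumage <- function(records) {
  for (tr in names(.PLUMAGE_TRAITS)) {
    v <- records[[tr]]
    if (tr != "rump" && anyNA(v))
      stop("missing score for required trait '", tr, "'")
    bad <- !is.na(v) & (v < 0 | v > .PLUMAGE_TRAITS[[tr]] | v != round(v))
    if (any(bad))
      stop("score out of range for trait '", tr, "': ",
           paste(v[bad], collapse = ", "),
           " (allowed 0..", .PLUMAGE_TRAITS[[tr]], ")")
  }
  invisible(records)
}

#' Convert trait scores to proportions
#'
#' Each score is divided by its trait maximum (4 for all traits except the
#' cheek patch, max 2), giving per-trait proportions in [0, 1] with higher
#' values more B-type (P. eximius-like).
#'
#' @param records Plumage record data frame.
#' @return \code{records} with added columns \code{<trait>_prop}.
#' @export
score_to_proportions <- function(records) {
  validate_plumage(records)
  for (tr in names(.PLUMAGE_TRAITS)) {
    records[[paste0(tr, "_prop")]] <- records[[tr]] / .PLUMAGE_TRAITS[[tr]]
  }
  records
}

#' Plumage hybrid index
#'
#' Unweighted mean of the available (non-missing, non-excluded) trait
#' proportions; with an unscorable rump the mean runs over the remaining
#' five traits. 0 = pure A-type plumage, 1 = pure B-type.
#'
#' @param records Plumage record data frame.
#' @param exclude_traits Optional character vector of traits to drop (e.g.
#'   \code{"cheek_patch"}, whose polymorphism in the A-type parental
#'   population otherwise inflates parental indices).
#' @return \code{records} with added column \code{plumage_hi}.
#' @export
plumage_hybrid_index <- function(records, exclude_traits = NULL) {
  records <- score_to_proportions(records)
  traits <- setdiff(names(.PLUMAGE_TRAITS), exclude_traits)
  if (!length(traits)) stop("all traits excluded")
  props <- as.matrix(records[, paste0(traits, "_prop"), drop = FALSE])
  hi <- rowMeans(props, na.rm = TRUE)
  hi[rowSums(!is.na(props)) == 0] <- NA_real_
  records$plumage_hi <- hi
  records
}

#' Scaled PCA of plumage proportions
#'
#' Two variants guard against the bias of an incomplete score set: the
#' \code{ALL_TRAITS} variant drops individuals whose rump could not be
#' scored, the \code{NO_RUMP} variant drops the rump trait instead. Traits
#' are centered and scaled to unit variance before decomposition; component
#' signs are fixed by forcing the largest-magnitude loading of each
#' component positive, so a higher PC1 is more B-type under the package's
#' polarity convention.
#'
#' @param records Plumage record data frame.
#' @param variant \code{"ALL_TRAITS"} or \code{"NO_RUMP"}.
#' @return List of class \code{plumage_pca}: \code{variant}, \code{scores},
#'   \code{loadings} (traits x components), \code{explained_fraction},
#'   \code{sample_id}.
#' @export
plumage_pca <- function(records, variant = c("ALL_TRAITS", "NO_RUMP")) {
  variant <- match.arg(variant)
  records <- score_to_proportions(records)
  traits <- names(.PLUMAGE_TRAITS)
  if (variant == "NO_RUMP") {
    traits <- setdiff(traits, "rump")
  } else {
    records <- records[!is.na(records$rump), , drop = FALSE]
  }
  if (nrow(records) < 3)
    stop("need at least 3 individuals after variant exclusions")
  x <- as.matrix(records[, paste0(traits, "_prop"), drop = FALSE])
  colnames(x) <- traits
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance trait(s): ", paste(traits[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # sign convention: largest |loading| of each component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(variant = variant, scores = pc$x, loadings = pc$rotation,
                 explained_fraction = pc$sdev^2 / sum(pc$sdev^2),
                 sample_id = records$sample_id),
            class = "plumage_pca")
}

#' Locate the hybrid zone from plumage indices and coordinates
#'
#' An individual qualifies as zone-defining when its plumage hybrid index
#' lies strictly inside the intermediate band (default 0.2-0.8), or when it
#' shares a latitude bin (default width 0.25 degrees) with both a
#' near-pure-A (< 0.1) and a near-pure-B (> 0.9) individual, i.e. the two
#' phenotypes co-occur there. Latitude bounds are the min/max latitude of
#' qualifying individuals; longitude bounds are the min/max longitude of
#' in-band individuals within those latitude bounds.
#'
#' @param records Plumage records with \code{plumage_hi}, \code{latitude},
#'   \code{longitude} (see \code{\link{plumage_hybrid_index}}).
#' @param band Intermediate-index band (open interval).
#' @param bin_width Latitude bin width in degrees for the co-occurrence
#'   rule.
#' @return List of class \code{zone_profile}: \code{zone_lat_bounds}
#'   (south, north), \code{zone_lon_bounds}, \code{n_intermediate},
#'   \code{qualifying_ids}. Bounds are \code{NA} with a warning when no
#'   individual qualifies.
#' @export
zone_profile <- function(records, band = c(0.2, 0.8), bin_width = 0.25) {
  stopifnot("plumage_hi" %in% colnames(records))
  ok <- !is.na(records$plumage_hi) & !is.na(records$latitude)
  rec <- records[ok, , drop = FALSE]
  hi <- rec$plumage_hi

  in_band <- hi > band[1] & hi < band[2]
  bin <- floor(rec$latitude / bin_width)
  co_occ <- vapply(seq_along(bin), function(i) {
    same <- bin == bin[i]
    any(hi[same] < 0.1) && any(hi[same] > 0.9)
  }, logical(1))
  qual <- in_band | co_occ

  if (!any(qual)) {
    warning("no zone-defining individuals; bounds undefined")
    return(structure(list(zone_lat_bounds = c(NA_real_, NA_real_),
                          zone_lon_bounds = c(NA_real_, NA_real_),
                          n_intermediate = 0L,
                          qualifying_ids = character(0)),
                     class = "zone_profile"))
  }
  lat_bounds <- range(rec$latitude[qual])
  in_lat <- rec$latitude >= lat_bounds[1] & rec$latitude <= lat_bounds[2]
  lon_ok <- in_band & in_lat & !is.na(rec$longitude)
  lon_bounds <- if (any(lon_ok)) range(rec$longitude[lon_ok])
                else c(NA_real_, NA_real_)
  structure(list(zone_lat_bounds = lat_bounds, zone_lon_bounds = lon_bounds,
                 n_intermediate = sum(in_band),
                 qualifying_ids = rec$sample_id[qual]),
            class = "zone_profile")
}
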