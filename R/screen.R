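## Batch co-occupancy screen: a catalog of factor peak sets is tested for
## association with a two-class partition of target sites (e.g. remodeler
## binding sites partitioned by presence of a histone-variant mark), via
## per-site 2x2 tables, sample odds ratios and Fisher's exact test.

#' Partition target sites by overlap with a marker set
#'
#' @param targets flattened `GRanges` of target sites.
#' @param marker flattened `GRanges`; sites with at least `min_bp` bp of
#'   marker overlap go to the positive class.
#' @param min_bp minimum overlap in bp (default 1).
#' @return List with `positive` and `negative` `GRanges`; their union is
#'   `targets`.
#' @export
partition_targets <- function(targets, marker, min_bp = 1L) {
  validate_intervals(targets, "targets")
  hit <- site_overlaps(targets, marker, min_bp)
  list(positive = targets[hit], negative = targets[!hit])
}

## per-site logical: does each site overlap `other` by >= min_bp bp
site_overlaps <- function(sites, other, min_bp = 1L) {
  if (length(sites) == 0L) return(logical(0))
  if (length(other) == 0L) return(rep(FALSE, length(sites)))
  other <- GenomicRanges::reduce(other, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(sites, other, ignore.strand = TRUE)
  out <- rep(FALSE, length(sites))
  if (length(hits) > 0L) {
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      sites[S4Vectors::queryHits(hits)], other[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- agg >= min_bp
  }
  out
}

#' Factor co-occupancy screen against a two-class site partition
#'
#' For each factor in the catalog, target sites are cross-classified by
#' factor overlap (at least 1 bp, per site) and by class
#' (positive/negative), giving a 2x2 table; the sample odds ratio and the
#' two-tailed Fisher p are computed, along with the fraction of all target
#' sites the factor overlaps. A factor passes the screen filters iff
#' `odds_ratio > or_min` and `overlap_fraction > overlap_min`.
#'
#' @param catalog named list of flattened `GRanges`, one per factor.
#' @param positive,negative disjoint `GRanges` of the two site classes.
#' @param or_min odds-ratio filter (default 2).
#' @param overlap_min overlap-fraction filter (default 0.001, i.e. 0.1%).
#' @param min_bp minimum per-site overlap in bp (default 1).
#' @return `data.frame`, one row per factor, ordered by decreasing odds
#'   ratio: `factor`, `a`, `b`, `c`, `d` (table cells), `odds_ratio`, `p`,
#'   `overlap_fraction`, `passes_filters`.
#' @export
factor_screen <- function(catalog, positive, negative, or_min = 2,
                          overlap_min = 0.001, min_bp = 1L) {
  if (length(catalog) == 0L) stop("empty factor catalog")
  if (is.null(names(catalog)) || anyDuplicated(names(catalog)))
    stop("catalog must have unique factor names")
  if (length(positive) == 0L || length(negative) == 0L)
    stop("both site classes must be non-empty")
  n_pos <- length(positive); n_neg <- length(negative)
  n_all <- n_pos + n_neg
  rows <- lapply(names(catalog), function(nm) {
    fac <- catalog[[nm]]
    hp <- site_overlaps(positive, fac, min_bp)
    hn <- site_overlaps(negative, fac, min_bp)
    a <- sum(hp); b <- n_pos - a; c <- sum(hn); d <- n_neg - c
    fe <- fisher_exact_2x2(a, b, c, d)
    ovf <- (a + c) / n_all
    data.frame(factor = nm, a = a, b = b, c = c, d = d,
               odds_ratio = fe$odds_ratio, p = fe$p,
               overlap_fraction = ovf,
               passes_filters = !is.na(fe$odds_ratio) &
                 fe$odds_ratio > or_min & ovf > overlap_min)
  })
  out <- do.call(rbind, rows)
  out[order(-out$odds_ratio), , drop = FALSE]
}
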