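## Interval arithmetic and co-occupancy statistics.
##
## All user-facing coordinates follow the BED convention: 0-based,
## half-open [start, end). Internally intervals are held as GRanges
## (1-based closed); `gintervals()` and the BED readers/writers perform
## the conversion bit-exactly.

#' Construct a genomic interval set
#'
#' Builds a [GenomicRanges::GRanges] from BED-convention coordinates
#' (0-based half-open).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open, so `start < end`.
#' @param genome optional genome (named vector of chromosome lengths, see
#'   [genome_sizes()]); when supplied, intervals are checked against bounds
#'   and seqlengths are attached.
#' @return A `GRanges` object.
#' @export
gintervals <- function(chrom, start, end, genome = NULL) {
  if (length(chrom) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    chrom <- as.character(chrom)
    if (any(is.na(chrom)) || any(!nzchar(chrom)))
      stop("chromosome names must be non-empty")
    if (any(start < 0)) stop("start must be >= 0")
    if (any(start >= end)) stop("malformed interval: start >= end")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  }
  if (!is.null(genome)) {
    bad <- !as.character(GenomicRanges::seqnames(gr)) %in% names(genome)
    if (any(bad)) stop("interval chromosome not in genome")
    if (any(GenomicRanges::end(gr) > genome[as.character(GenomicRanges::seqnames(gr))]))
      stop("interval extends beyond chromosome length")
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- genome
  }
  sort(gr, ignore.strand = TRUE)
}

#' Define a genome as named chromosome lengths
#'
#' @param lengths numeric vector of chromosome lengths in bp, named by
#'   chromosome.
#' @return Named numeric vector with class checks applied; `sum()` of it is
#'   the total genome size G used as the denominator of per-bp statistics.
#' @export
genome_sizes <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (any(lengths <= 0)) stop("all chromosome lengths must be > 0")
  stats::setNames(as.numeric(lengths), names(lengths))
}

validate_intervals <- function(gr, what = "intervals") {
  if (!methods::is(gr, "GRanges")) stop(what, " must be a GRanges")
  if (any(GenomicRanges::width(gr) < 1L)) stop("malformed interval: start >= end")
  invisible(gr)
}

#' Flatten an interval set
#'
#' Merges overlapping or abutting intervals so that no two intervals on the
#' same chromosome overlap or touch; the set of covered bp is unchanged.
#'
#' @param gr a `GRanges`.
#' @return Flattened `GRanges`, sorted by (chrom, start).
#' @export
flatten_intervals <- function(gr) {
  validate_intervals(gr)
  GenomicRanges::reduce(sort(gr, ignore.strand = TRUE), ignore.strand = TRUE)
}

#' Total bp covered by both of two flattened interval sets
#'
#' @param a,b flattened `GRanges`.
#' @return Integer-valued bp count.
#' @export
intersect_bp <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (length(a) == 0L || length(b) == 0L) return(0)
  hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
  if (length(hits) == 0L) return(0)
  ov <- GenomicRanges::pintersect(a[S4Vectors::queryHits(hits)],
                                  b[S4Vectors::subjectHits(hits)],
                                  ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(ov)))
}

total_bp <- function(gr) sum(as.numeric(GenomicRanges::width(gr)))

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N population, K successes, n draws).
#'
#' @param k observed successes in the draw.
#' @param n draw size.
#' @param K successes in the population.
#' @param N population size.
#' @return Probability in \[0, 1\].
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0)) stop("arguments must be non-negative")
  if (any(k > n) || any(n > N) || any(K > N))
    stop("inconsistent hypergeometric arguments")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-bp fold enrichment of one interval set in another
#'
#' Observed bp overlap of `a` with `b`, against the expectation
#' `|a| * |b| / G` under random placement, with an upper-tail hypergeometric
#' p-value at bp granularity (population G bp, `|b|` success bp, `|a|` drawn
#' bp).
#'
#' @param a,b flattened `GRanges`.
#' @param genome named chromosome lengths ([genome_sizes()]).
#' @return A one-row `data.frame` with columns `observed`, `expected`,
#'   `fold`, `p`. `fold` is `NA` when either set is empty (expected 0).
#' @export
fold_enrichment_bp <- function(a, b, genome) {
  G <- sum(genome)
  na <- total_bp(a); nb <- total_bp(b)
  if (na > G || nb > G) stop("interval set larger than genome")
  obs <- intersect_bp(a, b)
  expected <- na * nb / G
  if (na == 0 || nb == 0)
    return(data.frame(observed = obs, expected = expected, fold = NA_real_, p = 1))
  data.frame(observed = obs, expected = expected, fold = obs / expected,
             p = hypergeom_upper_tail(obs, na, nb, G))
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' The odds ratio is the sample cross-product ratio `a*d / (b*c)` (not the
#' conditional MLE): `Inf` when `b*c == 0` and `a*d > 0`, `NaN` when both
#' products are zero. The p-value is the standard exact two-sided
#' definition: the sum of probabilities of all margin-fixed tables whose
#' point probability does not exceed the observed table's.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, 2, byrow = TRUE)`.
#' @return `data.frame` with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) stop("cells must be non-negative integers")
  if (sum(cells) == 0) stop("all-zero contingency table")
  or <- if (b * c > 0) (a * d) / (b * c) else if (a * d > 0) Inf else NaN
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  data.frame(odds_ratio = or, p = p)
}

#' Pearson chi-squared test on a 2x2 table (no continuity correction)
#'
#' @inheritParams fisher_exact_2x2
#' @return `data.frame` with `statistic` and `p`; a zero row or column
#'   margin yields `statistic = NA`, `p = 1`.
#' @export
chi_squared_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cells must be non-negative")
  n <- sum(cells)
  if (n == 0) stop("all-zero contingency table")
  m1 <- a + b; m2 <- c + d; m3 <- a + c; m4 <- b + d
  if (min(m1, m2, m3, m4) == 0)
    return(data.frame(statistic = NA_real_, p = 1))
  stat <- n * (a * d - b * c)^2 / (m1 * m2 * m3 * m4)
  data.frame(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Naive overlapping peak set
#'
#' Retains a pooled peak iff, for every replicate, at least `min_frac` of
#' the pooled peak's length is covered by the union of that replicate's
#' peaks (boundary inclusive).
#'
#' @param pooled `GRanges` of peaks called on pooled replicates.
#' @param replicates list of `GRanges`, one per biological replicate.
#' @param min_frac minimum covered fraction (default 0.5).
#' @return Subset of `pooled`.
#' @export
naive_overlap_peakset <- function(pooled, replicates, min_frac = 0.5) {
  validate_intervals(pooled, "pooled")
  if (!is.list(replicates) || length(replicates) == 0L)
    stop("at least one replicate set is required")
  keep <- rep(TRUE, length(pooled))
  for (rep_gr in replicates) {
    rep_flat <- flatten_intervals(rep_gr)
    cov <- numeric(length(pooled))
    hits <- GenomicRanges::findOverlaps(pooled, rep_flat, ignore.strand = TRUE)
    if (length(hits) > 0L) {
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        pooled[S4Vectors::queryHits(hits)], rep_flat[S4Vectors::subjectHits(hits)],
        ignore.strand = TRUE))
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      cov[as.integer(names(agg))] <- agg
    }
    keep <- keep & (cov / GenomicRanges::width(pooled) >= min_frac)
  }
  pooled[keep]
}

#' Merge nearby regions carrying a representative p-value
#'
#' Greedy left-to-right chaining per chromosome: the current merged region
#' is extended by the next region iff the gap between them is at most
#' `max_gap` bp AND the resulting merged width is at most `max_width` bp.
#' The representative p of a merged region is the minimum over its members.
#' A single input region wider than `max_width` passes through unmerged.
#'
#' @param regions sorted `GRanges`.
#' @param p numeric vector of per-region p-values, aligned with `regions`.
#' @param max_gap maximum gap in bp to bridge (inclusive; default 500).
#' @param max_width maximum merged region width in bp (default 5000).
#' @return `GRanges` of merged regions with metadata columns `p`
#'   (representative minimum), `n_members`, and `which_min` (index into the
#'   input of the minimum-p member).
#' @export
merge_nearby_regions <- function(regions, p, max_gap = 500, max_width = 5000) {
  validate_intervals(regions, "regions")
  if (length(p) != length(regions)) stop("one p-value per region is required")
  if (length(regions) == 0L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$p <- numeric(0)
    S4Vectors::mcols(out)$n_members <- integer(0)
    S4Vectors::mcols(out)$which_min <- integer(0)
    return(out)
  }
  o <- order(as.character(GenomicRanges::seqnames(regions)), GenomicRanges::start(regions))
  regions <- regions[o]; p <- p[o]; orig_idx <- o

  chrom <- as.character(GenomicRanges::seqnames(regions))
  s <- GenomicRanges::start(regions); e <- GenomicRanges::end(regions)

  res_chrom <- character(0); res_s <- integer(0); res_e <- integer(0)
  res_p <- numeric(0); res_n <- integer(0); res_wm <- integer(0)

  cur_chrom <- chrom[1]; cur_s <- s[1]; cur_e <- e[1]
  cur_p <- p[1]; cur_n <- 1L; cur_wm <- orig_idx[1]
  flush <- function() {
    res_chrom <<- c(res_chrom, cur_chrom); res_s <<- c(res_s, cur_s)
    res_e <<- c(res_e, cur_e); res_p <<- c(res_p, cur_p)
    res_n <<- c(res_n, cur_n); res_wm <<- c(res_wm, cur_wm)
  }
  if (length(regions) > 1L) {
    for (i in 2:length(regions)) {
      gap <- s[i] - cur_e - 1L           # bp between half-open ends
      new_width <- max(cur_e, e[i]) - cur_s + 1L
      if (chrom[i] == cur_chrom && gap <= max_gap && new_width <= max_width) {
        cur_e <- max(cur_e, e[i]); cur_n <- cur_n + 1L
        if (p[i] < cur_p) { cur_p <- p[i]; cur_wm <- orig_idx[i] }
      } else {
        flush()
        cur_chrom <- chrom[i]; cur_s <- s[i]; cur_e <- e[i]
        cur_p <- p[i]; cur_n <- 1L; cur_wm <- orig_idx[i]
      }
    }
  }
  flush()
  out <- GenomicRanges::GRanges(res_chrom, IRanges::IRanges(res_s, res_e))
  S4Vectors::mcols(out)$p <- res_p
  S4Vectors::mcols(out)$n_members <- res_n
  S4Vectors::mcols(out)$which_min <- res_wm
  out
}

## nearest-edge distance (bp) from each peak to the closest TSS point;
## 0 when the TSS falls inside the peak.
peak_tss_distance <- function(peaks, tss) {
  d <- rep(Inf, length(peaks))
  pchrom <- as.character(GenomicRanges::seqnames(peaks))
  for (chr in unique(pchrom)) {
    pos <- tss$position[tss$chrom == chr]   # 0-based points
    if (length(pos) == 0L) next
    idx <- which(pchrom == chr)
    s0 <- GenomicRanges::start(peaks[idx]) - 1L   # back to 0-based
    e0 <- GenomicRanges::end(peaks[idx])          # half-open end
    for (j in seq_along(idx)) {
      dj <- ifelse(pos >= s0[j] & pos < e0[j], 0,
                   ifelse(pos < s0[j], s0[j] - pos, pos - e0[j] + 1L))
      d[idx[j]] <- min(dj)
    }
  }
  d
}

#' Classify peaks into promoter-proximal / enhancer categories
#'
#' Classifies each H3K27ac peak: a peak overlapping ATAC and a
#' super-enhancer is a `super_enhancer_constituent`; otherwise a peak whose
#' nearest-edge distance to any TSS is at most `flank` bp is
#' `promoter_proximal` (boundary inclusive; ties favour the promoter
#' class); otherwise a peak overlapping ATAC more than `flank` bp from
#' every TSS is a `typical_enhancer`; anything else is `other`.
#'
#' @param h3k27ac `GRanges` of H3K27ac peaks (flattened).
#' @param atac `GRanges` of accessible regions (flattened).
#' @param superenhancers `GRanges` of super-enhancer intervals (flattened).
#' @param tss `data.frame` with columns `gene_id`, `chrom`, `position`
#'   (0-based bp), `strand` (see [read_tss()]).
#' @param flank promoter distance in bp (default 3000).
#' @return Character vector of class labels, one per `h3k27ac` peak.
#' @export
classify_enhancers <- function(h3k27ac, atac, superenhancers, tss, flank = 3000) {
  validate_intervals(h3k27ac, "h3k27ac")
  if (nrow(tss) == 0L) stop("TSS list must be non-empty")
  has_atac <- GenomicRanges::countOverlaps(h3k27ac, atac, ignore.strand = TRUE) > 0
  in_se <- GenomicRanges::countOverlaps(h3k27ac, superenhancers, ignore.strand = TRUE) > 0
  d <- peak_tss_distance(h3k27ac, tss)
  label <- rep("other", length(h3k27ac))
  label[has_atac & in_se] <- "super_enhancer_constituent"
  label[label == "other" & d <= flank] <- "promoter_proximal"
  label[label == "other" & has_atac & !in_se & d > flank] <- "typical_enhancer"
  label
}
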