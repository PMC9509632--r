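## Promoter-proximal peak-to-gene assignment and gene-level association
## statistics linking chromatin classes to differential-expression tables.

#' Genes with a peak in the promoter-proximal window
#'
#' A gene is included iff at least one peak overlaps the strand-symmetric
#' window `[position - flank, position + flank)` (0-based half-open)
#' around its TSS. Duplicate gene ids with different TSS are allowed: the
#' union of their windows is used (with a warning).
#'
#' @param peaks `GRanges`.
#' @param tss `data.frame` with columns `gene_id`, `chrom`, `position`
#'   (0-based), `strand`.
#' @param flank half-window in bp (default 3000).
#' @return Character vector of gene ids.
#' @export
promoter_proximal_genes <- function(peaks, tss, flank = 3000) {
  validate_intervals(peaks, "peaks")
  if (nrow(tss) == 0L) stop("TSS table must be non-empty")
  if (anyDuplicated(tss$gene_id))
    warning("duplicate gene ids in TSS table; using the union of windows")
  s0 <- pmax(tss$position - flank, 0)
  e0 <- tss$position + flank          # half-open right edge
  windows <- GenomicRanges::GRanges(tss$chrom, IRanges::IRanges(s0 + 1L, e0))
  hits <- GenomicRanges::findOverlaps(windows, peaks, ignore.strand = TRUE)
  unique(tss$gene_id[unique(S4Vectors::queryHits(hits))])
}

#' Gene-set enrichment by hypergeometric and Fisher tests
#'
#' @param query,annotated character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe character vector of all genes considered.
#' @return One-row `data.frame`: `overlap`, `expected`, `fold`,
#'   `p_hyper` (upper-tail hypergeometric), `odds_ratio` and `p_fisher`
#'   (two-tailed) on the induced 2x2 table.
#' @export
geneset_enrichment <- function(query, annotated, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query); annotated <- unique(annotated)
  if (!all(query %in% universe) || !all(annotated %in% universe))
    stop("query and annotated must be subsets of the universe")
  N <- length(universe); n <- length(query); K <- length(annotated)
  k <- length(intersect(query, annotated))
  expected <- n * K / N
  a <- k; b <- n - k; c <- K - k; d <- N - n - K + k
  fe <- fisher_exact_2x2(a, b, c, d)
  data.frame(overlap = k, expected = expected,
             fold = if (expected > 0) k / expected else NA_real_,
             p_hyper = hypergeom_upper_tail(k, n, K, N),
             odds_ratio = fe$odds_ratio, p_fisher = fe$p)
}

#' Directional association of two differential-expression tables
#'
#' Restricts to genes significant in both tables (`fdr < fdr_cut`),
#' cross-tabulates direction (up/down by sign of log2FC) in A versus B,
#' and applies the 2x2 chi-squared test (no continuity correction).
#'
#' @param deA,deB `data.frame`s with columns `gene_id`, `log2FC`, `fdr`
#'   (see [read_dge_table()]).
#' @param fdr_cut significance cut applied to both tables (default 0.05).
#' @return List with `table` (2x2 matrix, rows = A up/down, cols = B
#'   up/down), `statistic`, `p`, `odds_ratio`, `n_genes`. With fewer than
#'   two shared significant genes, or a zero margin, `statistic` is `NA`
#'   and `p` is 1.
#' @export
directional_association <- function(deA, deB, fdr_cut = 0.05) {
  sigA <- deA[!is.na(deA$fdr) & deA$fdr < fdr_cut, ]
  sigB <- deB[!is.na(deB$fdr) & deB$fdr < fdr_cut, ]
  shared <- intersect(sigA$gene_id, sigB$gene_id)
  upA <- sigA$log2FC[match(shared, sigA$gene_id)] > 0
  upB <- sigB$log2FC[match(shared, sigB$gene_id)] > 0
  tab <- matrix(c(sum(upA & upB), sum(upA & !upB),
                  sum(!upA & upB), sum(!upA & !upB)),
                nrow = 2, byrow = TRUE,
                dimnames = list(A = c("up", "down"), B = c("up", "down")))
  if (length(shared) < 2) {
    return(list(table = tab, statistic = NA_real_, p = 1,
                odds_ratio = NA_real_, n_genes = length(shared)))
  }
  cs <- chi_squared_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  or <- if (tab[1, 2] * tab[2, 1] > 0) tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
        else if (tab[1, 1] * tab[2, 2] > 0) Inf else NaN
  list(table = tab, statistic = cs$statistic, p = cs$p, odds_ratio = or,
       n_genes = length(shared))
}

#' Correlation of log2 fold changes between two DE tables
#'
#' Pearson and Spearman correlation of log2FC over genes detected in both
#' tables.
#'
#' @inheritParams directional_association
#' @return List with `pearson`, `spearman`, `n_genes`; `NA` correlations
#'   on zero-variance input.
#' @export
fc_correlation <- function(deA, deB) {
  dA <- deA[isTRUE_vec(deA$detected), ]
  dB <- deB[isTRUE_vec(deB$detected), ]
  shared <- intersect(dA$gene_id, dB$gene_id)
  if (length(shared) < 3) stop("need at least 3 shared detected genes")
  x <- dA$log2FC[match(shared, dA$gene_id)]
  y <- dB$log2FC[match(shared, dB$gene_id)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_, n_genes = length(shared)))
  list(pearson = stats::cor(x, y, method = "pearson"),
       spearman = stats::cor(x, y, method = "spearman"),
       n_genes = length(shared))
}

isTRUE_vec <- function(x) if (is.null(x)) TRUE else !is.na(x) & x

#' Genes co-regulated across several DE tables
#'
#' Thin set-intersection utility: genes significant (`fdr < fdr_cut`) with
#' the requested direction in every supplied table.
#'
#' @param de_tables list of DE `data.frame`s.
#' @param direction `"up"`, `"down"` or `"any"`.
#' @param fdr_cut significance cut (default 0.05).
#' @return Character vector of gene ids.
#' @export
coregulated_genes <- function(de_tables, direction = c("up", "down", "any"),
                              fdr_cut = 0.05) {
  direction <- match.arg(direction)
  stopifnot(length(de_tables) > 0)
  sets <- lapply(de_tables, function(de) {
    sig <- !is.na(de$fdr) & de$fdr < fdr_cut
    sig <- sig & switch(direction,
                        up = de$log2FC > 0,
                        down = de$log2FC < 0,
                        any = TRUE)
    de$gene_id[sig]
  })
  Reduce(intersect, sets)
}
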