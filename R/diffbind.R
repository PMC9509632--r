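## Windowed differential-abundance testing between two conditions over
## consensus peak regions: abundance filtering, loess MA normalization,
## moderated negative-binomial quasi-likelihood testing, region merging
## with a representative p, and BH FDR.

#' Region x sample count matrix
#'
#' @param regions `GRanges`, one per row of `counts`.
#' @param counts non-negative integer matrix, regions x samples.
#' @param condition condition label per sample (exactly two levels for
#'   testing).
#' @param lib_size genome-wide total counts per sample (not restricted to
#'   the regions).
#' @return Object of class `region_count_matrix`.
#' @export
region_count_matrix <- function(regions, counts, condition, lib_size) {
  counts <- as.matrix(counts)
  if (length(regions) != nrow(counts)) stop("one count row per region required")
  if (length(condition) != ncol(counts)) stop("one condition label per sample required")
  if (length(lib_size) != ncol(counts)) stop("one library size per sample required")
  if (any(lib_size <= 0)) stop("library sizes must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(regions = regions, counts = counts,
                 condition = as.character(condition),
                 lib_size = as.numeric(lib_size)),
            class = "region_count_matrix")
}

#' @export
print.region_count_matrix <- function(x, ...) {
  cat(sprintf("region_count_matrix: %d regions x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$condition), collapse = " vs ")))
  invisible(x)
}

#' Consensus peak set across conditions
#'
#' Flattened union of the per-condition (replicate-intersected, filtered)
#' peak sets.
#'
#' @param regions_by_condition list of `GRanges`, one per condition.
#' @return Flattened `GRanges`.
#' @export
build_consensus <- function(regions_by_condition) {
  stopifnot(is.list(regions_by_condition), length(regions_by_condition) > 0)
  flatten_intervals(do.call(c, unname(regions_by_condition)))
}

## log2 counts-per-million with prior count 2:
## log2((y + prior) / (lib + 2 * prior) * 1e6)
log2_cpm <- function(counts, lib_size, prior = 2) {
  t(log2(t(counts + prior) / (lib_size + 2 * prior) * 1e6))
}

#' Average log2CPM per region
#' @param m a [region_count_matrix()].
#' @param prior prior count (default 2).
#' @return Numeric vector, mean over samples of per-sample log2CPM.
#' @export
ave_log2_cpm <- function(m, prior = 2) {
  rowMeans(log2_cpm(m$counts, m$lib_size, prior))
}

#' Remove low-abundance regions
#'
#' Regions with average log2CPM strictly below the cutoff are removed
#' (a region sitting exactly at the cutoff is retained).
#'
#' @param m a [region_count_matrix()].
#' @param min_avg_log2cpm abundance cutoff (default -3).
#' @return Filtered [region_count_matrix()]; the kept-row indices are in
#'   attribute `kept`.
#' @export
filter_low_abundance <- function(m, min_avg_log2cpm = -3) {
  stopifnot(inherits(m, "region_count_matrix"))
  a <- ave_log2_cpm(m)
  keep <- a >= min_avg_log2cpm
  out <- region_count_matrix(m$regions[keep], m$counts[keep, , drop = FALSE],
                             m$condition, m$lib_size)
  attr(out, "kept") <- which(keep)
  out
}

#' Loess MA normalization offsets
#'
#' For each sample, M (the sample's log2CPM minus the reference, the row
#' mean of log2CPM across samples, i.e. the log2 geometric-mean CPM) is
#' regressed on A (average log2CPM) by loess; the fitted trend is the
#' sample's per-region offset, so that offset-adjusted M has approximately
#' zero trend and the MA distribution is symmetric under the null of no
#' change.
#'
#' @param m a [region_count_matrix()] with at least 2 samples and regions.
#' @param span loess span (default 0.4).
#' @param degree loess degree (default 1).
#' @return Regions x samples offset matrix on the log2 scale.
#' @export
loess_offsets <- function(m, span = 0.4, degree = 1) {
  stopifnot(inherits(m, "region_count_matrix"))
  if (ncol(m$counts) < 2) stop("at least two samples are required")
  if (nrow(m$counts) < 2) stop("at least two regions are required")
  L <- log2_cpm(m$counts, m$lib_size)
  A <- rowMeans(L)
  off <- matrix(0, nrow(L), ncol(L), dimnames = dimnames(L))
  for (s in seq_len(ncol(L))) {
    M <- L[, s] - A
    fit <- stats::loess(M ~ A, span = span, degree = degree,
                        family = "gaussian")
    off[, s] <- stats::predict(fit, A)
  }
  off
}

## Vectorised Newton scoring for the NB log-link model with per-sample
## offsets and fixed per-region dispersion phi. Solves, per region, the
## one-parameter MLE for each column-group in `groups` (a list of sample
## index vectors). Returns the beta matrix (regions x groups).
nb_fit_groups <- function(y, logN, phi, groups, iter = 50, tol = 1e-10) {
  nr <- nrow(y)
  beta <- matrix(0, nr, length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    Ng <- exp(logN[, idx, drop = FALSE])
    yg <- y[, idx, drop = FALSE]
    b <- log((rowSums(yg) + 1e-8) / rowSums(Ng))
    for (it in seq_len(iter)) {
      mu <- exp(b) * Ng
      w <- 1 + phi * mu
      score <- rowSums((yg - mu) / w)
      info <- rowSums(mu / w)
      step <- score / pmax(info, 1e-12)
      step <- pmax(pmin(step, 5), -5)
      b <- pmax(pmin(b + step, 50), -50)
      if (max(abs(step)) < tol) break
    }
    beta[, g] <- b
  }
  beta
}

## NB log-likelihood (dropping terms free of mu) with fixed phi;
## phi = 0 reduces to Poisson.
nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-12)
  phi <- rep_len(phi, nrow(y))          # per-region dispersion
  ll <- y * log(mu) - mu                 # Poisson rows (phi == 0)
  pos <- phi > 0
  if (any(pos)) {
    yp <- y[pos, , drop = FALSE]; mp <- mu[pos, , drop = FALSE]
    php <- phi[pos]                      # recycles down columns (by region)
    ll[pos, ] <- yp * log(mp) - (yp + 1 / php) * log1p(php * mp)
  }
  rowSums(ll)
}

#' Differential-abundance test between two conditions
#'
#' Per-region negative-binomial model with offset-adjusted effective
#' library sizes. Dispersion is estimated by method of moments per region,
#' smoothed by a loess trend on abundance, and the trended dispersion is
#' used in the GLM fits. The condition effect is tested by a moderated
#' quasi-likelihood F-test: the likelihood-ratio statistic is scaled by an
#' empirical-Bayes squeezed quasi-dispersion (deviance-based, shrunk
#' toward its abundance trend) and referred to an F distribution whose
#' denominator df is the residual df plus the estimated (or supplied)
#' prior df.
#'
#' @param m a [region_count_matrix()] with exactly two condition levels.
#' @param offsets optional regions x samples log2-scale offsets from
#'   [loess_offsets()].
#' @param prior.df prior df for the quasi-dispersion squeeze; `NULL`
#'   (default) estimates it empirically via [limma::squeezeVar()].
#' @param trend.span span of the dispersion loess trend (default 0.5).
#' @return `data.frame` with per-region `log2FC` (second condition level
#'   relative to the first, in order of appearance), `p`, `A` (average
#'   log2CPM), `dispersion` (trended NB dispersion) and `ql_disp`
#'   (posterior quasi-dispersion).
#' @export
test_differential <- function(m, offsets = NULL, prior.df = NULL,
                              trend.span = 0.5) {
  stopifnot(inherits(m, "region_count_matrix"))
  conds <- unique(m$condition)
  if (length(conds) != 2) stop("exactly two conditions are required")
  y <- m$counts
  S <- ncol(y); nr <- nrow(y)
  if (nr < 2) stop("at least two regions are required")
  df_resid <- S - 2
  if (df_resid < 1) stop("at least three samples are required for testing")
  logN <- matrix(log(m$lib_size), nr, S, byrow = TRUE)
  if (!is.null(offsets)) {
    if (!all(dim(offsets) == dim(y))) stop("offsets must match the count matrix")
    logN <- logN + log(2) * offsets
  }
  groups <- lapply(conds, function(cc) which(m$condition == cc))
  A <- ave_log2_cpm(m)

  # 1. Poisson group fit for method-of-moments dispersion
  beta0 <- nb_fit_groups(y, logN, phi = 0, groups)
  mu0 <- matrix(0, nr, S)
  for (g in seq_along(groups))
    mu0[, groups[[g]]] <- exp(beta0[, g]) * exp(logN[, groups[[g]], drop = FALSE])
  mu0 <- pmax(mu0, 1e-8)
  phi_mom <- rowSums(((y - mu0)^2 - mu0) / mu0^2) / df_resid

  # 2. loess trend of dispersion on abundance
  tr_fit <- stats::loess(phi_mom ~ A, span = trend.span, degree = 1)
  phi_trend <- pmin(pmax(stats::predict(tr_fit, A), 1e-6), 10)

  # 3. full (per-group) and null (common) fits at the trended dispersion
  beta_full <- nb_fit_groups(y, logN, phi_trend, groups)
  beta_null <- nb_fit_groups(y, logN, phi_trend, list(seq_len(S)))
  mu_full <- matrix(0, nr, S)
  for (g in seq_along(groups))
    mu_full[, groups[[g]]] <- exp(beta_full[, g]) * exp(logN[, groups[[g]], drop = FALSE])
  mu_null <- exp(beta_null[, 1]) * exp(logN)
  ll_full <- nb_loglik(y, mu_full, phi_trend)
  ll_null <- nb_loglik(y, mu_null, phi_trend)
  lr <- pmax(2 * (ll_full - ll_null), 0)

  # 4. deviance-based quasi-dispersion, squeezed empirically
  ll_sat <- nb_loglik(y, pmax(y, 1e-12), phi_trend)
  dev <- pmax(2 * (ll_sat - ll_full), 0)
  s2 <- dev / df_resid
  if (is.null(prior.df)) {
    if (all(s2 < 1e-8)) {           # degenerate (e.g. identical samples)
      var_post <- rep(1, nr); df_prior <- Inf
    } else {
      sq <- limma::squeezeVar(s2, df = df_resid, covariate = A, robust = FALSE)
      var_post <- sq$var.post
      df_prior <- sq$df.prior
    }
  } else {
    s2_fit <- stats::loess(s2 ~ A, span = trend.span, degree = 1)
    s2_trend <- pmax(stats::predict(s2_fit, A), 1e-8)
    var_post <- (prior.df * s2_trend + df_resid * s2) / (prior.df + df_resid)
    df_prior <- prior.df
  }
  df_total <- df_prior + df_resid
  f_stat <- lr / pmax(var_post, 1e-12)
  p <- stats::pf(f_stat, 1, df_total, lower.tail = FALSE)

  data.frame(log2FC = (beta_full[, 2] - beta_full[, 1]) / log(2),
             p = p, A = A, dispersion = phi_trend, ql_disp = var_post)
}

#' Merge nearby tested regions and compute FDR
#'
#' Applies [merge_nearby_regions()] (gap at most `max_gap` bp, merged
#' width at most `max_width` bp, representative p = minimum over members),
#' takes the log2FC of the minimum-p member, then Benjamini-Hochberg
#' adjusts across the merged regions. Direction is the sign of log2FC
#' where `fdr < fdr_threshold`, otherwise `stable`.
#'
#' @param regions `GRanges` of tested regions.
#' @param p,log2FC aligned per-region vectors.
#' @param max_gap,max_width merging parameters in bp (defaults 500, 5000).
#' @param fdr_threshold significance threshold (default 0.05).
#' @return `GRanges` of merged regions with metadata columns `log2FC`,
#'   `p`, `fdr`, `direction`.
#' @export
merge_and_adjust <- function(regions, p, log2FC, max_gap = 500,
                             max_width = 5000, fdr_threshold = 0.05) {
  if (length(p) != length(regions) || length(log2FC) != length(regions))
    stop("p and log2FC must align with regions")
  merged <- merge_nearby_regions(regions, p, max_gap = max_gap,
                                 max_width = max_width)
  lfc <- log2FC[S4Vectors::mcols(merged)$which_min]
  fdr <- stats::p.adjust(S4Vectors::mcols(merged)$p, method = "BH")
  direction <- ifelse(fdr < fdr_threshold,
                      ifelse(lfc > 0, "increasing", "decreasing"),
                      "stable")
  S4Vectors::mcols(merged)$log2FC <- lfc
  S4Vectors::mcols(merged)$fdr <- fdr
  S4Vectors::mcols(merged)$direction <- direction
  merged
}

#' Full differential-abundance pipeline
#'
#' Convenience wrapper: abundance filter, loess offsets, moderated QL
#' test, merge and BH adjust.
#'
#' @inheritParams test_differential
#' @inheritParams merge_and_adjust
#' @param min_avg_log2cpm abundance cutoff (default -3).
#' @param normalize apply loess MA normalization (default TRUE).
#' @return List with `merged` (the [merge_and_adjust()] output), `table`
#'   (per-region test results) and `filtered` (the filtered matrix).
#' @export
differential_abundance <- function(m, min_avg_log2cpm = -3, normalize = TRUE,
                                   prior.df = NULL, max_gap = 500,
                                   max_width = 5000, fdr_threshold = 0.05) {
  mf <- filter_low_abundance(m, min_avg_log2cpm)
  off <- if (normalize) loess_offsets(mf) else NULL
  tab <- test_differential(mf, offsets = off, prior.df = prior.df)
  merged <- merge_and_adjust(mf$regions, tab$p, tab$log2FC,
                             max_gap = max_gap, max_width = max_width,
                             fdr_threshold = fdr_threshold)
  list(merged = merged, table = tab, filtered = mf)
}
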