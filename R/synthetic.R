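## Synthetic-data generator: produces every input the pipeline consumes,
## with recorded ground truth, so each stage is testable without any
## external data. Emulates the study design: 200-bp binned two-condition
## tracks driven by a hidden Markov state path with per-state Bernoulli
## feature emissions, Poisson read counts over present bins, planted
## condition-specific state switches in contiguous blocks, factor peak
## catalogs with planted odds ratios, and NB count matrices with planted
## log2 fold changes.

#' Default block-structured emission matrix
#'
#' Deterministic K x F matrix against a 0.05 background: the first F
#' states each carry one strong feature (0.9), subsequent states each
#' carry a distinct feature pair (0.85 / 0.6), so all rows are
#' well-separated and recoverable. Requires `K <= F + choose(F, 2)`.
#'
#' @param K states; @param F features.
#' @return K x F matrix.
#' @export
default_emissions <- function(K, F) {
  pairs <- utils::combn(F, 2)
  if (K > F + ncol(pairs))
    stop("default emission design supports at most F + choose(F, 2) states")
  E <- matrix(0.05, K, F)
  for (k in seq_len(K)) {
    if (k <= F) {
      E[k, k] <- 0.9
    } else {
      E[k, pairs[1, k - F]] <- 0.85
      E[k, pairs[2, k - F]] <- 0.6
    }
  }
  E
}

#' Synthetic study scenario
#'
#' Holds every parameter of the generators. Defaults reflect the study
#' design the package targets: a 3 x 1 Mb toy genome at 200-bp bins
#' (5,000 bins per chromosome), 8 hidden states over 6 features with mean
#' state dwell 20 bins, Poisson depth 10 reads per present bin over
#' background rate 1, 5% of bins switching state between conditions in
#' contiguous blocks, and an NB count design of 2 vs 2 samples at library
#' size 1e6 with dispersion 0.05 and 10% planted 4-fold regions.
#'
#' @param genome named chromosome lengths (default 3 chromosomes x 1 Mb).
#' @param bin_size bin width in bp (default 200).
#' @param K_true number of hidden states (default 8).
#' @param n_features number of features F (default 6).
#' @param E_true K x F emission matrix (default [default_emissions()]).
#' @param mean_dwell mean state run length in bins (default 20).
#' @param depth mean reads per present bin (default 10).
#' @param background background Poisson rate per bin (default 1).
#' @param diff_state_fraction fraction of bins whose state switches in
#'   condition B (default 0.05), in geometric blocks of mean
#'   `diff_block_bins` bins (default 10).
#' @param n_factors factors in the simulated catalog (default 20).
#' @param planted_or planted odds ratio per factor (recycled; default 3).
#' @param base_rate per-site overlap probability in the negative class
#'   (default 0.1).
#' @param n_regions regions in the NB count simulation (default 2000).
#' @param planted_frac fraction of regions with a planted effect
#'   (default 0.1, half up / half down).
#' @param planted_log2fc planted |log2FC| (default 2).
#' @param dispersion NB dispersion (default 0.05).
#' @param lib_sizes per-sample library sizes (default 4 x 1e6).
#' @param conditions sample condition labels (default A,A,B,B).
#' @param seed integer seed recorded in all outputs.
#' @return Object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(genome = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                               bin_size = 200, K_true = 8, n_features = 6,
                               E_true = NULL, mean_dwell = 20, depth = 10,
                               background = 1, diff_state_fraction = 0.05,
                               diff_block_bins = 10,
                               n_factors = 20, planted_or = 3, base_rate = 0.1,
                               n_regions = 2000, planted_frac = 0.1,
                               planted_log2fc = 2, dispersion = 0.05,
                               lib_sizes = rep(1e6, 4),
                               conditions = c("A", "A", "B", "B"),
                               seed = 1L) {
  if (is.null(E_true)) E_true <- default_emissions(K_true, n_features)
  E_true <- as.matrix(E_true)
  stopifnot(nrow(E_true) == K_true, ncol(E_true) == n_features,
            all(E_true >= 0 & E_true <= 1), mean_dwell > 1, depth > 0,
            diff_state_fraction >= 0, diff_state_fraction <= 1,
            length(lib_sizes) == length(conditions))
  structure(list(genome = genome_sizes(genome), bin_size = bin_size,
                 K_true = K_true, n_features = n_features, E_true = E_true,
                 mean_dwell = mean_dwell, depth = depth,
                 background = background,
                 diff_state_fraction = diff_state_fraction,
                 diff_block_bins = diff_block_bins,
                 n_factors = n_factors, planted_or = planted_or,
                 base_rate = base_rate, n_regions = n_regions,
                 planted_frac = planted_frac,
                 planted_log2fc = planted_log2fc, dispersion = dispersion,
                 lib_sizes = lib_sizes, conditions = conditions,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

markov_path <- function(n, K, A, pi) {
  path <- integer(n)
  path[1] <- sample.int(K, 1, prob = pi)
  for (t in 2:n) path[t] <- sample.int(K, 1, prob = A[path[t - 1], ])
  path
}

#' Simulate two-condition binned chromatin data
#'
#' Draws a hidden Markov state path per chromosome (self-transition
#' `1 - 1/mean_dwell`, off-diagonal uniform), copies it for condition B
#' with contiguous blocks (geometric length, mean `diff_block_bins`)
#' reassigned to a different random state until `diff_state_fraction` of
#' bins is switched, emits per-feature presence by Bernoulli draws from
#' the state's emission row, and overlays Poisson counts (`depth` per
#' present bin over `background` everywhere). Controls are pure-background
#' Poisson tracks. Deterministic for a fixed scenario seed.
#'
#' @param s a [synthetic_scenario()].
#' @return List with `tracks` (`condition -> feature -> binned_track` of
#'   counts), `controls` (`condition -> binned_track`), `presence`
#'   (`condition -> feature -> binary_calls`, the true Bernoulli draws),
#'   `truth_segmentation` (a `segmentation` of the true paths),
#'   `truth_model` (the true [emission_model()]) and `scenario`.
#' @export
simulate_chromatin <- function(s) {
  stopifnot(inherits(s, "synthetic_scenario"))
  set.seed(s$seed)
  K <- s$K_true; F <- s$n_features
  A <- matrix(if (K > 1) (1 / s$mean_dwell) / (K - 1) else 0, K, K)
  diag(A) <- if (K > 1) 1 - 1 / s$mean_dwell else 1
  pi <- rep(1 / K, K)
  feats <- paste0("feat", seq_len(F))
  n_bins <- as.integer(ceiling(s$genome / s$bin_size))
  names(n_bins) <- names(s$genome)

  paths <- list(A = list(), B = list())
  for (chr in names(n_bins)) {
    n <- n_bins[[chr]]
    pA <- markov_path(n, K, A, pi)
    pB <- pA
    quota <- round(s$diff_state_fraction * n)
    switched <- 0L
    while (switched < quota) {
      len <- min(stats::rgeom(1, 1 / s$diff_block_bins) + 1L, quota - switched)
      start <- sample.int(n - len + 1L, 1)
      idx <- start:(start + len - 1L)
      new_state <- if (K > 1) sample(setdiff(seq_len(K), pB[start]), 1) else 1L
      pB[idx] <- new_state
      switched <- switched + len
    }
    paths$A[[chr]] <- pA; paths$B[[chr]] <- pB
  }

  tracks <- list(); controls <- list(); presence <- list()
  for (cond in c("A", "B")) {
    ctrl_vals <- list()
    for (chr in names(n_bins)) ctrl_vals[[chr]] <- stats::rpois(n_bins[[chr]], s$background)
    controls[[cond]] <- binned_track(ctrl_vals, feature = "control",
                                     condition = cond, bin_size = s$bin_size)
    for (f in seq_len(F)) {
      vals <- list(); calls <- list()
      for (chr in names(n_bins)) {
        st <- paths[[cond]][[chr]]
        pres <- stats::rbinom(length(st), 1, s$E_true[st, f]) == 1L
        cnt <- stats::rpois(length(st), s$background) +
          ifelse(pres, stats::rpois(length(st), s$depth), 0L)
        vals[[chr]] <- as.numeric(cnt); calls[[chr]] <- pres
      }
      tracks[[cond]][[feats[f]]] <- binned_track(vals, feature = feats[f],
                                                 condition = cond,
                                                 bin_size = s$bin_size)
      presence[[cond]][[feats[f]]] <- binary_calls(calls, feature = feats[f],
                                                   condition = cond,
                                                   bin_size = s$bin_size)
    }
  }
  truth_seg <- structure(list(states = paths, K = K, bin_size = s$bin_size),
                         class = "segmentation")
  truth_model <- emission_model(s$E_true, A, pi, feats, bin_size = s$bin_size,
                                seed = s$seed)
  list(tracks = tracks, controls = controls, presence = presence,
       truth_segmentation = truth_seg, truth_model = truth_model,
       scenario = s)
}

#' Simulate a factor peak catalog with planted odds ratios
#'
#' For each factor, positive-class sites are overlapped with probability
#' `p1` and negative-class sites with probability `p0 = base_rate`, where
#' `p1` solves `odds(p1)/odds(p0) = planted_or`. Factor peaks are placed
#' as the central half of each overlapped site. With `base_rate = 0` the
#' planted odds ratio must be `Inf` (positive-class rate 0.3 is used);
#' a finite odds ratio with `base_rate = 0`, or any combination pushing
#' `p1` out of (0, 1), is a validation error.
#'
#' @param s a [synthetic_scenario()] (`n_factors`, `planted_or`,
#'   `base_rate`, `seed`).
#' @param positive,negative disjoint `GRanges` site classes.
#' @return List with `catalog` (named list of `GRanges`) and `truth`
#'   (`data.frame` of factor, planted_or, p0, p1, and the realized 2x2
#'   cells a,b,c,d), plus `membership` (per-factor list of logical
#'   vectors over positive and negative sites).
#' @export
simulate_factor_catalog <- function(s, positive, negative) {
  stopifnot(inherits(s, "synthetic_scenario"))
  set.seed(s$seed + 1L)
  or <- rep(s$planted_or, length.out = s$n_factors)
  p0 <- s$base_rate
  p1 <- vapply(or, function(r) {
    if (p0 == 0) {
      if (!is.infinite(r)) stop("finite planted OR unattainable at base_rate 0")
      return(0.3)
    }
    if (is.infinite(r)) stop("infinite planted OR unattainable at base_rate > 0")
    odds1 <- r * p0 / (1 - p0)
    odds1 / (1 + odds1)
  }, 0)
  if (any(p1 <= 0 & or > 0) || any(p1 >= 1))
    stop("planted OR unattainable for the given base rate")
  mid_half <- function(gr) {
    w <- GenomicRanges::width(gr)
    s1 <- GenomicRanges::start(gr) + w %/% 4
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                           IRanges::IRanges(s1, width = pmax(w %/% 2, 1L)))
  }
  catalog <- list(); membership <- list(); rows <- list()
  for (i in seq_len(s$n_factors)) {
    nm <- sprintf("factor%02d", i)
    mp <- stats::rbinom(length(positive), 1, p1[i]) == 1L
    mn <- stats::rbinom(length(negative), 1, p0) == 1L
    peaks <- c(mid_half(positive[mp]), mid_half(negative[mn]))
    catalog[[nm]] <- flatten_intervals(peaks)
    membership[[nm]] <- list(positive = mp, negative = mn)
    rows[[nm]] <- data.frame(factor = nm, planted_or = or[i], p0 = p0,
                             p1 = p1[i], a = sum(mp),
                             b = length(positive) - sum(mp),
                             c = sum(mn), d = length(negative) - sum(mn))
  }
  list(catalog = catalog, truth = do.call(rbind, rows),
       membership = membership, scenario = s)
}

#' Simulate an NB region count matrix with planted fold changes
#'
#' Regions are laid down as 400-bp intervals every 1 kb along the
#' scenario genome (gaps of 600 bp, so merging never joins distinct
#' regions). Baseline relative abundances are gamma-distributed and
#' normalized; counts are NB with the scenario dispersion and library
#' sizes. A `planted_frac` subset of regions receives `planted_log2fc` in
#' condition-B samples, half up and half down.
#'
#' @param s a [synthetic_scenario()].
#' @param null if TRUE, no effects are planted (type-I error studies).
#' @return List with `matrix` (a [region_count_matrix()]) and `truth`
#'   (`data.frame` with per-region `log2fc` and `label` in
#'   up/down/stable).
#' @export
simulate_counts <- function(s, null = FALSE) {
  stopifnot(inherits(s, "synthetic_scenario"))
  set.seed(s$seed + 2L)
  n <- s$n_regions
  # tile regions across chromosomes: 400 bp wide, 1 kb apart
  per_chrom <- floor(s$genome / 1000)
  all_chroms <- rep(names(s$genome), times = per_chrom)
  if (length(all_chroms) < n) stop("scenario genome too small for n_regions")
  all_offs <- unlist(lapply(names(s$genome), function(ch) seq_len(per_chrom[[ch]]) - 1))
  chroms <- all_chroms[seq_len(n)]
  offs <- all_offs[seq_len(n)]
  regions <- gintervals(chroms, offs * 1000, offs * 1000 + 400)
  o <- order(as.character(GenomicRanges::seqnames(regions)), GenomicRanges::start(regions))
  regions <- regions[o]

  rel <- stats::rgamma(n, shape = 2, rate = 2)
  rel <- rel / sum(rel)
  lfc <- numeric(n)
  if (!null && s$planted_frac > 0) {
    n_eff <- round(s$planted_frac * n)
    idx <- sample.int(n, n_eff)
    half <- seq_len(n_eff) <= n_eff / 2
    lfc[idx[half]] <- s$planted_log2fc
    lfc[idx[!half]] <- -s$planted_log2fc
  }
  S <- length(s$conditions)
  condB <- unique(s$conditions)[2]
  counts <- matrix(0L, n, S)
  for (j in seq_len(S)) {
    mu <- rel * s$lib_sizes[j] * 2^(lfc * (s$conditions[j] == condB))
    counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / s$dispersion)
  }
  colnames(counts) <- paste0(s$conditions, seq_len(S))
  label <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "stable"))
  list(matrix = region_count_matrix(regions, counts, s$conditions, s$lib_sizes),
       truth = data.frame(log2fc = lfc, label = label), scenario = s)
}
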