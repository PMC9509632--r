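# Brute-force oracles, kept deliberately independent of the package
# implementations they check.

# per-bp boolean coverage of a GRanges over a toy genome
cover_bits <- function(gr, genome) {
  bits <- lapply(genome, function(len) logical(len))
  for (i in seq_along(gr)) {
    chr <- as.character(GenomicRanges::seqnames(gr[i]))
    s <- GenomicRanges::start(gr[i]); e <- GenomicRanges::end(gr[i])
    bits[[chr]][s:e] <- TRUE
  }
  unlist(bits, use.names = FALSE)
}

# random interval set on a toy genome (BED-convention inputs)
random_intervals <- function(n, genome, max_width = 500) {
  chroms <- sample(names(genome), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(genome[[chroms[i]]] - w[i], 1) - 1L, 0L)
  gintervals(chroms, start, start + w, genome)
}

# upper-tail hypergeometric by direct combinatorial summation
# (log-scale binomial coefficients so that bp-scale populations work)
hyper_tail_direct <- function(k, n, K, N) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# two-sided Fisher p by margin-fixed enumeration
fisher_two_sided_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(support, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), 0)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-squared closed form (no continuity correction)
chisq_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Poisson upper tail P(X >= x) by direct summation
pois_tail_direct <- function(x, lambda, upto = 1000) {
  if (x <= 0) return(1)
  1 - sum(exp(-lambda) * lambda^(0:(x - 1)) / factorial(0:(x - 1)))
}

# greedy merge rule, re-stated directly from the contract
merge_oracle <- function(df, p, max_gap = 500, max_width = 5000) {
  # df: chrom, start, end (BED convention), sorted
  out <- list()
  cur <- NULL; cur_p <- NULL
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!is.null(cur) && row$chrom == cur$chrom &&
        (row$start - cur$end) <= max_gap &&
        (max(cur$end, row$end) - cur$start) <= max_width) {
      cur$end <- max(cur$end, row$end)
      cur_p <- min(cur_p, p[i])
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cbind(cur, p = cur_p)
      cur <- row; cur_p <- p[i]
    }
  }
  out[[length(out) + 1L]] <- cbind(cur, p = cur_p)
  do.call(rbind, out)
}

# exact HMM posterior by path enumeration (tiny sequences only)
posterior_enum <- function(X, E, A, pi) {
  T_ <- nrow(X); K <- nrow(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  w <- apply(paths, 1, function(path) {
    pr <- pi[path[1]]
    for (t in 2:T_) pr <- pr * A[path[t - 1], path[t]]
    for (t in 1:T_) {
      pr <- pr * prod(E[path[t], ]^X[t, ] * (1 - E[path[t], ])^(1 - X[t, ]))
    }
    pr
  })
  gamma <- matrix(0, T_, K)
  for (t in 1:T_) for (k in 1:K)
    gamma[t, k] <- sum(w[paths[, t] == k])
  gamma / rowSums(gamma)
}

# Benjamini-Hochberg by sort and cumulative minimum
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# best between/total SS over all 2-cluster partitions of a point set
kmeans2_exhaustive <- function(X) {
  n <- nrow(X)
  totss <- sum(scale(X, scale = FALSE)^2)
  best <- 0
  for (mask in 1:(2^(n - 1) - 1)) {
    g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(g) || all(g)) next
    wss <- sum(scale(X[g, , drop = FALSE], scale = FALSE)^2) +
      sum(scale(X[!g, , drop = FALSE], scale = FALSE)^2)
    best <- max(best, (totss - wss) / totss)
  }
  best
}

# binary-calls fixture builder
make_calls <- function(v, feature = "f", condition = "A", chrom = "chr1") {
  calls <- list(); calls[[chrom]] <- as.logical(v)
  binary_calls(calls, feature = feature, condition = condition)
}

make_track <- function(v, feature = "f", condition = "A", chrom = "chr1") {
  vals <- list(); vals[[chrom]] <- as.numeric(v)
  binned_track(vals, feature = feature, condition = condition)
}
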