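test_that("flatten merges overlapping intervals and conserves covered bp", {
  g <- genome_sizes(c(chrT = 10000))
  a <- gintervals(c("chrT", "chrT"), c(0, 5), c(10, 20), g)
  fl <- flatten_intervals(a)
  expect_equal(length(fl), 1L)
  expect_equal(GenomicRanges::start(fl), 1L)  # 0-based 0
  expect_equal(GenomicRanges::end(fl), 20L)

  expect_equal(length(flatten_intervals(GenomicRanges::GRanges())), 0L)
  expect_error(gintervals("chrT", 10, 10, g), "start >= end")

  set.seed(42)
  for (rep in 1:5) {
    r <- random_intervals(50, g, max_width = 400)
    fl <- flatten_intervals(r)
    bits <- cover_bits(r, g)
    expect_equal(sum(GenomicRanges::width(fl)), sum(bits))
    # flattened: no overlaps or abutments
    if (length(fl) > 1) {
      expect_true(all(GenomicRanges::start(fl)[-1] -
                        GenomicRanges::end(fl)[-length(fl)] > 1))
    }
  }
})

test_that("intersect_bp equals the per-bp boolean AND oracle", {
  g <- genome_sizes(c(chr1 = 60000, chr2 = 40000))
  a <- gintervals("chr1", 0, 100, g)
  b <- gintervals("chr1", 50, 150, g)
  expect_equal(intersect_bp(a, b), 50)
  expect_equal(intersect_bp(a, gintervals("chr2", 0, 100, g)), 0)

  set.seed(7)
  for (rep in 1:5) {
    A <- flatten_intervals(random_intervals(30, g))
    B <- flatten_intervals(random_intervals(40, g))
    expect_equal(intersect_bp(A, B), sum(cover_bits(A, g) & cover_bits(B, g)))
  }
})

test_that("fold_enrichment_bp matches oracle and self-enrichment identity", {
  g <- genome_sizes(c(chr1 = 1000))
  a <- gintervals("chr1", 0, 100, g)
  fe <- fold_enrichment_bp(a, a, g)
  expect_equal(fe$observed, 100)
  expect_equal(fe$expected, 10)
  expect_equal(fe$fold, 10)

  b <- gintervals("chr1", 500, 600, g)
  expect_equal(fold_enrichment_bp(a, b, g)$fold, 0)
  expect_true(is.na(fold_enrichment_bp(GenomicRanges::GRanges(), b, g)$fold))
  expect_equal(fold_enrichment_bp(GenomicRanges::GRanges(), b, g)$p, 1)

  g2 <- genome_sizes(c(chr1 = 60000, chr2 = 40000))
  set.seed(11)
  for (rep in 1:3) {
    A <- flatten_intervals(random_intervals(20, g2))
    B <- flatten_intervals(random_intervals(30, g2))
    fe <- fold_enrichment_bp(A, B, g2)
    bits_a <- cover_bits(A, g2); bits_b <- cover_bits(B, g2)
    obs <- sum(bits_a & bits_b)
    expect_equal(fe$observed, obs)
    expect_equal(fe$fold, obs / (sum(bits_a) * sum(bits_b) / 1e5))
    expect_equal(fe$p, hyper_tail_direct(obs, sum(bits_a), sum(bits_b), 1e5),
                 tolerance = 1e-9)
    # self-enrichment identity: fold(A, A) = G / |A|
    expect_equal(fold_enrichment_bp(A, A, g2)$fold, 1e5 / sum(bits_a))
  }
})

test_that("hypergeometric upper tail matches direct enumeration", {
  expect_equal(hypergeom_upper_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(4, 4, 10, 10), 1)
  expect_equal(hypergeom_upper_tail(4, 4, 5, 10),
               hyper_tail_direct(4, 4, 5, 10), tolerance = 1e-12)
  for (N in c(10, 25)) {
    for (i in 1:10) {
      K <- sample.int(N, 1); n <- sample.int(N, 1); k <- sample.int(min(n, K), 1)
      expect_equal(hypergeom_upper_tail(k, n, K, N),
                   hyper_tail_direct(k, n, K, N), tolerance = 1e-10)
    }
  }
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), "inconsistent")
})

test_that("Fisher 2x2 uses the sample odds ratio and exact two-sided p", {
  r <- fisher_exact_2x2(10, 10, 10, 10)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)

  expect_equal(fisher_exact_2x2(5, 0, 2, 3)$odds_ratio, Inf)
  expect_true(is.nan(fisher_exact_2x2(0, 5, 0, 3)$odds_ratio))
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")

  r <- fisher_exact_2x2(3, 1, 1, 3)
  expect_equal(r$odds_ratio, 9)
  expect_equal(r$p, fisher_two_sided_enum(3, 1, 1, 3), tolerance = 1e-10)

  set.seed(5)
  for (i in 1:20) {
    tb <- sample.int(12, 4, replace = TRUE) - 1L
    if (sum(tb) == 0) next
    r <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(r$p, fisher_two_sided_enum(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-7)
    # symmetry under simultaneous row and column swap
    r2 <- fisher_exact_2x2(tb[4], tb[3], tb[2], tb[1])
    expect_equal(r$p, r2$p, tolerance = 1e-12)
    # OR inverts under a single row swap
    r3 <- fisher_exact_2x2(tb[3], tb[4], tb[1], tb[2])
    if (is.finite(r$odds_ratio) && r$odds_ratio > 0)
      expect_equal(r3$odds_ratio, 1 / r$odds_ratio)
  }
})

test_that("chi-squared 2x2 equals the closed form, without correction", {
  r <- chi_squared_2x2(25, 25, 25, 25)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  r <- chi_squared_2x2(50, 0, 0, 50)
  expect_equal(r$statistic, chisq_closed_form(50, 0, 0, 50))

  expect_true(is.na(chi_squared_2x2(5, 3, 0, 0)$statistic))
  expect_equal(chi_squared_2x2(5, 3, 0, 0)$p, 1)

  set.seed(9)
  for (i in 1:20) {
    tb <- sample.int(30, 4, replace = TRUE)
    r <- chi_squared_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(r$statistic, chisq_closed_form(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
})

test_that("naive overlap peak set enforces >= 50% coverage per replicate", {
  g <- genome_sizes(c(chr1 = 100000))
  pooled <- gintervals("chr1", c(0, 1000, 2000), c(100, 1100, 2100), g)

  # identical replicate peaks retain everything
  expect_equal(length(naive_overlap_peakset(pooled, list(pooled, pooled))), 3L)

  # 49% coverage drops the peak, exactly 50% keeps it (inclusive boundary)
  r49 <- gintervals("chr1", 0, 49, g)
  r50 <- gintervals("chr1", 0, 50, g)
  pk <- gintervals("chr1", 0, 100, g)
  expect_equal(length(naive_overlap_peakset(pk, list(r49))), 0L)
  expect_equal(length(naive_overlap_peakset(pk, list(r50))), 1L)

  # coverage is against the union of a replicate's peaks
  r_split <- gintervals(c("chr1", "chr1"), c(0, 30), c(25, 55), g)
  expect_equal(length(naive_overlap_peakset(pk, list(r_split))), 1L)

  # monotone: adding a replicate never grows the output
  set.seed(13)
  reps <- lapply(1:3, function(i) flatten_intervals(random_intervals(40, g)))
  outs <- lapply(1:3, function(k) naive_overlap_peakset(pooled, reps[seq_len(k)]))
  expect_true(all(lengths(outs) == cummin(lengths(outs))))
  for (k in 2:3)
    expect_true(all(GenomicRanges::start(outs[[k]]) %in%
                      GenomicRanges::start(outs[[k - 1]])))
  expect_error(naive_overlap_peakset(pooled, list()), "at least one")
})

test_that("merge_nearby_regions follows the greedy gap/width rule", {
  g <- genome_sizes(c(chr1 = 100000))
  one <- gintervals("chr1", 100, 200, g)
  m <- merge_nearby_regions(one, 0.04)
  expect_equal(length(m), 1L)
  expect_equal(m$p, 0.04)

  # gap of exactly 500 merges (inclusive)
  two <- gintervals("chr1", c(0, 600), c(100, 700), g)
  m <- merge_nearby_regions(two, c(0.5, 0.01))
  expect_equal(length(m), 1L)
  expect_equal(m$p, 0.01)

  # gap of 501 does not
  two <- gintervals("chr1", c(0, 601), c(100, 701), g)
  expect_equal(length(merge_nearby_regions(two, c(0.5, 0.01))), 2L)

  # worked chain: [0,100) p=.04, [550,650) p=.001, [700,800) p=.2 -- the
  # greedy rule chains all three (gaps 450 and 50, total width 800 < cap)
  chain <- gintervals("chr1", c(0, 550, 700), c(100, 650, 800), g)
  m <- merge_nearby_regions(chain, c(0.04, 0.001, 0.2))
  df <- data.frame(chrom = "chr1", start = c(0, 550, 700), end = c(100, 650, 800))
  oracle <- merge_oracle(df, c(0.04, 0.001, 0.2))
  expect_equal(GenomicRanges::start(m) - 1L, oracle$start)
  expect_equal(GenomicRanges::end(m), oracle$end)
  expect_equal(m$p, oracle$p)
  expect_equal(length(m), 1L)
  expect_equal(m$p, 0.001)

  # a single region wider than the cap passes through
  wide <- gintervals("chr1", c(0, 6000), c(5500, 6100), g)
  m <- merge_nearby_regions(wide, c(0.1, 0.2))
  expect_equal(length(m), 2L)

  # randomized agreement with the directly-stated greedy oracle,
  # plus the width-cap invariant
  set.seed(21)
  for (rep in 1:10) {
    n <- 30
    s <- sort(sample.int(50000, n)) - 1L
    w <- sample.int(800, n, replace = TRUE)
    s <- cumsum(c(s[1], pmax(diff(s), 1)))  # keep sorted, distinct
    regions <- gintervals("chr1", s, s + w, g)
    o <- order(GenomicRanges::start(regions))
    regions <- regions[o]
    p <- runif(n)
    m <- merge_nearby_regions(regions, p)
    df <- data.frame(chrom = "chr1",
                     start = GenomicRanges::start(regions) - 1L,
                     end = GenomicRanges::end(regions))
    oracle <- merge_oracle(df, p)
    expect_equal(GenomicRanges::start(m) - 1L, oracle$start)
    expect_equal(GenomicRanges::end(m), oracle$end)
    expect_equal(m$p, oracle$p)
    single_wide <- GenomicRanges::width(regions)[match(
      GenomicRanges::start(m), GenomicRanges::start(regions))] > 5000
    expect_true(all(GenomicRanges::width(m) <= 5000 |
                      (m$n_members == 1 & !is.na(single_wide) & single_wide)))
  }
})

test_that("enhancer classification applies distance and set rules", {
  g <- genome_sizes(c(chr1 = 1000000))
  tss <- data.frame(gene_id = "g1", chrom = "chr1", position = 500000,
                    strand = "+")
  atac <- gintervals("chr1", c(100000, 496000, 520000), c(110000, 504000, 521000), g)
  se <- gintervals("chr1", 100000, 115000, g)

  peaks <- gintervals("chr1",
                      c(499000,   # covers the TSS
                        503001,   # edge distance 3001 -> typical (ATAC+)
                        105000,   # inside SE with ATAC
                        800000),  # nothing
                      c(501000, 504000, 106000, 801000), g)
  lab <- classify_enhancers(peaks, atac, se, tss)
  lab <- lab[order(GenomicRanges::start(peaks))]  # gintervals sorts; align
  peaks_sorted <- sort(peaks)
  expect_equal(
    lab[match(c(105001, 499001, 503002, 800001),
              GenomicRanges::start(peaks_sorted))],
    c("super_enhancer_constituent", "promoter_proximal",
      "typical_enhancer", "other"))

  # boundary: nearest-edge distance exactly 3000 is promoter-proximal
  pk <- gintervals("chr1", 503000, 504000, g)
  expect_equal(classify_enhancers(pk, atac, se, tss), "promoter_proximal")
})
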