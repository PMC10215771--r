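test_that("window hit fractions are 1 for all-homozygous and 0 for all-het", {
  p <- roh_params()
  expect_equal(window_scan(rep(0L, 60), p), rep(1, 60))
  expect_equal(window_scan(rep(2L, 60), p), rep(1, 60))
  expect_equal(window_scan(rep(1L, 60), p), rep(0, 60))
  # shorter than one window: all-zero fractions
  expect_equal(window_scan(rep(0L, 49), p), rep(0, 49))
})

test_that("window hit fractions equal exhaustive window enumeration", {
  p <- roh_params()
  codes <- rep(0L, 120)
  codes[c(10, 55, 90)] <- 1L
  expect_equal(window_scan(codes, p), oracle_window_scan(codes, p))
  set.seed(21)
  for (rep in 1:10) {
    s <- sample(30:200, 1)
    codes <- sample(c(0L, 1L, 2L, NA), s, replace = TRUE,
                    prob = c(0.55, 0.15, 0.25, 0.05))
    pp <- roh_params(window_snps = sample(c(10, 25, 50), 1),
                     window_max_het = sample(0:2, 1),
                     window_max_missing = sample(c(1, 5), 1),
                     min_snps = 10, min_length = 1)
    expect_equal(window_scan(codes, pp), oracle_window_scan(codes, pp))
  }
})

test_that("window_scan rejects unsorted positions", {
  expect_error(window_scan(rep(0L, 10), roh_params(), pos = c(5, 3, 8:15)),
               "sorted")
})

test_that("call_roh finds the single maximal run of a homozygous individual", {
  pos <- round(seq(1000, 250000, length.out = 60))
  gm <- genotype_matrix(matrix(0L, 1, 60),
                        data.frame(chrom = "1", pos = pos, ref = "A",
                                   alt = "C"), "homo")
  cl <- data.frame(chrom = "1", length_bp = 3e5)
  r <- call_roh(gm, cl, roh_params())
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_snps, 60L)
  expect_equal(r$start, 1000)
  expect_equal(r$end, 250000)
  expect_equal(r$length_bp, 249001)
  # fully heterozygous individual: no segments
  gm2 <- genotype_matrix(matrix(1L, 1, 60), gm$sites, "het")
  expect_equal(nrow(call_roh(gm2, cl, roh_params())), 0L)
})

test_that("a 2 Mb SNP desert splits a run into two segments", {
  pos <- c(seq(10000, 500000, length.out = 100),
           seq(2600000, 3100000, length.out = 100))
  gm <- genotype_matrix(matrix(0L, 1, 200),
                        data.frame(chrom = "1", pos = round(pos), ref = "A",
                                   alt = "C"), "x")
  cl <- data.frame(chrom = "1", length_bp = 4e6)
  p <- roh_params()
  r <- call_roh(gm, cl, p)
  expect_equal(nrow(r), 2L)
  ora <- oracle_call_roh_one(rep(0L, 200), round(pos), p)
  expect_equal(r$start, ora$start)
  expect_equal(r$end, ora$end)
  expect_equal(r$n_snps, ora$n_snps)
})

test_that("caller equals the brute-force oracle on randomized instances", {
  set.seed(33)
  for (rep in 1:60) {
    s <- sample(20:300, 1)
    pos <- sort(sample.int(3e6, s))
    codes <- sample(c(0L, 1L, 2L, NA), s, replace = TRUE,
                    prob = c(0.6, 0.1, 0.25, 0.05))
    p <- roh_params(window_snps = sample(c(5, 10, 20, 50), 1),
                    window_max_het = sample(0:1, 1),
                    window_max_missing = sample(c(1, 5), 1),
                    min_snps = sample(c(5, 10, 25), 1),
                    min_length = sample(c(1e4, 1e5), 1),
                    max_gap = sample(c(1e5, 1e6), 1),
                    min_density = sample(c(5e4, 5e5), 1))
    gm <- genotype_matrix(matrix(codes, 1),
                          data.frame(chrom = "1", pos = pos, ref = "A",
                                     alt = "C"), "x")
    r <- call_roh(gm, data.frame(chrom = "1", length_bp = 3e6 + 1), p)
    ora <- oracle_call_roh_one(codes, pos, p)
    expect_equal(nrow(r), nrow(ora))
    if (nrow(ora)) {
      expect_equal(r$start, ora$start)
      expect_equal(r$end, ora$end)
      expect_equal(r$n_snps, ora$n_snps)
    }
  }
})

test_that("raising min_length or min_snps only removes segments", {
  set.seed(8)
  gm <- random_gm(4, 300, n_chrom = 1, miss = 0.02, span = 3e6)
  cl <- data.frame(chrom = "1", length_bp = 3e6)
  base <- roh_params(window_snps = 10, window_max_het = 1, min_snps = 10,
                     min_length = 1e4, min_density = 5e5)
  r0 <- call_roh(gm, cl, base)
  for (variant in list(c(min_length = 1e5), c(min_snps = 30))) {
    p2 <- base
    p2[names(variant)] <- variant
    r2 <- call_roh(gm, cl, p2)
    key0 <- with(r0, paste(individual, chrom, start, end))
    key2 <- with(r2, paste(individual, chrom, start, end))
    expect_true(all(key2 %in% key0))
  }
  # disjointness per individual and chromosome
  for (grp in split(r0, paste(r0$individual, r0$chrom))) {
    grp <- grp[order(grp$start), ]
    if (nrow(grp) > 1)
      expect_true(all(grp$start[-1] > grp$end[-nrow(grp)]))
  }
})

test_that("call_roh requires every chromosome in the length table", {
  gm <- random_gm(2, 20, n_chrom = 2, miss = 0)
  expect_error(call_roh(gm, data.frame(chrom = "1", length_bp = 5e6)),
               "absent from chrom_lengths")
})

test_that("length classes partition segments with lower-inclusive bounds", {
  segs <- data.frame(length_bp = c(0.5, 1.5, 2.5, 3.5) * 1e6)
  cl <- classify_lengths(segs)
  expect_equal(cl$n, c(1, 1, 1, 1, 4))
  expect_equal(cl$pct_count, c(25, 25, 25, 25, 100))
  expect_equal(cl$class, c("<1 Mb", "1-2 Mb", "2-3 Mb", ">3 Mb", "total"))
  one <- classify_lengths(data.frame(length_bp = 9e5))
  expect_equal(one$n, c(1, 0, 0, 0, 1))
  expect_equal(one$pct_total_length[c(1, 5)], c(100, 100))
  # exactly 1 Mb falls in the 1-2 Mb class
  bnd <- classify_lengths(data.frame(length_bp = 1e6))
  expect_equal(bnd$n[1:2], c(0, 1))
  # empty list: zeros, not an error
  empty <- classify_lengths(data.frame(length_bp = numeric(0)))
  expect_equal(empty$n, rep(0L, 5))
  expect_equal(empty$pct_count, rep(0, 5))
})

test_that("class counts match a histogram oracle on simulated lengths", {
  set.seed(14)
  len <- exp(runif(1000, log(1e5), log(6e6)))
  cl <- classify_lengths(data.frame(length_bp = len))
  expect_equal(cl$n[1:4],
               c(sum(len < 1e6), sum(len >= 1e6 & len < 2e6),
                 sum(len >= 2e6 & len < 3e6), sum(len >= 3e6)))
  expect_equal(sum(cl$n[1:4]), cl$n[5])
  expect_equal(sum(cl$pct_count[1:4]), 100)
  expect_equal(sum(cl$pct_total_length[1:4]), 100)
})

test_that("chromosome coverage is the per-individual mean ROH fraction", {
  segs <- data.frame(individual = "a", chrom = "1", start = 1,
                     end = 250000, n_snps = 50L, length_bp = 250000)
  cov1 <- chromosome_coverage(segs,
                              chrom_lengths = data.frame(chrom = "1",
                                                         length_bp = 1e6),
                              n_indiv = 1)
  expect_equal(cov1$coverage, 0.25)
  cl <- data.frame(chrom = c("1", "2"), length_bp = c(1e6, 2e6))
  cov0 <- chromosome_coverage(segs[0, ], chrom_lengths = cl, n_indiv = 3)
  expect_equal(cov0$coverage, c(0, 0))
  # identity: pooled coverage equals mean of per-individual coverages
  set.seed(2)
  multi <- data.frame(individual = rep(c("a", "b", "c"), each = 4),
                      chrom = rep(c("1", "2"), 6),
                      start = 1, end = round(runif(12, 1e4, 5e5)))
  multi$length_bp <- multi$end - multi$start + 1
  pooled <- chromosome_coverage(multi, chrom_lengths = cl, n_indiv = 3)
  for (ch in c("1", "2")) {
    per_ind <- sapply(c("a", "b", "c"), function(i)
      sum(multi$length_bp[multi$individual == i & multi$chrom == ch]) /
        cl$length_bp[cl$chrom == ch])
    expect_equal(pooled$coverage[pooled$chrom == ch], mean(per_ind))
  }
})

test_that("sensitivity sweep degenerates correctly and is stable when trivial", {
  set.seed(4)
  gm <- random_gm(3, 200, n_chrom = 1, miss = 0.02, span = 3e6)
  cl <- data.frame(chrom = "1", length_bp = 3e6)
  p <- roh_params(window_snps = 20, min_snps = 20, min_length = 1e4,
                  min_density = 5e5)
  sw <- sensitivity_sweep(gm, cl, window_snps_grid = 20, params = p)
  direct <- classify_lengths(call_roh(gm, cl, p))
  expect_equal(sw$n, direct$n)
  # all-homozygous panel: identical counts across the grid
  gm2 <- genotype_matrix(matrix(0L, 2, 300),
                         data.frame(chrom = "1",
                                    pos = sort(sample.int(3e6, 300)),
                                    ref = "A", alt = "C"), c("a", "b"))
  sw2 <- sensitivity_sweep(gm2, cl, window_snps_grid = c(50, 100, 150),
                           params = roh_params())
  totals <- sw2$n[sw2$class == "total"]
  expect_equal(totals, rep(totals[1], 3))
})

test_that("called segments recover simulated autozygous tracts", {
  panel <- cached_mixed_panel()
  gmq <- qc_filter(panel$genotypes)
  r <- call_roh(gmq, panel$chrom_lengths)
  truth <- panel$truth$segments
  truth <- truth[truth$length_bp >= 5e5, ]
  hit <- logical(nrow(truth))
  for (k in seq_len(nrow(truth))) {
    cand <- r[r$individual == truth$individual[k] &
                r$chrom == truth$chrom[k], ]
    if (!nrow(cand)) next
    ov <- pmin(cand$end, truth$end[k]) - pmax(cand$start, truth$start[k]) + 1
    hit[k] <- any(ov >= 0.8 * truth$length_bp[k] & ov >= 0.8 * cand$length_bp)
  }
  expect_gte(mean(hit), 0.9)
})
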