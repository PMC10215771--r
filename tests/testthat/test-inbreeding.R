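roh_of <- function(ind, len, l_auto = 9e8) {
  data.frame(individual = ind, chrom = rep("1", length(ind)),
             start = rep(1, length(ind)), end = len,
             n_snps = rep(60L, length(ind)), length_bp = len)
}

test_that("f_roh is total ROH length over genome length, by class", {
  expect_equal(f_roh(roh_of(character(0), numeric(0)),
                     samples = "a")$froh_all, 0)
  segs <- roh_of("a", 9e8)
  expect_equal(f_roh(segs, samples = "a")$froh_all, 1)
  # 50.94 Mb of ROH over a 900 Mb genome
  segs2 <- rbind(roh_of("a", 50e6), roh_of("a", 0.94e6))
  fr <- f_roh(segs2, samples = "a")
  expect_equal(fr$froh_all, 50.94 / 900)
  expect_equal(fr$froh_all, 0.0566, tolerance = 1e-4)
  expect_error(f_roh(roh_of("a", 10e6), l_auto = 5e6), "inconsistent")
})

test_that("f_roh class components always sum exactly to the total", {
  set.seed(19)
  for (rep in 1:20) {
    n_seg <- sample(0:30, 1)
    segs <- data.frame(individual = sample(letters[1:5], n_seg,
                                           replace = TRUE),
                       chrom = rep("1", n_seg), start = rep(1, n_seg),
                       length_bp = exp(runif(n_seg, log(1e5), log(5e6))))
    segs$end <- segs$length_bp
    fr <- f_roh(segs, samples = letters[1:5])
    cls <- as.matrix(fr[grep("^froh_(lt|gt|[0-9])", names(fr))])
    expect_equal(unname(rowSums(cls)), fr$froh_all)
    expect_true(all(fr$froh_all >= 0 & fr$froh_all <= 1))
  }
})

test_that("f_hom matches a hand-computed oracle on a small matrix", {
  calls <- rbind(c(0L, 2L, 1L, 0L, 2L, 0L),
                 c(1L, 1L, 0L, 0L, NA, 2L),
                 c(2L, 0L, 0L, 1L, 2L, 2L),
                 c(0L, 0L, 1L, 1L, 0L, NA))
  gm <- genotype_matrix(calls,
                        data.frame(chrom = "1", pos = 1:6 * 100, ref = "A",
                                   alt = "C"), c("w", "x", "y", "z"))
  f <- f_hom(gm)
  # oracle: explicit per-site expectations
  e_site <- sapply(1:6, function(j) {
    v <- calls[, j]; n <- sum(!is.na(v))
    p <- sum(v, na.rm = TRUE) / (2 * n)
    1 - 2 * p * (1 - p) * 2 * n / (2 * n - 1)
  })
  for (i in 1:4) {
    ok <- !is.na(calls[i, ])
    o <- sum(calls[i, ok] != 1)
    l <- sum(ok)
    e <- sum(e_site[ok])
    expect_equal(unname(f[i]), (o - e) / (l - e))
  }
  # an individual homozygous everywhere scores exactly 1
  allhom <- rbind(calls, hom = c(0L, 0L, 2L, 0L, 2L, 2L))
  gm2 <- genotype_matrix(allhom, gm$sites, c("w", "x", "y", "z", "hom"))
  expect_equal(unname(f_hom(gm2)["hom"]), 1)
})

test_that("GRM matches brute-force VanRaden arithmetic on a toy panel", {
  calls <- rbind(c(0L, 1L, 2L, 1L),
                 c(2L, 1L, 0L, 0L),
                 c(1L, 2L, 1L, 0L))
  gm <- genotype_matrix(calls,
                        data.frame(chrom = "1", pos = 1:4 * 10, ref = "A",
                                   alt = "C"), c("a", "b", "c"))
  g <- grm_vanraden(gm)
  p <- colSums(calls) / 6
  z <- sweep(calls, 2, 2 * p)
  g_oracle <- (z %*% t(z)) / (2 * sum(p * (1 - p)))
  expect_equal(unname(g$G), unname(g_oracle))
  expect_equal(g$G, t(g$G))
  expect_equal(f_grm(gm), diag(g$G) - 1)
})

test_that("GRM diagonal hits its closed-form extremes", {
  # all-missing individual is imputed to 2p everywhere: G_jj = 0, F = -1
  calls <- rbind(c(0L, 1L, 2L, 1L, 0L, 2L),
                 c(2L, 1L, 0L, 1L, 2L, 0L),
                 rep(NA_integer_, 6))
  gm <- genotype_matrix(calls,
                        data.frame(chrom = "1", pos = 1:6 * 10, ref = "A",
                                   alt = "C"), c("a", "b", "null"))
  expect_equal(unname(f_grm(gm)["null"]), -1)
  # fully homozygous individual in an exact p = 0.5 panel: G_jj = 2
  calls2 <- rbind(rep(0L, 20), rep(2L, 20), rep(1L, 20), rep(1L, 20))
  gm2 <- genotype_matrix(calls2,
                         data.frame(chrom = "1", pos = 1:20 * 10, ref = "A",
                                    alt = "C"), c("hom", "alt", "h1", "h2"))
  g2 <- grm_vanraden(gm2)
  expect_equal(unname(diag(g2$G)[c("hom", "alt")]), c(2, 2))
  expect_equal(unname(f_grm(gm2)[c("h1", "h2")]), c(-1, -1))
  # monomorphic sites are rejected
  calls3 <- cbind(calls2, rep(0L, 4))
  gm3 <- genotype_matrix(calls3,
                         data.frame(chrom = "1", pos = c(1:20 * 10, 500),
                                    ref = "A", alt = "C"),
                         c("hom", "alt", "h1", "h2"))
  expect_error(grm_vanraden(gm3), "monomorphic")
})

test_that("F_HOM and F_GRM are centred near zero under Hardy-Weinberg", {
  set.seed(101)
  n <- 150; n_site <- 2500
  p <- runif(n_site, 0.1, 0.5)
  calls <- matrix(rbinom(n * n_site, 2, rep(p, each = n)), nrow = n)
  mono <- apply(calls, 2, function(v) length(unique(v)) == 1)
  gm <- genotype_matrix(calls[, !mono],
                        data.frame(chrom = "1",
                                   pos = seq_len(n_site)[!mono] * 100,
                                   ref = "A", alt = "C"),
                        paste0("i", 1:n))
  fh <- f_hom(gm)
  fg <- f_grm(gm)
  expect_lt(abs(mean(fh)), 0.02)
  expect_lt(abs(mean(fg) - mean(fh)), 0.03)
})

test_that("estimator table handles perfect, inverted and constant columns", {
  rec <- data.frame(individual = letters[1:5],
                    a = 1:5 / 10, b = 1:5 / 10, c = -(1:5) / 10,
                    d = rep(0.2, 5))
  et <- estimator_table(rec)
  expect_equal(et$correlations["a", "b"], 1)
  expect_equal(et$correlations["a", "c"], -1)
  expect_true(is.na(et$correlations["a", "d"]))
  expect_equal(diag(et$correlations), c(a = 1, b = 1, c = 1, d = 1))
  expect_error(estimator_table(rec[1:2, ]), "at least 3")
})

test_that("short-ROH-dominated cohorts tie F_ROH(all) to the short class", {
  set.seed(55)
  n <- 40
  segs <- do.call(rbind, lapply(seq_len(n), function(i) {
    n_short <- rpois(1, 40)
    n_long <- rbinom(1, 2, 0.3)
    len <- c(runif(n_short, 1e5, 9e5), runif(n_long, 3e6, 5e6))
    if (!length(len)) len <- 2e5
    data.frame(individual = paste0("i", i), chrom = "1", start = 1,
               end = len, n_snps = 50L, length_bp = len)
  }))
  fr <- f_roh(segs, samples = paste0("i", seq_len(n)))
  c_short <- cor(fr$froh_lt1, fr$froh_all)
  c_long <- cor(fr$froh_gt3, fr$froh_all)
  expect_gt(c_short, c_long)
})

test_that("inbreeding() assembles all coefficients and respects l_auto", {
  panel <- cached_mixed_panel()
  gmq <- qc_filter(panel$genotypes)
  r <- call_roh(gmq, panel$chrom_lengths)
  inb <- inbreeding(gmq, roh = r, chrom_lengths = panel$chrom_lengths,
                    l_auto = "from-lengths")
  expect_s3_class(inb, "inbreeding")
  expect_equal(attr(inb, "l_auto"),
               sum(panel$chrom_lengths$length_bp))
  cls <- as.matrix(inb[grep("^froh_(lt|gt|[0-9])", names(inb))])
  expect_equal(unname(rowSums(cls)), inb$froh_all)
  # F_ROH invariant to individual order
  perm <- sample(nrow(gmq$calls))
  inb2 <- inbreeding(gmq[perm, ], roh = r,
                     chrom_lengths = panel$chrom_lengths,
                     l_auto = "from-lengths")
  expect_equal(inb2$froh_all[match(inb$individual, inb2$individual)],
               inb$froh_all)
  co <- coef(inb)
  expect_equal(colnames(co)[ncol(co)], "f_grm")
  expect_equal(nrow(co), 60)
})
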