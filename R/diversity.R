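#' Per-site genetic-diversity statistics
#'
#' For every site with at least one non-missing call, with `n` the number of
#' non-missing individuals and `p` the sample alternate-allele frequency:
#' observed heterozygosity `H_O` = (het calls)/(non-missing calls), expected
#' heterozygosity `H_E = 2p(1-p)` (no small-sample correction, the usual
#' PLINK convention), minor allele frequency `MAF = min(p, 1-p)`, and the
#' unbiased per-site nucleotide diversity
#' `pi = 2p(1-p) * 2n/(2n-1)` for a biallelic SNP. Summary means and
#' standard deviations are taken over sites; the polymorphism rate `P_N` is
#' the fraction of sites with `MAF > 0`.
#'
#' @param gm A QC-passed [genotype_matrix()].
#' @return An object of class `"diversity_result"`: a list with `per_site`
#'   (data frame `chrom, pos, n_called, p_alt, maf, ho, he, pi`), the over-site
#'   summary `summary` (mean and sd of each index plus `p_n`), and
#'   `n_sites_excluded` (sites with zero non-missing calls).
#' @export
diversity_stats <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_called <- colSums(!is.na(gm$calls))
  keep <- n_called > 0L
  n_excl <- sum(!keep)
  gm2 <- if (n_excl) gm[, keep] else gm
  n <- n_called[keep]
  p <- alt_freq(gm2)
  ho <- colSums(gm2$calls == 1L, na.rm = TRUE) / n
  he <- 2 * p * (1 - p)
  maf <- pmin(p, 1 - p)
  pi <- he * (2 * n) / (2 * n - 1)
  per_site <- data.frame(chrom = gm2$sites$chrom, pos = gm2$sites$pos,
                         n_called = n, p_alt = p, maf = maf,
                         ho = ho, he = he, pi = pi)
  summ <- data.frame(
    index = c("ho", "he", "maf", "pi"),
    mean = c(mean(ho), mean(he), mean(maf), mean(pi)),
    sd = c(stats::sd(ho), stats::sd(he), stats::sd(maf), stats::sd(pi)))
  structure(list(per_site = per_site, summary = summ,
                 p_n = mean(maf > 0), n_sites_excluded = n_excl),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("Diversity over %d sites (%d excluded, all calls missing)\n",
              nrow(x$per_site), x$n_sites_excluded))
  s <- x$summary
  for (k in seq_len(nrow(s)))
    cat(sprintf("  %-4s %.4f +/- %.4f\n", s$index[k], s$mean[k], s$sd[k]))
  cat(sprintf("  P_N  %.4f (fraction of polymorphic sites)\n", x$p_n))
  invisible(x)
}

#' Minor-allele-frequency spectrum at chosen thresholds
#'
#' Reports, for each threshold, the fraction of sites with MAF strictly below
#' and strictly above it; ties at a threshold fall in neither fraction. The
#' defaults (0.10 and 0.40) mark the rare-variant and common-variant tails
#' customarily quoted for SNP panels.
#'
#' @param maf Numeric vector of per-site MAF values in `[0, 0.5]`.
#' @param thresholds MAF cut points.
#' @return Data frame `threshold, prop_below, prop_above`.
#' @export
maf_spectrum <- function(maf, thresholds = c(0.10, 0.40)) {
  if (length(maf) == 0L) stop("empty MAF vector")
  if (any(maf < 0 | maf > 0.5, na.rm = TRUE))
    stop("MAF values must lie in [0, 0.5]")
  maf <- maf[!is.na(maf)]
  data.frame(threshold = thresholds,
             prop_below = vapply(thresholds, function(t) mean(maf < t),
                                 numeric(1)),
             prop_above = vapply(thresholds, function(t) mean(maf > t),
                                 numeric(1)))
}

#' Linkage-disequilibrium decay curve
#'
#' For every intra-chromosomal site pair at distance at most `max_dist`,
#' computes `r^2` as the squared Pearson correlation of genotype dosages
#' across individuals with both calls non-missing (the Rogers–Huff composite
#' measure for unphased genotypes), then pools pairs into equal-width
#' distance bins.
#'
#' @param gm A [genotype_matrix()] with at least two sites on one chromosome.
#' @param max_dist Maximum pair distance in bp (default 300 kb).
#' @param n_bins Number of equal-width distance bins.
#' @return An object of class `"ld_decay"`: data frame `bin_start, bin_end,
#'   mean_r2, n_pairs` with attribute `n_pairs_skipped` counting pairs where
#'   one site had zero dosage variance (undefined `r^2`).
#' @export
ld_decay <- function(gm, max_dist = 300000, n_bins = 100) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_sites(gm) < 2L) stop("need at least two sites")
  edges <- seq(0, max_dist, length.out = n_bins + 1L)
  sums <- counts <- numeric(n_bins)
  skipped <- 0L
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    if (length(idx) < 2L) next
    pos <- gm$sites$pos[idx]
    calls <- gm$calls[, idx, drop = FALSE]
    hi <- findInterval(pos + max_dist, pos)  # last partner index per site
    for (a in seq_along(idx)) {
      if (hi[a] <= a) next
      for (b in (a + 1L):hi[a]) {
        ok <- !is.na(calls[, a]) & !is.na(calls[, b])
        if (sum(ok) < 2L) { skipped <- skipped + 1L; next }
        x <- calls[ok, a]; y <- calls[ok, b]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
          skipped <- skipped + 1L; next
        }
        r2 <- stats::cor(x, y)^2
        bin <- findInterval(pos[b] - pos[a], edges, left.open = TRUE,
                            rightmost.closed = TRUE)
        if (bin >= 1L && bin <= n_bins) {
          sums[bin] <- sums[bin] + r2
          counts[bin] <- counts[bin] + 1
        }
      }
    }
  }
  out <- data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1L],
                    mean_r2 = ifelse(counts > 0, sums / pmax(counts, 1), NA_real_),
                    n_pairs = counts)
  attr(out, "n_pairs_skipped") <- skipped
  class(out) <- c("ld_decay", "data.frame")
  out
}
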