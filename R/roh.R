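#' Sliding-window ROH detection parameters
#'
#' Defaults reproduce the PLINK v1.9 `--homozyg` semantics for
#' whole-genome-sequence panels: windows of 50 SNPs allowing at most one
#' heterozygous and five missing calls, runs of at least 50 SNPs and 100 kb,
#' split at gaps above 1 Mb, and at most 50 kb of sequence per supporting SNP.
#'
#' @param window_snps SNPs per sliding window.
#' @param window_max_het Maximum heterozygous calls for a window to count as
#'   homozygous.
#' @param window_max_missing Maximum missing calls per homozygous window.
#' @param min_snps Minimum SNPs in a reported run (inclusive).
#' @param min_length Minimum run length in bp (inclusive).
#' @param hit_threshold Minimum fraction of spanning windows that must be
#'   homozygous for a SNP to be in-run, in `(0, 1]`.
#' @param max_gap Maximum bp gap between adjacent in-run SNPs before a run is
#'   split.
#' @param min_density Maximum bp of run length per supporting SNP (a density
#'   floor of one SNP per `min_density` bp).
#' @return A list of class `"roh_params"`.
#' @export
roh_params <- function(window_snps = 50, window_max_het = 1,
                       window_max_missing = 5, min_snps = 50,
                       min_length = 100000, hit_threshold = 0.05,
                       max_gap = 1000000, min_density = 50000) {
  cnt <- c(window_snps, window_max_het, window_max_missing, min_snps)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (window_snps < 1) stop("window_snps must be >= 1")
  if (min_length <= 0) stop("min_length must be positive")
  if (hit_threshold <= 0 || hit_threshold > 1)
    stop("hit_threshold must lie in (0, 1]")
  structure(list(window_snps = as.integer(window_snps),
                 window_max_het = as.integer(window_max_het),
                 window_max_missing = as.integer(window_max_missing),
                 min_snps = as.integer(min_snps),
                 min_length = as.numeric(min_length),
                 hit_threshold = hit_threshold,
                 max_gap = as.numeric(max_gap),
                 min_density = as.numeric(min_density)),
            class = "roh_params")
}

#' Per-SNP homozygous-window hit fraction
#'
#' Slides a window of `window_snps` consecutive SNPs one SNP at a time along
#' one individual's calls on one chromosome. A window is homozygous iff it
#' holds at most `window_max_het` heterozygous and at most
#' `window_max_missing` missing calls. Each SNP's hit fraction is the number
#' of homozygous windows containing it divided by the number of windows
#' containing it. Chromosomes shorter than one window yield all-zero
#' fractions.
#'
#' @param codes Integer vector of genotype codes `{0, 1, 2, NA}` in position
#'   order for one individual on one chromosome.
#' @param params A [roh_params()] object.
#' @param pos Optional site positions; supplied positions must be strictly
#'   increasing or an error is raised.
#' @return Numeric vector of hit fractions, one per SNP.
#' @export
window_scan <- function(codes, params = roh_params(), pos = NULL) {
  if (!is.null(pos)) {
    if (length(pos) != length(codes)) stop("pos and codes lengths differ")
    if (is.unsorted(pos, strictly = TRUE))
      stop("sites must be sorted by position")
  }
  s <- length(codes)
  w <- params$window_snps
  if (s < w) return(numeric(s))
  n_win <- s - w + 1L
  het <- as.integer(!is.na(codes) & codes == 1L)
  mis <- as.integer(is.na(codes))
  chet <- c(0L, cumsum(het))
  cmis <- c(0L, cumsum(mis))
  t0 <- seq_len(n_win)
  hom_win <- (chet[t0 + w] - chet[t0]) <= params$window_max_het &
    (cmis[t0 + w] - cmis[t0]) <= params$window_max_missing
  chom <- c(0, cumsum(hom_win))
  i <- seq_len(s)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, n_win)
  (chom[hi + 1L] - chom[lo]) / (hi - lo + 1L)
}

#' Call runs of homozygosity for every individual
#'
#' Per individual and chromosome, SNPs whose [window_scan()] hit fraction
#' reaches `hit_threshold` are in-run. Maximal stretches of consecutive
#' in-run SNPs form candidate segments, split wherever the bp gap between
#' adjacent in-run SNPs exceeds `max_gap`. Candidates are reported iff they
#' hold at least `min_snps` SNPs, span at least `min_length` bp and carry at
#' least one SNP per `min_density` bp. Segment boundaries are the positions
#' of the first and last member SNP; lengths are `end - start + 1`
#' (coordinates 1-based inclusive).
#'
#' @param gm A QC-passed [genotype_matrix()].
#' @param chrom_lengths Data frame `chrom, length_bp` (see
#'   [read_chrom_lengths()]); every chromosome in `gm` must appear.
#' @param params A [roh_params()] object.
#' @return An object of class `"roh"`: a data frame with columns
#'   `individual, chrom, start, end, n_snps, length_bp`, sorted by
#'   (individual, chrom, start), carrying the call parameters, sample list
#'   and chromosome lengths as attributes.
#' @export
call_roh <- function(gm, chrom_lengths, params = roh_params()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  chroms <- unique(gm$sites$chrom)
  missing_chr <- setdiff(chroms, chrom_lengths$chrom)
  if (length(missing_chr))
    stop("chromosome(s) absent from chrom_lengths: ",
         paste(missing_chr, collapse = ", "))
  res <- vector("list", length(chroms) * n_indiv(gm))
  k <- 0L
  for (ch in chroms) {
    jdx <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[jdx]
    for (ind in seq_len(n_indiv(gm))) {
      codes <- gm$calls[ind, jdx]
      frac <- window_scan(codes, params)
      segs <- runs_from_hits(frac >= params$hit_threshold, pos, params)
      if (!is.null(segs)) {
        k <- k + 1L
        segs$individual <- gm$samples[ind]
        segs$chrom <- ch
        res[[k]] <- segs
      }
    }
  }
  out <- if (k) do.call(rbind, res[seq_len(k)]) else
    data.frame(start = numeric(0), end = numeric(0), n_snps = integer(0),
               individual = character(0), chrom = character(0))
  out <- out[c("individual", "chrom", "start", "end", "n_snps")]
  out$length_bp <- out$end - out$start + 1
  out <- out[order(match(out$individual, gm$samples),
                   match(out$chrom, chroms), out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, params = params, samples = gm$samples,
            chrom_lengths = chrom_lengths,
            class = c("roh", "data.frame"))
}

# turn the in-run indicator into filtered segments (positions sorted)
runs_from_hits <- function(in_run, pos, params) {
  idx <- which(in_run)
  if (!length(idx)) return(NULL)
  gap_break <- c(FALSE, diff(pos[idx]) > params$max_gap |
                   diff(idx) > 1L)
  grp <- cumsum(gap_break)
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  start <- pos[idx[first]]
  end <- pos[idx[last]]
  n_snps <- as.integer(tabulate(grp + 1L))
  len <- end - start + 1
  keep <- n_snps >= params$min_snps & len >= params$min_length &
    len / n_snps <= params$min_density
  if (!any(keep)) return(NULL)
  data.frame(start = start[keep], end = end[keep], n_snps = n_snps[keep])
}

#' @export
print.roh <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("ROH call set: %d segments in %d individuals\n",
              nrow(x), length(attr(x, "samples"))))
  cat(sprintf("  window %d SNPs (<= %d het, <= %d missing), min %d SNPs / %g kb\n",
              p$window_snps, p$window_max_het, p$window_max_missing,
              p$min_snps, p$min_length / 1000))
  if (nrow(x))
    cat(sprintf("  length: mean %.3f Mb, range %.3f-%.3f Mb\n",
                mean(x$length_bp) / 1e6, min(x$length_bp) / 1e6,
                max(x$length_bp) / 1e6))
  invisible(x)
}

#' @export
summary.roh <- function(object, breaks = c(1, 2, 3) * 1e6, ...) {
  out <- list(classes = classify_lengths(object, breaks),
              coverage = chromosome_coverage(object),
              n_indiv = length(attr(object, "samples")),
              per_indiv_n = nrow(object) / length(attr(object, "samples")),
              per_indiv_mb = sum(object$length_bp) / 1e6 /
                length(attr(object, "samples")))
  class(out) <- "summary.roh"
  out
}

#' @export
print.summary.roh <- function(x, ...) {
  cat(sprintf("Mean per individual: %.2f segments, %.2f Mb total length\n",
              x$per_indiv_n, x$per_indiv_mb))
  print(x$classes)
  cat("per-chromosome genome coverage:\n")
  print(x$coverage)
  invisible(x)
}

#' Stratify ROH segments into length classes
#'
#' Classes are lower-inclusive, upper-exclusive intervals over the break
#' points (defaults 1, 2 and 3 Mb: `<1`, `1-2`, `2-3`, `>3` Mb; a segment of
#' exactly 1 Mb falls in the 1-2 Mb class). For each class the count, its
#' percent of all segments, the mean and SD of segment length, and its
#' percent of the cumulative ROH length are reported, plus a total row.
#' An empty segment list gives a summary of zeros.
#'
#' @param segments An `"roh"` object or data frame with a `length_bp` column.
#' @param breaks Ascending class boundaries in bp.
#' @return Data frame of class `"roh_length_summary"` with columns
#'   `class, n, pct_count, mean_length_mb, sd_length_mb, pct_total_length`.
#' @export
classify_lengths <- function(segments, breaks = c(1, 2, 3) * 1e6) {
  stopifnot(!is.unsorted(breaks, strictly = TRUE))
  lab_mb <- function(b) {
    if (b == round(b / 1e6) * 1e6) sprintf("%g Mb", b / 1e6)
    else sprintf("%g bp", b)
  }
  labels <- c(paste0("<", lab_mb(breaks[1L])),
              if (length(breaks) > 1L)
                paste0(sub(" .*$", "", vapply(breaks[-length(breaks)], lab_mb,
                                              character(1))),
                       "-", vapply(breaks[-1L], lab_mb, character(1))),
              paste0(">", lab_mb(breaks[length(breaks)])))
  len <- segments$length_bp
  cls <- findInterval(len, breaks) + 1L   # lower-inclusive classes
  n <- tabulate(cls, nbins = length(labels))
  total_n <- length(len)
  total_len <- sum(len)
  mean_l <- sd_l <- rep(NA_real_, length(labels))
  class_len <- numeric(length(labels))
  for (k in seq_along(labels)) {
    lk <- len[cls == k]
    if (length(lk)) {
      mean_l[k] <- mean(lk)
      sd_l[k] <- if (length(lk) > 1L) stats::sd(lk) else 0
      class_len[k] <- sum(lk)
    }
  }
  out <- data.frame(
    class = c(labels, "total"),
    n = c(n, total_n),
    pct_count = if (total_n) 100 * c(n, total_n) / total_n else
      numeric(length(labels) + 1L),
    mean_length_mb = c(mean_l, if (total_n) mean(len) else NA_real_) / 1e6,
    sd_length_mb = c(sd_l, if (total_n > 1L) stats::sd(len) else
      if (total_n) 0 else NA_real_) / 1e6,
    pct_total_length = if (total_len > 0) 100 * c(class_len, total_len) /
      total_len else numeric(length(labels) + 1L))
  class(out) <- c("roh_length_summary", "data.frame")
  out
}

#' Per-chromosome ROH genome coverage
#'
#' The fraction of each chromosome lying in ROH, averaged over individuals:
#' sum of all individuals' segment lengths on the chromosome divided by
#' (chromosome length x number of individuals).
#'
#' @param segments An `"roh"` object (carries its sample list and chromosome
#'   lengths), or a plain segment data frame if `chrom_lengths` and `n_indiv`
#'   are given.
#' @param chrom_lengths Data frame `chrom, length_bp`; defaults to the one
#'   attached to `segments`.
#' @param n_indiv Number of individuals genotyped; defaults to the sample
#'   list attached to `segments`.
#' @return Data frame `chrom, length_bp, roh_bp, coverage` (coverage as a
#'   fraction).
#' @export
chromosome_coverage <- function(segments, chrom_lengths = NULL,
                                n_indiv = NULL) {
  if (is.null(chrom_lengths)) chrom_lengths <- attr(segments, "chrom_lengths")
  if (is.null(n_indiv)) n_indiv <- length(attr(segments, "samples"))
  if (is.null(chrom_lengths) || is.null(n_indiv) || n_indiv < 1L)
    stop("chrom_lengths and n_indiv are required for plain segment tables")
  missing_chr <- setdiff(unique(segments$chrom), chrom_lengths$chrom)
  if (length(missing_chr))
    stop("chromosome(s) absent from chrom_lengths: ",
         paste(missing_chr, collapse = ", "))
  roh_bp <- vapply(chrom_lengths$chrom, function(ch)
    sum(segments$length_bp[segments$chrom == ch]), numeric(1))
  data.frame(chrom = chrom_lengths$chrom,
             length_bp = chrom_lengths$length_bp,
             roh_bp = roh_bp,
             coverage = roh_bp / (chrom_lengths$length_bp * n_indiv),
             row.names = NULL)
}

#' Window-size sensitivity sweep for ROH calling
#'
#' Re-runs [call_roh()] for each window size in `window_snps_grid`, keeping
#' all other parameters fixed, and tabulates the per-length-class counts —
#' the standard check that conclusions about short-ROH dominance are robust
#' to the sliding-window width.
#'
#' @param gm A QC-passed [genotype_matrix()].
#' @param chrom_lengths Data frame `chrom, length_bp`.
#' @param window_snps_grid Ascending window sizes (default 50, 100, 150, 200).
#' @param params Base [roh_params()]; `window_snps` is overridden per grid
#'   point.
#' @param scale_min_snps When `TRUE` (default) the minimum run support
#'   `min_snps` is set equal to the window size at every grid point — the
#'   two are one "SNP number" setting stepped together, as in the usual
#'   PLINK-style sweep; `FALSE` holds `min_snps` at its base value.
#' @param breaks Length-class boundaries passed to [classify_lengths()].
#' @return Data frame with one row per (window size, length class):
#'   `window_snps, class, n, pct_count, mean_length_mb, sd_length_mb,
#'   pct_total_length`.
#' @export
sensitivity_sweep <- function(gm, chrom_lengths,
                              window_snps_grid = c(50, 100, 150, 200),
                              params = roh_params(), scale_min_snps = TRUE,
                              breaks = c(1, 2, 3) * 1e6) {
  if (is.unsorted(window_snps_grid, strictly = TRUE))
    stop("window_snps_grid must be ascending")
  out <- lapply(window_snps_grid, function(w) {
    p <- params
    p$window_snps <- as.integer(w)
    if (scale_min_snps) p$min_snps <- as.integer(w)
    cl <- classify_lengths(call_roh(gm, chrom_lengths, p), breaks)
    cbind(window_snps = w, as.data.frame(cl))
  })
  do.call(rbind, out)
}

#' Write ROH segments as TSV
#'
#' Columns `individual, chrom, start, end, n_snps, length_bp`; coordinates
#' 1-based inclusive (stated in the header comment line).
#'
#' @param roh An `"roh"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roh <- function(roh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based, inclusive (start and end are SNP positions)",
             con)
  utils::write.table(as.data.frame(roh), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
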