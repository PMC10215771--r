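#' ROH-based inbreeding coefficient, total and by length class
#'
#' `F_ROH` for an individual is the summed length of its ROH segments divided
#' by the autosomal genome length `l_auto`; the per-class values use only the
#' segments of that length class, so the class values add up to the total
#' exactly.
#'
#' @param roh An `"roh"` object from [call_roh()] (or a segment data frame
#'   with `individual` and `length_bp`; then `samples` must be given).
#' @param l_auto Autosomal genome length in bp. The default 900 Mb is the
#'   conventional chicken autosome total; [l_auto_from_lengths()] derives it
#'   from a chromosome-length table instead.
#' @param breaks Length-class boundaries in bp (see [classify_lengths()]).
#' @param samples Individual IDs to report (individuals without segments get
#'   zero); defaults to the sample list attached to `roh`.
#' @return Data frame with one row per individual: `individual`, one
#'   `froh_<class>` column per length class, and `froh_all`.
#' @export
f_roh <- function(roh, l_auto = 9e8, breaks = c(1, 2, 3) * 1e6,
                  samples = NULL) {
  if (is.null(samples)) samples <- attr(roh, "samples")
  if (is.null(samples)) samples <- sort(unique(roh$individual))
  if (l_auto <= 0) stop("l_auto must be positive")
  if (nrow(roh) && any(roh$length_bp > l_auto))
    stop("segment longer than l_auto: inconsistent inputs")
  cls <- findInterval(roh$length_bp, breaks) + 1L
  n_cls <- length(breaks) + 1L
  labels <- c(paste0("froh_", c(paste0("lt", breaks[1L] / 1e6),
                                if (length(breaks) > 1L)
                                  paste0(breaks[-length(breaks)] / 1e6, "_",
                                         breaks[-1L] / 1e6),
                                paste0("gt", breaks[length(breaks)] / 1e6))))
  m <- matrix(0, nrow = length(samples), ncol = n_cls,
              dimnames = list(samples, labels))
  if (nrow(roh)) {
    agg <- stats::aggregate(roh$length_bp,
                            by = list(ind = roh$individual, cls = cls), sum)
    bad <- setdiff(agg$ind, samples)
    if (length(bad)) stop("segments for unknown individual(s): ",
                          paste(bad, collapse = ", "))
    m[cbind(match(agg$ind, samples), agg$cls)] <- agg$x / l_auto
  }
  total <- rowSums(m)
  if (any(total > 1))
    stop("total ROH length exceeds l_auto: inconsistent inputs")
  out <- data.frame(individual = samples, m, froh_all = total,
                    row.names = NULL, check.names = FALSE)
  attr(out, "l_auto") <- l_auto
  out
}

#' Autosome length from a chromosome-length table
#'
#' @param chrom_lengths Data frame `chrom, length_bp`.
#' @return The summed length in bp.
#' @export
l_auto_from_lengths <- function(chrom_lengths) sum(chrom_lengths$length_bp)

#' Excess-homozygosity inbreeding coefficient (method-of-moments)
#'
#' Per individual, over its non-missing sites:
#' `F_HOM = (O - E) / (L - E)` with `O` the observed homozygote count, `L`
#' the non-missing site count, and `E = sum(1 - 2p(1-p) * 2n/(2n-1))` the
#' expected homozygote count under Hardy–Weinberg using the in-sample
#' alternate-allele frequency `p` and non-missing sample count `n` at each
#' site (the PLINK `--het` convention). May legitimately be negative for
#' individuals less homozygous than expected.
#'
#' @param gm A QC-passed [genotype_matrix()].
#' @return Named numeric vector of per-individual coefficients (`NA` for an
#'   individual with no non-missing calls).
#' @export
f_hom <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- colSums(!is.na(gm$calls))
  p <- alt_freq(gm)
  e_site <- 1 - 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
  e_site[n == 0L] <- NA_real_
  called <- !is.na(gm$calls)
  use <- !is.na(e_site)
  obs_hom <- rowSums(gm$calls[, use, drop = FALSE] != 1L, na.rm = TRUE)
  l_i <- rowSums(called[, use, drop = FALSE])
  e_i <- as.vector(called[, use, drop = FALSE] %*% e_site[use])
  f <- (obs_hom - e_i) / (l_i - e_i)
  f[l_i == 0L] <- NA_real_
  names(f) <- gm$samples
  f
}

#' VanRaden method-1 genomic relationship matrix
#'
#' Dosages are centered on twice the in-sample alternate-allele frequency,
#' `z_ij = d_ij - 2 p_j`, missing dosages are mean-imputed to `2 p_j` (zero
#' after centering), and `G = Z Z' / (2 sum_j p_j (1 - p_j))`.
#'
#' @param gm A QC-passed [genotype_matrix()] with no monomorphic site.
#' @return An object of class `"grm"`: list with the symmetric matrix `G`
#'   (individuals x individuals) and the allele-frequency vector `p` used.
#' @export
grm_vanraden <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  p <- alt_freq(gm)
  if (any(is.na(p)) || any(p <= 0 | p >= 1))
    stop("monomorphic or all-missing site present; run QC first")
  z <- sweep(gm$calls, 2L, 2 * p)
  z[is.na(z)] <- 0
  g <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  dimnames(g) <- list(gm$samples, gm$samples)
  structure(list(G = g, p = p), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("VanRaden genomic relationship matrix: %d individuals, %d SNPs\n",
              nrow(x$G), length(x$p)))
  cat(sprintf("  diagonal: mean %.4f, range %.4f-%.4f\n",
              mean(diag(x$G)), min(diag(x$G)), max(diag(x$G))))
  invisible(x)
}

#' GRM-diagonal inbreeding coefficient
#'
#' `F_GRM_j = G_jj - 1`, with `G` the VanRaden method-1 matrix.
#'
#' @param gm A QC-passed [genotype_matrix()], or a precomputed `"grm"`.
#' @return Named numeric vector of per-individual coefficients.
#' @export
f_grm <- function(gm) {
  g <- if (inherits(gm, "grm")) gm else grm_vanraden(gm)
  diag(g$G) - 1
}

#' Estimate all genomic inbreeding coefficients
#'
#' Fits the three standard genomic inbreeding estimators on one panel:
#' ROH-based `F_ROH` (total and per length class, from [call_roh()] segments
#' and `l_auto`), excess-homozygosity `F_HOM` ([f_hom()]) and GRM-diagonal
#' `F_GRM` ([f_grm()]).
#'
#' @param gm A QC-passed [genotype_matrix()].
#' @param roh Optional precomputed `"roh"` object; called with `params` when
#'   absent (then `chrom_lengths` is required).
#' @param chrom_lengths Data frame `chrom, length_bp`; required when `roh` is
#'   not supplied or when `l_auto = "from-lengths"`.
#' @param l_auto Autosomal genome length in bp, or `"from-lengths"` to use
#'   the summed chromosome lengths. Default 900 Mb (chicken autosomes).
#' @param params [roh_params()] used when `roh` is absent.
#' @param breaks ROH length-class boundaries in bp.
#' @return An object of class `"inbreeding"`: a data frame with one row per
#'   individual (`individual`, per-class `froh_*`, `froh_all`, `f_hom`,
#'   `f_grm`) with the `l_auto` used as an attribute.
#' @export
inbreeding <- function(gm, roh = NULL, chrom_lengths = NULL, l_auto = 9e8,
                       params = roh_params(), breaks = c(1, 2, 3) * 1e6) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(roh)) {
    if (is.null(chrom_lengths))
      stop("chrom_lengths is required when 'roh' is not supplied")
    roh <- call_roh(gm, chrom_lengths, params)
  }
  if (identical(l_auto, "from-lengths")) {
    cl <- if (!is.null(chrom_lengths)) chrom_lengths else
      attr(roh, "chrom_lengths")
    if (is.null(cl)) stop("l_auto = \"from-lengths\" needs chrom_lengths")
    l_auto <- l_auto_from_lengths(cl)
  }
  fr <- f_roh(roh, l_auto = l_auto, breaks = breaks, samples = gm$samples)
  out <- cbind(fr, f_hom = unname(f_hom(gm)), f_grm = unname(f_grm(gm)))
  attr(out, "l_auto") <- l_auto
  class(out) <- c("inbreeding", "data.frame")
  out
}

#' @export
print.inbreeding <- function(x, ...) {
  cat(sprintf("Genomic inbreeding coefficients for %d individuals (l_auto = %g Mb)\n",
              nrow(x), attr(x, "l_auto") / 1e6))
  num <- vapply(x, is.numeric, logical(1))
  m <- colMeans(as.data.frame(x)[num], na.rm = TRUE)
  s <- vapply(as.data.frame(x)[num], stats::sd, numeric(1), na.rm = TRUE)
  for (k in names(m))
    cat(sprintf("  %-12s %+.4f +/- %.4f\n", k, m[k], s[k]))
  invisible(x)
}

#' @export
coef.inbreeding <- function(object, ...) {
  num <- vapply(object, is.numeric, logical(1))
  m <- as.matrix(as.data.frame(object)[num])
  rownames(m) <- object$individual
  m
}

#' @export
summary.inbreeding <- function(object, ...) estimator_table(object)

#' Summary table and correlation matrix of inbreeding estimators
#'
#' Means and SDs of every coefficient plus the Pearson correlation matrix
#' among them (per-class and total `F_ROH`, `F_HOM`, `F_GRM`). Correlations
#' involving a constant column are reported as `NA`, not zero.
#'
#' @param records An `"inbreeding"` object (or any data frame of numeric
#'   coefficient columns plus `individual`), at least 3 rows.
#' @return An object of class `"inbreeding_summary"`: list with data frame
#'   `summary` (`coefficient, mean, sd`) and matrix `correlations`.
#' @export
estimator_table <- function(records) {
  if (nrow(records) < 3L) stop("need at least 3 individuals")
  num <- vapply(records, is.numeric, logical(1))
  m <- as.matrix(as.data.frame(records)[num])
  const <- apply(m, 2L, function(v) stats::sd(v, na.rm = TRUE) == 0)
  cors <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  cors[const, ] <- NA_real_
  cors[, const] <- NA_real_
  diag(cors) <- 1
  structure(list(summary = data.frame(coefficient = colnames(m),
                                      mean = colMeans(m, na.rm = TRUE),
                                      sd = apply(m, 2L, stats::sd,
                                                 na.rm = TRUE),
                                      row.names = NULL),
                 correlations = cors),
            class = "inbreeding_summary")
}

#' @export
print.inbreeding_summary <- function(x, digits = 4, ...) {
  cat("Inbreeding estimators, mean +/- SD over individuals:\n")
  s <- x$summary
  for (k in seq_len(nrow(s)))
    cat(sprintf("  %-12s %+.4f +/- %.4f\n", s$coefficient[k], s$mean[k],
                s$sd[k]))
  cat("Pearson correlations:\n")
  print(round(x$correlations, digits))
  invisible(x)
}
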