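#' Construct a genotype matrix
#'
#' The central container of the package: a panel of diploid genotype calls at
#' biallelic SNPs, coded per (individual, site) as 0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, `NA` = missing.
#'
#' @param calls Integer matrix, individuals in rows, sites in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param sites Data frame with one row per site and columns `chrom`
#'   (character), `pos` (integer, 1-based), `ref`, `alt` (single-nucleotide
#'   alleles) and optionally `qual` (numeric Phred-like calling quality,
#'   `NA` when absent).
#' @param samples Character vector of individual IDs, one per row of `calls`.
#'
#' @details Sites are stored sorted by (chromosome, position); chromosomes
#'   keep their order of first appearance, positions are ascending and must be
#'   unique within a chromosome. All coordinates in the package are 1-based
#'   and inclusive.
#'
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(calls, sites, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sites$qual)) sites$qual <- rep(NA_real_, nrow(sites))
  sites <- data.frame(chrom = as.character(sites$chrom),
                      pos = as.integer(sites$pos),
                      ref = as.character(sites$ref),
                      alt = as.character(sites$alt),
                      qual = as.numeric(sites$qual),
                      stringsAsFactors = FALSE)
  samples <- as.character(samples)
  if (nrow(calls) != length(samples))
    stop("number of rows of 'calls' must equal length of 'samples'")
  if (ncol(calls) != nrow(sites))
    stop("number of columns of 'calls' must equal number of sites")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(sites$pos < 1L)) stop("site positions must be >= 1")
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(sites) <- NULL
  if (anyDuplicated(sites[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) site coordinates")
  dimnames(calls) <- list(samples, paste(sites$chrom, sites$pos, sep = ":"))
  structure(list(calls = calls, sites = sites, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d biallelic SNPs on %d chromosome(s)\n",
              n_indiv(x), n_sites(x), length(unique(x$sites$chrom))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  p <- alt_freq(object)
  out <- list(n_indiv = n_indiv(object), n_sites = n_sites(object),
              chroms = table(object$sites$chrom),
              missing_rate = mean(is.na(object$calls)),
              maf = summary(pmin(p, 1 - p, na.rm = TRUE)))
  class(out) <- "summary.genotype_matrix"
  out
}

#' @export
print.summary.genotype_matrix <- function(x, ...) {
  cat(sprintf("%d individuals x %d SNPs; missing %.2f%%\n",
              x$n_indiv, x$n_sites, 100 * x$missing_rate))
  cat("sites per chromosome:\n")
  print(x$chroms)
  cat("MAF:\n")
  print(x$maf)
  invisible(x)
}

n_indiv <- function(gm) nrow(gm$calls)
n_sites <- function(gm) ncol(gm$calls)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param i Individual (row) index.
#' @param j Site (column) index.
#' @param ... Ignored.
#' @return A `genotype_matrix` restricted to the selected individuals/sites.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_indiv(x))
  if (missing(j)) j <- seq_len(n_sites(x))
  genotype_matrix(x$calls[i, j, drop = FALSE], x$sites[j, , drop = FALSE],
                  x$samples[i])
}

#' Per-site alternate-allele frequency
#'
#' Computed over non-missing calls only: `p = sum(dosage) / (2 * n_called)`.
#' Sites with no non-missing call get `NA`.
#'
#' @param gm A `genotype_matrix`.
#' @return Numeric vector of length `n_sites`.
#' @export
alt_freq <- function(gm) {
  n_called <- colSums(!is.na(gm$calls))
  p <- colSums(gm$calls, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0L] <- NA_real_
  p
}

site_missing_rate <- function(gm) colMeans(is.na(gm$calls))
indiv_call_rate <- function(gm) rowMeans(!is.na(gm$calls))
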