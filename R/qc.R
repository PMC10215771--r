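#' Quality-control parameters for a SNP panel
#'
#' Defaults follow standard whole-genome SNP panel filtering: minor allele
#' frequency at least 0.05, per-site missing rate at most 0.1, per-individual
#' call rate at least 0.9, and site calling quality at least 30 (Phred scale)
#' where a QUAL value is present.
#'
#' @param maf_min Minimum minor allele frequency (inclusive), in `[0, 1]`.
#' @param site_missing_max Maximum per-site missing-call fraction (inclusive).
#' @param indiv_call_min Minimum per-individual call rate (inclusive).
#' @param qual_min Minimum site QUAL; sites with no QUAL value are kept.
#' @return A list of class `"qc_params"`.
#' @export
qc_params <- function(maf_min = 0.05, site_missing_max = 0.1,
                      indiv_call_min = 0.9, qual_min = 30) {
  fr <- c(maf_min = maf_min, site_missing_max = site_missing_max,
          indiv_call_min = indiv_call_min)
  if (any(fr < 0 | fr > 1))
    stop("maf_min, site_missing_max and indiv_call_min must lie in [0, 1]")
  structure(list(maf_min = maf_min, site_missing_max = site_missing_max,
                 indiv_call_min = indiv_call_min, qual_min = qual_min),
            class = "qc_params")
}

#' Filter a genotype matrix by individual- and site-level QC
#'
#' Individuals with call rate below `indiv_call_min` are removed first, on the
#' raw panel (individual call rate is defined before any site is dropped).
#' Sites are then removed, with frequencies recomputed on the remaining
#' individuals, when QUAL is present and below `qual_min`, when the missing
#' rate exceeds `site_missing_max`, or when the minor allele frequency
#' (non-missing alleles in the denominator) is below `maf_min`. All
#' site thresholds are inclusive in the direction that keeps the site
#' (e.g. MAF exactly at `maf_min` is retained).
#'
#' @param gm A [genotype_matrix()].
#' @param params A [qc_params()] object.
#' @param chroms Optional chromosome whitelist (e.g. autosomes only); sites on
#'   other chromosomes are dropped before any threshold is applied.
#' @return The filtered `genotype_matrix`, with the QC report attached as
#'   attribute `"qc_report"` (see [qc_report()]).
#' @export
qc_filter <- function(gm, params = qc_params(), chroms = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_indiv(gm) == 0L || n_sites(gm) == 0L) stop("empty genotype matrix")
  n_chrom_dropped <- 0L
  if (!is.null(chroms)) {
    on_wl <- gm$sites$chrom %in% chroms
    n_chrom_dropped <- sum(!on_wl)
    if (!any(on_wl)) stop("no sites on whitelisted chromosomes")
    gm <- gm[, on_wl]
  }
  cr <- indiv_call_rate(gm)
  keep_ind <- cr >= params$indiv_call_min
  n_ind_removed <- sum(!keep_ind)
  if (!any(keep_ind)) stop("empty after QC: all individuals removed")
  gm2 <- gm[keep_ind, ]

  fail_qual <- !is.na(gm2$sites$qual) & gm2$sites$qual < params$qual_min
  fail_miss <- site_missing_rate(gm2) > params$site_missing_max
  p <- alt_freq(gm2)
  maf <- pmin(p, 1 - p)
  fail_maf <- !is.na(maf) & maf < params$maf_min
  fail_all_missing <- is.na(maf)
  keep_site <- !(fail_qual | fail_miss | fail_maf | fail_all_missing)
  if (!any(keep_site)) stop("empty after QC: all sites removed")
  out <- gm2[, keep_site]
  report <- structure(list(
    params = params,
    n_indiv_in = n_indiv(gm), n_indiv_out = n_indiv(out),
    n_sites_in = n_sites(gm), n_sites_out = n_sites(out),
    n_sites_off_whitelist = n_chrom_dropped,
    n_indiv_removed_callrate = n_ind_removed,
    n_sites_fail_qual = sum(fail_qual),
    n_sites_fail_missing = sum(fail_miss),
    n_sites_fail_maf = sum(fail_maf),
    n_sites_all_missing = sum(fail_all_missing),
    filter_order = c("individual call rate (raw panel)",
                     "site QUAL / missing rate / MAF (remaining individuals)")),
    class = "qc_report")
  attr(out, "qc_report") <- report
  out
}

#' Extract the QC report from a filtered genotype matrix
#'
#' @param gm A `genotype_matrix` returned by [qc_filter()].
#' @return The `"qc_report"` object, or `NULL` if `gm` was never filtered.
#' @export
qc_report <- function(gm) attr(gm, "qc_report")

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP panel QC report\n")
  cat(sprintf("  individuals: %d -> %d (%d removed, call rate < %g)\n",
              x$n_indiv_in, x$n_indiv_out, x$n_indiv_removed_callrate,
              x$params$indiv_call_min))
  cat(sprintf("  sites: %d -> %d\n", x$n_sites_in, x$n_sites_out))
  if (x$n_sites_off_whitelist)
    cat(sprintf("    off chromosome whitelist: %d\n", x$n_sites_off_whitelist))
  cat(sprintf("    QUAL < %g: %d\n", x$params$qual_min, x$n_sites_fail_qual))
  cat(sprintf("    missing rate > %g: %d\n", x$params$site_missing_max,
              x$n_sites_fail_missing))
  cat(sprintf("    MAF < %g: %d\n", x$params$maf_min, x$n_sites_fail_maf))
  if (x$n_sites_all_missing)
    cat(sprintf("    no non-missing calls: %d\n", x$n_sites_all_missing))
  invisible(x)
}

#' Write a QC report as TSV and JSON
#'
#' @param report A `"qc_report"` from [qc_filter()].
#' @param tsv,json Output paths; either may be `NULL` to skip.
#' @return Invisibly, the report.
#' @export
write_qc_report <- function(report, tsv = NULL, json = NULL) {
  stopifnot(inherits(report, "qc_report"))
  flat <- c(unlist(report$params),
            report[grep("^n_", names(report), value = TRUE)])
  if (!is.null(tsv)) {
    df <- data.frame(key = names(flat), value = unlist(flat))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json))
    jsonlite::write_json(report[names(report) != "params"] |>
                           c(list(params = unclass(report$params))),
                         json, auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
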