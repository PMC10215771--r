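#' Per-SNP ROH incidence across individuals
#'
#' For every genotyped SNP, counts the individuals whose ROH cover it (a SNP
#' at `pos` is covered by a segment iff `start <= pos <= end` on the same
#' chromosome) and reports the incidence fraction `count / n_individuals`.
#' Segments of one individual on one chromosome are disjoint by
#' construction, so each individual contributes at most once per SNP.
#'
#' @param segments An `"roh"` object or segment data frame
#'   (`individual, chrom, start, end`).
#' @param sites Data frame `chrom, pos` of the genotyped SNPs (e.g.
#'   `gm$sites`).
#' @param n_individuals Number of genotyped individuals; defaults to the
#'   sample list attached to `segments`.
#' @return An object of class `"snp_incidence"`: data frame
#'   `chrom, pos, count, incidence` in site order.
#' @export
snp_incidence <- function(segments, sites, n_individuals = NULL) {
  if (is.null(n_individuals))
    n_individuals <- length(attr(segments, "samples"))
  if (is.null(n_individuals) || n_individuals == 0L)
    stop("n_individuals must be positive")
  count <- integer(nrow(sites))
  for (ch in unique(sites$chrom)) {
    jdx <- which(sites$chrom == ch)
    pos <- sites$pos[jdx]
    segs <- segments[segments$chrom == ch, , drop = FALSE]
    if (!nrow(segs)) next
    # interval indexing on the sorted position vector
    lo <- findInterval(segs$start - 1, pos) + 1L
    hi <- findInterval(segs$end, pos)
    for (s in seq_len(nrow(segs)))
      if (lo[s] <= hi[s])
        count[jdx[lo[s]:hi[s]]] <- count[jdx[lo[s]:hi[s]]] + 1L
  }
  structure(data.frame(chrom = sites$chrom, pos = sites$pos, count = count,
                       incidence = count / n_individuals),
            n_individuals = n_individuals,
            class = c("snp_incidence", "data.frame"))
}

#' Top-percentile incidence threshold and candidate SNP selection
#'
#' The threshold is the `k`-th largest incidence with
#' `k = ceiling(top_fraction * n)` (the empirical upper `top_fraction`
#' order-statistic quantile); selected SNPs are those with incidence at or
#' above it. Ties at the threshold are all included, so slightly more than
#' `top_fraction` of SNPs may be selected. When every incidence is
#' identical the threshold is degenerate: a warning is emitted and all SNPs
#' are selected.
#'
#' @param incidence A [snp_incidence()] object.
#' @param top_fraction Fraction of SNPs to select (default 0.01, the top 1%).
#' @return List with `threshold`, logical vector `selected_mask`, and
#'   `selected` (the selected rows of `incidence`).
#' @export
top_percentile_threshold <- function(incidence, top_fraction = 0.01) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  inc <- incidence$incidence
  if (!length(inc)) stop("empty incidence table")
  k <- ceiling(top_fraction * length(inc))
  thr <- sort(inc, decreasing = TRUE)[k]
  sel <- inc >= thr
  if (all(sel))
    warning("degenerate threshold: all SNPs selected (uniform incidence)")
  list(threshold = thr, selected_mask = sel,
       selected = incidence[sel, , drop = FALSE])
}

#' Merge selected SNPs into ROH islands
#'
#' Consecutive selected SNPs on one chromosome separated by at most
#' `max_gap` bp form one island; islands supported by fewer than `min_snps`
#' SNPs are dropped. Island boundaries are the first and last member SNP
#' positions (1-based inclusive).
#'
#' @param selected Data frame of selected SNPs (`chrom, pos`, optionally
#'   `incidence`), sorted by position within chromosome.
#' @param max_gap Maximum intra-island gap in bp (default 500 kb).
#' @param min_snps Minimum member SNPs per island (default 2).
#' @return An object of class `"roh_islands"`: data frame
#'   `chrom, start, end, length_bp, n_snps, peak_incidence`.
#' @export
merge_islands <- function(selected, max_gap = 500000, min_snps = 2) {
  out <- list()
  for (ch in unique(selected$chrom)) {
    s <- selected[selected$chrom == ch, , drop = FALSE]
    if (is.unsorted(s$pos, strictly = TRUE))
      stop("selected SNPs must be sorted by position within chromosome")
    grp <- cumsum(c(FALSE, diff(s$pos) > max_gap))
    for (g in unique(grp)) {
      sg <- s[grp == g, , drop = FALSE]
      if (nrow(sg) < min_snps) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = sg$pos[1L], end = sg$pos[nrow(sg)],
        n_snps = nrow(sg),
        peak_incidence = if (is.null(sg$incidence)) NA_real_ else
          max(sg$incidence))
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_snps = integer(0), peak_incidence = numeric(0))
  res$length_bp <- if (nrow(res)) res$end - res$start + 1 else numeric(0)
  res <- res[c("chrom", "start", "end", "length_bp", "n_snps",
               "peak_incidence")]
  rownames(res) <- NULL
  class(res) <- c("roh_islands", "data.frame")
  res
}

#' Annotate ROH islands with overlapping genes
#'
#' Reads gene annotation from a BED or GFF3 file (via
#' \pkg{rtracklayer}; BED's 0-based half-open intervals become 1-based
#' inclusive on import) and lists, for every island, the genes whose
#' interval overlaps the island interval by at least 1 bp. For GFF3, only
#' features of type `gene` are used when present; gene identifiers are taken
#' from the `Name`, `ID` or `gene_id` attribute (BED: the name column).
#'
#' @param islands An `"roh_islands"` object.
#' @param annotation Path to a BED or GFF3 file, or a
#'   `GenomicRanges::GRanges` of gene intervals with a usable name column.
#' @return `islands` with an added list-column `genes` (character vector of
#'   gene IDs per island); a warning and empty lists if no gene feature is
#'   found.
#' @export
annotate_genes <- function(islands, annotation) {
  gr <- if (inherits(annotation, "GRanges")) annotation else
    rtracklayer::import(annotation)
  meta <- S4Vectors::mcols(gr)
  if (!is.null(meta$type) && any(as.character(meta$type) == "gene")) {
    gr <- gr[as.character(meta$type) == "gene"]
    meta <- S4Vectors::mcols(gr)
  }
  ids <- NULL
  for (field in c("Name", "ID", "gene_id", "name"))
    if (is.null(ids) && !is.null(meta[[field]]))
      ids <- as.character(meta[[field]])
  if (length(gr) == 0L || is.null(ids)) {
    warning("no gene features found in annotation; empty gene lists")
    islands$genes <- replicate(nrow(islands), character(0), simplify = FALSE)
    return(islands)
  }
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  isl_gr <- GenomicRanges::GRanges(
    islands$chrom, IRanges::IRanges(islands$start, islands$end))
  hits <- GenomicRanges::findOverlaps(isl_gr, gr, minoverlap = 1L)
  islands$genes <- lapply(seq_len(nrow(islands)), function(k)
    unique(ids[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == k]]))
  islands
}

#' Detect and annotate ROH islands on a panel
#'
#' Convenience wrapper chaining [snp_incidence()],
#' [top_percentile_threshold()], [merge_islands()] and (optionally)
#' [annotate_genes()].
#'
#' @param roh An `"roh"` object from [call_roh()].
#' @param sites Data frame `chrom, pos` of the genotyped SNPs.
#' @param n_individuals Number of genotyped individuals (defaults to the
#'   sample list on `roh`).
#' @param top_fraction Fraction of SNPs selected as candidates.
#' @param max_gap,min_snps Island merging parameters (see [merge_islands()]).
#' @param annotation Optional BED/GFF3 path or `GRanges` of genes.
#' @return List of class `"roh_island_scan"`: `incidence`, `threshold`,
#'   `islands` (annotated when `annotation` given).
#' @export
roh_islands <- function(roh, sites, n_individuals = NULL,
                        top_fraction = 0.01, max_gap = 500000, min_snps = 2,
                        annotation = NULL) {
  inc <- snp_incidence(roh, sites, n_individuals)
  top <- top_percentile_threshold(inc, top_fraction)
  isl <- merge_islands(top$selected, max_gap = max_gap, min_snps = min_snps)
  if (!is.null(annotation)) isl <- annotate_genes(isl, annotation)
  structure(list(incidence = inc, threshold = top$threshold, islands = isl),
            class = "roh_island_scan")
}

#' @export
print.roh_island_scan <- function(x, ...) {
  cat(sprintf("ROH island scan: %d SNPs, incidence threshold %.4f\n",
              nrow(x$incidence), x$threshold))
  cat(sprintf("  %d island(s)\n", nrow(x$islands)))
  if (nrow(x$islands)) {
    df <- as.data.frame(x$islands)
    if (!is.null(df$genes))
      df$genes <- vapply(df$genes, function(g)
        if (length(g)) paste(g, collapse = ",") else "", character(1))
    print(df)
  }
  invisible(x)
}
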