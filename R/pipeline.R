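#' Run the full ROH analysis pipeline on a genotype panel
#'
#' Orchestrates QC, diversity and LD statistics, ROH calling with length
#' classification, the three genomic inbreeding estimators, and the ROH
#' island scan, writing every stage's result as TSV into `out_dir` together
#' with a JSON run manifest (package version, full parameter set, input
#' checksums).
#'
#' @param vcf Path to a multi-sample VCF, or a [genotype_matrix()].
#' @param chrom_lengths Path to a `chrom<TAB>length_bp` TSV, or a data frame.
#' @param out_dir Output directory (created if needed).
#' @param qc A [qc_params()] object, or `NULL` to skip QC.
#' @param roh A [roh_params()] object.
#' @param l_auto `"900Mb"` (the chicken autosome convention, 9e8 bp),
#'   `"from-lengths"` (sum of `chrom_lengths`), or a number in bp.
#' @param autosomes Optional chromosome whitelist passed to [qc_filter()];
#'   defaults to all chromosomes in `chrom_lengths`.
#' @param top_fraction,island_max_gap,island_min_snps Island-scan parameters
#'   (see [roh_islands()]).
#' @param annotation Optional BED/GFF3 gene annotation for island annotation.
#' @param ld_max_dist,ld_n_bins LD-decay parameters (see [ld_decay()]);
#'   `ld_max_dist = 0` skips the LD stage.
#' @param window_grid Optional ascending window sizes for a
#'   [sensitivity_sweep()]; `NULL` skips the sweep.
#' @return Invisibly, a list with every stage's in-memory result
#'   (`genotypes, qc_report, diversity, ld, roh, length_classes, coverage,
#'   inbreeding, inbreeding_summary, islands, sweep, manifest`).
#' @export
analyze_panel <- function(vcf, chrom_lengths, out_dir,
                          qc = qc_params(), roh = roh_params(),
                          l_auto = "900Mb", autosomes = NULL,
                          top_fraction = 0.01, island_max_gap = 500000,
                          island_min_snps = 2, annotation = NULL,
                          ld_max_dist = 300000, ld_n_bins = 100,
                          window_grid = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (is.character(vcf)) inputs <- c(inputs, vcf = vcf)
  if (is.character(chrom_lengths))
    inputs <- c(inputs, chrom_lengths = chrom_lengths)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  gm <- stage("read", if (inherits(vcf, "genotype_matrix")) vcf else
    read_vcf(vcf))
  cl <- stage("read", if (is.data.frame(chrom_lengths)) chrom_lengths else
    read_chrom_lengths(chrom_lengths))
  if (is.null(autosomes)) autosomes <- cl$chrom
  l_auto_bp <- switch(as.character(l_auto[1L]),
                      "900Mb" = 9e8,
                      "from-lengths" = l_auto_from_lengths(cl),
                      as.numeric(l_auto))
  rep_obj <- NULL
  if (!is.null(qc)) {
    gm <- stage("qc", qc_filter(gm, qc, chroms = autosomes))
    rep_obj <- qc_report(gm)
    write_qc_report(rep_obj, tsv = file.path(out_dir, "qc_report.tsv"),
                    json = file.path(out_dir, "qc_report.json"))
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    name
  }
  div <- stage("diversity", diversity_stats(gm))
  tsv(div$per_site, "diversity_per_site.tsv")
  tsv(cbind(div$summary, p_n = div$p_n), "diversity_summary.tsv")
  ld <- NULL
  if (ld_max_dist > 0) {
    ld <- stage("ld", ld_decay(gm, max_dist = ld_max_dist,
                               n_bins = ld_n_bins))
    tsv(as.data.frame(ld), "ld_decay.tsv")
  }
  roh_set <- stage("roh", call_roh(gm, cl, roh))
  write_roh(roh_set, file.path(out_dir, "roh.tsv"))
  classes <- classify_lengths(roh_set)
  tsv(as.data.frame(classes), "roh_length_classes.tsv")
  cov <- chromosome_coverage(roh_set)
  tsv(cov, "roh_chromosome_coverage.tsv")
  inb <- stage("inbreeding",
               inbreeding(gm, roh = roh_set, chrom_lengths = cl,
                          l_auto = if (identical(l_auto[1L], "from-lengths"))
                            "from-lengths" else l_auto_bp))
  tsv(as.data.frame(inb), "inbreeding.tsv")
  inb_sum <- estimator_table(inb)
  tsv(inb_sum$summary, "inbreeding_summary.tsv")
  utils::write.table(inb_sum$correlations,
                     file.path(out_dir, "inbreeding_correlations.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  isl <- stage("islands",
               roh_islands(roh_set, gm$sites,
                           top_fraction = top_fraction,
                           max_gap = island_max_gap,
                           min_snps = island_min_snps,
                           annotation = annotation))
  tsv(isl$incidence, "incidence.tsv")
  tsv(cbind(isl$incidence, threshold = isl$threshold), "manhattan.tsv")
  isl_df <- as.data.frame(isl$islands)
  if (!is.null(isl_df$genes)) {
    writeLines(unique(unlist(isl_df$genes)),
               file.path(out_dir, "island_genes.txt"))
    isl_df$genes <- vapply(isl_df$genes, paste, character(1), collapse = ",")
  }
  tsv(isl_df, "islands.tsv")
  sweep_tab <- NULL
  if (!is.null(window_grid)) {
    sweep_tab <- stage("sweep",
                       sensitivity_sweep(gm, cl, window_grid, roh))
    tsv(sweep_tab, "sensitivity_sweep.tsv")
  }
  manifest <- list(
    package = "rohscan",
    version = as.character(utils::packageVersion("rohscan")),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    n_individuals = n_indiv(gm), n_sites_after_qc = n_sites(gm),
    params = list(qc = if (!is.null(qc)) unclass(qc),
                  roh = unclass(roh), l_auto = l_auto_bp,
                  autosomes = autosomes,
                  islands = list(top_fraction = top_fraction,
                                 max_gap = island_max_gap,
                                 min_snps = island_min_snps),
                  ld = list(max_dist = ld_max_dist, n_bins = ld_n_bins),
                  window_grid = window_grid))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genotypes = gm, qc_report = rep_obj, diversity = div,
                 ld = ld, roh = roh_set, length_classes = classes,
                 coverage = cov, inbreeding = inb,
                 inbreeding_summary = inb_sum, islands = isl,
                 sweep = sweep_tab, manifest = manifest))
}

#' Simulate a panel and write it to disk
#'
#' Convenience wrapper around [sim_panel()] and [write_sim_panel()] for
#' driving the pipeline from files.
#'
#' @param out_dir Output directory.
#' @param ped A [pedigree()] or path to a pedigree TSV.
#' @param config A [sim_config()].
#' @return Named vector of written paths, invisibly.
#' @export
simulate_panel_files <- function(out_dir, ped = mixed_pedigree(),
                                 config = sim_config()) {
  if (is.character(ped)) ped <- read_pedigree(ped)
  panel <- sim_panel(ped, config)
  write_sim_panel(panel, out_dir)
}
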