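#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) and keeps only biallelic SNP
#' records: exactly one alternate allele, both REF and ALT a single base in
#' `A/C/G/T`. Indels, multiallelic and symbolic records are dropped silently.
#' GT is parsed phase-insensitively (`0/1` and `0|1` are equivalent);
#' `./.` and half-calls such as `./1` become missing. Haploid GT fields are
#' rejected — the package models diploid autosomes only.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L)
    stop("VCF has zero sample columns: ", path)
  fix <- v@fix
  keep <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  if (!any(keep)) {
    fix <- fix[0, , drop = FALSE]
    gt_raw <- gt_raw[0, , drop = FALSE]
  } else {
    fix <- fix[keep, , drop = FALSE]
    gt_raw <- gt_raw[keep, , drop = FALSE]
  }
  samples <- colnames(gt_raw)[-1L]
  fmt <- gt_raw[, 1L]
  has_gt <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (nrow(fix) && !all(has_gt))
    stop("record ", which(!has_gt)[1L], " lacks GT in its FORMAT field")
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  gt_str <- gt_raw[, -1L, drop = FALSE]
  if (nrow(fix)) {
    # strip trailing FORMAT subfields, keeping only GT
    first <- !is.na(gt_idx) & gt_idx == 1L
    gt_str[first, ] <- sub(":.*$", "", gt_str[first, ])
    if (any(!first))
      for (r in which(!first))
        gt_str[r, ] <- vapply(strsplit(gt_str[r, ], ":", fixed = TRUE),
                              `[`, character(1), gt_idx[r])
  }
  codes <- decode_gt(gt_str)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      qual = qual, stringsAsFactors = FALSE)
  genotype_matrix(t(codes), sites, samples)
}

# map GT strings (records x samples) to codes; errors name the record index
decode_gt <- function(gt_str) {
  u <- unique(as.vector(gt_str))
  map <- vapply(u, function(g) {
    if (is.na(g) || g == "." || g == "./." || g == ".|.") return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (length(al) == 1L)
      return(-2L)   # haploid -> rejected below
    if (length(al) != 2L) return(-1L)
    if (any(al == ".")) return(NA_integer_)   # half-call -> missing
    if (!all(al %in% c("0", "1"))) return(-1L)
    sum(as.integer(al))
  }, integer(1))
  codes <- matrix(map[match(as.vector(gt_str), u)],
                  nrow = nrow(gt_str), ncol = ncol(gt_str))
  if (any(codes == -2L, na.rm = TRUE)) {
    r <- which(apply(codes == -2L, 1L, any, na.rm = TRUE))[1L]
    stop("haploid GT in record ", r, "; diploid calls required")
  }
  if (any(codes == -1L, na.rm = TRUE)) {
    r <- which(apply(codes == -1L, 1L, any, na.rm = TRUE))[1L]
    stop("malformed GT field in record ", r)
  }
  codes
}

#' Write a genotype matrix as a minimal VCF v4.2
#'
#' Emits CHROM, POS, ID (`.`), REF, ALT, QUAL, FILTER (`.`), INFO (`.`),
#' FORMAT (`GT`) and one column per sample. `read_vcf(write_vcf(m))`
#' reproduces `m` exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rohscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  if (n_sites(gm) > 0L) {
    gt_char <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L],
                      nrow = n_indiv(gm))
    gt_char[is.na(gm$calls)] <- "./."
    qual <- ifelse(is.na(gm$sites$qual), ".", as.character(gm$sites$qual))
    body <- cbind(gm$sites$chrom, as.character(gm$sites$pos), ".",
                  gm$sites$ref, gm$sites$alt, qual, ".", ".", "GT",
                  t(gt_char))
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a chromosome-length table
#'
#' Two-column tab-separated file `chrom<TAB>length_bp`, no header required
#' (a `chrom` header line is tolerated and skipped).
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `chrom` (character) and `length_bp`
#'   (numeric).
#' @export
read_chrom_lengths <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length_bp"),
                           colClasses = c("character", "character"),
                           comment.char = "#")
  if (tab$chrom[1L] == "chrom") tab <- tab[-1L, , drop = FALSE]
  tab$length_bp <- as.numeric(tab$length_bp)
  if (any(is.na(tab$length_bp)) || any(tab$length_bp <= 0))
    stop("chromosome lengths must be positive numbers")
  rownames(tab) <- NULL
  tab
}
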