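#' Construct and validate a pedigree
#'
#' @param id Character vector of individual IDs (unique).
#' @param sire,dam Parent IDs; `NA`, `""` or `"0"` marks an unknown parent.
#'   An individual with both parents unknown is a founder.
#' @details Parents must precede their offspring in the listed order (which
#'   also makes the pedigree acyclic); individuals with exactly one known
#'   parent are rejected — gene dropping needs either two parents or none.
#' @return Data frame of class `"pedigree"` with columns
#'   `id, sire, dam, founder`.
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id)
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  sire <- clean(sire); dam <- clean(dam)
  if (anyDuplicated(id)) stop("duplicate individual IDs")
  founder <- is.na(sire) & is.na(dam)
  if (any(xor(is.na(sire), is.na(dam))))
    stop("individuals must have two known parents or none")
  for (k in which(!founder)) {
    for (par in c(sire[k], dam[k])) {
      at <- match(par, id)
      if (is.na(at)) stop("unknown parent '", par, "' of '", id[k], "'")
      if (at >= k) stop("parent '", par, "' listed at or after offspring '",
                        id[k], "'")
    }
  }
  structure(data.frame(id = id, sire = sire, dam = dam, founder = founder,
                       stringsAsFactors = FALSE),
            class = c("pedigree", "data.frame"))
}

#' Read a pedigree TSV
#'
#' Three tab-separated columns `id<TAB>sire<TAB>dam`, `"0"` for an unknown
#' parent; an optional `id` header line is skipped.
#'
#' @param path Path to the TSV.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           col.names = c("id", "sire", "dam"))
  if (tab$id[1L] == "id") tab <- tab[-1L, , drop = FALSE]
  pedigree(tab$id, tab$sire, tab$dam)
}

#' Pedigree inbreeding coefficients (tabular method)
#'
#' Builds the additive (numerator) relationship matrix by the standard
#' recursion — `A[i,j] = (A[sire_i,j] + A[dam_i,j]) / 2` for earlier `j`,
#' `A[i,i] = 1 + A[sire_i, dam_i] / 2` — and returns `F = diag(A) - 1`.
#' Founders are taken as unrelated and non-inbred.
#'
#' @param ped A [pedigree()].
#' @return Named numeric vector of pedigree inbreeding coefficients.
#' @export
pedigree_f <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  a <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      a[i, i] <- 1
    } else {
      if (i > 1L) {
        j <- seq_len(i - 1L)
        a[i, j] <- (a[si[i], j] + a[di[i], j]) / 2
        a[j, i] <- a[i, j]
      }
      a[i, i] <- 1 + a[si[i], di[i]] / 2
    }
  }
  stats::setNames(diag(a) - 1, ped$id)
}

#' Simulation configuration
#'
#' Defaults describe the package's standard validation panel: 6 chromosomes
#' of 40 Mb with 8,000 SNPs each (one SNP per 5 kb, 240 Mb genome — large
#' enough that Mendelian sampling noise in realized autozygosity does not
#' swamp pedigree expectations), founder alternate-allele frequencies
#' uniform on `[0.05, 0.5]`, a chicken-like average recombination rate of
#' 3 cM/Mb, 0.1% genotyping error and 1% missingness.
#'
#' @param n_chrom Number of autosomes.
#' @param chrom_length Chromosome length in bp (all chromosomes equal).
#' @param n_sites SNPs per chromosome.
#' @param maf_range Founder alternate-allele frequency range
#'   `c(lo, hi)`, drawn uniformly per site.
#' @param recomb_rate Recombination rate in cM/Mb.
#' @param error_rate Per-call genotyping error probability.
#' @param missing_rate Per-call missingness probability.
#' @param seed Integer seed; fixes every source of randomness downstream.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_chrom = 6, chrom_length = 4e7, n_sites = 8000,
                       maf_range = c(0.05, 0.5), recomb_rate = 3,
                       error_rate = 0.001, missing_rate = 0.01, seed = 1) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (maf_range[1L] > maf_range[2L])
    stop("maf_range lower bound exceeds upper bound")
  if (any(c(error_rate, missing_rate) < 0 | c(error_rate, missing_rate) > 1))
    stop("rates must lie in [0, 1]")
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_length = as.numeric(chrom_length),
                 n_sites = as.integer(n_sites),
                 maf_range = as.numeric(maf_range),
                 recomb_rate = as.numeric(recomb_rate),
                 error_rate = error_rate, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a founder haplotype pool
#'
#' Site positions are drawn uniformly without replacement per chromosome and
#' sorted; the per-site alternate-allele frequency is uniform on
#' `maf_range`; founder haplotype alleles are drawn independently per site
#' (founders in linkage equilibrium). Each founder chromosome copy carries a
#' unique ancestral label (`1 .. 2 * n_founders`) that gene dropping
#' propagates to define true autozygosity.
#'
#' @param config A [sim_config()]; seeds the generator with `config$seed`.
#' @param n_founders Number of founder individuals.
#' @return An object of class `"founder_pool"`: list with `sites`
#'   (`chrom, pos, ref, alt`), per-site `freq`, per-chromosome haplotype
#'   allele matrices `haps` (`2 * n_founders` rows), `chrom_lengths` and
#'   `n_founders`.
#' @export
simulate_founders <- function(config, n_founders) {
  stopifnot(inherits(config, "sim_config"), n_founders >= 1)
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  sites <- list(); haps <- list(); freq <- list()
  for (ch in seq_len(config$n_chrom)) {
    pos <- sort(sample.int(config$chrom_length, config$n_sites))
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                  character(1))
    p <- stats::runif(length(pos), config$maf_range[1L],
                      config$maf_range[2L])
    h <- matrix(stats::rbinom(2L * n_founders * length(pos), 1L,
                              rep(p, each = 2L * n_founders)),
                nrow = 2L * n_founders)
    sites[[ch]] <- data.frame(chrom = as.character(ch), pos = pos,
                              ref = unname(ref), alt = unname(alt),
                              qual = NA_real_)
    freq[[ch]] <- p
    haps[[ch]] <- h
  }
  structure(list(sites = do.call(rbind, sites), freq = unlist(freq),
                 haps = haps,
                 chrom_lengths = data.frame(
                   chrom = as.character(seq_len(config$n_chrom)),
                   length_bp = rep(config$chrom_length, config$n_chrom)),
                 n_founders = as.integer(n_founders), config = config),
            class = "founder_pool")
}

# a haplotype track: data.frame(start, end, label), contiguous from 1 to L
new_track <- function(label, chrom_len)
  data.frame(start = 1, end = chrom_len, label = label)

# clip a track to [lo, hi]
clip_track <- function(track, lo, hi) {
  keep <- track$end >= lo & track$start <= hi
  t2 <- track[keep, , drop = FALSE]
  t2$start[1L] <- max(t2$start[1L], lo)
  t2$end[nrow(t2)] <- min(t2$end[nrow(t2)], hi)
  t2
}

# merge adjacent rows carrying the same label
compact_track <- function(track) {
  if (nrow(track) < 2L) return(track)
  new_run <- c(TRUE, track$label[-1L] != track$label[-nrow(track)])
  grp <- cumsum(new_run)
  data.frame(start = track$start[new_run],
             end = track$end[!duplicated(grp, fromLast = TRUE)],
             label = track$label[new_run])
}

# recombine two parental tracks into one gamete track
make_gamete <- function(h1, h2, chrom_len, morgans) {
  n_cross <- stats::rpois(1L, morgans)
  use_first <- stats::runif(1L) < 0.5
  if (n_cross == 0L) return(if (use_first) h1 else h2)
  bks <- sort(unique(ceiling(stats::runif(n_cross) * (chrom_len - 1))))
  cuts <- c(0, bks, chrom_len)
  pieces <- vector("list", length(cuts) - 1L)
  for (k in seq_along(pieces)) {
    src <- if (xor(use_first, k %% 2L == 0L)) h1 else h2
    pieces[[k]] <- clip_track(src, cuts[k] + 1, cuts[k + 1L])
  }
  compact_track(do.call(rbind, pieces))
}

# maximal intervals where the two tracks carry the same ancestral label
autozygous_intervals <- function(h1, h2) {
  cuts <- sort(unique(c(h1$start, h2$start)))
  ends <- c(cuts[-1L] - 1, h1$end[nrow(h1)])
  l1 <- h1$label[findInterval(cuts, h1$start)]
  l2 <- h2$label[findInterval(cuts, h2$start)]
  same <- l1 == l2
  if (!any(same)) return(NULL)
  piece <- data.frame(start = cuts[same], end = ends[same])
  # merge touching pieces
  gap_new <- c(TRUE, piece$start[-1L] != piece$end[-nrow(piece)] + 1)
  grp <- cumsum(gap_new)
  data.frame(start = piece$start[gap_new],
             end = piece$end[!duplicated(grp, fromLast = TRUE)])
}

#' Drop founder haplotypes through a pedigree
#'
#' Every non-founder inherits one recombinant gamete per parent: the
#' crossover count per chromosome is Poisson with mean equal to the map
#' length in Morgans (`chrom_length/1e6 * recomb_rate / 100`; no
#' interference, no obligate chiasma), breakpoints uniform along the
#' chromosome. Ancestral labels travel with the recombining haplotypes;
#' the true autozygous segments of an individual are the maximal intervals
#' where its two labels coincide. Pedigree inbreeding coefficients come from
#' [pedigree_f()].
#'
#' @param ped A [pedigree()].
#' @param founders A [simulate_founders()] pool with at least as many
#'   founders as `ped` declares. Gene dropping is seeded with
#'   `config$seed + 1` so the founder pool and the drop are independently
#'   reproducible.
#' @param config The [sim_config()] used for the pool.
#' @return List of class `"sim_panel"`: `genotypes` (a noise-free
#'   [genotype_matrix()]), `truth` (list with `f_ped` and data frame
#'   `segments`: `individual, chrom, start, end, length_bp`),
#'   `chrom_lengths`, `pedigree` and `config`.
#' @export
gene_drop <- function(ped, founders, config = founders$config) {
  stopifnot(inherits(ped, "pedigree"), inherits(founders, "founder_pool"))
  n_f <- sum(ped$founder)
  if (n_f > founders$n_founders)
    stop("pedigree has more founders than the founder pool")
  set.seed(config$seed + 1L)
  chrom_len <- config$chrom_length
  morgans <- chrom_len / 1e6 * config$recomb_rate / 100
  n <- nrow(ped)
  tracks <- vector("list", n)           # tracks[[i]][[chrom]] = list(h1, h2)
  names(tracks) <- ped$id
  f_idx <- cumsum(ped$founder)
  for (i in seq_len(n)) {
    tracks[[i]] <- vector("list", config$n_chrom)
    if (ped$founder[i]) {
      for (ch in seq_len(config$n_chrom))
        tracks[[i]][[ch]] <- list(h1 = new_track(2L * f_idx[i] - 1L, chrom_len),
                                  h2 = new_track(2L * f_idx[i], chrom_len))
    } else {
      s <- tracks[[match(ped$sire[i], ped$id)]]
      d <- tracks[[match(ped$dam[i], ped$id)]]
      for (ch in seq_len(config$n_chrom))
        tracks[[i]][[ch]] <- list(
          h1 = make_gamete(s[[ch]]$h1, s[[ch]]$h2, chrom_len, morgans),
          h2 = make_gamete(d[[ch]]$h1, d[[ch]]$h2, chrom_len, morgans))
    }
  }
  # genotypes from ancestral labels
  calls <- matrix(NA_integer_, nrow = n, ncol = nrow(founders$sites))
  offset <- 0L
  for (ch in seq_len(config$n_chrom)) {
    pos <- founders$sites$pos[founders$sites$chrom == as.character(ch)]
    sidx <- offset + seq_along(pos)
    hap <- founders$haps[[ch]]
    for (i in seq_len(n)) {
      tr <- tracks[[i]][[ch]]
      l1 <- tr$h1$label[findInterval(pos, tr$h1$start)]
      l2 <- tr$h2$label[findInterval(pos, tr$h2$start)]
      calls[i, sidx] <- hap[cbind(l1, seq_along(pos))] +
        hap[cbind(l2, seq_along(pos))]
    }
    offset <- offset + length(pos)
  }
  # truth autozygous segments
  segs <- list()
  for (i in seq_len(n))
    for (ch in seq_len(config$n_chrom)) {
      iv <- autozygous_intervals(tracks[[i]][[ch]]$h1, tracks[[i]][[ch]]$h2)
      if (!is.null(iv))
        segs[[length(segs) + 1L]] <- cbind(individual = ped$id[i],
                                           chrom = as.character(ch), iv)
    }
  truth_segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(individual = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0))
  truth_segments$length_bp <- truth_segments$end - truth_segments$start + 1
  rownames(truth_segments) <- NULL
  gm <- genotype_matrix(calls, founders$sites, ped$id)
  structure(list(genotypes = gm,
                 truth = list(f_ped = pedigree_f(ped),
                              segments = truth_segments),
                 chrom_lengths = founders$chrom_lengths,
                 pedigree = ped, config = config),
            class = "sim_panel")
}

#' Add genotyping error and missingness to a panel
#'
#' Each call is independently flipped to one of the two other genotype codes
#' (uniformly) with probability `error_rate`, then set missing with
#' probability `missing_rate`.
#'
#' @param gm A [genotype_matrix()].
#' @param error_rate,missing_rate Per-call probabilities in `[0, 1]`.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return The perturbed `genotype_matrix`.
#' @export
add_noise <- function(gm, error_rate, missing_rate, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (any(c(error_rate, missing_rate) < 0 | c(error_rate, missing_rate) > 1))
    stop("rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  calls <- gm$calls
  nc <- length(calls)
  if (error_rate > 0) {
    flip <- which(stats::runif(nc) < error_rate & !is.na(calls))
    if (length(flip)) {
      shift <- sample(1:2, length(flip), replace = TRUE)
      calls[flip] <- (calls[flip] + shift) %% 3L
    }
  }
  if (missing_rate > 0)
    calls[stats::runif(nc) < missing_rate] <- NA_integer_
  genotype_matrix(calls, gm$sites, gm$samples)
}

#' Simulate a complete genotype panel with truth
#'
#' Chains [simulate_founders()], [gene_drop()] and [add_noise()] under a
#' single configuration; all randomness derives from `config$seed`.
#'
#' @param ped A [pedigree()].
#' @param config A [sim_config()].
#' @return A `"sim_panel"` (see [gene_drop()]) whose `genotypes` carry the
#'   configured error and missingness; the noise-free matrix is kept as
#'   `genotypes_clean`.
#' @export
sim_panel <- function(ped, config = sim_config()) {
  founders <- simulate_founders(config, sum(ped$founder))
  panel <- gene_drop(ped, founders, config)
  panel$genotypes_clean <- panel$genotypes
  panel$genotypes <- add_noise(panel$genotypes, config$error_rate,
                               config$missing_rate, seed = config$seed + 2L)
  panel
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("Simulated panel: %d individuals (%d founders), %d chromosomes x %g Mb\n",
              nrow(x$pedigree), sum(x$pedigree$founder), x$config$n_chrom,
              x$config$chrom_length / 1e6))
  cat(sprintf("  %d SNPs; pedigree F: %s\n", n_sites(x$genotypes),
              paste(format(sort(unique(round(x$truth$f_ped, 4)))),
                    collapse = ", ")))
  invisible(x)
}

#' Write a simulated panel to disk
#'
#' Emits the genotypes as VCF (round-trips through [read_vcf()]), the truth
#' tables `truth_f.tsv` (`id, f_ped`) and `truth_segments.tsv`
#' (`id, chrom, start, end`, 1-based inclusive), and `chrom_lengths.tsv`.
#'
#' @param panel A `"sim_panel"` from [sim_panel()] or [gene_drop()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "sim_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "panel.vcf"),
             truth_f = file.path(dir, "truth_f.tsv"),
             truth_segments = file.path(dir, "truth_segments.tsv"),
             chrom_lengths = file.path(dir, "chrom_lengths.tsv"))
  write_vcf(panel$genotypes, paths["vcf"])
  utils::write.table(data.frame(id = names(panel$truth$f_ped),
                                f_ped = panel$truth$f_ped),
                     paths["truth_f"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  segs <- panel$truth$segments
  utils::write.table(data.frame(id = segs$individual, chrom = segs$chrom,
                                start = segs$start, end = segs$end),
                     paths["truth_segments"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$chrom_lengths, paths["chrom_lengths"],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(paths)
}

#' Example pedigrees for simulation studies
#'
#' `founder_pedigree(n)` is `n` unrelated founders (a Hardy–Weinberg panel
#' under gene dropping). `fullsib_pedigree(n_families, n_offspring)` builds
#' independent families, each mating two founders, taking two of their
#' full-sib offspring and mating those, yielding `n_offspring` terminal
#' individuals per family with pedigree F = 0.25; independent families keep
#' the Mendelian noise of realized autozygosity uncorrelated across
#' families, so the cohort mean converges to 0.25. `mixed_pedigree()` is a
#' fixed 60-individual pedigree of 6 independent full-sib-mating units
#' (terminal F = 0.25) and 5 independent half-sib-mating units (terminal
#' F = 0.125); all other individuals are outbred (F = 0).
#'
#' @param n Number of founders.
#' @param n_families Number of independent full-sib families.
#' @param n_offspring Terminal inbred offspring per family.
#' @return A [pedigree()].
#' @export
founder_pedigree <- function(n) {
  pedigree(paste0("f", seq_len(n)), rep(NA, n), rep(NA, n))
}

#' @rdname founder_pedigree
#' @export
fullsib_pedigree <- function(n_families = 40, n_offspring = 2) {
  rows <- list()
  for (f in seq_len(n_families)) {
    p <- function(x) paste0(x, f)
    rows <- c(rows, list(
      c(p("fa"), NA, NA), c(p("fb"), NA, NA),
      c(p("sa"), p("fa"), p("fb")), c(p("sb"), p("fa"), p("fb"))))
    for (k in seq_len(n_offspring))
      rows <- c(rows, list(c(paste0("o", f, "_", k), p("sa"), p("sb"))))
  }
  m <- do.call(rbind, rows)
  pedigree(m[, 1L], m[, 2L], m[, 3L])
}

#' @rdname founder_pedigree
#' @export
mixed_pedigree <- function() {
  rows <- list()
  # 6 independent full-sib units: founders fa/fb, sibs sa/sb, offspring o
  for (f in 1:6) {
    p <- function(x) paste0(x, f)
    rows <- c(rows, list(
      c(p("fa"), NA, NA), c(p("fb"), NA, NA),
      c(p("sa"), p("fa"), p("fb")), c(p("sb"), p("fa"), p("fb")),
      c(p("o"), p("sa"), p("sb"))))
  }
  # 5 independent half-sib units: one sire, two dams, half sibs ha/hb,
  # offspring v
  for (f in 1:5) {
    p <- function(x) paste0(x, f)
    rows <- c(rows, list(
      c(p("ms"), NA, NA), c(p("da"), NA, NA), c(p("db"), NA, NA),
      c(p("ha"), p("ms"), p("da")), c(p("hb"), p("ms"), p("db")),
      c(p("v"), p("ha"), p("hb"))))
  }
  m <- do.call(rbind, rows)
  pedigree(m[, 1L], m[, 2L], m[, 3L])
}

#' Simulated selection-sweep ROH fixture
#'
#' Builds a segment set emulating a selective sweep for validating the
#' island scan end-to-end without genotypes: a fraction of individuals
#' carry an ROH over one sweep locus (segment endpoints jittered across
#' carriers so the incidence ramps at the edges), on top of a uniform
#' background of short random ROH tuned to a target per-SNP incidence.
#'
#' @param n_individuals Panel size.
#' @param n_sites SNPs on a regular grid along the chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param sweep_center Sweep locus position in bp.
#' @param sweep_width Width of the swept haplotype in bp.
#' @param carrier_frac Fraction of individuals homozygous over the sweep.
#' @param background Target background per-SNP ROH incidence.
#' @param seed Integer seed.
#' @return List with `segments` (`individual, chrom, start, end,
#'   length_bp`), `sites` (`chrom, pos`), `n_individuals`, and
#'   `sweep_center`.
#' @export
sweep_fixture <- function(n_individuals = 50, n_sites = 5000,
                          chrom_length = 1e7, sweep_center = 5e6,
                          sweep_width = 1e5, carrier_frac = 0.8,
                          background = 0.05, seed = 1) {
  set.seed(seed)
  spacing <- chrom_length / n_sites
  sites <- data.frame(chrom = "1",
                      pos = round(seq(spacing / 2, chrom_length,
                                      by = spacing)))
  ids <- sprintf("ind%03d", seq_len(n_individuals))
  segs <- list()
  bg_len <- 12 * spacing                       # short background runs
  n_bg <- round(background * chrom_length / bg_len)
  for (i in seq_len(n_individuals)) {
    starts <- sort(sample.int(chrom_length - bg_len, n_bg))
    segs[[length(segs) + 1L]] <- data.frame(
      individual = ids[i], chrom = "1", start = starts,
      end = starts + bg_len - 1)
  }
  carriers <- sample(ids, round(carrier_frac * n_individuals))
  for (id in carriers) {
    shift <- round(stats::runif(1, -sweep_width / 4, sweep_width / 4))
    segs[[length(segs) + 1L]] <- data.frame(
      individual = id, chrom = "1",
      start = sweep_center - sweep_width / 2 + shift,
      end = sweep_center + sweep_width / 2 + shift)
  }
  segments <- do.call(rbind, segs)
  segments$length_bp <- segments$end - segments$start + 1
  list(segments = segments, sites = sites, n_individuals = n_individuals,
       sweep_center = sweep_center)
}

#' @rdname founder_pedigree
#' @param n_per_gen Individuals bred per generation.
#' @param n_gen Number of closed-breeding generations after the founders.
#' @param seed Seed for the random mate pairing.
#' @details `closed_line_pedigree()` breeds a small closed population by
#'   random pair mating for several generations, accumulating inbreeding by
#'   drift. The resulting autozygous segments span many ages, so short ROH
#'   dominate — the regime typical of conserved livestock populations.
#' @export
closed_line_pedigree <- function(n_per_gen = 10, n_gen = 8, seed = 1) {
  set.seed(seed)
  id <- paste0("g0_", seq_len(n_per_gen))
  sire <- rep(NA_character_, n_per_gen)
  dam <- rep(NA_character_, n_per_gen)
  prev <- id
  for (g in seq_len(n_gen)) {
    cur <- paste0("g", g, "_", seq_len(n_per_gen))
    for (k in seq_len(n_per_gen)) {
      pair <- sample(prev, 2L)
      id <- c(id, cur[k]); sire <- c(sire, pair[1L]); dam <- c(dam, pair[2L])
    }
    prev <- cur
  }
  pedigree(id, sire, dam)
}
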