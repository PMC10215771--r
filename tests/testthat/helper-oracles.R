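# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorised code paths.

# hit fractions by explicit enumeration of every window
oracle_window_scan <- function(codes, params) {
  s <- length(codes)
  w <- params$window_snps
  frac <- numeric(s)
  if (s < w) return(frac)
  starts <- 1:(s - w + 1)
  hom <- logical(length(starts))
  for (t in starts) {
    win <- codes[t:(t + w - 1)]
    hom[t] <- sum(win == 1, na.rm = TRUE) <= params$window_max_het &&
      sum(is.na(win)) <= params$window_max_missing
  }
  for (i in 1:s) {
    cover <- starts[starts <= i & starts + w - 1 >= i]
    frac[i] <- if (length(cover)) mean(hom[cover]) else 0
  }
  frac
}

# full caller for one individual on one chromosome, rules applied literally
oracle_call_roh_one <- function(codes, pos, params) {
  frac <- oracle_window_scan(codes, params)
  in_run <- frac >= params$hit_threshold
  segs <- list()
  cur <- integer(0)
  flush <- function(cur, segs) {
    if (length(cur)) {
      start <- pos[cur[1]]; end <- pos[cur[length(cur)]]
      len <- end - start + 1
      if (length(cur) >= params$min_snps && len >= params$min_length &&
          len / length(cur) <= params$min_density)
        segs[[length(segs) + 1]] <- data.frame(start = start, end = end,
                                               n_snps = length(cur))
    }
    segs
  }
  for (i in seq_along(codes)) {
    if (in_run[i]) {
      if (length(cur) &&
          (i - cur[length(cur)] > 1 ||
           pos[i] - pos[cur[length(cur)]] > params$max_gap)) {
        segs <- flush(cur, segs)
        cur <- integer(0)
      }
      cur <- c(cur, i)
    } else {
      segs <- flush(cur, segs)
      cur <- integer(0)
    }
  }
  segs <- flush(cur, segs)
  if (length(segs)) do.call(rbind, segs) else
    data.frame(start = numeric(0), end = numeric(0), n_snps = integer(0))
}

# per-SNP ROH incidence by the naive double loop
oracle_incidence <- function(segments, sites, n_individuals) {
  count <- integer(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    covered <- character(0)
    for (s in seq_len(nrow(segments))) {
      if (segments$chrom[s] == sites$chrom[k] &&
          segments$start[s] <= sites$pos[k] &&
          segments$end[s] >= sites$pos[k])
        covered <- union(covered, segments$individual[s])
    }
    count[k] <- length(covered)
  }
  count / n_individuals
}

# random genotype matrix on a handful of chromosomes
random_gm <- function(n_ind, n_site, n_chrom = 2, miss = 0.05,
                      span = 5e6) {
  chrom <- sort(rep_len(as.character(seq_len(n_chrom)), n_site))
  pos <- unlist(lapply(split(seq_len(n_site), chrom), function(ix)
    sort(sample.int(span, length(ix)))), use.names = FALSE)
  calls <- matrix(sample(0:2, n_ind * n_site, replace = TRUE,
                         prob = c(0.4, 0.3, 0.3)),
                  nrow = n_ind)
  calls[runif(length(calls)) < miss] <- NA
  genotype_matrix(calls,
                  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C"),
                  paste0("ind", seq_len(n_ind)))
}

# small shared simulated cohort, built once per test run
sim_cache <- new.env()
cached_mixed_panel <- function(seed = 20240915) {
  key <- paste0("mixed_", seed)
  if (is.null(sim_cache[[key]]))
    sim_cache[[key]] <- sim_panel(mixed_pedigree(), sim_config(seed = seed))
  sim_cache[[key]]
}
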