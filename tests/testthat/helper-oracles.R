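# Independent brute-force oracles and fixture builders. These deliberately
# re-derive every quantity with plain loops, sharing no code with the
# package internals they check.

# Build a genotype_matrix from per-individual genotype strings, e.g.
# "0011.2" -> HOM,HOM,HET,HET,MISSING,HOM_ALT; positions default to an even
# grid.
make_gm <- function(geno, chrom = NULL, pos = NULL, spacing = 20000) {
  m <- nchar(geno[[1]])
  calls <- do.call(rbind, lapply(geno, function(s) {
    x <- strsplit(s, "")[[1]]
    suppressWarnings(as.integer(x))  # "." -> NA
  }))
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) {
    pos <- unlist(lapply(split(seq_len(m), chrom)[as.character(unique(chrom))],
                         function(ix) seq_along(ix) * spacing))
  }
  genotype_matrix(calls,
                  data.frame(snp_id = paste0("s", seq_len(m)), chrom = chrom,
                             pos_bp = pos, allele1 = "A", allele2 = "G",
                             stringsAsFactors = FALSE),
                  paste0("I", seq_along(geno)))
}

# Brute-force sliding-window ROH caller: explicit enumeration of windows,
# per-SNP support, gap splitting and all filters.
oracle_detect_roh <- function(gm, p) {
  out <- list()
  for (i in seq_along(gm$individuals)) {
    for (chr in unique(gm$markers$chrom)) {
      jx <- which(gm$markers$chrom == chr)
      m <- length(jx)
      w <- p$window_snps
      if (m < w) next
      pos <- gm$markers$pos_bp[jx]
      g <- gm$calls[i, jx]
      W <- m - w + 1L
      hom <- logical(W)
      for (s in seq_len(W)) {
        win <- g[s:(s + w - 1L)]
        hom[s] <- sum(win == 1L, na.rm = TRUE) <= p$max_het_per_window &&
                  sum(is.na(win)) <= p$max_missing_per_window
      }
      inrun <- logical(m)
      for (j in seq_len(m)) {
        cover <- max(1L, j - w + 1L):min(j, W)
        inrun[j] <- mean(hom[cover]) >= p$window_support_threshold
      }
      # maximal stretches, split at big gaps
      j <- 1L
      while (j <= m) {
        if (!inrun[j]) { j <- j + 1L; next }
        k <- j
        while (k < m && inrun[k + 1L] && pos[k + 1L] - pos[k] <= p$max_gap_bp)
          k <- k + 1L
        nsnp <- k - j + 1L
        len <- pos[k] - pos[j]
        if (nsnp >= p$min_snps_in_run && len >= p$min_length_bp &&
            (p$min_density <= 0 || nsnp / len >= p$min_density))
          out[[length(out) + 1L]] <- data.frame(
            individual = gm$individuals[i], chrom = chr,
            start_bp = pos[j], end_bp = pos[k], n_snps = nsnp, length_bp = len)
        j <- k + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(individual = character(0), chrom = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), length_bp = numeric(0)))
  res <- do.call(rbind, out)
  res[order(match(res$individual, gm$individuals), res$chrom, res$start_bp), ]
}

# O(n*m) interval-stabbing oracle for SNP incidence.
oracle_incidence <- function(segments, gm) {
  counts <- integer(nrow(gm$markers))
  for (j in seq_len(nrow(gm$markers))) {
    chr <- gm$markers$chrom[j]; pp <- gm$markers$pos_bp[j]
    hit <- unique(segments$individual[segments$chrom == chr &
                                        segments$start_bp <= pp &
                                        segments$end_bp >= pp])
    counts[j] <- length(hit)
  }
  counts
}

# Direct log-factorial enumeration of the exact HWE p-value (independent of
# the package's ratio recurrence).
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2 * n_aa + n_ab
  nB <- 2 * n - nA
  if (nA == 0 || nB == 0) return(1)
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  lp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2; nbb <- (nB - h) / 2
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp)
  p_obs <- pr[match(n_ab, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# All-pairs interval overlap oracle (1-based closed intervals).
oracle_overlap_count <- function(islands, genes) {
  cnt <- 0L
  for (i in seq_len(nrow(islands)))
    for (g in seq_len(nrow(genes)))
      if (islands$chrom[i] == genes$chrom[g] &&
          islands$start_bp[i] <= genes$end_bp[g] &&
          islands$end_bp[i] >= genes$start_bp[g])
        cnt <- cnt + 1L
  cnt
}

# Random genotype matrix for fuzz tests.
rand_gm <- function(n, m, het = 0.3, miss = 0.02, n_chrom = 1L,
                    spacing_max = 60000) {
  chrom <- sort(rep_len(seq_len(n_chrom), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    cumsum(sample.int(spacing_max, length(ix), replace = TRUE))))
  calls <- matrix(sample(c(0L, 1L, 2L), n * m, replace = TRUE,
                         prob = c((1 - het) / 2, het, (1 - het) / 2)), n, m)
  calls[matrix(runif(n * m) < miss, n, m)] <- NA_integer_
  genotype_matrix(calls,
                  data.frame(snp_id = paste0("s", seq_len(m)), chrom = chrom,
                             pos_bp = as.numeric(pos), allele1 = "A",
                             allele2 = "G", stringsAsFactors = FALSE),
                  paste0("I", seq_len(n)))
}

rand_roh_params <- function() {
  roh_params(window_snps = sample(5:25, 1),
             min_snps_in_run = sample(5:30, 1),
             window_support_threshold = runif(1, 0.02, 0.5),
             max_gap_bp = sample(c(5e4, 1e5, 1e6), 1),
             min_length_bp = sample(c(1e4, 1e5, 5e5), 1),
             max_het_per_window = sample(0:1, 1),
             max_missing_per_window = sample(0:2, 1),
             min_density = sample(c(0, 1 / 50000), 1))
}
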