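# Synthetic SNP-array populations with planted ROH structure.
#
# Background genotypes are independent Hardy-Weinberg draws given per-SNP
# allele frequencies from a symmetric Beta chosen so the mean expected
# heterozygosity matches the target; homozygous tracts (per-individual, in
# four length classes) and shared islands (fixed interval, chosen carrier
# fraction) are planted on top by overwriting calls with the locally major
# homozygote; missingness is applied last. The generator trades linkage
# realism for an analyzable ground truth: every downstream statistic in
# the package depends only on hom/het/missing runs.

#' Simulation configuration
#'
#' The default configuration emulates the diversity and ROH landscape of a
#' medium-density equine array study at desk scale: background
#' heterozygosity 0.32, SNP density 28 per Mb, per-individual tract counts
#' split across the four generational length classes in roughly 76/13/9/2
#' proportions with total coverage near 0.15 of the genome. The default
#' genome is 5 chromosomes of 100 Mb (2,800 SNPs each).
#'
#' @param seed RNG seed (mandatory).
#' @param n number of individuals.
#' @param chromosomes data.frame with `chrom`, `n_snps`, `length_bp`.
#' @param het target mean expected heterozygosity, must be < 0.5.
#' @param missing_rate per-call missing probability (applied after
#'   planting).
#' @param tract_error_rate per-SNP probability of a heterozygous
#'   genotyping error inside planted tracts.
#' @param tract_rates_per_gb expected number of planted tracts per
#'   individual per Gb of genome, one entry per length class.
#' @param class_bounds_mb length-class boundaries in Mb; tract lengths are
#'   uniform within their class.
#' @param islands data.frame with `chrom`, `center_bp`, `span_bp`,
#'   `carrier_frac` (possibly empty = no islands).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n = 50L,
                       chromosomes = data.frame(chrom = 1:5,
                                                n_snps = 2800L,
                                                length_bp = 1e8),
                       het = 0.32,
                       missing_rate = 0.005,
                       tract_error_rate = 0,
                       tract_rates_per_gb = c(26.7, 4.4, 3.2, 0.65),
                       class_bounds_mb = c(1, 5.5, 8.3, 16.6, 30),
                       islands = data.frame(chrom = integer(0),
                                            center_bp = numeric(0),
                                            span_bp = numeric(0),
                                            carrier_frac = numeric(0))) {
  if (missing(seed)) stop("seed is mandatory")
  if (het >= 0.5) stop("infeasible heterozygosity target: must be < 0.5")
  stopifnot(het > 0, missing_rate >= 0, missing_rate <= 1,
            tract_error_rate >= 0, tract_error_rate <= 1,
            length(tract_rates_per_gb) == length(class_bounds_mb) - 1L,
            all(diff(class_bounds_mb) > 0),
            all(islands$carrier_frac >= 0 & islands$carrier_frac <= 1),
            all(islands$span_bp <
                  chromosomes$length_bp[match(islands$chrom, chromosomes$chrom)]))
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 chromosomes = chromosomes, het = het,
                 missing_rate = missing_rate,
                 tract_error_rate = tract_error_rate,
                 tract_rates_per_gb = tract_rates_per_gb,
                 class_bounds_mb = class_bounds_mb,
                 islands = islands),
            class = "sim_config")
}

#' Simulate a SNP-array population with planted ROH structure
#'
#' Draws SNP positions uniformly per chromosome, per-SNP alternate-allele
#' frequencies from `Beta(a, a)` with `a = het / (1 - 2 het)` (so the mean
#' of `2p(1-p)` equals the target heterozygosity), background genotypes as
#' independent Hardy-Weinberg draws, then plants per-individual homozygous
#' tracts and shared island tracts by overwriting calls with the
#' major-allele homozygote, and finally applies missingness. Identical
#' seeds give identical output.
#'
#' @param cfg a [sim_config].
#' @return list with `gm` (a [genotype_matrix]) and `truth`, a list of
#'   `tracts` (planted intervals incl. island copies: `individual`,
#'   `chrom`, `start_bp`, `end_bp`, `class`, `source`, plus grid-snapped
#'   `start_snap`/`end_snap` of the first/last covered SNP), `islands`
#'   (the configured intervals with a `carriers` list-column), `q`
#'   (named per-individual planted coverage: merged snapped tract length
#'   over covered genome length) and `genome` (the [genome_spec] of
#'   SNP-covered lengths).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrs <- cfg$chromosomes
  n <- cfg$n
  a <- cfg$het / (1 - 2 * cfg$het)

  pos_l <- lapply(seq_len(nrow(chrs)), function(k)
    sort(sample.int(chrs$length_bp[k], chrs$n_snps[k])))
  m <- sum(chrs$n_snps)
  markers <- data.frame(
    snp_id = paste0("snp", seq_len(m)),
    chrom = rep(chrs$chrom, chrs$n_snps),
    pos_bp = as.numeric(unlist(pos_l)),
    allele1 = "A", allele2 = "G", stringsAsFactors = FALSE)

  p_alt <- stats::rbeta(m, a, a)
  calls <- matrix(stats::rbinom(n * m, 2L, rep(p_alt, each = n)), n, m)
  major_hom <- ifelse(p_alt >= 0.5, GT_HOM_ALT, GT_HOM_REF)

  individuals <- sprintf("ind%03d", seq_len(n))
  genome_gb <- sum(chrs$length_bp) / 1e9
  exp_counts <- cfg$tract_rates_per_gb * genome_gb
  bounds <- cfg$class_bounds_mb * 1e6
  n_class <- length(exp_counts)

  tracts <- list()
  plant <- function(i, chrom, start, end, class, source) {
    k <- which(markers$chrom == chrom & markers$pos_bp >= start &
                 markers$pos_bp <= end)
    if (length(k)) {
      g <- major_hom[k]
      if (cfg$tract_error_rate > 0) {
        err <- stats::runif(length(k)) < cfg$tract_error_rate
        g[err] <- GT_HET
      }
      calls[i, k] <<- g
    }
    snap_s <- if (length(k)) markers$pos_bp[k[1]] else NA_real_
    snap_e <- if (length(k)) markers$pos_bp[k[length(k)]] else NA_real_
    tracts[[length(tracts) + 1L]] <<- data.frame(
      individual = individuals[i], chrom = chrom, start_bp = start,
      end_bp = end, class = class, source = source,
      start_snap = snap_s, end_snap = snap_e, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n)) {
    placed <- list()
    for (cl in seq_len(n_class)) {
      cnt <- stats::rpois(1L, exp_counts[cl])
      for (t in seq_len(cnt)) {
        for (try in 1:20) {
          chrom_k <- sample.int(nrow(chrs), 1L, prob = chrs$length_bp)
          len <- stats::runif(1L, bounds[cl], bounds[cl + 1L])
          if (len >= chrs$length_bp[chrom_k]) next
          start <- floor(stats::runif(1L, 1, chrs$length_bp[chrom_k] - len))
          end <- start + len
          chrom <- chrs$chrom[chrom_k]
          ovl <- any(vapply(placed, function(pl)
            pl$chrom == chrom && start <= pl$end && end >= pl$start,
            logical(1)))
          if (!ovl) {
            placed[[length(placed) + 1L]] <- list(chrom = chrom, start = start,
                                                  end = end)
            plant(i, chrom, start, end, cl, "tract")
            break
          }
        }
      }
    }
  }

  isl <- cfg$islands
  carriers_l <- vector("list", nrow(isl))
  if (nrow(isl)) {
    for (s in seq_len(nrow(isl))) {
      carr <- sort(sample.int(n, round(isl$carrier_frac[s] * n)))
      carriers_l[[s]] <- individuals[carr]
      start <- max(1, isl$center_bp[s] - isl$span_bp[s] / 2)
      end <- min(chrs$length_bp[match(isl$chrom[s], chrs$chrom)],
                 isl$center_bp[s] + isl$span_bp[s] / 2)
      for (i in carr) plant(i, isl$chrom[s], start, end, NA_integer_, "island")
    }
  }
  isl$carriers <- carriers_l

  if (cfg$missing_rate > 0) {
    miss <- stats::runif(n * m) < cfg$missing_rate
    calls[miss] <- NA_integer_
  }

  gm <- genotype_matrix(calls, markers, individuals)
  spec <- genome_spec_from_gm(gm)
  tr <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(individual = character(0), chrom = integer(0),
               start_bp = numeric(0), end_bp = numeric(0),
               class = integer(0), source = character(0),
               start_snap = numeric(0), end_snap = numeric(0))
  q <- planted_coverage(tr, individuals, spec)
  list(gm = gm,
       truth = list(tracts = tr, islands = isl, q = q, genome = spec))
}

# Per-individual planted coverage on the SNP grid: merged snapped tract
# length (end - start) over total covered genome length.
planted_coverage <- function(tracts, individuals, spec) {
  q <- stats::setNames(numeric(length(individuals)), individuals)
  tr <- tracts[!is.na(tracts$start_snap), , drop = FALSE]
  if (!nrow(tr)) return(q)
  for (i in unique(tr$individual)) {
    tot <- 0
    ti <- tr[tr$individual == i, , drop = FALSE]
    for (ch in unique(ti$chrom)) {
      tc <- ti[ti$chrom == ch, , drop = FALSE]
      o <- order(tc$start_snap)
      s <- tc$start_snap[o]; e <- tc$end_snap[o]
      cur_s <- s[1]; cur_e <- e[1]
      for (k in seq_along(s)[-1]) {
        if (s[k] <= cur_e) cur_e <- max(cur_e, e[k])
        else { tot <- tot + (cur_e - cur_s); cur_s <- s[k]; cur_e <- e[k] }
      }
      tot <- tot + (cur_e - cur_s)
    }
    q[i] <- tot / spec$total_bp
  }
  q
}
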