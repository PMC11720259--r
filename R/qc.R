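# Genotype quality control and per-SNP diversity statistics.

#' Quality-control thresholds
#'
#' Call-rate filters applied to the raw genotype matrix. Note the deliberate
#' asymmetry in the comparators: SNPs are kept when their call rate is *at
#' least* `snp_call_rate`, individuals when theirs is *strictly above*
#' `individual_call_rate`.
#'
#' @param snp_call_rate keep SNPs genotyped in at least this fraction of
#'   samples (inclusive). Default 0.90.
#' @param individual_call_rate keep samples with more than this fraction of
#'   SNPs genotyped (strict). Default 0.95.
#' @param autosomes_only drop markers outside autosomes 1..31. Default TRUE.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(snp_call_rate = 0.90,
                          individual_call_rate = 0.95,
                          autosomes_only = TRUE) {
  stopifnot(snp_call_rate >= 0, snp_call_rate <= 1,
            individual_call_rate >= 0, individual_call_rate <= 1)
  structure(list(snp_call_rate = snp_call_rate,
                 individual_call_rate = individual_call_rate,
                 autosomes_only = autosomes_only),
            class = "qc_thresholds")
}

#' Apply quality-control filters to a genotype matrix
#'
#' Runs the SNP call-rate filter (keep rate >= threshold), the individual
#' call-rate filter (keep rate > threshold) and the autosome restriction
#' (chromosomes 1..31), in a configurable order. Each step is recorded in
#' the `qc_log` attribute of the result.
#'
#' @param gm a [genotype_matrix].
#' @param thresholds a [qc_thresholds] object.
#' @param order character vector giving the filter order; any permutation of
#'   `c("snp", "individual", "autosome")`.
#' @return the filtered [genotype_matrix] with a `qc_log` attribute
#'   (data.frame: step, kept, dropped).
#' @export
apply_qc <- function(gm, thresholds = qc_thresholds(),
                     order = c("snp", "individual", "autosome")) {
  validate_genotype_matrix(gm)
  stopifnot(setequal(order, c("snp", "individual", "autosome")))
  log <- list()
  for (step in order) {
    if (step == "snp") {
      rate <- colMeans(!is.na(gm$calls))
      keep <- rate >= thresholds$snp_call_rate
      if (!any(keep)) stop("empty after QC: all SNPs removed by call-rate filter")
      log[[length(log) + 1L]] <- data.frame(step = "snp_call_rate",
                                            kept = sum(keep), dropped = sum(!keep))
      gm <- gm[, keep]
    } else if (step == "individual") {
      rate <- rowMeans(!is.na(gm$calls))
      keep <- rate > thresholds$individual_call_rate
      if (!any(keep)) stop("empty after QC: all individuals removed by call-rate filter")
      log[[length(log) + 1L]] <- data.frame(step = "individual_call_rate",
                                            kept = sum(keep), dropped = sum(!keep))
      gm <- gm[keep, ]
    } else if (step == "autosome" && thresholds$autosomes_only) {
      keep <- !is.na(gm$markers$chrom) & gm$markers$chrom >= 1L & gm$markers$chrom <= 31L
      if (!any(keep)) stop("empty after QC: no autosomal markers left")
      log[[length(log) + 1L]] <- data.frame(step = "autosomes_only",
                                            kept = sum(keep), dropped = sum(!keep))
      gm <- gm[, keep]
    }
  }
  attr(gm, "qc_log") <- do.call(rbind, log)
  gm
}

# Per-SNP genotype counts on non-missing calls.
snp_counts <- function(gm) {
  calls <- gm$calls
  n_het <- colSums(calls == GT_HET, na.rm = TRUE)
  n_alt <- colSums(calls == GT_HOM_ALT, na.rm = TRUE)
  n_ref <- colSums(calls == GT_HOM_REF, na.rm = TRUE)
  n_called <- n_ref + n_het + n_alt
  data.frame(snp_id = gm$markers$snp_id, chrom = gm$markers$chrom,
             pos_bp = gm$markers$pos_bp,
             n_ref = n_ref, n_het = n_het, n_alt = n_alt,
             n_called = n_called, stringsAsFactors = FALSE)
}

#' Observed and expected heterozygosity
#'
#' Per-SNP observed heterozygosity `Ho` (heterozygote count / non-missing
#' count) and expected heterozygosity `He = 2p(1-p)`, with `p` the
#' alternate-allele frequency among non-missing calls. Chromosome and
#' population means are unweighted means over SNPs; SNPs with zero
#' non-missing calls are excluded from the means with a warning.
#'
#' @param gm a [genotype_matrix].
#' @return a list with `per_snp` (snp_id, chrom, pos_bp, n_called, p_alt,
#'   ho, he), `per_chrom` (chrom, mean_ho, mean_he, n_snps) and `overall`
#'   (mean_ho, mean_he).
#' @export
heterozygosity <- function(gm) {
  validate_genotype_matrix(gm)
  if (nrow(gm$markers) == 0L) stop("empty genotype matrix")
  cnt <- snp_counts(gm)
  zero <- cnt$n_called == 0L
  if (any(zero))
    warning(sum(zero), " SNP(s) with zero non-missing calls excluded from means")
  p <- (2 * cnt$n_alt + cnt$n_het) / (2 * cnt$n_called)
  ho <- cnt$n_het / cnt$n_called
  he <- 2 * p * (1 - p)
  per_snp <- data.frame(cnt[c("snp_id", "chrom", "pos_bp", "n_called")],
                        p_alt = p, ho = ho, he = he, stringsAsFactors = FALSE)
  ok <- !zero
  per_chrom <- do.call(rbind, lapply(split(which(ok), per_snp$chrom[ok]), function(ix) {
    data.frame(chrom = per_snp$chrom[ix[1]],
               mean_ho = mean(ho[ix]), mean_he = mean(he[ix]),
               n_snps = length(ix))
  }))
  rownames(per_chrom) <- NULL
  list(per_snp = per_snp,
       per_chrom = per_chrom,
       overall = list(mean_ho = mean(ho[ok]), mean_he = mean(he[ok])))
}

# Exact Hardy-Weinberg distribution of the heterozygote count conditional on
# the minor-allele count, built by the stable ratio recurrence
#   P(h+2)/P(h) = (nA - h)(nB - h) / ((h+2)(h+1))
# over heterozygote counts h with the parity of nA.
hwe_het_distribution <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2L * n_aa + n_ab
  nB <- 2L * n - nA
  if (nA > nB) { tmp <- nA; nA <- nB; nB <- tmp }
  hs <- seq.int(nA %% 2L, min(nA, nB), by = 2L)
  lp <- numeric(length(hs))
  for (k in seq_along(hs)[-1]) {
    h <- hs[k - 1L]
    lp[k] <- lp[k - 1L] + log((nA - h) * (nB - h)) - log((h + 2) * (h + 1))
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  list(h = hs, p = p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Per-SNP exact HWE p-value computed by full enumeration of heterozygote
#' counts conditional on the observed allele counts (the usual exact test;
#' the p-value sums the probabilities of all heterozygote counts no more
#' probable than the observed one). Monomorphic SNPs get `p = 1` by
#' convention. A mid-p variant is available.
#'
#' @param gm a [genotype_matrix].
#' @param midp use the mid-p variant (half weight on the observed
#'   configuration). Default `FALSE`.
#' @return a list with `per_snp` (snp_id, chrom, pos_bp, hwe_p) and
#'   `per_chrom` (chrom, mean_p, n_snps).
#' @export
hwe_test <- function(gm, midp = FALSE) {
  validate_genotype_matrix(gm)
  cnt <- snp_counts(gm)
  pv <- mapply(hwe_exact_p, cnt$n_ref, cnt$n_het, cnt$n_alt,
               MoreArgs = list(midp = midp))
  per_snp <- data.frame(cnt[c("snp_id", "chrom", "pos_bp")], hwe_p = pv,
                        stringsAsFactors = FALSE)
  ok <- !is.na(pv)
  per_chrom <- do.call(rbind, lapply(split(which(ok), cnt$chrom[ok]), function(ix) {
    data.frame(chrom = cnt$chrom[ix[1]], mean_p = mean(pv[ix]), n_snps = length(ix))
  }))
  rownames(per_chrom) <- NULL
  list(per_snp = per_snp, per_chrom = per_chrom)
}

#' Exact HWE p-value from genotype counts
#'
#' @param n_aa,n_ab,n_bb counts of the three genotype classes at one
#'   biallelic SNP.
#' @param midp use the mid-p variant.
#' @return the exact p-value; 1 for monomorphic SNPs, `NA` when no calls.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb, midp = FALSE) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  nA <- 2L * n_aa + n_ab
  if (nA == 0L || nA == 2L * n) return(1)
  d <- hwe_het_distribution(n_aa, n_ab, n_bb)
  p_obs <- d$p[match(n_ab, d$h)]
  p <- sum(d$p[d$p <= p_obs * (1 + 1e-7)])
  if (midp) p <- p - p_obs / 2
  min(1, p)
}
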