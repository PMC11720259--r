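# Sliding-window detection of runs of homozygosity (ROH).
#
# The scan mirrors the sliding-window convention of PLINK/detectRUNS:
# fixed-size windows of w consecutive SNPs are scored homozygous when they
# contain at most max_het heterozygous and at most max_missing missing
# calls; a SNP is in-run when the fraction of homozygous windows among the
# windows actually covering it reaches the support threshold; maximal
# in-run stretches are split at large inter-SNP gaps and then filtered on
# SNP count, physical length and (optionally) SNP density.

#' ROH detection parameters
#'
#' Defaults follow the published equine SNP-array setting: window of 52
#' SNPs, at least 52 SNPs per run, window support threshold 0.05, maximal
#' gap and minimal run length of 1 Mb, no heterozygote and at most one
#' missing call per window. `min_density` (SNPs per bp, comparator `>=`,
#' applied after gap splitting) is available but disabled by default: at
#' typical medium-density array spacing (~1 SNP per 35 kb) a density screen
#' of 1 SNP per 10 kb would reject every run, and published landscapes show
#' the screen is not binding in practice.
#'
#' @param window_snps window size in SNPs.
#' @param min_snps_in_run minimum number of SNPs in a reported run.
#' @param window_support_threshold minimum fraction of homozygous windows
#'   covering a SNP for the SNP to be in-run (inclusive).
#' @param max_gap_bp maximum gap between consecutive SNPs within a run.
#' @param min_length_bp minimum run length (end - start) in bp.
#' @param max_het_per_window maximum heterozygous calls per window.
#' @param max_missing_per_window maximum missing calls per window.
#' @param min_density minimum SNPs per bp of a reported run; `0` disables.
#' @return a `roh_params` list.
#' @export
roh_params <- function(window_snps = 52L,
                       min_snps_in_run = 52L,
                       window_support_threshold = 0.05,
                       max_gap_bp = 1e6,
                       min_length_bp = 1e6,
                       max_het_per_window = 0L,
                       max_missing_per_window = 1L,
                       min_density = 0) {
  stopifnot(window_snps >= 1, min_snps_in_run >= 1,
            window_support_threshold >= 0, max_gap_bp >= 0,
            min_length_bp >= 1, max_het_per_window >= 0,
            max_missing_per_window >= 0, min_density >= 0)
  structure(list(window_snps = as.integer(window_snps),
                 min_snps_in_run = as.integer(min_snps_in_run),
                 window_support_threshold = window_support_threshold,
                 max_gap_bp = max_gap_bp,
                 min_length_bp = min_length_bp,
                 max_het_per_window = as.integer(max_het_per_window),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 min_density = min_density),
            class = "roh_params")
}

#' Minimum number of SNPs defining a run
#'
#' Computes the false-positive-controlling minimum SNP count
#' `L = ln(alpha / (ns * ni)) / ln(1 - het)`, rounded to the nearest
#' integer. Both numerator and denominator are negative, so the quotient is
#' positive. With the study-scale inputs (alpha 0.05, 64,203 SNPs, 506
#' individuals, mean heterozygosity 0.323) this gives 52.
#'
#' @param alpha tolerated fraction of false-positive ROH (0 < alpha < 1).
#' @param ns number of SNPs per individual.
#' @param ni number of individuals genotyped.
#' @param het mean population heterozygosity (0 < het < 1).
#' @return integer `L`.
#' @export
min_snp_threshold <- function(alpha = 0.05, ns, ni, het) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(het > 0 && het < 1)) stop("het must be in (0, 1)")
  stopifnot(ns >= 1, ni >= 1)
  as.integer(round_half_up(log(alpha / (ns * ni)) / log(1 - het)))
}

#' Detect runs of homozygosity by the sliding-window method
#'
#' Scans each individual and chromosome with windows of
#' `params$window_snps` consecutive SNPs. A window is homozygous when it
#' contains at most `max_het_per_window` heterozygous and at most
#' `max_missing_per_window` missing calls (a missing call never counts as
#' heterozygous). Windows are fully contained in the chromosome; a SNP's
#' support is the fraction of homozygous windows among those covering it,
#' and the SNP is in-run when support `>=` the threshold. Maximal in-run
#' stretches are split wherever consecutive SNPs are farther apart than
#' `max_gap_bp`, then filtered: at least `min_snps_in_run` SNPs, length
#' (`end_bp - start_bp`) at least `min_length_bp`, and, when enabled,
#' density `n_snps / length_bp >= min_density`.
#'
#' @param gm a QC-passed [genotype_matrix].
#' @param params a [roh_params] object.
#' @return data.frame of segments: `individual`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`, sorted by individual (input order),
#'   chromosome and start. Chromosomes with fewer SNPs than the window are
#'   skipped and listed in the `skipped_chroms` attribute.
#' @export
detect_roh <- function(gm, params = roh_params()) {
  validate_genotype_matrix(gm)
  w <- params$window_snps
  n <- length(gm$individuals)
  out <- list()
  skipped <- integer(0)
  for (chr in unique(gm$markers$chrom)) {
    jx <- which(gm$markers$chrom == chr)
    m_c <- length(jx)
    if (m_c < w) { skipped <- c(skipped, chr); next }
    pos <- gm$markers$pos_bp[jx]
    calls <- gm$calls[, jx, drop = FALSE]
    inrun <- in_run_snps(calls, params)
    gapbreak <- c(FALSE, diff(pos) > params$max_gap_bp)
    for (i in seq_len(n)) {
      segs <- segments_from_inrun(inrun[i, ], gapbreak, pos, params)
      if (nrow(segs)) {
        segs$individual <- gm$individuals[i]
        segs$chrom <- chr
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start_bp = numeric(0), end_bp = numeric(0),
               n_snps = integer(0), length_bp = numeric(0),
               individual = character(0), chrom = integer(0))
  res <- res[c("individual", "chrom", "start_bp", "end_bp", "n_snps", "length_bp")]
  res <- res[order(match(res$individual, gm$individuals), res$chrom, res$start_bp), ]
  rownames(res) <- NULL
  attr(res, "skipped_chroms") <- skipped
  attr(res, "params") <- params
  res
}

# n x m logical matrix: SNP in-run per individual, for one chromosome.
in_run_snps <- function(calls, params) {
  n <- nrow(calls); m <- ncol(calls)
  w <- params$window_snps
  W <- m - w + 1L
  het <- calls == GT_HET
  het[is.na(het)] <- FALSE
  mis <- is.na(calls)
  csH <- cbind(0L, t(apply(het, 1L, cumsum)))
  csM <- cbind(0L, t(apply(mis, 1L, cumsum)))
  win_ix_hi <- (w + 1L):(m + 1L)
  win_ix_lo <- 1L:W
  hom <- (csH[, win_ix_hi, drop = FALSE] - csH[, win_ix_lo, drop = FALSE]) <=
           params$max_het_per_window &
         (csM[, win_ix_hi, drop = FALSE] - csM[, win_ix_lo, drop = FALSE]) <=
           params$max_missing_per_window
  csHom <- cbind(0L, t(apply(hom, 1L, cumsum)))
  j <- seq_len(m)
  lo <- pmax(1L, j - w + 1L)   # first window start covering SNP j
  hi <- pmin(j, W)             # last window start covering SNP j
  den <- hi - lo + 1L
  num <- csHom[, hi + 1L, drop = FALSE] - csHom[, lo, drop = FALSE]
  sweep(num, 2L, den, "/") >= params$window_support_threshold
}

# Maximal in-run stretches for one individual, split at gap breaks and
# filtered on SNP count, length and density.
segments_from_inrun <- function(inrun, gapbreak, pos, params) {
  grp <- cumsum(!inrun | gapbreak)
  idx <- which(inrun)
  if (!length(idx))
    return(data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), length_bp = numeric(0)))
  pieces <- split(idx, grp[idx])
  res <- lapply(pieces, function(ix) {
    k <- length(ix)
    start <- pos[ix[1]]; end <- pos[ix[k]]
    len <- end - start
    if (k >= params$min_snps_in_run && len >= params$min_length_bp &&
        (params$min_density <= 0 || k / len >= params$min_density))
      data.frame(start_bp = start, end_bp = end, n_snps = k, length_bp = len)
    else NULL
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res))
    return(data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), length_bp = numeric(0)))
  do.call(rbind, res)
}
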