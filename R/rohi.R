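# ROH islands: per-SNP incidence, randomization null, island calling.
#
# The null hypothesis is that ROH are uniformly distributed along the
# genome: each SNP's incidence is compared with draws uniform on the
# integers {0, ..., M_k}, M_k being the maximum observed incidence on the
# SNP's chromosome. The upper-tail probability P(r >= c) has the closed
# form (M - c + 1) / (M + 1), which the Monte-Carlo estimate converges to;
# small p marks enrichment.

#' Per-SNP ROH incidence
#'
#' Counts, for every SNP, the number of distinct individuals whose ROH
#' (closed interval `[start_bp, end_bp]`) covers the SNP position. Each
#' individual counts at most once per SNP (segments of one individual are
#' non-overlapping by construction of [detect_roh()]).
#'
#' @param segments data.frame of ROH segments.
#' @param gm the [genotype_matrix] the segments were called on (supplies
#'   the SNP grid and the number of individuals).
#' @return an `incidence_track` data.frame: `snp_id`, `chrom`, `pos_bp`,
#'   `count`, `frequency` (`count / n`), `p` (NA until
#'   [incidence_pvalues()] is run), with the number of individuals in the
#'   `n_individuals` attribute.
#' @export
snp_incidence <- function(segments, gm) {
  validate_genotype_matrix(gm)
  mk <- gm$markers
  n <- length(gm$individuals)
  count <- integer(nrow(mk))
  for (chr in unique(mk$chrom)) {
    jx <- which(mk$chrom == chr)
    pos <- mk$pos_bp[jx]
    seg <- segments[segments$chrom == chr, , drop = FALSE]
    if (!nrow(seg)) next
    delta <- integer(length(jx) + 1L)
    i_lo <- findInterval(seg$start_bp - 0.5, pos) + 1L
    i_hi <- findInterval(seg$end_bp, pos)
    ok <- i_hi >= i_lo
    for (s in which(ok)) {
      delta[i_lo[s]] <- delta[i_lo[s]] + 1L
      delta[i_hi[s] + 1L] <- delta[i_hi[s] + 1L] - 1L
    }
    count[jx] <- cumsum(delta[-length(delta)])
  }
  res <- data.frame(snp_id = mk$snp_id, chrom = mk$chrom, pos_bp = mk$pos_bp,
                    count = count, frequency = count / n, p = NA_real_,
                    stringsAsFactors = FALSE)
  attr(res, "n_individuals") <- n
  class(res) <- c("incidence_track", "data.frame")
  res
}

#' Null tail probability of a SNP incidence
#'
#' Probability that a draw uniform on the integers `{0, ..., M}` is at
#' least `c`: `(M - c + 1) / (M + 1)`. The literal lower tail
#' (`P(r < c) = c / (M + 1)`), under which enriched SNPs score *high*, is
#' available for fidelity with the original verbal description.
#'
#' @param c observed incidence (0..M).
#' @param M maximum incidence on the chromosome.
#' @param tail `"upper"` (default; small p = enrichment) or `"literal"`.
#' @return probability in `[0, 1]`.
#' @export
incidence_null_p <- function(c, M, tail = c("upper", "literal")) {
  tail <- match.arg(tail)
  stopifnot(all(c >= 0), all(c <= M))
  if (tail == "upper") (M - c + 1) / (M + 1) else c / (M + 1)
}

#' Randomization p-values for SNP incidences
#'
#' For each SNP on chromosome `k`, compares its incidence `c` with draws
#' uniform on `{0, ..., M_k}` (`M_k` = maximum incidence on that
#' chromosome): `p = P(r >= c)`, so small p marks enrichment and ties
#' (`r = c`) count toward the tail. The closed form
#' `(M_k - c + 1) / (M_k + 1)` is exact and is the default; the
#' Monte-Carlo mode draws `reps` times with one seeded stream per
#' chromosome, chromosomes processed in increasing order, and converges to
#' the closed form. Chromosomes with `M_k = 0` get `p = 1` everywhere.
#'
#' @param track an `incidence_track` from [snp_incidence()].
#' @param method `"closed_form"` (default) or `"monte_carlo"`.
#' @param reps number of random draws per chromosome (Monte-Carlo mode).
#' @param seed RNG seed (required in Monte-Carlo mode).
#' @param tail see [incidence_null_p()].
#' @return the track with its `p` column filled in and a `max_by_chrom`
#'   attribute (named vector of `M_k`).
#' @export
incidence_pvalues <- function(track, method = c("closed_form", "monte_carlo"),
                              reps = 1e6, seed = NULL,
                              tail = c("upper", "literal")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  if (method == "monte_carlo") {
    if (reps <= 0) stop("reps must be positive")
    if (is.null(seed)) stop("seed is required in Monte-Carlo mode")
    set.seed(seed)
  }
  chroms <- sort(unique(track$chrom))
  maxes <- stats::setNames(numeric(length(chroms)), chroms)
  for (chr in chroms) {
    jx <- which(track$chrom == chr)
    M <- max(track$count[jx])
    maxes[as.character(chr)] <- M
    if (M == 0) { track$p[jx] <- 1; next }
    if (method == "closed_form") {
      track$p[jx] <- incidence_null_p(track$count[jx], M, tail)
    } else {
      r <- sample.int(M + 1L, reps, replace = TRUE) - 1L
      tab <- tabulate(r + 1L, nbins = M + 1L)
      if (tail == "upper") {
        ge <- rev(cumsum(rev(tab)))          # ge[c+1] = #{r >= c}
        track$p[jx] <- ge[track$count[jx] + 1L] / reps
      } else {
        lt <- c(0, cumsum(tab))[seq_len(M + 1L)]  # lt[c+1] = #{r < c}
        track$p[jx] <- lt[track$count[jx] + 1L] / reps
      }
    }
  }
  attr(track, "max_by_chrom") <- maxes
  track
}

#' Call ROH islands from an incidence track
#'
#' Islands are maximal stretches of consecutive SNPs whose ROH frequency is
#' at least `freq_min`; a stretch is reported when it contains at least
#' `min_sig_snps` SNPs with `p < p_max`. Boundaries are the first and last
#' SNP positions of the stretch; `mean_p` averages over all SNPs in the
#' stretch and `length_bp = end_bp - start_bp`.
#'
#' @param track an `incidence_track` with p-values filled in.
#' @param freq_min minimum ROH frequency on every SNP of the island.
#' @param p_max significance cutoff (strict `<`).
#' @param min_sig_snps minimum number of significant SNPs per island.
#' @return data.frame: `island`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `mean_p`, `length_bp`, sorted by chromosome and start.
#' @export
call_islands <- function(track, freq_min = 0.5, p_max = 0.01,
                         min_sig_snps = 3L) {
  if (all(is.na(track$p)) && nrow(track))
    stop("p-values not computed; run incidence_pvalues() first")
  out <- list()
  for (chr in sort(unique(track$chrom))) {
    jx <- which(track$chrom == chr)
    ok <- track$frequency[jx] >= freq_min
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      ix <- jx[starts[k]:ends[k]]
      if (sum(track$p[ix] < p_max, na.rm = TRUE) < min_sig_snps) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr,
        start_bp = track$pos_bp[ix[1]],
        end_bp = track$pos_bp[ix[length(ix)]],
        n_snps = length(ix),
        mean_p = mean(track$p[ix]),
        length_bp = track$pos_bp[ix[length(ix)]] - track$pos_bp[ix[1]])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = integer(0), start_bp = numeric(0), end_bp = numeric(0),
               n_snps = integer(0), mean_p = numeric(0), length_bp = numeric(0))
  res <- res[order(res$chrom, res$start_bp), ]
  res <- cbind(island = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}
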