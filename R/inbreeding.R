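# F_ROH: genomic inbreeding from ROH, with recent/ancestral decomposition.
#
# F_ROH is the fraction of the SNP-covered genome lying inside an
# individual's ROH. Restricting the sum to ROH above a length threshold
# dates the underlying inbreeding: after g generations the expected tract
# length from a common ancestor is 100/(2g) cM, taken as Mb at the 1 cM ~
# 1 Mb approximation.

# Total covered genome length of the published equine array (bp).
EQUINE_COVERED_GENOME_BP <- 2276871601

#' Genome specification: covered lengths used as F_ROH denominators
#'
#' @param chrom_lengths named numeric vector of per-chromosome covered
#'   lengths in bp (names = chromosome numbers); optional.
#' @param total_bp total covered length in bp; defaults to
#'   `sum(chrom_lengths)` when those are given, else to the published
#'   equine-array constant 2,276,871,601 bp.
#' @return a `genome_spec` list with `chrom_lengths` and `total_bp`.
#' @export
genome_spec <- function(chrom_lengths = NULL, total_bp = NULL) {
  if (!is.null(chrom_lengths)) {
    stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
    if (is.null(total_bp)) total_bp <- sum(chrom_lengths)
    else if (abs(total_bp - sum(chrom_lengths)) > 1e-6)
      stop("total_bp must equal sum(chrom_lengths) when both are supplied")
  } else if (is.null(total_bp)) {
    total_bp <- EQUINE_COVERED_GENOME_BP
  }
  stopifnot(total_bp > 0)
  structure(list(chrom_lengths = chrom_lengths, total_bp = total_bp),
            class = "genome_spec")
}

#' Genome specification from a genotype matrix
#'
#' Per-chromosome covered length taken as last minus first SNP position,
#' the same end-minus-start convention used for ROH lengths.
#'
#' @param gm a [genotype_matrix].
#' @return a [genome_spec].
#' @export
genome_spec_from_gm <- function(gm) {
  validate_genotype_matrix(gm)
  lens <- vapply(split(gm$markers$pos_bp, gm$markers$chrom),
                 function(p) max(p) - min(p), numeric(1))
  genome_spec(chrom_lengths = lens)
}

#' Minimum ROH length dating inbreeding to g generations
#'
#' Expected tract length from a common ancestor g generations back is
#' 100/(2g) cM; at 1 cM ~ 1 Mb this is taken as Mb and truncated (not
#' rounded) to one decimal, reproducing the conventional 16.6 / 8.3 / 5.5
#' Mb cutoffs for g = 3, 6, 9.
#'
#' @param g number of generations (positive integer).
#' @return threshold length in Mb.
#' @export
generation_threshold <- function(g) {
  if (any(g <= 0)) stop("g must be positive")
  trunc1(100 / (2 * g))
}

default_generations <- c(3L, 6L, 9L)

#' Per-individual F_ROH with generational decomposition
#'
#' For each individual, `F_ROH` is the summed ROH length divided by the
#' covered genome length; `F_ROHgG` restricts the sum to ROH with
#' `length_bp >= generation_threshold(g) * 1e6` (comparator `>=`); the
#' ancestral component `F_ROHANC` is `F_ROH` minus the longest-horizon
#' generational component. Chromosome-scope records divide by the
#' chromosome's covered length instead. Individuals without segments get
#' all-zero records.
#'
#' @param segments data.frame of ROH segments from [detect_roh()].
#' @param spec a [genome_spec]; chromosome-scope records require
#'   `chrom_lengths`.
#' @param generations integer vector of generation horizons (default 3, 6, 9).
#' @param individuals character vector of all individuals (so that ROH-free
#'   ones are reported); defaults to those present in `segments`.
#' @return data.frame: `individual`, `scope` (`"genome"` or the chromosome
#'   number as character), `froh`, one `froh_<g>g` column per horizon, and
#'   `froh_anc`.
#' @export
compute_froh <- function(segments, spec = genome_spec(),
                         generations = default_generations,
                         individuals = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  generations <- sort(as.integer(generations))
  thr_bp <- generation_threshold(generations) * 1e6
  if (is.null(individuals)) individuals <- unique(segments$individual)
  individuals <- as.character(individuals)

  scopes <- list(list(name = "genome", denom = spec$total_bp, chrom = NULL))
  if (!is.null(spec$chrom_lengths)) {
    if (nrow(segments) &&
        !all(as.character(segments$chrom) %in% names(spec$chrom_lengths)))
      stop("segment on chromosome absent from genome spec")
    for (ch in names(spec$chrom_lengths))
      scopes[[length(scopes) + 1L]] <-
        list(name = ch, denom = spec$chrom_lengths[[ch]], chrom = ch)
  } else if (nrow(segments)) {
    # genome scope only; still refuse unknown chromosomes when lengths known
  }

  rows <- lapply(scopes, function(sc) {
    seg <- segments
    if (!is.null(sc$chrom)) seg <- seg[as.character(seg$chrom) == sc$chrom, , drop = FALSE]
    sum_by <- function(sel) {
      s <- tapply(seg$length_bp[sel], factor(seg$individual[sel], levels = individuals),
                  sum, default = 0)
      as.numeric(s)
    }
    froh <- sum_by(rep(TRUE, nrow(seg))) / sc$denom
    comp <- vapply(thr_bp, function(t) sum_by(seg$length_bp >= t) / sc$denom,
                   numeric(length(individuals)))
    comp <- matrix(comp, nrow = length(individuals))
    df <- data.frame(individual = individuals, scope = sc$name, froh = froh,
                     stringsAsFactors = FALSE)
    for (k in seq_along(generations))
      df[[paste0("froh_", generations[k], "g")]] <- comp[, k]
    df$froh_anc <- froh - comp[, length(generations)]
    df
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' ROH length-class summary
#'
#' Bins segments into the generational length classes `[1, 5.5)`,
#' `[5.5, 8.3)`, `[8.3, 16.6)`, `[16.6, Inf)` Mb and reports per class the
#' count, percentage of all segments, mean and SD length (Mb) and the
#' percentage of individuals carrying at least one segment in the class.
#'
#' @param segments data.frame of ROH segments.
#' @param individuals character vector of all individuals (denominator of
#'   the carrier percentage); defaults to those present in `segments`.
#' @param breaks_mb class boundaries in Mb (left-closed).
#' @return data.frame: `class`, `n`, `pct_of_total`, `mean_mb`, `sd_mb`,
#'   `pct_individuals`, plus a `Total` row.
#' @export
length_class_summary <- function(segments, individuals = NULL,
                                 breaks_mb = c(1, 5.5, 8.3, 16.6, Inf)) {
  if (is.null(individuals)) individuals <- unique(segments$individual)
  n_ind <- max(length(individuals), 1L)
  len_mb <- segments$length_bp / 1e6
  lab <- character(length(breaks_mb) - 1L)
  for (k in seq_along(lab)) {
    lab[k] <- if (is.infinite(breaks_mb[k + 1])) paste0(">=", breaks_mb[k], " Mb")
              else paste0("[", breaks_mb[k], ", ", breaks_mb[k + 1], ") Mb")
  }
  cls <- cut(len_mb, breaks_mb, right = FALSE, labels = lab)
  total <- nrow(segments)
  rows <- lapply(seq_along(lab), function(k) {
    sel <- which(cls == lab[k])
    data.frame(class = lab[k], n = length(sel),
               pct_of_total = if (total) 100 * length(sel) / total else 0,
               mean_mb = if (length(sel)) mean(len_mb[sel]) else 0,
               sd_mb = if (length(sel) > 1) stats::sd(len_mb[sel]) else 0,
               pct_individuals =
                 100 * length(unique(segments$individual[sel])) / n_ind,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- rbind(res, data.frame(
    class = "Total", n = total, pct_of_total = if (total) 100 else 0,
    mean_mb = if (total) mean(len_mb) else 0,
    sd_mb = if (total > 1) stats::sd(len_mb) else 0,
    pct_individuals = 100 * length(unique(segments$individual)) / n_ind))
  rownames(res) <- NULL
  res
}
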