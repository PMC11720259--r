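# End-to-end pipeline: QC -> diversity -> ROH -> F_ROH -> islands -> genes.

#' Summarize genome-scope inbreeding records
#'
#' Mean and SD of `F_ROH` and each generational component over individuals,
#' plus each component's share of mean `F_ROH` as an integer percentage
#' (rounded half up). Shares are `NA` when mean `F_ROH` is zero.
#'
#' @param records data.frame from [compute_froh()]; only `scope == "genome"`
#'   rows are used.
#' @return data.frame: `coefficient`, `mean`, `sd`, `pct_of_froh`.
#' @export
summarize_froh <- function(records) {
  rec <- records[records$scope == "genome", , drop = FALSE]
  if (!nrow(rec)) stop("no genome-scope records")
  cols <- c("froh", grep("^froh_", names(rec), value = TRUE))
  mu <- vapply(rec[cols], mean, numeric(1))
  sd <- vapply(rec[cols], function(x) if (length(x) > 1) stats::sd(x) else 0,
               numeric(1))
  share <- if (mu[["froh"]] > 0)
    round_half_up(100 * mu / mu[["froh"]]) else rep(NA_real_, length(mu))
  res <- data.frame(coefficient = toupper(sub("froh", "F_ROH", cols)),
                    mean = unname(mu), sd = unname(sd),
                    pct_of_froh = unname(share), stringsAsFactors = FALSE)
  res$pct_of_froh[res$coefficient == "F_ROH"] <- NA_real_
  res
}

#' Run the full ROH analysis pipeline
#'
#' Executes, in order: PLINK text input (or an in-memory genotype matrix),
#' quality control, heterozygosity and exact HWE statistics, optional
#' recomputation of the minimum-SNP threshold L from the data, sliding-window
#' ROH detection, genome- and chromosome-scope F_ROH with generational
#' decomposition, length-class summary, SNP incidence with randomization
#' p-values, island calling, and (when an annotation file is given) gene
#' annotation. All tables are written to `out_dir` together with a
#' `run_manifest.json` recording every parameter, comparator choice and
#' seed; outputs are pure functions of (inputs, config, seed).
#'
#' @param gm a [genotype_matrix], or `NULL` to read from `ped`/`map`.
#' @param ped,map PLINK text paths (used when `gm` is `NULL`).
#' @param out_dir output directory (created if needed).
#' @param qc a [qc_thresholds].
#' @param roh a [roh_params], or `NULL` to recompute `L` from the data via
#'   [min_snp_threshold()] (alpha 0.05, observed mean Ho) and use it as both
#'   window size and minimum SNPs per run.
#' @param genome a [genome_spec]; default derived from the QC-passed data.
#' @param generations generation horizons for the F_ROH decomposition.
#' @param rohi_method `"closed_form"` or `"monte_carlo"`.
#' @param reps Monte-Carlo draws per chromosome.
#' @param seed RNG seed (required for Monte-Carlo mode).
#' @param genes_path optional BED/GFF3 gene annotation.
#' @param freq_min,p_max,min_sig_snps island-calling settings, see
#'   [call_islands()].
#' @return invisibly, a list with every intermediate object (`gm`, `het`,
#'   `hwe`, `L`, `segments`, `froh`, `classes`, `incidence`, `islands`,
#'   `island_genes`, `manifest`).
#' @export
run_pipeline <- function(gm = NULL, ped = NULL, map = NULL, out_dir,
                         qc = qc_thresholds(), roh = roh_params(),
                         genome = NULL, generations = c(3L, 6L, 9L),
                         rohi_method = c("closed_form", "monte_carlo"),
                         reps = 1e6, seed = NULL, genes_path = NULL,
                         freq_min = 0.5, p_max = 0.01, min_sig_snps = 3L) {
  rohi_method <- match.arg(rohi_method)
  stage <- "input"
  tryCatch({
    if (is.null(gm)) gm <- read_ped_map(ped, map)
    validate_genotype_matrix(gm)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "qc"
    gm_qc <- apply_qc(gm, qc)
    qc_log <- attr(gm_qc, "qc_log")

    stage <- "diversity"
    het <- heterozygosity(gm_qc)
    hwe <- hwe_test(gm_qc)

    stage <- "roh"
    recomputed_L <- NA_integer_
    if (is.null(roh)) {
      recomputed_L <- min_snp_threshold(0.05, ns = nrow(gm_qc$markers),
                                        ni = length(gm_qc$individuals),
                                        het = het$overall$mean_ho)
      roh <- roh_params(window_snps = recomputed_L,
                        min_snps_in_run = recomputed_L)
    }
    segments <- detect_roh(gm_qc, roh)

    stage <- "inbreeding"
    if (is.null(genome)) genome <- genome_spec_from_gm(gm_qc)
    froh <- compute_froh(segments, genome, generations,
                         individuals = gm_qc$individuals)
    classes <- length_class_summary(segments, individuals = gm_qc$individuals)

    stage <- "islands"
    track <- snp_incidence(segments, gm_qc)
    track <- incidence_pvalues(track, method = rohi_method, reps = reps,
                               seed = seed)
    islands <- call_islands(track, freq_min, p_max, min_sig_snps)

    stage <- "annotation"
    island_genes <- NULL
    if (!is.null(genes_path)) {
      genes <- load_genes(genes_path)
      island_genes <- annotate_islands(islands, genes)
    }

    stage <- "report"
    wtsv <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wcsv <- function(x, f) utils::write.csv(
      x, file.path(out_dir, f), row.names = FALSE)
    wtsv(qc_log, "qc_summary.tsv")
    byc <- merge(het$per_chrom, hwe$per_chrom[c("chrom", "mean_p")], by = "chrom")
    wtsv(byc, "het_hwe_by_chrom.tsv")
    wtsv(segments, "roh_segments.tsv")
    wtsv(classes, "roh_length_classes.tsv")
    wcsv(froh[froh$scope == "genome", ], "froh_individual.csv")
    wcsv(froh[froh$scope != "genome", ], "froh_by_chrom.csv")
    wtsv(track, "incidence.tsv")
    wcsv(islands, "islands.csv")
    # BED is 0-based half-open: start - 1, end unchanged.
    bed <- data.frame(chrom = islands$chrom,
                      start = format(islands$start_bp - 1, scientific = FALSE, trim = TRUE),
                      end = format(islands$end_bp, scientific = FALSE, trim = TRUE),
                      name = sprintf("ROHi%d", islands$island))
    utils::write.table(bed, file.path(out_dir, "islands.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    if (!is.null(island_genes)) {
      flat <- island_genes
      flat$genes <- vapply(flat$genes, paste, "", collapse = ",")
      wcsv(flat, "island_genes.csv")
    }

    manifest <- list(
      n_individuals_raw = length(gm$individuals),
      n_snps_raw = nrow(gm$markers),
      n_individuals = length(gm_qc$individuals),
      n_snps = nrow(gm_qc$markers),
      qc = unclass(qc),
      qc_comparators = list(snp_call_rate = ">=", individual_call_rate = ">"),
      filter_order = c("snp", "individual", "autosome"),
      roh_params = unclass(roh),
      recomputed_L = recomputed_L,
      support_comparator = ">=",
      length_convention = "end_minus_start",
      genome_total_bp = genome$total_bp,
      generations = generations,
      generation_thresholds_mb = generation_threshold(generations),
      rohi = list(method = rohi_method, reps = reps, seed = seed,
                  tail = "upper", freq_min = freq_min, p_max = p_max,
                  min_sig_snps = min_sig_snps),
      mean_ho = het$overall$mean_ho,
      n_segments = nrow(segments),
      n_islands = nrow(islands))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    invisible(list(gm = gm_qc, het = het, hwe = hwe, L = recomputed_L,
                   segments = segments, froh = froh, classes = classes,
                   incidence = track, islands = islands,
                   island_genes = island_genes, manifest = manifest))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
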