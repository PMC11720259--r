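# Gene-interval annotation of ROH islands.
#
# Internal convention is 1-based inclusive (the MAP convention); BED input
# (0-based half-open) is converted on import by rtracklayer, GFF3 is
# 1-based already. Overlap means >= 1 shared bp between closed intervals.

#' Load gene intervals from BED or GFF3
#'
#' Reads gene annotation into a data.frame of 1-based inclusive intervals.
#' GFF3 features are filtered to type `"gene"`; gene names come from the
#' BED name column or the GFF3 `Name` (falling back to `gene_id` / `ID`)
#' attribute. Chromosome labels (`"3"`, `"chr3"`, `"ECA3"`) are normalized
#' to integers; records on unrecognized chromosomes are skipped with a
#' warning. Duplicate gene names at different loci are all kept.
#'
#' @param path annotation file path.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return data.frame: `gene`, `chrom`, `start_bp`, `end_bp`, `source`
#'   (file and record index of origin).
#' @export
load_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3"
              else stop("cannot infer format from extension; pass format=")
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  meta <- as.data.frame(gr)
  if (format == "gff3") {
    keep <- !is.na(meta$type) & meta$type == "gene"
    meta <- meta[keep, , drop = FALSE]
    nm <- meta$Name
    if (is.null(nm)) nm <- rep(NA_character_, nrow(meta))
    for (alt in c("gene_id", "ID"))
      if (!is.null(meta[[alt]])) nm[is.na(nm)] <- meta[[alt]][is.na(nm)]
    meta$name <- nm
    idx <- which(keep)
  } else {
    idx <- seq_len(nrow(meta))
  }
  chrom <- normalize_chrom(as.character(meta$seqnames))
  bad <- is.na(chrom)
  if (any(bad)) {
    warning(sum(bad), " record(s) on unknown chromosome label(s) skipped: ",
            paste(unique(meta$seqnames[bad]), collapse = ", "))
  }
  res <- data.frame(gene = as.character(meta$name),
                    chrom = chrom,
                    start_bp = meta$start,   # GRanges is 1-based inclusive
                    end_bp = meta$end,
                    source = paste0(basename(path), ":", idx),
                    stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate ROH islands with overlapping genes
#'
#' Reports a gene for an island when their 1-based closed intervals share
#' at least one bp (`mode = "overlap"`, default) or when the gene is fully
#' contained in the island (`mode = "within"`). Every island appears in the
#' result; islands without genes carry an empty gene list.
#'
#' @param islands data.frame from [call_islands()] (needs `island`,
#'   `chrom`, `start_bp`, `end_bp`).
#' @param genes data.frame from [load_genes()].
#' @param mode `"overlap"` or `"within"`.
#' @return data.frame with one row per island: island columns plus
#'   `n_genes` and a `genes` list-column of gene-name character vectors
#'   (sorted, possibly empty).
#' @export
annotate_islands <- function(islands, genes, mode = c("overlap", "within")) {
  mode <- match.arg(mode)
  res <- islands
  res$n_genes <- 0L
  res$genes <- replicate(nrow(islands), character(0), simplify = FALSE)
  if (nrow(islands) == 0L) return(res)
  if (nrow(genes) > 0L) {
    gr_i <- GenomicRanges::GRanges(as.character(islands$chrom),
                                   IRanges::IRanges(islands$start_bp, islands$end_bp))
    gr_g <- GenomicRanges::GRanges(as.character(genes$chrom),
                                   IRanges::IRanges(genes$start_bp, genes$end_bp))
    hits <- GenomicRanges::findOverlaps(
      gr_g, gr_i, type = if (mode == "within") "within" else "any")
    for (k in seq_len(nrow(islands))) {
      g <- genes$gene[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == k]]
      res$genes[[k]] <- sort(unique(g))
      res$n_genes[k] <- length(res$genes[[k]])
    }
  }
  res
}
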