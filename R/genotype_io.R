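# PLINK text (PED/MAP) reading and writing.
#
# Only the text dialect is supported: a MAP file with 3 or 4 whitespace
# separated columns (chrom, snp_id, [cM,] pos) and a PED file with 6 family
# columns followed by two allele columns per marker. "0 0" genotype pairs are
# missing. Coordinates are 1-based inclusive, as in MAP files.

#' Read PLINK text genotypes (PED + MAP)
#'
#' Parses a PED/MAP pair into a validated [genotype_matrix]. Alleles are
#' recorded per marker in order of first appearance (`allele1`, `allele2`);
#' a genotype is heterozygous when its two non-missing alleles differ, and
#' `"0 0"` becomes missing. Markers must be strictly sorted by position
#' within each chromosome unless `sort_markers = TRUE`, in which case they
#' are reordered (original order is preserved when already sorted).
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @param sort_markers sort markers by (chromosome block, position) instead
#'   of erroring on unsorted input. Default `FALSE`.
#' @return a [genotype_matrix].
#' @export
read_ped_map <- function(ped_path, map_path, sort_markers = FALSE) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "\\s+")
  ncol_map <- lengths(map_tok)
  if (length(map_tok) && !all(ncol_map %in% c(3L, 4L)))
    stop("MAP parse error at line ", which(!(ncol_map %in% c(3L, 4L)))[1],
         ": expected 3 or 4 columns")
  m <- length(map_tok)
  chrom <- normalize_chrom(vapply(map_tok, `[[`, "", 1L))
  snp_id <- vapply(map_tok, `[[`, "", 2L)
  pos_bp <- as.numeric(vapply(map_tok, function(t) t[[length(t)]], ""))
  if (anyNA(pos_bp)) stop("MAP parse error: non-numeric position at line ",
                          which(is.na(pos_bp))[1])

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  calls <- matrix(NA_integer_, n, m)
  a1 <- rep(NA_character_, m)
  a2 <- rep(NA_character_, m)
  fam <- data.frame(fid = character(n), iid = character(n), pat = character(n),
                    mat = character(n), sex = character(n), pheno = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(ped_lines[i]), "\\s+")[[1]]
    if (length(tok) != 6L + 2L * m)
      stop("PED parse error at line ", i, ": found ", length(tok),
           " fields, expected ", 6L + 2L * m,
           " for ", m, " MAP markers")
    fam[i, ] <- as.list(tok[1:6])
    x <- tok[seq(7L, length(tok), by = 2L)]
    y <- tok[seq(8L, length(tok), by = 2L)]
    half <- xor(x == "0", y == "0")
    if (any(half))
      stop("PED parse error at line ", i, ": half-missing genotype at SNP ",
           snp_id[which(half)[1]])
    for (j in which(x != "0")) {
      if (is.na(a1[j])) a1[j] <- x[j]
      for (al in c(x[j], y[j])) {
        if (al != a1[j]) {
          if (is.na(a2[j])) a2[j] <- al
          else if (al != a2[j])
            stop("more than 2 alleles at SNP ", snp_id[j])
        }
      }
    }
    code <- rep(NA_integer_, m)
    nm <- x != "0"
    code[nm] <- ifelse(x[nm] != y[nm], GT_HET,
                       ifelse(x[nm] == a1[nm], GT_HOM_REF, GT_HOM_ALT))
    calls[i, ] <- code
  }
  fam$iid[!nzchar(fam$iid)] <- as.character(seq_len(n))

  markers <- data.frame(snp_id = snp_id, chrom = chrom, pos_bp = pos_bp,
                        allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  o <- order_markers(markers)
  if (!identical(o, seq_len(m))) {
    if (!sort_markers)
      stop("markers are not sorted by position within chromosome; ",
           "use sort_markers = TRUE to reorder")
    markers <- markers[o, , drop = FALSE]
    rownames(markers) <- NULL
    calls <- calls[, o, drop = FALSE]
  }
  genotype_matrix(calls, markers, fam$iid, fam)
}

# Order markers by (chromosome in order of first appearance, position);
# returns seq_len(m) when the map is already valid so input order is kept.
order_markers <- function(markers) {
  chr <- as.integer(markers$chrom)
  first <- match(chr, unique(chr))
  order(first, markers$pos_bp)
}

#' Write PLINK text genotypes (PED + MAP)
#'
#' Emits a PED/MAP pair readable by [read_ped_map()]. Missing genotypes are
#' written as `"0 0"`; the MAP genetic-distance column is written as `0`.
#' Fields are single-space (PED) / tab (MAP) separated, so
#' `write_ped_map(read_ped_map(...))` round-trips files written by this
#' function byte-identically.
#'
#' @param gm a [genotype_matrix].
#' @param ped_path output PED path.
#' @param map_path output MAP path.
#' @return invisibly, `NULL`.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  validate_genotype_matrix(gm)
  mk <- gm$markers
  map <- paste(mk$chrom, mk$snp_id, 0L, format(mk$pos_bp, scientific = FALSE, trim = TRUE),
               sep = "\t")
  writeLines(map, map_path)

  n <- length(gm$individuals)
  a1 <- ifelse(is.na(mk$allele1), "0", mk$allele1)
  a2 <- ifelse(is.na(mk$allele2), "0", mk$allele2)
  # Heterozygotes are written in the order matching the first allele that
  # appears in the output for the marker, so that reading the file back and
  # rewriting it reproduces it byte-identically.
  fc <- apply(gm$calls, 2, function(g) {
    k <- which(!is.na(g))
    if (length(k)) g[k[1]] else NA_integer_
  })
  swap <- !is.na(fc) & fc == GT_HOM_ALT
  het_x <- ifelse(swap, a2, a1)
  het_y <- ifelse(swap, a1, a2)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    g <- gm$calls[i, ]
    x <- ifelse(is.na(g), "0",
                ifelse(g == GT_HOM_ALT, a2, ifelse(g == GT_HET, het_x, a1)))
    y <- ifelse(is.na(g), "0",
                ifelse(g == GT_HOM_REF, a1, ifelse(g == GT_HET, het_y, a2)))
    geno <- as.vector(rbind(x, y))
    writeLines(paste(c(unlist(gm$fam[i, ]), geno), collapse = " "), con)
  }
  invisible(NULL)
}
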