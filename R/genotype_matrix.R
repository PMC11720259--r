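# In-memory genotype container: individuals x markers with phase-free calls.
#
# Calls are stored as an integer matrix with codes
#   0 = homozygous for allele1, 1 = heterozygous, 2 = homozygous for allele2,
#   NA = missing.
# ROH logic only distinguishes hom / het / missing, so allele order carries no
# meaning beyond round-tripping the input files.

GT_HOM_REF <- 0L
GT_HET     <- 1L
GT_HOM_ALT <- 2L

#' Construct a genotype matrix
#'
#' Bundles sample identifiers, a marker map and an `n x m` integer matrix of
#' genotype calls (`0` hom/allele1, `1` het, `2` hom/allele2, `NA` missing)
#' into a validated `genotype_matrix` object, the substrate of every scan in
#' the package.
#'
#' @param calls integer matrix, individuals in rows, markers in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param markers data.frame with columns `snp_id`, `chrom` (integer),
#'   `pos_bp` (1-based base-pair position), `allele1`, `allele2`. Markers of
#'   one chromosome must form a contiguous block sorted by position.
#' @param individuals character vector of sample identifiers (row order of
#'   `calls`).
#' @param fam optional data.frame of PLINK family fields (`fid`, `iid`,
#'   `pat`, `mat`, `sex`, `pheno`); defaults are synthesized from
#'   `individuals`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, markers, individuals, fam = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  individuals <- as.character(individuals)
  if (is.null(fam)) {
    fam <- data.frame(fid = individuals, iid = individuals,
                      pat = "0", mat = "0", sex = "0", pheno = "-9",
                      stringsAsFactors = FALSE)
  }
  gm <- structure(list(calls = calls, markers = markers,
                       individuals = individuals, fam = fam),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

#' Validate a genotype matrix
#'
#' Checks dimensions, genotype codes, marker-field types, uniqueness of SNP
#' ids, positivity of positions, contiguity of chromosome blocks and strict
#' position sorting within each chromosome. Called by every operation that
#' consumes a `genotype_matrix`.
#'
#' @param gm a `genotype_matrix`.
#' @return `gm`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls; mk <- gm$markers
  need <- c("snp_id", "chrom", "pos_bp", "allele1", "allele2")
  if (!all(need %in% names(mk)))
    stop("markers must have columns: ", paste(need, collapse = ", "))
  if (nrow(calls) != length(gm$individuals))
    stop("calls has ", nrow(calls), " rows but there are ",
         length(gm$individuals), " individuals")
  if (ncol(calls) != nrow(mk))
    stop("calls has ", ncol(calls), " columns but there are ",
         nrow(mk), " markers")
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(mk$snp_id)) stop("duplicated snp_id in marker map")
  if (any(mk$pos_bp <= 0)) stop("marker positions must be positive")
  if (nrow(mk) > 0) {
    r <- rle(as.integer(mk$chrom))
    if (anyDuplicated(r$values))
      stop("markers of one chromosome must form a contiguous block")
    d <- diff(mk$pos_bp)
    new_chr <- diff(as.integer(mk$chrom)) != 0
    if (any(d[!new_chr] <= 0))
      stop("markers must be strictly sorted by position within chromosome")
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$individuals), " individuals x ",
      nrow(x$markers), " SNPs on ",
      length(unique(x$markers$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing rate %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i row (individual) index.
#' @param j column (marker) index.
#' @param ... unused.
#' @return a `genotype_matrix` restricted to the selected individuals/markers.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$individuals)
  if (missing(j)) j <- seq_len(nrow(x$markers))
  genotype_matrix(x$calls[i, j, drop = FALSE],
                  x$markers[j, , drop = FALSE],
                  x$individuals[i],
                  x$fam[i, , drop = FALSE])
}
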