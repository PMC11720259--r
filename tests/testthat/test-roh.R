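test_that("minimum-SNP threshold follows the false-positive formula", {
  expect_identical(min_snp_threshold(0.05, 64203, 506, 0.323), 52L)
  # ln(0.05/1e4)/ln(0.5) = 17.61 -> 18
  expect_identical(min_snp_threshold(0.05, 1000, 10, 0.5), 18L)
  # very high heterozygosity: threshold collapses but stays >= 1
  expect_gte(min_snp_threshold(0.05, 1000, 10, 0.999), 1L)
  expect_error(min_snp_threshold(0.05, 1000, 10, 0), "het")
  expect_error(min_snp_threshold(0.05, 1000, 10, 1), "het")
  expect_error(min_snp_threshold(1.5, 1000, 10, 0.3), "alpha")
})

test_that("a fully homozygous chromosome yields a single full-span run", {
  # 100 all-HOM SNPs evenly spaced over ~2 Mb
  gm <- make_gm(paste(rep("0", 100), collapse = ""))
  seg <- detect_roh(gm)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 100L)
  expect_equal(seg$start_bp, gm$markers$pos_bp[1])
  expect_equal(seg$end_bp, gm$markers$pos_bp[100])

  # one heterozygote in the middle kills every window: no run at all
  g <- rep("0", 100); g[50] <- "1"
  seg <- detect_roh(make_gm(paste(g, collapse = "")))
  expect_equal(nrow(seg), 0L)

  # a single missing call only consumes the missing budget
  g <- rep("0", 100); g[50] <- "."
  seg <- detect_roh(make_gm(paste(g, collapse = "")))
  expect_equal(nrow(seg), 1L)
})

test_that("runs split at gaps larger than the maximal-gap parameter", {
  pos <- c(seq_len(60) * 20000, 60 * 20000 + 1.5e6 + seq_len(60) * 20000)
  gm <- make_gm(paste(rep("0", 120), collapse = ""), pos = pos)
  seg <- detect_roh(gm)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$n_snps, c(60L, 60L))
  expect_true(all(seg$length_bp >= 1e6))
  # raising the minimum SNP count above the side size removes both
  seg2 <- detect_roh(gm, roh_params(min_snps_in_run = 61L))
  expect_equal(nrow(seg2), 0L)
})

test_that("chromosomes shorter than the window are skipped", {
  gm <- make_gm(paste(rep("0", 30), collapse = ""))
  seg <- detect_roh(gm)  # default window 52 > 30 SNPs
  expect_equal(nrow(seg), 0L)
  expect_equal(attr(seg, "skipped_chroms"), 1L)
})

test_that("sliding-window caller matches the brute-force oracle", {
  set.seed(101)
  for (rep in 1:25) {
    gm <- rand_gm(n = sample(1:5, 1), m = sample(60:200, 1),
                  het = runif(1, 0.05, 0.4), miss = runif(1, 0, 0.08),
                  n_chrom = sample(1:2, 1))
    p <- rand_roh_params()
    got <- detect_roh(gm, p)
    want <- oracle_detect_roh(gm, p)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got[names(want)], want, ignore_attr = TRUE)
    }
  }
})

test_that("tightening run filters never adds segments", {
  set.seed(55)
  gm <- rand_gm(3, 300, het = 0.1, n_chrom = 2)
  base <- roh_params(window_snps = 10, min_snps_in_run = 10,
                     min_length_bp = 1e5)
  n0 <- nrow(detect_roh(gm, base))
  for (len in c(2e5, 5e5, 1e6)) {
    p <- base; p$min_length_bp <- len
    expect_lte(nrow(detect_roh(gm, p)), n0)
  }
  for (k in c(15, 25, 60)) {
    p <- base; p$min_snps_in_run <- k
    expect_lte(nrow(detect_roh(gm, p)), n0)
  }
})

test_that("reported segments honor every invariant and allele-label swaps", {
  set.seed(77)
  for (rep in 1:10) {
    gm <- rand_gm(4, 250, het = runif(1, 0.05, 0.3), miss = 0.03, n_chrom = 2)
    p <- rand_roh_params()
    seg <- detect_roh(gm, p)
    if (nrow(seg)) {
      expect_true(all(seg$end_bp > seg$start_bp))
      expect_true(all(seg$n_snps >= p$min_snps_in_run))
      expect_true(all(seg$length_bp >= p$min_length_bp))
      expect_equal(seg$length_bp, seg$end_bp - seg$start_bp)
      if (p$min_density > 0)
        expect_true(all(seg$n_snps / seg$length_bp >= p$min_density))
      # no internal gap exceeds the maximum
      for (r in seq_len(nrow(seg))) {
        jx <- which(gm$markers$chrom == seg$chrom[r] &
                      gm$markers$pos_bp >= seg$start_bp[r] &
                      gm$markers$pos_bp <= seg$end_bp[r])
        expect_true(all(diff(gm$markers$pos_bp[jx]) <= p$max_gap_bp))
      }
    }
    sw <- gm
    sw$calls <- 2L - sw$calls
    expect_equal(detect_roh(sw, p), seg, ignore_attr = TRUE)
  }
})
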