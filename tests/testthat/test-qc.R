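test_that("call-rate comparators are inclusive for SNPs, strict for individuals", {
  # 10 individuals, SNP 1 called in 9/10 (rate exactly 0.90) -> kept;
  # SNP 2 called in 8/10 -> dropped
  g <- c("00", "00", "00", "00", "00", "00", "00", "00", "0.", "..")
  gm <- make_gm(g)
  out <- apply_qc(gm, qc_thresholds(individual_call_rate = 0))
  expect_equal(out$markers$snp_id, "s1")

  # 100 SNPs, individual with exactly 95 calls (rate 0.95) removed under ">";
  # individual with 96 calls kept
  s95 <- paste(c(rep("0", 95), rep(".", 5)), collapse = "")
  s96 <- paste(c(rep("0", 96), rep(".", 4)), collapse = "")
  gm <- make_gm(c(s95, s96), spacing = 1000)
  out <- apply_qc(gm, qc_thresholds(snp_call_rate = 0))
  expect_equal(out$individuals, "I2")
})

test_that("non-autosomal markers are dropped and emptiness errors", {
  gm <- make_gm(c("000", "000"), chrom = c(1L, 31L, 32L),
                pos = c(100, 100, 100))
  out <- apply_qc(gm)
  expect_equal(out$markers$chrom, c(1L, 31L))
  gm_x <- make_gm(c("000", "000"), chrom = c(32L, 32L, 32L),
                  pos = c(100, 200, 300))
  expect_error(apply_qc(gm_x), "empty after QC")
})

test_that("applying QC twice equals applying once", {
  set.seed(11)
  gm <- rand_gm(30, 200, miss = 0.01, n_chrom = 2)
  # plant low-call individuals (fail the 95% filter) and SNPs (fail 90%)
  gm$calls[1:2, sample(200, 50)] <- NA_integer_
  for (j in 1:5) gm$calls[sample(3:30, 8), j] <- NA_integer_
  once <- apply_qc(gm)
  twice <- apply_qc(once)
  expect_equal(twice$calls, once$calls, ignore_attr = TRUE)
  expect_equal(twice$markers$snp_id, once$markers$snp_id)
  expect_equal(twice$individuals, once$individuals)
})

test_that("observed and expected heterozygosity follow allele frequencies", {
  gm <- make_gm(c("0", "1", "2"))
  h <- heterozygosity(gm)
  expect_equal(h$per_snp$ho, 1 / 3)
  expect_equal(h$per_snp$p_alt, 0.5)
  expect_equal(h$per_snp$he, 0.5)

  gm_mono <- make_gm(c("0", "0", "0"))
  h <- heterozygosity(gm_mono)
  expect_equal(h$per_snp$ho, 0)
  expect_equal(h$per_snp$he, 0)

  # invariance to allele-label swap at every SNP
  set.seed(3)
  gm <- rand_gm(20, 100)
  sw <- gm
  sw$calls <- 2L - sw$calls
  expect_equal(heterozygosity(sw)$per_snp$ho, heterozygosity(gm)$per_snp$ho)
  expect_equal(heterozygosity(sw)$per_snp$he, heterozygosity(gm)$per_snp$he)

  # SNPs with no calls are excluded from means, with a warning
  gm$calls[, 1] <- NA_integer_
  expect_warning(h <- heterozygosity(gm), "zero non-missing")
  expect_true(is.na(h$per_snp$ho[1]))
  expect_false(anyNA(h$overall$mean_ho))
})

test_that("simulated panels reproduce the generator's target heterozygosity", {
  sim <- simulate_population(sim_config(
    seed = 5, n = 40L, tract_rates_per_gb = c(0, 0, 0, 0),
    chromosomes = data.frame(chrom = 1L, n_snps = 2000L, length_bp = 8e7)))
  h <- heterozygosity(sim$gm)
  expect_lt(abs(h$overall$mean_he - 0.32), 0.01)
  expect_lt(abs(h$overall$mean_ho - 0.32), 0.01)
})

test_that("exact HWE p-values match direct enumeration and conventions", {
  # perfect Hardy-Weinberg proportions -> p = 1
  expect_equal(hwe_exact_p(25, 50, 25), 1)
  # total heterozygote deficit -> overwhelming rejection
  expect_lt(hwe_exact_p(50, 0, 50), 1e-6)
  # monomorphic -> 1 by convention
  expect_equal(hwe_exact_p(30, 0, 0), 1)
  # mid-p is strictly smaller for polymorphic SNPs
  expect_lt(hwe_exact_p(20, 5, 10, midp = TRUE), hwe_exact_p(20, 5, 10))

  # equivalence with the log-factorial oracle across random configurations
  set.seed(9)
  for (rep in 1:200) {
    n <- sample(2:30, 1)
    naa <- sample(0:n, 1)
    nab <- sample(0:(n - naa), 1)
    nbb <- n - naa - nab
    expect_equal(hwe_exact_p(naa, nab, nbb), oracle_hwe_p(naa, nab, nbb),
                 tolerance = 1e-10)
  }
})

test_that("hwe_test reports per-SNP and per-chromosome p-values", {
  set.seed(21)
  gm <- rand_gm(25, 60, n_chrom = 3)
  res <- hwe_test(gm)
  expect_equal(nrow(res$per_snp), 60)
  expect_true(all(res$per_snp$hwe_p >= 0 & res$per_snp$hwe_p <= 1))
  expect_equal(nrow(res$per_chrom), 3)
  # HW-simulated genotypes should not reject on average
  expect_gt(mean(res$per_chrom$mean_p), 0.05)
})
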