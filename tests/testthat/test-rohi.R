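track_from <- function(counts, n, chrom = 1L, spacing = 1e5) {
  structure(data.frame(snp_id = paste0("s", seq_along(counts)),
                       chrom = chrom, pos_bp = seq_along(counts) * spacing,
                       count = counts, frequency = counts / n, p = NA_real_,
                       stringsAsFactors = FALSE),
            n_individuals = n, class = c("incidence_track", "data.frame"))
}

test_that("SNP incidence counts distinct covering individuals", {
  gm <- make_gm(rep("00000", 4), pos = c(10, 20, 30, 40, 50) * 1e4)
  seg <- data.frame(individual = c("I1", "I2"), chrom = 1L,
                    start_bp = c(1e5, 2e5), end_bp = c(3e5, 4e5),
                    n_snps = 3L, length_bp = 2e5)
  tr <- snp_incidence(seg, gm)
  expect_equal(tr$count, c(1L, 2L, 2L, 1L, 0L))
  expect_equal(tr$frequency, c(1, 2, 2, 1, 0) / 4)

  empty <- snp_incidence(seg[integer(0), ], gm)
  expect_true(all(empty$count == 0))
})

test_that("incidence matches the interval-stabbing oracle on random sets", {
  set.seed(17)
  for (rep in 1:10) {
    gm <- rand_gm(6, 80, n_chrom = 2)
    k <- sample(5:25, 1)
    jx <- sample(nrow(gm$markers), k, replace = TRUE)
    seg <- data.frame(
      individual = sample(gm$individuals, k, replace = TRUE),
      chrom = gm$markers$chrom[jx],
      start_bp = gm$markers$pos_bp[jx],
      end_bp = gm$markers$pos_bp[jx] + sample.int(5e5, k),
      n_snps = 0L, length_bp = 0)
    # de-overlap per individual to honor the caller's guarantee
    seg <- seg[!duplicated(seg[c("individual", "chrom")]), ]
    tr <- snp_incidence(seg, gm)
    expect_equal(tr$count, oracle_incidence(seg, gm))
  }
})

test_that("closed-form null tail probability is (M - c + 1) / (M + 1)", {
  expect_equal(incidence_null_p(99, 99), 0.01)
  expect_equal(incidence_null_p(0, 99), 1)
  expect_equal(incidence_null_p(5, 9, tail = "literal"), 0.5)

  tr <- track_from(c(0L, 3L, 9L, 9L), n = 10)
  tr <- incidence_pvalues(tr)
  expect_equal(tr$p, c(10, 7, 1, 1) / 10)
  expect_equal(unname(attr(tr, "max_by_chrom")), 9)

  # all-zero chromosome: p = 1 everywhere
  tr0 <- incidence_pvalues(track_from(c(0L, 0L), n = 5))
  expect_equal(tr0$p, c(1, 1))

  expect_error(incidence_pvalues(track_from(1L, 2), method = "monte_carlo",
                                 reps = 0, seed = 1), "reps")
  expect_error(incidence_pvalues(track_from(1L, 2), method = "monte_carlo"),
               "seed")
})

test_that("Monte-Carlo p-values converge to the closed form", {
  reps <- 1e4
  counts <- c(0L, 1L, 5L, 10L, 25L, 40L, 50L)
  tr <- track_from(counts, n = 50)
  mc <- incidence_pvalues(tr, method = "monte_carlo", reps = reps, seed = 42)
  cf <- incidence_pvalues(tr)
  tol <- 4 * sqrt(cf$p * (1 - cf$p) / reps)
  expect_true(all(abs(mc$p - cf$p) <= tol))
  # determinism under a fixed seed
  mc2 <- incidence_pvalues(tr, method = "monte_carlo", reps = reps, seed = 42)
  expect_identical(mc$p, mc2$p)
  # p is non-increasing in the incidence at fixed M
  expect_true(all(diff(mc$p[order(counts)]) <= 0))
  expect_true(all(diff(cf$p[order(counts)]) <= 0))
})

test_that("islands need >= 50% frequency and three significant SNPs", {
  n <- 500
  base <- c(100L, 100L, 300L, 300L, 300L, 300L, 300L, 100L)
  tr <- incidence_pvalues(track_from(base, n))
  tr$count[3:7] <- 300L
  # 5 consecutive SNPs at 60% frequency, all highly significant
  isl <- call_islands(tr)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$n_snps, 5L)
  expect_equal(isl$start_bp, tr$pos_bp[3])
  expect_equal(isl$end_bp, tr$pos_bp[7])
  expect_equal(isl$length_bp, isl$end_bp - isl$start_bp)
  expect_equal(isl$mean_p, mean(tr$p[3:7]))

  # only two significant SNPs in the frequent stretch -> no island
  tr2 <- track_from(c(100L, 300L, 300L, 260L, 100L), n)
  tr2 <- incidence_pvalues(tr2)
  expect_lt(sum(tr2$p[2:4] < 0.01), 3)
  expect_equal(nrow(call_islands(tr2)), 0L)

  # frequency just below one half -> no island regardless of significance
  tr3 <- incidence_pvalues(track_from(rep(249L, 5), n))
  expect_equal(nrow(call_islands(tr3)), 0L)
})

test_that("called islands are sorted and non-overlapping", {
  sim <- simulate_population(sim_config(
    seed = 3, n = 30L,
    islands = data.frame(chrom = c(2L, 4L), center_bp = c(3e7, 6e7),
                         span_bp = 3e6, carrier_frac = 1)))
  seg <- detect_roh(sim$gm)
  tr <- incidence_pvalues(snp_incidence(seg, sim$gm))
  isl <- call_islands(tr, p_max = 0.05)
  if (nrow(isl) > 1) {
    expect_true(all(diff(order(isl$chrom, isl$start_bp)) == 1))
    same <- isl$chrom[-1] == isl$chrom[-nrow(isl)]
    expect_true(all(isl$start_bp[-1][same] > isl$end_bp[-nrow(isl)][same]))
  }
  expect_gte(nrow(isl), 1L)
})
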