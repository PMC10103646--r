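test_that("reference tiling matches window/step arithmetic", {
  ref <- simulate_reference(1, 8000, 800, 800, seed = 1)
  expect_equal(nrow(ref$windows), 10L)
  expect_equal(ref$windows$end - ref$windows$start, rep(800L, 10))

  ref2 <- simulate_reference(1, 8000, 800, 400, seed = 1)
  expect_equal(nrow(ref2$windows), 19L)
  expect_equal(ref2$windows$start, seq(0L, 7200L, by = 400L))

  expect_true(all(ref2$windows$gc >= 0 & ref2$windows$gc <= 1))
  expect_error(simulate_reference(1, 8000, -800, 800), "positive")
  expect_error(simulate_reference(1, 8000, 800, 300), "step")
  expect_error(simulate_reference(1, 5000, 800, 800), "10")
})

test_that("identical seeds give identical references and depth", {
  r1 <- simulate_reference(2, 1e5, 800, 400, seed = 42)
  r2 <- simulate_reference(2, 1e5, 800, 400, seed = 42)
  expect_identical(r1, r2)

  sim1 <- simulate_cohort(chrom_length = 2e5, n_events = 3, seed = 7)
  sim2 <- simulate_cohort(chrom_length = 2e5, n_events = 3, seed = 7)
  expect_identical(sim1$depth$counts, sim2$depth$counts)
})

test_that("implanting respects allele-frequency extremes and empty truth", {
  ref <- simulate_reference(1, 1e5, 800, 800, seed = 1)
  ev <- cnv_events("chr1", 40000, 48000, "deletion", -1,
                   data.frame(A = 1.0, B = 0.0))
  truth <- implant_cnvs(ref, c(A = 10L, B = 10L), ev, seed = 1)
  span <- ref$windows$start < 48000 & ref$windows$end > 40000
  a_cols <- truth$samples$population == "A"
  expect_true(all(truth$cn[span, a_cols] == 0))
  expect_true(all(truth$cn[span, !a_cols] == 2))
  expect_true(all(truth$cn[!span, ] == 2))

  empty <- cnv_events(character(0), integer(0), integer(0), character(0),
                      integer(0), data.frame(A = numeric(0), B = numeric(0)))
  t0 <- implant_cnvs(ref, c(A = 5L, B = 5L), empty, seed = 1)
  expect_true(all(t0$cn == 2))
})

test_that("carrier fraction follows the diploid binomial expectation", {
  ref <- simulate_reference(1, 1e5, 800, 800, seed = 1)
  ev <- cnv_events("chr1", 40000, 48000, "deletion", -1,
                   data.frame(A = 0.5))
  truth <- implant_cnvs(ref, c(A = 1000L), ev, seed = 3)
  carrier <- mean(truth$deltas[1, ] != 0)
  p <- 1 - (1 - 0.5)^2
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(carrier - p), 5 * se)
})

test_that("overlapping or out-of-bounds events are rejected", {
  ref <- simulate_reference(1, 1e5, 800, 800, seed = 1)
  ov <- cnv_events(c("chr1", "chr1"), c(1000, 4000), c(5000, 9000),
                   "deletion", -1, data.frame(A = c(0.5, 0.5)))
  expect_error(implant_cnvs(ref, c(A = 5L), ov, seed = 1), "overlap")
  oob <- cnv_events("chr1", 99000, 101000, "deletion", -1, data.frame(A = 0.5))
  expect_error(implant_cnvs(ref, c(A = 5L), oob, seed = 1), "bounds")
})

test_that("truth track equals 2 plus the carried copy changes per window", {
  sim <- simulate_cohort(chrom_length = 5e5, n_events = 5, seed = 11)
  ev <- sim$truth$events
  w <- sim$ref$windows
  rebuilt <- matrix(2L, nrow(w), nrow(sim$truth$samples))
  for (e in seq_len(nrow(ev))) {
    hit <- w$chrom == ev$chrom[e] & w$start < ev$end[e] & w$end > ev$start[e]
    rebuilt[hit, ] <- rebuilt[hit, ] +
      matrix(sim$truth$deltas[e, ], sum(hit), ncol(rebuilt), byrow = TRUE)
  }
  rebuilt[rebuilt < 0L] <- 0L
  expect_equal(unname(sim$truth$cn), rebuilt)
})

test_that("depth means are proportional to copy number and to coverage", {
  ref <- simulate_reference(1, 8.0008e6, 800, 800, seed = 5)  # 10001 windows
  ev <- cnv_events("chr1", 0, 4e6, "duplication", 1, data.frame(A = 1.0))
  truth <- implant_cnvs(ref, c(A = 2L), ev, seed = 5)
  truth$deltas[] <- 2L  # force homozygous: cn = 4 on the left half
  truth$cn[ref$windows$start < 4e6, ] <- 4L
  truth$dosage[ref$windows$start < 4e6, ] <- 4
  dep <- simulate_depth(truth, ref, mean_depth = 12, gc_bias_amplitude = 0,
                        dispersion = Inf, seed = 6)
  mu <- 12 * (800 + 150) / 150
  left <- ref$windows$end <= 4e6
  m_left <- mean(dep$counts[left, ])
  m_right <- mean(dep$counts[!left, ])
  se_left <- sd(dep$counts[left, ]) / sqrt(sum(left) * 2)
  se_right <- sd(dep$counts[!left, ]) / sqrt(sum(!left) * 2)
  expect_lt(abs(m_left - 2 * mu), 3 * se_left)
  expect_lt(abs(m_right - mu), 3 * se_right)

  # doubling coverage doubles the mean within 2%
  dep2 <- simulate_depth(truth, ref, mean_depth = 24, gc_bias_amplitude = 0,
                         dispersion = Inf, seed = 7)
  expect_lt(abs(mean(dep2$counts) / mean(dep$counts) - 2), 0.04)
})

test_that("zero copy number yields zero counts; marginal mean is calibrated", {
  ref <- simulate_reference(1, 8.0008e6, 800, 800, seed = 2)
  ev <- cnv_events("chr1", 0, 8.0008e6, "deletion", -2, data.frame(A = 1.0))
  truth <- implant_cnvs(ref, c(A = 3L), ev, seed = 2)
  dep <- simulate_depth(truth, ref, seed = 2)
  hom <- truth$deltas[1, ] == -2L
  expect_true(any(hom))
  expect_true(all(dep$counts[, hom] == 0))

  empty <- cnv_events(character(0), integer(0), integer(0), character(0),
                      integer(0), data.frame(A = numeric(0)))
  t0 <- implant_cnvs(ref, c(A = 2L), empty, seed = 2)
  d0 <- simulate_depth(t0, ref, mean_depth = 12, gc_bias_amplitude = 0,
                       dispersion = 150, seed = 3)
  expect_lt(abs(mean(d0$counts) / (12 * 950 / 150) - 1), 0.01)
})

test_that("negative binomial counts are overdispersed relative to Poisson", {
  ref <- simulate_reference(1, 8.0008e6, 800, 800, seed = 9)
  empty <- cnv_events(character(0), integer(0), integer(0), character(0),
                      integer(0), data.frame(A = numeric(0)))
  truth <- implant_cnvs(ref, c(A = 1L), empty, seed = 9)
  dep <- simulate_depth(truth, ref, gc_bias_amplitude = 0, dispersion = 50,
                        seed = 9)
  mu <- mean(dep$counts)
  expect_gt(var(as.numeric(dep$counts)), 1.5 * mu)
})

test_that("CNVR-level generator reproduces the requested dosage frequencies", {
  freq <- cbind(A = rep(0.5, 200), B = rep(0.0, 200))
  sim <- simulate_cnvr_matrix(c(A = 50L, B = 50L), freq, kind = "deletion",
                              noise_sd = 0, seed = 4)
  a <- sim$popmap$population == "A"
  # mean dosage in A: 2 - 2*0.5 = 1; in B: exactly 2
  expect_lt(abs(mean(sim$cnvrs$cn[, a]) - 1), 0.05)
  expect_equal(unname(mean(sim$cnvrs$cn[, !a])), 2)
})
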