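test_that("vst reproduces hand-computed and boundary values", {
  expect_equal(vst(c(1, 3), c(1, 3))$vst, 0)
  v1 <- vst(c(0, 0, 0), c(4, 4, 4))
  expect_equal(v1$v_s, 0)
  expect_gt(v1$v_t, 0)
  expect_equal(v1$vst, 1)
  # denominator-n hand computation
  v <- vst(c(2, 2, 2, 2), c(0, 0, 2, 2))
  expect_equal(v$v_t, 0.75)
  expect_equal(v$v_s, 0.5)
  expect_equal(v$vst, 1 / 3)
  # monomorphic locus: vst defined as 0
  expect_equal(vst(c(2, 2), c(2, 2))$vst, 0)
  expect_error(vst(1, c(1, 2)), "at least 2")
})

test_that("vst is symmetric, affine-invariant and bounded by one", {
  set.seed(20)
  w_sym <- w_aff <- w_orc <- 0
  for (i in 1:200) {
    a <- runif(sample(2:50, 1)); b <- runif(sample(2:50, 1))
    va <- vst(a, b)$vst
    expect_lte(va, 1)
    w_sym <- max(w_sym, abs(va - vst(b, a)$vst))
    w_aff <- max(w_aff, abs(va - vst(3 * a - 1, 3 * b - 1)$vst))
    w_orc <- max(w_orc, abs(va - vst_oracle(a, b)))
  }
  expect_lt(w_sym, 1e-14)
  expect_lt(w_aff, 1e-9)
  expect_lt(w_orc, 1e-12)
})

test_that("vst scan under the null is centred at zero and pair-independent", {
  means <- vapply(1:20, function(s) {
    set.seed(s)
    cn <- matrix(rnorm(1000 * 40, 2, 0.3), 1000, 40,
                 dimnames = list(NULL, sprintf("s%02d", 1:40)))
    fx <- cnvr_fixture(rep("deletion", 1000), 2000, 0.9, n_samples = 40)
    fx$cn <- cn
    popmap <- data.frame(sample = colnames(cn),
                         population = rep(c("A", "B"), 20))
    mean(vst_scan(fx, popmap, "A")$vst)
  }, numeric(1))
  expect_true(all(abs(means) < 0.05))

  # scanning pairs separately equals the pooled scan restricted per pair
  fx <- cnvr_fixture(rep("deletion", 20), 2000, 0.9, n_samples = 12)
  set.seed(30)
  fx$cn <- matrix(runif(20 * 12, 0, 4), 20, 12,
                  dimnames = list(NULL, fx$samples))
  popmap <- data.frame(sample = fx$samples,
                       population = rep(c("A", "X", "Y"), each = 4))
  all_scan <- vst_scan(fx, popmap, "A", c("X", "Y"))
  x_only <- vst_scan(fx, popmap, "A", "X")
  expect_equal(all_scan[all_scan$pop_b == "X", ], x_only, ignore_attr = TRUE)

  bad <- popmap; bad$population[1:3] <- c("Z", "A", "A")
  expect_error(vst_scan(fx, bad, "A", "Z"), "'Z'")
})

test_that("fixed differences give vst one within the scan", {
  fx <- cnvr_fixture(rep("deletion", 3), 2000, 0.9, n_samples = 8)
  fx$cn <- rbind(c(rep(2, 4), rep(0, 4)),
                 matrix(2, 2, 8))
  colnames(fx$cn) <- fx$samples
  popmap <- data.frame(sample = fx$samples,
                       population = rep(c("A", "B"), each = 4))
  rec <- vst_scan(fx, popmap, "A")
  expect_equal(rec$vst, c(1, 0, 0))
})

test_that("top-outlier selection uses the interpolated quantile with ties", {
  fx <- cnvr_fixture(rep("deletion", 100), 2000, 0.9, n_samples = 4)
  rec <- data.frame(cnvr_id = seq_len(100), chrom = "chr1",
                    start = seq_len(100) * 1000L,
                    end = seq_len(100) * 1000L + 500L,
                    kind = "deletion", pop_a = "A", pop_b = "B",
                    v_t = 1, v_s = 0, vst = seq(0.001, 0.1, length.out = 100),
                    stringsAsFactors = FALSE)
  out <- top_outliers(rec, 0.01)
  expect_equal(sum(out$outlier), 1L)
  expect_equal(out$cnvr_id[out$outlier], 100)
  expect_equal(out$rank[out$outlier], 1L)

  rec$vst <- 0.5
  out2 <- top_outliers(rec, 0.01)
  expect_true(all(out2$outlier))

  expect_error(top_outliers(rec, 1.0), "q must")
  rec2 <- rec[1:2, ]
  rec2$vst <- c(0.1, 0.9)
  out3 <- top_outliers(rec2, 0.5)
  expect_equal(out3$cnvr_id[out3$outlier], 2)
})

test_that("outlier gene mapping enumerates overlaps and deduplicates", {
  model <- toy_gene_model()
  out <- data.frame(cnvr_id = c("a", "b", "c"), chrom = "chr1",
                    start = c(1500L, 8500L, 30000L),
                    end = c(1800L, 12500L, 30500L),
                    pop_a = "A", pop_b = "B",
                    vst = c(0.9, 0.8, 0.7), stringsAsFactors = FALSE)
  genes <- map_outliers_to_genes(out, model)
  # a hits G1; b spans G1 end and G2 start; c hits nothing
  expect_setequal(genes$gene, c("G1", "G2"))
  expect_equal(genes$best_vst[genes$gene == "G1"], 0.9)
  expect_equal(genes$n_cnvrs[genes$gene == "G1"], 2L)
})

test_that("per-population profiles match direct recomputation", {
  fx <- cnvr_fixture(rep("deletion", 2), 2000, 0.9, n_samples = 6)
  set.seed(31)
  fx$cn <- matrix(runif(12, 0, 4), 2, 6, dimnames = list(NULL, fx$samples))
  popmap <- data.frame(sample = fx$samples,
                       population = rep(c("A", "B"), each = 3))
  prof <- copy_number_profile(fx, 2, popmap)
  expect_equal(prof$summary$mean[prof$summary$population == "A"],
               mean(fx$cn[2, 1:3]))
  expect_equal(prof$summary$median[prof$summary$population == "B"],
               median(fx$cn[2, 4:6]))
  expect_equal(prof$values$A, fx$cn[2, 1:3])
})

test_that("differential CNVRs dominate the top percentile of the scan", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    f_null <- runif(500, 0.05, 0.5)
    # carrier frequencies 0.9 vs 0.1 -> allele frequencies via 1-(1-p)^2
    p_hi <- 1 - sqrt(1 - 0.9); p_lo <- 1 - sqrt(1 - 0.1)
    freq <- cbind(A = c(f_null, rep(p_hi, 5)), B = c(f_null, rep(p_lo, 5)))
    sim <- simulate_cnvr_matrix(c(A = 20L, B = 20L), freq, seed = s)
    out <- top_outliers(vst_scan(sim$cnvrs, sim$popmap, "A"), 0.01)
    diff_start <- sim$cnvrs$regions$start[501:505]
    sum(out$outlier & out$start %in% diff_start)
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.9)
})
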