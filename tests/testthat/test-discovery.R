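test_that("silhouette matches hand-computed and boundary cases", {
  expect_equal(silhouette_score(c(0, 0, 4, 4), c("A", "A", "B", "B")), 1)
  # {0,1,2,3} with a 2/2 split: s = (0.6 + 1/3 + 1/3 + 0.6)/4 = 7/15,
  # frozen from the brute-force all-pairs oracle
  expect_equal(silhouette_score(0:3, c("A", "A", "B", "B")), 7 / 15)
  expect_equal(silhouette_oracle(0:3, c("A", "A", "B", "B")), 7 / 15)
  expect_error(silhouette_score(1:4, rep("A", 4)), "2 clusters")
  # singleton clusters contribute zero
  expect_equal(silhouette_score(c(0, 0, 5), c("A", "A", "B")),
               mean(c((5 - 0) / 5, (5 - 0) / 5, 0)))
})

test_that("silhouette of random labels on iid values is centred near zero", {
  means <- vapply(1:100, function(s) {
    set.seed(s)
    x <- runif(200)
    lab <- sample(c("A", "B"), 200, replace = TRUE)
    silhouette_score(x, lab)
  }, numeric(1))
  expect_gt(mean(means), -0.1)
  expect_lt(mean(means), 0.1)
})

test_that("silhouette agrees with the brute-force oracle on random data", {
  set.seed(99)
  worst <- 0
  for (i in 1:50) {
    n <- sample(5:50, 1)
    k <- sample(2:4, 1)
    x <- runif(n)
    lab <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
    worst <- max(worst, abs(silhouette_score(x, lab) - silhouette_oracle(x, lab)))
  }
  expect_lt(worst, 1e-12)
})

test_that("candidate windows follow the deviant-count threshold", {
  cn40 <- function(cn_deviants, value) {
    m <- matrix(2, 3, 40, dimnames = list(NULL, sprintf("s%02d", 1:40)))
    m[2, seq_len(cn_deviants)] <- value
    cn_fixture(m)
  }
  # 4 of 40 at cn 1.0: 4 >= max(3, ceil(0.1*40)) = 4 -> candidate
  cand <- detect_candidates(cn40(4, 1.0))
  expect_equal(cand$window, 2L)
  expect_equal(cand$n_loss, 4L)
  # 2 of 40 at cn 0.5 -> below threshold
  expect_equal(nrow(detect_candidates(cn40(2, 0.5))), 0L)
  # all-diploid: nothing
  expect_equal(nrow(detect_candidates(cn_fixture(matrix(2, 5, 40)))), 0L)
  expect_error(detect_candidates(cn40(4, 1), loss_threshold = 2.5), "loss_threshold")
})

test_that("raising f or h never increases the candidate count", {
  sim <- simulate_cohort(chrom_length = 1e6, n_events = 5, seed = 13)
  cn <- normalize_depth(sim$depth)
  n_base <- nrow(detect_candidates(cn, f = 0.1, h = 3))
  expect_lte(nrow(detect_candidates(cn, f = 0.2, h = 3)), n_base)
  expect_lte(nrow(detect_candidates(cn, f = 0.1, h = 6)), n_base)
})

test_that("merging respects the gap rule and the correlation rule", {
  v <- c(1, 1, 1, 1, 2, 2, 2, 2)           # 4 carriers of 8
  m <- rbind(v, v, 2, 2, 2)                 # windows 1,2 deviant
  cn <- cn_fixture(m, step = 800L)
  cand <- detect_candidates(cn, f = 0.1, h = 3)
  expect_equal(cand$window, c(1L, 2L))
  regs <- merge_candidates(cand, cn, r = 0.1, max_gap = 1)
  expect_length(regs, 1L)
  expect_equal(regs[[1]]$windows, c(1L, 2L))
  expect_equal(c(regs[[1]]$start, regs[[1]]$end), c(0L, 1600L))

  # exactly anticorrelated adjacent windows never merge at r = 0.1
  v2 <- c(3, 3, 3, 3, 2, 2, 2, 2)
  expect_lt(cor(v, v2), -0.99)
  m2 <- rbind(v, v2, 2, 2, 2)
  cn2 <- cn_fixture(m2, step = 800L)
  regs2 <- merge_candidates(detect_candidates(cn2), cn2, r = 0.1)
  expect_length(regs2, 2L)

  # a 5-step gap is never bridged with max_gap = 1
  m3 <- rbind(v, 2, 2, 2, 2, v, 2)
  cn3 <- cn_fixture(m3, step = 800L)
  regs3 <- merge_candidates(detect_candidates(cn3), cn3, r = -1, max_gap = 1)
  expect_length(regs3, 2L)
  expect_error(merge_candidates(detect_candidates(cn3), cn3, r = 2), "r must")
})

test_that("genotyping separates clusters and picks k by silhouette", {
  vals <- c(rep(2, 20), rep(1, 20)) + rep(c(-0.01, 0.01), 20)
  m <- rbind(vals, vals)
  cn <- cn_fixture(m, step = 800L)
  g <- genotype_cnvr(list(chrom = "chr1", start = 0L, end = 1600L,
                          windows = 1:2), cn)
  expect_equal(g$kind, "deletion")
  expect_gt(g$silhouette, 0.9)
  gt <- attr(g, "genotype")
  expect_equal(sum(gt == "loss"), 20L)

  # all-identical summaries: no valid clustering, silhouette -1
  g2 <- genotype_cnvr(list(chrom = "chr1", start = 0L, end = 800L,
                           windows = 1L), cn_fixture(matrix(2, 1, 10)))
  expect_equal(g2$silhouette, -1)
  expect_equal(g2$kind, "none")

  # three well-separated levels: k = 3 wins, kind both
  vals3 <- c(rep(1, 12), rep(2, 12), rep(3, 12)) + rep(c(-0.01, 0.01), 18)
  cn3 <- cn_fixture(rbind(vals3, vals3), step = 800L)
  g3 <- genotype_cnvr(list(chrom = "chr1", start = 0L, end = 1600L,
                           windows = 1:2), cn3)
  expect_equal(g3$kind, "both")
  km2 <- silhouette_oracle(vals3, ifelse(vals3 < 1.5, 1, 2))
  expect_gt(g3$silhouette, km2)  # k=3 beats the best 2-split
})

test_that("filters implement strict silhouette and kind-specific lengths", {
  fx <- cnvr_fixture(
    kind = c("deletion", "deletion", "deletion", "deletion", "duplication",
             "duplication", "duplication", "duplication", "both", "both",
             "both", "deletion"),
    length_bp = c(2000, 50000, 50001, 2000, 499999, 500000, 2000, 2000,
                  50000, 60000, 1000, 60000),
    silhouette = c(0.9, 0.9, 0.9, 0.6, 0.7, 0.7, 0.61, 0.59, 0.95, 0.95,
                   0.6, 0.9))
  kept <- filter_cnvrs(fx)
  expect_equal(sort(kept$regions$start), sort(fx$regions$start[c(1, 2, 5, 7, 9)]))

  # raising the silhouette cutoff never increases the retained count
  expect_lte(nrow(filter_cnvrs(fx, silhouette_min = 0.8)$regions),
             nrow(filter_cnvrs(fx, silhouette_min = 0.6)$regions))
})

test_that("boundary refinement trims diluted edge windows only", {
  dev_profile <- c(0.2, 0.45, 1, 1, 1, 1, 0.3)
  m <- 2 - outer(dev_profile, c(rep(1, 6), rep(0, 2)))  # 6 carriers, 2 ref
  cn <- cn_fixture(m, step = 800L)
  reg <- list(chrom = "chr1", start = 0L, end = 7L * 800L, windows = 1:7)
  out <- refine_boundaries(reg, cn)
  expect_equal(out$windows, 3:6)
  expect_equal(c(out$start, out$end), c(1600L, 4800L))
})

test_that("calling is deterministic and recovers implanted events", {
  sim <- simulate_cohort(chrom_length = 2e6, n_events = 8, seed = 21)
  cn <- normalize_depth(sim$depth)
  c1 <- call_cnvrs(cn)
  c2 <- call_cnvrs(cn)
  expect_identical(c1$regions, c2$regions)

  ev <- sim$truth$events
  hit <- vapply(seq_len(nrow(ev)), function(i) {
    any(c1$regions$start < ev$end[i] & c1$regions$end > ev$start[i] &
        (c1$regions$kind == ev$kind[i] | c1$regions$kind == "both"))
  }, logical(1))
  expect_gte(mean(hit), 0.85)
})
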