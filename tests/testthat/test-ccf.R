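test_that("read-support filters match the stated thresholds", {
  maf <- data.frame(
    t_depth    = c(9, 100, 100, 10, 100),
    t_alt_count = c(5, 2, 3, 3, 30))
  # depth 9 fails depth>=10; alt 2 fails alt>=3; 3/100 fails VAF>=0.05;
  # 3/10 = 0.30 passes all three at the boundary; 30/100 passes
  kept <- filter_mutations(maf)
  expect_equal(as.integer(rownames(kept)), c(4L, 5L))
  expect_error(filter_mutations(data.frame(t_depth = 5, t_alt_count = 9)),
               "exceeds depth")
  expect_error(filter_mutations(data.frame(x = 1)), "missing required")
})

test_that("expected VAF follows the purity/copy-number formula", {
  expect_equal(expected_vaf(1, 1, 2, 2), 0.5)
  expect_equal(expected_vaf(1, 0.6, 2, 2), 0.3)
  expect_equal(expected_vaf(0, 0.37, 2, 3), 0)
  expect_equal(expected_vaf(0.5, 0.6, 2, 2), 0.15)
  # triploid locus dilutes the allele at multiplicity 1
  expect_equal(expected_vaf(1, 0.5, 2, 4), 0.5 / (2 * 0.5 + 0.5 * 4))
})

test_that("the deviance minimizer recovers exactly solvable CCFs", {
  e1 <- estimate_ccf(alt = 30, depth = 100, purity = 0.6, local_cn = 2)
  expect_equal(e1$ccf, 1.0)
  expect_equal(e1$timing, "early")
  e2 <- estimate_ccf(alt = 15, depth = 100, purity = 0.6, local_cn = 2)
  expect_equal(e2$ccf, 0.5, tolerance = 1e-3)
  expect_equal(e2$timing, "late")
  e3 <- estimate_ccf(alt = 50, depth = 100, purity = 1, local_cn = 2)
  expect_equal(e3$ccf, 1.0)
})

test_that("estimator agrees with the 1e-3 grid-search deviance oracle", {
  set.seed(42)
  for (i in 1:100) {
    depth <- sample(20:300, 1)
    purity <- runif(1, 0.2, 1)
    cn <- sample(1:5, 1)
    alt <- rbinom(1, depth, runif(1, 0.02, 0.6))
    alt <- min(alt, depth)
    est <- estimate_ccf(alt, depth, purity, cn)$ccf
    oracle <- ccf_grid_oracle(alt, depth, purity, 2, cn)
    expect_lt(abs(est - oracle), 1e-3 + 1e-9)
  }
})

test_that("X-chromosome germline copy number follows patient sex", {
  male <- estimate_ccf(20, 100, 0.5, 2, chrom = "chrX", sex = "male")
  female <- estimate_ccf(20, 100, 0.5, 2, chrom = "chrX", sex = "female")
  auto <- estimate_ccf(20, 100, 0.5, 2, chrom = "chr5", sex = "male")
  expect_equal(male$cn_normal, 1L)
  expect_equal(female$cn_normal, 2L)
  expect_equal(auto$cn_normal, 2L)
  # fewer normal copies -> lower expected VAF -> higher CCF for same reads
  expect_lt(male$ccf, female$ccf)
})

test_that("ties at CCF exactly 0.8 are classified early", {
  # depth/purity chosen so the MLE lands on 0.8: vaf = 0.8 * p/2
  est <- estimate_ccf(alt = 40, depth = 100, purity = 1, local_cn = 2)
  expect_equal(est$ccf, 0.8, tolerance = 1e-6)
  expect_equal(est$timing, "early")
})

test_that("cohort-level estimation joins purity and local copy number", {
  maf <- data.frame(sample_id = c("s1", "s1", "s2"),
                    chrom = c("chr1", "chr2", "chr1"),
                    pos = c(100L, 500L, 100L),
                    t_depth = c(100L, 100L, 100L),
                    t_alt_count = c(30L, 15L, 24L))
  prof <- data.frame(sample_id = c("s1", "s2"), purity = c(0.6, 0.8),
                     sex = "female")
  seg <- data.frame(sample_id = "s1", chrom = "chr2",
                    start = 1L, end = 1000L, integer_cn = 4L)
  out <- estimate_ccf_cohort(maf, prof, seg)
  expect_equal(out$cn_mutation, c(2, 4, 2))
  expect_equal(out$ccf[1], 1.0)
  # tetraploid locus: vaf 0.15 -> ccf = 0.15 * (2*0.4 + 0.6*4)/0.6 = 0.8
  expect_equal(out$ccf[2], 0.15 * (2 * 0.4 + 0.6 * 4) / 0.6, tolerance = 1e-3)
})

test_that("subclone clustering recovers planted mixtures and degenerate input", {
  expect_warning(m0 <- cluster_subclones(rep(1, 3)), "fewer than 5")
  expect_equal(m0$n_clusters, 1L)
  m1 <- cluster_subclones(rep(1, 30))
  expect_equal(m1$n_clusters, 1L)
  expect_equal(m1$means, 1)
  set.seed(9)
  ccf2 <- c(rep(1, 50), pmin(rnorm(50, 0.4, 0.03), 1))
  m2 <- cluster_subclones(ccf2)
  expect_equal(m2$n_clusters, 2L)
  expect_lt(abs(sort(m2$means)[1] - 0.4), 0.05)
  expect_lt(abs(sort(m2$means)[2] - 1.0), 0.05)
  expect_equal(sum(m2$counts), 100L)
})

test_that("undersized clusters are merged into their nearest neighbour", {
  set.seed(4)
  ccf <- c(rep(1, 40), pmax(rnorm(40, 0.3, 0.04), 0.01))
  m <- cluster_subclones(ccf, min_size = 45)
  expect_equal(m$n_clusters, 1L)
})

test_that("ITH metrics match their closed forms", {
  model2 <- list(assignment = rep(1:2, each = 5), means = c(1, 0.4),
                 counts = c(5L, 5L), n_clusters = 2L)
  # MATH on evenly spaced VAFs: 100 * 1.4826 * 0.1 / 0.3
  ith <- ith_metrics(ccf = rep(1, 10), vaf = rep(seq(.1, .5, .1), 2), model2)
  expect_equal(ith$math_score, 100 * 1.4826 * 0.1 / 0.3, tolerance = 1e-6)
  expect_equal(ith$plm, 0)
  expect_equal(ith$shannon, log(2), tolerance = 1e-9)

  model1 <- list(assignment = rep(1L, 4), means = 1, counts = 4L,
                 n_clusters = 1L)
  flat <- ith_metrics(rep(1, 4), rep(0.3, 4), model1)
  expect_equal(flat$math_score, 0)
  expect_equal(flat$shannon, 0)
  expect_error(ith_metrics(1, 0, model1), "median VAF")
})

test_that("pLM is the exact complement of the early fraction", {
  set.seed(2)
  ccf <- runif(200)
  model <- cluster_subclones(ccf)
  ith <- ith_metrics(ccf, runif(200, .05, .5), model)
  expect_equal(ith$plm + mean(ccf >= 0.8), 1)
  expect_lte(ith$shannon, log(model$n_clusters) + 1e-12)
})

test_that("Shannon index supports the mean-CCF weighting variant", {
  model <- list(assignment = rep(1:2, c(30, 10)), means = c(1, 0.25),
                counts = c(30L, 10L), n_clusters = 2L)
  ith_c <- ith_metrics(rep(1, 40), rep(0.3, 40), model)
  ith_m <- ith_metrics(rep(1, 40), rep(0.3, 40), model,
                       shannon_weights = "mean_ccf")
  p <- c(30, 10) / 40
  expect_equal(ith_c$shannon, -sum(p * log(p)))
  q <- c(1, 0.25) / 1.25
  expect_equal(ith_m$shannon, -sum(q * log(q)))
})

test_that("CCF recovery on simulated cohorts is accurate and near-unbiased", {
  b <- small_bundle()
  prof <- b$clinical[, c("sample_id", "purity", "sex")]
  est <- estimate_ccf_cohort(b$maf, prof, b$seg)
  tr <- b$truth$mutations
  key <- match(paste(est$sample_id, est$chrom, est$pos),
               paste(tr$sample_id, tr$chrom, tr$pos))
  expect_false(anyNA(key))
  rmse <- sqrt(mean((est$ccf - tr$true_ccf[key])^2))
  expect_lt(rmse, 0.12)
  # high depth shrinks the error (bias -> 0 as depth grows)
  deep <- est$t_depth >= 120
  expect_lt(mean(est$ccf[deep] - tr$true_ccf[key][deep]), 0.03)
})
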