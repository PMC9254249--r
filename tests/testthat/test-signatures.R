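test_that("the bundled catalog is a valid signature matrix", {
  cat96 <- sig_catalog_default()
  expect_equal(dim(cat96), c(10L, 96L))
  expect_equal(unname(rowSums(cat96)), rep(1, 10), tolerance = 1e-8)
  expect_true(all(cat96 >= 0))
  expect_equal(colnames(cat96), sbs_contexts())
  # deterministic and distinct rows
  expect_identical(cat96, sig_catalog_default())
  expect_lt(max(cor(t(cat96))[upper.tri(diag(10))]), 0.95)
})

test_that("catalog TSVs round-trip in both orientations", {
  cat96 <- sig_catalog_default()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat96, path)
  expect_equal(read_catalog(path), cat96, tolerance = 1e-12)
  # COSMIC layout: contexts in rows
  cosmic <- data.frame(Type = sbs_contexts(), t(cat96), check.names = FALSE)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(cosmic, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_catalog(path2), cat96, tolerance = 1e-12)
})

test_that("context counting conserves totals and validates labels", {
  ctx <- sbs_contexts()
  maf <- data.frame(sample_id = c(rep("s1", 10), rep("s2", 3)),
                    context96 = c(rep(ctx[1], 10), ctx[5:7]))
  m <- count_contexts(maf)
  expect_equal(m["s1", ctx[1]], 10L, ignore_attr = TRUE)
  expect_equal(sum(m), nrow(maf))
  m2 <- count_contexts(maf[0, ], samples = "empty")
  expect_equal(sum(m2), 0L)
  expect_error(count_contexts(data.frame(sample_id = "s", context96 = "bogus")),
               "unknown context")
})

test_that("deconvolution recovers pure and mixed profiles", {
  cat96 <- sig_catalog_default()
  # identity: a scaled catalog row comes back with weight 1, residual ~0
  d <- deconvolute(cat96["SBS22", ] * 500, cat96)
  expect_equal(unname(d$weights["SBS22"]), 1, tolerance = 1e-6)
  expect_lt(d$residual, 1e-12)
  # sampled two-signature mixture
  mix <- 0.7 * cat96["SBS22", ] + 0.3 * cat96["SBS5", ]
  counts <- with_seed_local(3, as.numeric(rmultinom(1, 10000, mix)))
  d2 <- deconvolute(counts, cat96)
  truth <- setNames(numeric(10), rownames(cat96))
  truth[c("SBS22", "SBS5")] <- c(0.7, 0.3)
  expect_lt(sum(abs(d2$weights - truth)), 0.05)
  expect_error(deconvolute(numeric(96), cat96), "empty")
})

test_that("exposures are invariant to profile scaling", {
  cat96 <- sig_catalog_default()
  counts <- with_seed_local(8, as.numeric(rmultinom(1, 2000,
    0.5 * cat96["SBS4", ] + 0.5 * cat96["SBS12", ])))
  d1 <- deconvolute(counts, cat96)
  d10 <- deconvolute(counts * 10, cat96)
  expect_equal(d1$weights, d10$weights, tolerance = 1e-10)
})

test_that("solver objective matches an NNLS-then-project oracle", {
  cat96 <- sig_catalog_default()
  A <- t(cat96)
  set.seed(11)
  for (i in 1:100) {
    w_true <- rgamma(10, 0.4); w_true <- w_true / sum(w_true)
    p <- as.numeric(rmultinom(1, 150, as.numeric(w_true %*% cat96)))
    d <- deconvolute(p, cat96, zero_threshold = 0)
    b <- p / sum(p)
    w_oracle <- pracma::lsqnonneg(A, b)$x
    if (sum(w_oracle) > 1) w_oracle <- w_oracle / sum(w_oracle)
    obj <- function(w) sum((A %*% w - b)^2)
    expect_lte(obj(d$weights), obj(w_oracle) + 1e-6)
    expect_equal(d$residual, obj(d$weights), tolerance = 1e-10)
  }
})

test_that("the 2%/20% retention rule keeps and drops exactly per rule", {
  cat96 <- sig_catalog_default()
  # construct a cohort whose fitted exposures are controlled:
  # 30 samples dominated by SBS5, one with a 25% SBS22 spike
  profiles <- t(vapply(1:30, function(i) {
    w <- c(SBS5 = 0.9, SBS1 = 0.1)
    if (i == 1) w <- c(SBS5 = 0.65, SBS1 = 0.1, SBS22 = 0.25)
    mix <- numeric(96)
    for (s in names(w)) mix <- mix + w[s] * cat96[s, ]
    with_seed_local(100 + i, as.numeric(rmultinom(1, 5000, mix)))
  }, numeric(96)))
  rownames(profiles) <- paste0("s", 1:30)
  ret <- iterative_retention(profiles, cat96)
  # SBS5/SBS1: mean > 2% -> kept; SBS22: mean ~0.8% but max ~25% -> kept
  expect_true(all(c("SBS5", "SBS1", "SBS22") %in% ret$kept))
  expect_lt(mean(ret$initial_exposures[, "SBS22"]), 0.02)
  # signatures never present (mean ~0, max << 20%) are dropped
  expect_false("SBS29" %in% ret$kept)
  expect_equal(sort(colnames(ret$exposures)), sort(ret$kept))
})

test_that("the retention rule is idempotent", {
  cat96 <- sig_catalog_default()
  set.seed(21)
  profiles <- t(vapply(1:10, function(i)
    as.numeric(rmultinom(1, 3000, 0.6 * cat96["SBS5", ] + 0.4 * cat96["SBS22", ])),
    numeric(96)))
  rownames(profiles) <- paste0("s", 1:10)
  r1 <- iterative_retention(profiles, cat96)
  r2 <- iterative_retention(profiles, r1$catalog)
  expect_equal(sort(r1$kept), sort(r2$kept))
  expect_equal(r1$exposures, r2$exposures, tolerance = 1e-10)
})

test_that("signature groups recover planted archetypes", {
  set.seed(31)
  e1 <- cbind(runif(25, .7, .9), runif(25, 0, .1), runif(25, 0, .1))
  e2 <- cbind(runif(25, 0, .1), runif(25, .7, .9), runif(25, 0, .1))
  expo <- rbind(e1, e2)
  expo <- expo / rowSums(expo)
  rownames(expo) <- paste0("s", 1:50)
  sg <- signature_groups(expo, k = 2)
  expect_equal(rand_index_adj(sg$groups, rep(1:2, each = 25)), 1)
  # k = n gives singleton groups
  sgn <- signature_groups(expo[1:5, ], k = 5)
  expect_equal(length(unique(sgn$groups)), 5L)
  expect_error(signature_groups(expo, k = 51), "exceeds")
})

test_that("early/late signature timing detects a planted enrichment", {
  cat96 <- sig_catalog_default()
  set.seed(77)
  n <- 24
  rows <- lapply(seq_len(n), function(i) {
    mk <- function(w22, m) {
      mix <- w22 * cat96["SBS22", ] + (1 - w22) * cat96["SBS5", ]
      ctx <- sample(sbs_contexts(), m, TRUE, prob = mix)
      ctx
    }
    data.frame(sample_id = sprintf("s%02d", i),
               context96 = c(mk(0.1, 60), mk(0.4, 60)),
               ccf = rep(c(1, 0.4), each = 60),
               stringsAsFactors = FALSE)
  })
  maf_ccf <- do.call(rbind, rows)
  res <- timing_of_signatures(maf_ccf, cat96)
  tt <- res$tests
  expect_true(tt$q[tt$signature == "SBS22"] < 0.1)
  expect_gt(tt$delta[tt$signature == "SBS22"], 0)
  # samples below the per-side minimum are excluded
  expect_error(timing_of_signatures(maf_ccf[1:30, ], cat96, min_side = 40),
               "no sample")
  # a single eligible sample yields exposures but no test
  one <- maf_ccf[maf_ccf$sample_id == "s01", ]
  expect_warning(r1 <- timing_of_signatures(one, cat96), "paired test skipped")
  expect_null(r1$tests)
})
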