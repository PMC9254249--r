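# constructed survival table with a planted binary risk feature + noise
planted_survival <- function(seed, n = 150, hr = 2.5, n_noise = 9,
                             cohort = "A") {
  set.seed(seed)
  x <- data.frame(strong = rbinom(n, 1, 0.4))
  for (j in seq_len(n_noise)) x[[paste0("noise", j)]] <- rnorm(n)
  lp <- log(hr) * x$strong
  t_ev <- rexp(n, 0.02 * exp(lp))
  cens <- runif(n, 0, 165)
  tab <- cbind(data.frame(sample_id = paste0("p", seq_len(n)),
                          os_time = pmin(t_ev, cens),
                          os_event = as.integer(t_ev <= cens),
                          cohort = cohort, stringsAsFactors = FALSE), x)
  attr(tab, "categories") <- setNames(rep("molecular", ncol(x)), names(x))
  tab
}

test_that("concordance index matches trivial orderings and handles errors", {
  tm <- c(5, 4, 3, 2, 1)
  ev <- rep(1, 5)
  expect_equal(concordance_index(risk = 1:5, tm, ev), 1)
  expect_equal(concordance_index(risk = 5:1, tm, ev), 0)
  expect_equal(concordance_index(rep(1, 5), tm, ev), 0.5)
  expect_error(concordance_index(1:3, c(1, 2, 3), c(0, 0, 0)),
               "no comparable")
})

test_that("a censored worked example equals the pair-enumeration oracle", {
  risk <- c(2.1, 0.5, 3.3, 1.0, 2.9)
  tm <- c(12, 30, 7, 30, 15)
  ev <- c(1, 0, 1, 1, 0)
  expect_equal(concordance_index(risk, tm, ev), cindex_oracle(risk, tm, ev))
  # by hand: 7 comparable pairs (earlier time has the event, unequal times);
  # all concordant except (1,5) where risk 2.1 < 2.9 despite t 12 < 15
  expect_equal(cindex_oracle(risk, tm, ev), 6 / 7)
  # independent cross-check against the survival package on tie-free times
  # (with tied times its Harrell variant also compares censored-vs-event
  # pairs at the same time, which the strict definition here excludes)
  set.seed(14)
  r2 <- rnorm(12); t2 <- sample(1:100, 12); e2 <- rbinom(12, 1, 0.7)
  sv <- survival::concordance(survival::Surv(t2, e2) ~ r2, reverse = TRUE)
  expect_equal(concordance_index(r2, t2, e2), unname(sv$concordance))
})

test_that("concordance equals the brute-force oracle on random small data", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    risk <- sample(1:5, n, TRUE)          # ties in risk
    tm <- sample(1:10, n, TRUE)           # ties in time
    ev <- rbinom(n, 1, 0.7)
    if (sum(outer(tm, tm, "<") & matrix(ev == 1, n, n)) == 0) next
    expect_equal(concordance_index(risk, tm, ev), cindex_oracle(risk, tm, ev))
  }
})

test_that("feature-table assembly applies the three inclusion rules", {
  n <- 60
  ids <- paste0("s", seq_len(n))
  clinical <- data.frame(sample_id = ids, cohort = rep(c("A", "B"), each = 30),
                         os_time = runif(n, 1, 100),
                         os_event = rbinom(n, 1, 0.7),
                         age = rnorm(n, 60), sex = sample(c("m", "f"), n, TRUE))
  set.seed(5)
  exposures <- cbind(SBS_low = rep(0.04, n), SBS_high = runif(n, 0.2, 0.5))
  rownames(exposures) <- ids
  cnv <- cbind(freq_arm = c(rep(1L, 14), rep(0L, 16), rbinom(30, 1, 0.1)),
               rare_arm = rbinom(n, 1, 0.05))
  rownames(cnv) <- ids
  drivers <- cbind(hot = c(rep(1L, 15), rep(0L, n - 15)),
                   cold = c(rep(1L, 14), rep(0L, n - 14)))
  rownames(drivers) <- ids
  ith <- data.frame(sample_id = ids, plm = runif(n), math_score = runif(n, 10, 60),
                    shannon = runif(n))
  molecular <- data.frame(sample_id = ids, purity = runif(n, .5, .9),
                          tmb = rpois(n, 60))
  tab <- build_feature_table(clinical, c("age", "sex"), molecular, exposures,
                             cnv, drivers, ith)
  cats <- attr(tab, "categories")
  expect_false("SBS_low" %in% names(cats))    # mean 4% < 5%
  expect_true("SBS_high" %in% names(cats))
  expect_true("freq_arm" %in% names(cats))    # 14/30 = 47% in cohort A
  expect_false("rare_arm" %in% names(cats))
  expect_true("hot" %in% names(cats))         # 15 mutations
  expect_false("cold" %in% names(cats))       # 14 mutations
  expect_equal(unname(cats[c("age", "plm", "hot", "SBS_high")]),
               c("clinical", "ith", "driver", "molecular"))
})

test_that("missing values are imputed per cohort and constants dropped", {
  n <- 40
  ids <- paste0("s", seq_len(n))
  clinical <- data.frame(sample_id = ids, cohort = rep(c("A", "B"), each = 20),
                         os_time = runif(n, 1, 100), os_event = 1)
  molecular <- data.frame(sample_id = ids,
                          gappy = c(NA, rnorm(19, 10), NA, rnorm(19, 20)),
                          holey = c(rep(NA, 15), rnorm(25)),
                          flat = 1)
  empty_m <- matrix(numeric(0), n, 0, dimnames = list(ids, NULL))
  ith <- data.frame(sample_id = ids, plm = runif(n),
                    math_score = runif(n, 10, 50), shannon = runif(n))
  expect_warning(
    tab <- build_feature_table(clinical, character(0), molecular,
                               empty_m, empty_m, empty_m, ith),
    "dropping")
  expect_false(anyNA(tab$gappy))
  # per-cohort median imputation
  expect_equal(tab$gappy[1], median(tab$gappy[2:20]))
  expect_false("holey" %in% names(attr(tab, "categories")))  # 37% missing
  expect_false("flat" %in% names(attr(tab, "categories")))   # constant
})

test_that("repeated selection keeps the planted feature and rejects noise", {
  tab <- planted_survival(11)
  sel <- select_features(tab, n_repeats = 20, threshold = 10,
                         num_trees = 300, seed = 3)
  expect_gte(sel$times_selected[sel$feature == "strong"], 18)
  expect_true(sel$selected[sel$feature == "strong"])
  expect_lte(sum(sel$selected[sel$feature != "strong"]), 1)
  # determinism and threshold monotonicity
  sel2 <- select_features(tab, n_repeats = 20, threshold = 10,
                          num_trees = 300, seed = 3)
  expect_identical(sel, sel2)
  stricter <- select_features(tab, n_repeats = 20, threshold = 18,
                              num_trees = 300, seed = 3)
  expect_true(all(stricter$selected <= sel$selected))
  expect_identical(stricter$times_selected, sel$times_selected)
})

test_that("per-cohort selection returns the union list", {
  tab <- rbind(planted_survival(21, n = 80, cohort = "A"),
               planted_survival(22, n = 80, cohort = "B"))
  attr(tab, "categories") <- setNames(rep("molecular", 10),
                                      grep("strong|noise", names(tab), value = TRUE))
  res <- select_features_by_cohort(tab, n_repeats = 10, threshold = 6,
                                   num_trees = 200, seed = 2)
  expect_named(res$per_cohort, c("A", "B", "combined"))
  expect_true("strong" %in% res$union)
})

test_that("importance ranking puts the planted feature first", {
  tab <- planted_survival(31)
  imp <- importance_ranking(tab, n_repeats = 10, num_trees = 300, seed = 4)
  expect_equal(imp$feature[1], "strong")
  expect_lt(imp$mean_rank[imp$feature == "strong"],
            min(imp$mean_rank[imp$feature != "strong"]))
  # single feature trivially ranks 1
  one <- planted_survival(32, n_noise = 0)
  imp1 <- importance_ranking(one, n_repeats = 3, num_trees = 100, seed = 1)
  expect_equal(imp1$mean_rank, 1)
})

test_that("evaluation separates informative from clinical-only categories", {
  # continuous prognostic score (unit log-hazard) among noise features
  set.seed(43)
  n <- 150
  x <- data.frame(risk_score = rnorm(n))
  for (j in 1:9) x[[paste0("noise", j)]] <- rnorm(n)
  t_ev <- rexp(n, 0.02 * exp(x$risk_score))
  cens <- runif(n, 0, 165)
  tab <- cbind(data.frame(sample_id = paste0("p", 1:n),
                          os_time = pmin(t_ev, cens),
                          os_event = as.integer(t_ev <= cens), cohort = "A"),
               x)
  cats <- setNames(rep("molecular", 10), names(x))
  cats["noise1"] <- "clinical"   # a noise feature stands in for clinical-only
  attr(tab, "categories") <- cats
  ev <- tune_and_evaluate(tab, categories = c("all", "clinical"),
                          cohorts = "A", n_splits = 25, num_trees = 300,
                          seed = 6)
  m <- with(ev$summary, setNames(cindex, category))
  expect_gt(m["all"], m["clinical"] + 0.05)
  expect_true(all(ev$cindex$cindex >= 0 & ev$cindex$cindex <= 1, na.rm = TRUE))
  expect_error(tune_and_evaluate(tab, categories = "driver"), "no features")
})

test_that("univariate Cox models recover hazard directions and drop degenerates", {
  set.seed(51)
  n <- 200
  protective <- rnorm(n)
  harmful <- rbinom(n, 1, 0.5)
  lp <- -0.8 * protective + 0.9 * harmful
  t_ev <- rexp(n, 0.02 * exp(lp))
  cens <- runif(n, 0, 165)
  tab <- data.frame(sample_id = paste0("p", 1:n),
                    os_time = pmin(t_ev, cens),
                    os_event = as.integer(t_ev <= cens), cohort = "A",
                    protective = protective, harmful = harmful,
                    allsame = 1L,
                    correlated = protective + rnorm(n, 0, 0.2))
  attr(tab, "categories") <- setNames(rep("molecular", 4),
                                      c("protective", "harmful", "allsame",
                                        "correlated"))
  expect_warning(net <- univariate_cox_network(tab), "degenerate")
  nodes <- net$nodes
  expect_lt(nodes$hr[nodes$feature == "protective"], 1)
  expect_equal(nodes$shape[nodes$feature == "protective"], "diamond")
  expect_gt(nodes$hr[nodes$feature == "harmful"], 1)
  expect_equal(nodes$shape[nodes$feature == "harmful"], "circle")
  edge <- net$edges[net$edges$feature_a == "protective" &
                    net$edges$feature_b == "correlated", ]
  expect_equal(nrow(edge), 1L)
  expect_gt(edge$correlation, 0.9)
})
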