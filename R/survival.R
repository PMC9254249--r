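#' Harrell's concordance index
#'
#' Among comparable pairs (the patient with the shorter time has an event),
#' the fraction where the higher risk score belongs to the shorter survival
#' time; risk ties count 0.5. Pairs with equal times where both have events
#' are comparable in neither direction and are skipped, following Harrell's
#' original definition.
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param time survival/censoring times.
#' @param event event indicator (1 = event, 0 = censored).
#' @return Concordance in \[0, 1\].
#' @export
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  conc <- 0; comp <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # orient so a has the shorter time; comparable iff a had the event
      if (time[i] == time[j]) next
      a <- if (time[i] < time[j]) i else j
      b <- if (time[i] < time[j]) j else i
      if (event[a] != 1) next
      comp <- comp + 1
      if (risk[a] > risk[b]) conc <- conc + 1
      else if (risk[a] == risk[b]) conc <- conc + 0.5
    }
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# random-survival-forest backend (ranger); risk = cumulative hazard mass
rsf_fit <- function(x, time, event, num_trees = 1500, min_node = 10,
                    mtry = 3, seed = 1, importance = "permutation") {
  df <- data.frame(x, check.names = FALSE)
  df$..time <- time
  df$..event <- event
  ranger::ranger(
    data = df, dependent.variable.name = "..time",
    status.variable.name = "..event",
    num.trees = num_trees, min.node.size = min_node,
    mtry = min(mtry, ncol(x)), importance = importance, seed = seed,
    respect.unordered.factors = "order", num.threads = 1)
}

rsf_risk <- function(fit, x) {
  pr <- predict(fit, data = data.frame(x, check.names = FALSE),
                num.threads = 1)
  rowSums(pr$chf)
}

#' Assemble the per-patient feature table
#'
#' Joins the pipeline outputs into the feature matrix used by the survival
#' harness, applying the inclusion rules: signature exposures with a cohort
#' mean of at least `sig_mean_min` (5%); copy-number events with frequency at
#' least `cnv_freq_min` (40%) in either cohort; driver genes with at least
#' `driver_min_mut` (15) mutated patients overall. Features missing in more
#' than `max_missing` of patients are dropped; remaining missing values are
#' median- (numeric) or mode- (categorical) imputed per cohort. Constant
#' features are dropped with a warning.
#'
#' @param clinical data.frame with `sample_id`, `os_time`, `os_event`,
#'   `cohort` and the clinical features.
#' @param clinical_features names of clinical columns to include.
#' @param molecular data.frame of per-sample molecular features (purity,
#'   ploidy, subtype, TMB, SCNA score, immune scores, ...), keyed by
#'   `sample_id`.
#' @param exposures samples x signatures exposure matrix (candidate
#'   signature features).
#' @param cnv_events samples x arms 0/1 matrix (candidate CNV features).
#' @param drivers samples x genes 0/1 matrix (candidate driver features).
#' @param ith data.frame with `sample_id`, `plm`, `math_score`, `shannon`.
#' @param sig_mean_min,cnv_freq_min,driver_min_mut inclusion thresholds.
#' @param max_missing maximum missing fraction per feature (default 0.2).
#' @return data.frame (one row per patient, `sample_id`, `os_time`,
#'   `os_event`, `cohort`, then features) with attribute `categories`, a
#'   named character vector mapping feature to
#'   clinical/molecular/driver/ith.
#' @export
build_feature_table <- function(clinical, clinical_features, molecular,
                                exposures, cnv_events, drivers, ith,
                                sig_mean_min = 0.05, cnv_freq_min = 0.40,
                                driver_min_mut = 15, max_missing = 0.2) {
  stop_if_missing_cols(clinical, c("sample_id", "os_time", "os_event", "cohort"),
                       "clinical table")
  ids <- clinical$sample_id
  cohort <- clinical$cohort

  sig_keep <- colnames(exposures)[colMeans(exposures, na.rm = TRUE) >= sig_mean_min]
  cnv_keep <- colnames(cnv_events)[vapply(colnames(cnv_events), function(a) {
    f <- tapply(cnv_events[ids, a], cohort, mean, na.rm = TRUE)
    any(f >= cnv_freq_min)
  }, logical(1))]
  drv_keep <- colnames(drivers)[colSums(drivers, na.rm = TRUE) >= driver_min_mut]

  tab <- data.frame(sample_id = ids, os_time = clinical$os_time,
                    os_event = clinical$os_event, cohort = cohort,
                    clinical[, clinical_features, drop = FALSE],
                    stringsAsFactors = FALSE)
  categories <- setNames(rep("clinical", length(clinical_features)),
                         clinical_features)
  add_block <- function(block, cat) {
    for (nm in colnames(block)) {
      tab[[nm]] <<- block[match(ids, rownames(block)), nm]
      categories[nm] <<- cat
    }
  }
  mol <- molecular[match(ids, molecular$sample_id),
                   setdiff(names(molecular), "sample_id"), drop = FALSE]
  rownames(mol) <- ids
  add_block(mol, "molecular")   # data.frame block: preserves column types
  add_block(exposures[, sig_keep, drop = FALSE], "molecular")
  add_block(cnv_events[, cnv_keep, drop = FALSE], "molecular")
  add_block(drivers[, drv_keep, drop = FALSE], "driver")
  ith_m <- as.matrix(ith[match(ids, ith$sample_id),
                         c("plm", "math_score", "shannon")])
  rownames(ith_m) <- ids
  add_block(ith_m, "ith")

  feats <- names(categories)
  # missingness rule, then per-cohort median/mode imputation
  for (nm in feats) {
    miss <- mean(is.na(tab[[nm]]))
    if (miss > max_missing) {
      tab[[nm]] <- NULL; categories <- categories[names(categories) != nm]
      warning("dropping feature '", nm, "' (", round(100 * miss), "% missing)")
    } else if (miss > 0) {
      for (co in unique(cohort)) {
        idx <- cohort == co & is.na(tab[[nm]])
        src <- tab[[nm]][cohort == co & !is.na(tab[[nm]])]
        fill <- if (is.numeric(tab[[nm]])) median(src)
                else names(sort(table(src), decreasing = TRUE))[1]
        tab[[nm]][idx] <- fill
      }
    }
  }
  for (nm in names(categories)) {
    if (length(unique(tab[[nm]])) < 2) {
      tab[[nm]] <- NULL; categories <- categories[names(categories) != nm]
      warning("dropping constant feature '", nm, "'")
    }
  }
  attr(tab, "categories") <- categories
  tab
}

feature_matrix <- function(table, features) {
  x <- table[, features, drop = FALSE]
  for (nm in names(x)) if (is.character(x[[nm]])) x[[nm]] <- factor(x[[nm]])
  x
}

#' Repeated random-forest survival feature selection
#'
#' Runs `n_repeats` seeded rounds; each round fits a random survival forest
#' on a random `subsample` fraction of patients, augmented with `n_shadow`
#' shadow features (permuted copies of randomly chosen real features), and
#' selects the features whose permutation importance exceeds the largest
#' shadow importance (and zero). Features selected in at least `threshold`
#' rounds are kept.
#'
#' @param table feature table from [build_feature_table()] (or any
#'   data.frame with `os_time`, `os_event` and feature columns).
#' @param features feature names to consider (default: all categorized
#'   features).
#' @param n_repeats,subsample,threshold the repeated-selection protocol
#'   (defaults 50 rounds, 75% subsamples, keep at >= 25).
#' @param n_shadow number of injected shadow features (default 5).
#' @param seed master seed.
#' @param num_trees trees per forest (default 1500).
#' @param min_node,mtry forest hyperparameters (defaults 10 and 3).
#' @return data.frame: `feature`, `times_selected`, `selected`.
#' @export
select_features <- function(table, features = names(attr(table, "categories")),
                            n_repeats = 50, subsample = 0.75, threshold = 25,
                            n_shadow = 5, seed = 1, num_trees = 1500,
                            min_node = 10, mtry = 3) {
  x <- feature_matrix(table, features)
  n <- nrow(x)
  seeds <- derive_seeds(seed, n_repeats)
  counts <- setNames(integer(length(features)), features)
  for (r in seq_len(n_repeats)) {
    idx <- with_seed(seeds[r], sample.int(n, round(subsample * n)))
    if (sum(table$os_event[idx]) < 10)
      stop("subsample contains fewer than 10 events")
    xr <- x[idx, , drop = FALSE]
    shadow_src <- with_seed(seeds[r] + 1L,
                            sample(features, n_shadow, replace = n_shadow > length(features)))
    for (s in seq_len(n_shadow)) {
      xr[[paste0("..shadow", s)]] <-
        with_seed(seeds[r] + 1L + s, sample(xr[[shadow_src[s]]]))
    }
    fit <- rsf_fit(xr, table$os_time[idx], table$os_event[idx],
                   num_trees = num_trees, min_node = min_node, mtry = mtry,
                   seed = seeds[r])
    vimp <- fit$variable.importance
    cut <- max(c(vimp[grep("^\\.\\.shadow", names(vimp))], 0))
    sel <- names(vimp)[vimp > cut]
    sel <- intersect(sel, features)
    counts[sel] <- counts[sel] + 1L
  }
  data.frame(feature = features, times_selected = unname(counts),
             selected = unname(counts) >= threshold,
             stringsAsFactors = FALSE)
}

#' Per-cohort feature selection with union list
#'
#' Applies [select_features()] within each cohort (and optionally the
#' combined cohort) and returns the union of the selected features.
#'
#' @inheritParams select_features
#' @param include_combined also run on the pooled cohort (default TRUE).
#' @param ... passed to [select_features()].
#' @return List: `per_cohort` (named list of selection tables), `union`
#'   (character vector of features selected in any run set).
#' @export
select_features_by_cohort <- function(table, include_combined = TRUE,
                                      seed = 1, ...) {
  cohorts <- unique(table$cohort)
  sets <- list()
  for (i in seq_along(cohorts)) {
    sets[[cohorts[i]]] <- select_features(table[table$cohort == cohorts[i], ],
                                          features = names(attr(table, "categories")),
                                          seed = seed + i, ...)
  }
  if (include_combined)
    sets[["combined"]] <- select_features(table, seed = seed, ...)
  union_list <- unique(unlist(lapply(sets, function(s) s$feature[s$selected])))
  list(per_cohort = sets, union = union_list)
}

random_search_tune <- function(x, time, event, n_search = 100, seed = 1,
                               num_trees = 1500) {
  if (n_search < 1)
    return(list(num_trees = num_trees, min_node = 10, mtry = 3))
  n <- nrow(x)
  folds <- with_seed(seed, sample(rep(1:5, length.out = n)))
  grid <- with_seed(seed + 1L, data.frame(
    min_node = sample(c(3, 5, 10, 15, 20), n_search, replace = TRUE),
    mtry = sample(seq_len(max(3, min(10, ncol(x)))), n_search, replace = TRUE)))
  grid <- unique(grid)
  best <- list(num_trees = num_trees, min_node = 10, mtry = 3)
  best_c <- -Inf
  for (g in seq_len(nrow(grid))) {
    cs <- numeric(5)
    for (f in 1:5) {
      tr <- folds != f
      fit <- rsf_fit(x[tr, , drop = FALSE], time[tr], event[tr],
                     num_trees = num_trees, min_node = grid$min_node[g],
                     mtry = grid$mtry[g], seed = seed + g, importance = "none")
      cs[f] <- tryCatch(
        concordance_index(rsf_risk(fit, x[!tr, , drop = FALSE]),
                          time[!tr], event[!tr]),
        error = function(e) NA_real_)
    }
    mc <- mean(cs, na.rm = TRUE)
    if (!is.na(mc) && mc > best_c) {
      best_c <- mc
      best <- list(num_trees = num_trees, min_node = grid$min_node[g],
                   mtry = grid$mtry[g])
    }
  }
  best
}

#' Evaluate survival models across cohorts and feature categories
#'
#' Optionally tunes forest hyperparameters per cohort by seeded random search
#' with 5-fold cross-validation (starting from the defaults: 1500 trees,
#' node size 10, mtry 3), then, for every cohort and feature category, runs
#' `n_splits` seeded 75/25 train/test splits and records the test-set
#' concordance index. Cohorts are compared per category with a two-sided
#' Wilcoxon rank-sum test against the reference (first) cohort.
#'
#' @param table feature table from [build_feature_table()].
#' @param categories subset of c("all", "clinical", "molecular", "driver",
#'   "ith").
#' @param cohorts cohort labels to evaluate (default: each cohort plus
#'   "combined").
#' @param n_splits number of train/test splits (default 50).
#' @param train_frac training fraction (default 0.75).
#' @param n_search random-search iterations for tuning (default 0 = use the
#'   default hyperparameters).
#' @param seed master seed.
#' @param num_trees trees per forest.
#' @return List: `cindex` (long data.frame cohort x category x split),
#'   `summary` (means), `comparisons` (Wilcoxon vs reference cohort),
#'   `tuned` (hyperparameters per cohort).
#' @export
tune_and_evaluate <- function(table, categories = c("all", "clinical",
                                                    "molecular", "driver", "ith"),
                              cohorts = NULL, n_splits = 50, train_frac = 0.75,
                              n_search = 0, seed = 1, num_trees = 1500) {
  cat_map <- attr(table, "categories")
  feats_of <- function(cat) {
    if (cat == "all") names(cat_map) else names(cat_map)[cat_map == cat]
  }
  for (cat in categories)
    if (length(feats_of(cat)) == 0) stop("category '", cat, "' has no features")
  cohorts <- cohorts %||% c(unique(table$cohort), "combined")
  rows <- list(); tuned <- list()
  for (co in cohorts) {
    sub <- if (co == "combined") table else table[table$cohort == co, ]
    x_all <- feature_matrix(sub, feats_of("all"))
    tuned[[co]] <- random_search_tune(x_all, sub$os_time, sub$os_event,
                                      n_search = n_search, seed = seed,
                                      num_trees = num_trees)
    seeds <- derive_seeds(seed + match(co, cohorts), n_splits)
    for (cat in categories) {
      x <- feature_matrix(sub, feats_of(cat))
      for (s in seq_len(n_splits)) {
        tr <- with_seed(seeds[s],
                        sample.int(nrow(x), round(train_frac * nrow(x))))
        fit <- rsf_fit(x[tr, , drop = FALSE], sub$os_time[tr], sub$os_event[tr],
                       num_trees = tuned[[co]]$num_trees,
                       min_node = tuned[[co]]$min_node,
                       mtry = tuned[[co]]$mtry,
                       seed = seeds[s], importance = "none")
        ci <- tryCatch(
          concordance_index(rsf_risk(fit, x[-tr, , drop = FALSE]),
                            sub$os_time[-tr], sub$os_event[-tr]),
          error = function(e) NA_real_)
        rows[[length(rows) + 1]] <- data.frame(
          cohort = co, category = cat, split = s, cindex = ci,
          stringsAsFactors = FALSE)
      }
    }
  }
  cindex <- do.call(rbind, rows)
  summary <- aggregate(cindex ~ cohort + category, cindex, mean, na.rm = TRUE)
  ref <- cohorts[1]
  comparisons <- do.call(rbind, lapply(categories, function(cat) {
    do.call(rbind, lapply(setdiff(cohorts, ref), function(co) {
      a <- cindex$cindex[cindex$cohort == ref & cindex$category == cat]
      b <- cindex$cindex[cindex$cohort == co & cindex$category == cat]
      data.frame(category = cat, reference = ref, cohort = co,
                 delta = mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE),
                 p = suppressWarnings(wilcox.test(a, b)$p.value),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(cindex = cindex, summary = summary, comparisons = comparisons,
       tuned = tuned)
}

#' Variable-importance ranking across repeated forests
#'
#' Fits `n_repeats` seeded forests on the full data, ranks features by
#' permutation importance within each run (rank 1 = most important), and
#' reports the mean rank per feature.
#'
#' @inheritParams select_features
#' @return data.frame: `feature`, `mean_rank`, sorted ascending.
#' @export
importance_ranking <- function(table, features = names(attr(table, "categories")),
                               n_repeats = 50, seed = 1, num_trees = 1500,
                               min_node = 10, mtry = 3) {
  x <- feature_matrix(table, features)
  seeds <- derive_seeds(seed, n_repeats)
  ranks <- matrix(NA_real_, n_repeats, length(features),
                  dimnames = list(NULL, features))
  for (r in seq_len(n_repeats)) {
    fit <- rsf_fit(x, table$os_time, table$os_event, num_trees = num_trees,
                   min_node = min_node, mtry = mtry, seed = seeds[r])
    vimp <- fit$variable.importance[features]
    ranks[r, ] <- rank(-vimp, ties.method = "average")
  }
  out <- data.frame(feature = features, mean_rank = colMeans(ranks),
                    stringsAsFactors = FALSE)
  out[order(out$mean_rank), ]
}

#' Univariate Cox models and feature-correlation network
#'
#' Fits a univariate Cox proportional-hazards model per feature (multi-level
#' factors are expanded and the most significant level reported), computes
#' pairwise feature correlations (Spearman for numeric pairs, Pearson/phi
#' when a binary feature is involved), and returns node and edge tables for
#' the prognostic-feature network: edges where the correlation p-value is
#' below `p_threshold` with width -log10(p); node shape encodes the hazard-
#' ratio direction and node size the Cox significance.
#'
#' @param table feature table from [build_feature_table()].
#' @param features features to include (default: all categorized features).
#' @param p_threshold edge significance cutoff (default 0.05).
#' @return List: `nodes` (feature, hr, p, shape, size), `edges` (feature_a,
#'   feature_b, correlation, p, width).
#' @export
univariate_cox_network <- function(table, features = names(attr(table, "categories")),
                                   p_threshold = 0.05) {
  x <- feature_matrix(table, features)
  y <- survival::Surv(table$os_time, table$os_event)
  nodes <- list()
  for (nm in features) {
    v <- x[[nm]]
    if (length(unique(v)) < 2) {
      warning("dropping degenerate feature '", nm, "'"); next
    }
    fit <- tryCatch(survival::coxph(y ~ v, data = data.frame(v = v)),
                    error = function(e) NULL)
    if (is.null(fit)) { warning("Cox fit failed for '", nm, "'"); next }
    sm <- summary(fit)$coefficients
    best <- which.min(sm[, "Pr(>|z|)"])  # most significant level
    nodes[[nm]] <- data.frame(
      feature = nm, hr = exp(sm[best, "coef"]), p = sm[best, "Pr(>|z|)"],
      stringsAsFactors = FALSE)
  }
  nodes <- do.call(rbind, nodes)
  nodes$shape <- ifelse(nodes$hr < 1, "diamond", "circle")
  nodes$size <- -log10(pmax(nodes$p, 1e-16))
  num <- lapply(x[nodes$feature], function(v) {
    if (is.factor(v)) as.numeric(v) else as.numeric(v)
  })
  is_bin <- vapply(num, function(v) length(unique(v)) == 2, logical(1))
  prs <- combn(nodes$feature, 2)
  edges <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
    a <- prs[1, k]; b <- prs[2, k]
    method <- if (is_bin[a] || is_bin[b]) "pearson" else "spearman"
    ct <- suppressWarnings(cor.test(num[[a]], num[[b]], method = method))
    data.frame(feature_a = a, feature_b = b, correlation = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }))
  edges <- edges[!is.na(edges$p) & edges$p < p_threshold, , drop = FALSE]
  edges$width <- -log10(pmax(edges$p, 1e-16))
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
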