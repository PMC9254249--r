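#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment (wraps [stats::p.adjust()])
#' with validation of the input p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\]; NA/NaN rejected.
#' @return q-values in \[0, 1\].
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Cohort-level mutation filters and event matrix
#'
#' Excludes hypermutated samples (more than `max_coding` coding mutations),
#' builds the gene x sample binary mutation matrix from coding mutations,
#' and drops genes mutated in fewer than `min_freq` of the retained samples.
#'
#' @param maf MAF-like data.frame with `sample_id`, `gene`, `coding`.
#' @param clinical data.frame with `sample_id` (defines the sample universe;
#'   samples without mutations keep all-zero rows).
#' @param max_coding hypermutation cutoff (default 1000; "> 1000" excluded).
#' @param min_freq minimum mutated fraction per gene (default 0.01).
#' @return List: `maf` (filtered), `events` (samples x genes 0/1 matrix),
#'   `excluded` (hypermutated sample ids).
#' @export
apply_cohort_filters <- function(maf, clinical, max_coding = 1000,
                                 min_freq = 0.01) {
  stop_if_missing_cols(maf, c("sample_id", "gene", "coding"), "MAF")
  stop_if_missing_cols(clinical, "sample_id", "clinical table")
  coding <- maf[maf$coding == 1, , drop = FALSE]
  n_coding <- table(factor(coding$sample_id, levels = clinical$sample_id))
  excluded <- names(n_coding)[n_coding > max_coding]
  keep_samples <- setdiff(clinical$sample_id, excluded)
  if (length(keep_samples) == 0) stop("all samples excluded as hypermutated")
  maf <- maf[maf$sample_id %in% keep_samples, , drop = FALSE]
  coding <- coding[coding$sample_id %in% keep_samples, , drop = FALSE]
  genes <- sort(unique(coding$gene))
  events <- matrix(0L, nrow = length(keep_samples), ncol = length(genes),
                   dimnames = list(keep_samples, genes))
  if (nrow(coding) > 0) {
    tab <- table(factor(coding$sample_id, levels = keep_samples),
                 factor(coding$gene, levels = genes))
    events[] <- as.integer(tab > 0)
  }
  freq_ok <- colMeans(events) >= min_freq
  events <- events[, freq_ok, drop = FALSE]
  list(maf = maf, events = events, excluded = excluded)
}

fisher_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = 1, or = NA_real_))
  ft <- fisher.test(tab)
  or <- (a * d) / (b * c)   # sample odds ratio; 0/Inf kept symbolically
  list(p = min(ft$p.value, 1), or = or)   # guard floating-point p > 1
}

#' Pairwise mutual exclusivity / co-occurrence tests
#'
#' For every pair of binary events, a two-sided Fisher's exact test on the
#' 2 x 2 presence table; the direction is labelled from the sample odds
#' ratio (co-occurrence for OR > 1, mutual exclusivity for OR < 1), and
#' p-values are BH-adjusted over all pairs.
#'
#' @param events samples x events 0/1 matrix.
#' @param fdr significance cutoff on q (default 0.1).
#' @return data.frame: `event_a`, `event_b`, `odds_ratio`, `direction`,
#'   `p`, `q`, `significant`.
#' @export
fisher_pairwise <- function(events, fdr = 0.1) {
  if (ncol(events) < 2) stop("need at least 2 events")
  prs <- combn(colnames(events), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
    x <- events[, prs[1, k]]; y <- events[, prs[2, k]]
    ft <- fisher_2x2(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
    dir <- if (is.na(ft$or)) NA_character_
           else if (ft$or > 1) "co-occur" else if (ft$or < 1) "exclusive"
           else NA_character_
    data.frame(event_a = prs[1, k], event_b = prs[2, k],
               odds_ratio = ft$or, direction = dir, p = ft$p,
               stringsAsFactors = FALSE)
  }))
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < fdr
  out
}

#' Compare binary event frequencies between two cohorts
#'
#' Per event, a two-sided Fisher's exact test on the 2 x 2 table of event
#' presence versus cohort, BH-adjusted across events.
#'
#' @param events samples x events 0/1 matrix.
#' @param cohorts named vector/factor mapping sample id to cohort.
#' @param fdr significance cutoff (default 0.1).
#' @return data.frame per event with per-cohort frequencies, `odds_ratio`,
#'   `direction` ("enriched-<cohort>"), `p`, `q`, `significant`.
#' @export
compare_event_frequencies <- function(events, cohorts, fdr = 0.1) {
  co <- factor(cohorts[rownames(events)])
  if (nlevels(co) != 2) stop("exactly two cohorts are required")
  lv <- levels(co)
  out <- do.call(rbind, lapply(colnames(events), function(ev) {
    x <- events[, ev]
    a <- sum(x[co == lv[1]]); b <- sum(co == lv[1]) - a
    c <- sum(x[co == lv[2]]); d <- sum(co == lv[2]) - c
    ft <- fisher_2x2(a, b, c, d)
    f1 <- a / (a + b); f2 <- c / (c + d)
    dir <- if (f1 == f2) NA_character_
           else paste0("enriched-", lv[which.max(c(f1, f2))])
    data.frame(event = ev, freq_1 = f1, freq_2 = f2,
               odds_ratio = ft$or, direction = dir, p = ft$p,
               stringsAsFactors = FALSE)
  }))
  names(out)[2:3] <- paste0("freq_", lv)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < fdr
  out
}

#' Covariate-adjusted tumor mutation burden comparison
#'
#' Fits a linear model of log10(TMB + 1) on the cohort indicator plus the
#' supplied covariates, and reports the cohort coefficient with its 95%
#' confidence interval alongside the unadjusted two-sided Wilcoxon rank-sum
#' test. Collinear covariates (aliased coefficients) are reported with a
#' warning.
#'
#' @param tmb per-sample coding mutation counts.
#' @param cohort two-level factor.
#' @param covariates data.frame of covariates (e.g. viral status, sex, age,
#'   purity); may be NULL for the unadjusted model.
#' @return List: `coefficient` (named vector: estimate, ci_low, ci_high, p
#'   for the cohort term), `model` (the lm fit), `wilcoxon_p`, `aliased`.
#' @export
adjusted_tmb_comparison <- function(tmb, cohort, covariates = NULL) {
  stopifnot(all(tmb >= 0))
  cohort <- factor(cohort)
  if (nlevels(cohort) != 2) stop("cohort must have exactly two levels")
  df <- data.frame(y = log10(tmb + 1), cohort = cohort)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  fit <- lm(y ~ ., data = df)
  al <- is.na(coef(fit))
  if (any(al)) warning("collinear covariate(s): ",
                       paste(names(coef(fit))[al], collapse = ", "))
  term <- grep("^cohort", names(coef(fit)), value = TRUE)[1]
  ci <- suppressMessages(confint(fit))[term, ]
  sm <- summary(fit)$coefficients
  wp <- suppressWarnings(
    wilcox.test(tmb[cohort == levels(cohort)[2]],
                tmb[cohort == levels(cohort)[1]])$p.value)
  list(coefficient = c(estimate = unname(coef(fit)[term]),
                       ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                       p = unname(sm[term, 4])),
       model = fit, wilcoxon_p = wp, aliased = names(coef(fit))[al])
}
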