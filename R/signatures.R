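#' Tabulate SBS-96 context counts per sample
#'
#' @param maf data.frame with `sample_id` and `context96`.
#' @param samples optional character vector fixing the row set/order.
#' @return Integer matrix, samples x 96 contexts.
#' @export
count_contexts <- function(maf, samples = NULL) {
  ctx <- sbs_contexts()
  stop_if_missing_cols(maf, c("sample_id", "context96"), "mutation table")
  bad <- setdiff(unique(maf$context96), ctx)
  if (length(bad) > 0)
    stop("unknown context label(s): ", paste(head(bad, 3), collapse = ", "))
  samples <- samples %||% unique(maf$sample_id)
  M <- matrix(0L, nrow = length(samples), ncol = 96,
              dimnames = list(samples, ctx))
  if (nrow(maf) > 0) {
    tab <- table(factor(maf$sample_id, levels = samples),
                 factor(maf$context96, levels = ctx))
    M[] <- as.integer(tab)
  }
  M
}

# Euclidean projection of v onto the probability simplex scaled to total z
project_simplex <- function(v, z = 1) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u > (css - z) / seq_along(u)))
  theta <- (css[rho] - z) / rho
  pmax(v - theta, 0)
}

# minimize ||A w - b||^2 over {w >= 0, sum(w) <= 1}: NNLS, then projected
# gradient refinement when the sum constraint is active
solve_exposure <- function(A, b, max_iter = 2000, tol = 1e-14) {
  w <- pracma::lsqnonneg(A, b)$x
  if (sum(w) <= 1 + 1e-12) return(pmax(w, 0))
  w <- project_simplex(w, 1)
  L <- 2 * max(svd(A, nu = 0, nv = 0)$d)^2
  obj <- function(w) sum((A %*% w - b)^2)
  f_old <- obj(w)
  for (i in seq_len(max_iter)) {
    g <- as.numeric(2 * crossprod(A, A %*% w - b))
    w_new <- w - g / L
    w_new <- if (sum(pmax(w_new, 0)) > 1) project_simplex(w_new, 1) else pmax(w_new, 0)
    f_new <- obj(w_new)
    if (f_old - f_new < tol && max(abs(w_new - w)) < 1e-10) { w <- w_new; break }
    w <- w_new; f_old <- f_new
  }
  w
}

#' Deconvolute a 96-context profile into signature exposures
#'
#' Solves min ||normalize(profile) - t(catalog) w||^2 subject to w >= 0 and
#' sum(w) <= 1 (non-negative least squares with a simplex-projection
#' refinement). Weights below `zero_threshold` (default 0.06, the
#' deconstructSigs convention) are then zeroed and the remaining weights
#' rescaled to preserve the fitted total. The residual is the least-squares
#' objective at the constrained optimum, before zeroing.
#'
#' @param profile numeric 96-vector of context counts (or proportions).
#' @param catalog K x 96 signature matrix (rows sum to 1).
#' @param zero_threshold minimum retained weight; set 0 to disable.
#' @return List with `weights` (named, sums to <= 1) and `residual`.
#' @export
deconvolute <- function(profile, catalog, zero_threshold = 0.06) {
  stopifnot(length(profile) == ncol(catalog))
  tot <- sum(profile)
  if (tot <= 0) stop("cannot deconvolute an empty (zero-count) profile")
  b <- as.numeric(profile) / tot
  A <- t(catalog)
  w <- solve_exposure(A, b)
  residual <- sum((A %*% w - b)^2)
  if (zero_threshold > 0 && any(w > 0)) {
    s <- sum(w)
    w[w < zero_threshold] <- 0
    if (sum(w) > 0) w <- w * s / sum(w)
  }
  names(w) <- rownames(catalog)
  list(weights = w, residual = residual)
}

#' Fit exposures for a cohort of context profiles
#'
#' @param profiles samples x 96 count matrix (from [count_contexts()]).
#' @param catalog K x 96 signature matrix.
#' @param zero_threshold passed to [deconvolute()].
#' @return List: `exposures` (samples x K matrix) and `residuals`.
#' @export
fit_exposures <- function(profiles, catalog, zero_threshold = 0.06) {
  fits <- apply(profiles, 1, deconvolute, catalog = catalog,
                zero_threshold = zero_threshold)
  E <- do.call(rbind, lapply(fits, `[[`, "weights"))
  rownames(E) <- rownames(profiles)
  list(exposures = E, residuals = vapply(fits, `[[`, numeric(1), "residual"))
}

#' Iterative signature retention and refit
#'
#' Keeps signatures whose cohort mean exposure exceeds `mean_min` (2%) or
#' whose maximum exposure in any sample reaches `max_min` (20%), then refits
#' every sample against the reduced catalog exactly once.
#'
#' @param profiles samples x 96 count matrix.
#' @param catalog K x 96 signature matrix.
#' @param mean_min,max_min retention thresholds (defaults 0.02 and 0.20).
#' @param zero_threshold passed to [deconvolute()].
#' @return List: `catalog` (reduced), `exposures` (refit), `kept` (names),
#'   `initial_exposures`.
#' @export
iterative_retention <- function(profiles, catalog, mean_min = 0.02,
                                max_min = 0.20, zero_threshold = 0.06) {
  if (nrow(profiles) < 2) stop("retention rule needs at least 2 samples")
  init <- fit_exposures(profiles, catalog, zero_threshold)$exposures
  keep <- colMeans(init) > mean_min | apply(init, 2, max) >= max_min
  if (!any(keep)) stop("all signatures fell below the retention thresholds")
  reduced <- catalog[keep, , drop = FALSE]
  refit <- fit_exposures(profiles, reduced, zero_threshold)$exposures
  list(catalog = reduced, exposures = refit,
       kept = rownames(catalog)[keep], initial_exposures = init)
}

#' Cluster patients into signature groups
#'
#' Hierarchical clustering (Euclidean distance, Ward's "ward.D" linkage) of
#' the exposure vectors, cut at `k` groups labelled SG1..SGk.
#'
#' @param exposures samples x K exposure matrix.
#' @param k number of groups (default 5).
#' @return List: `groups` (named factor SG1..SGk) and `hclust`.
#' @export
signature_groups <- function(exposures, k = 5) {
  if (k > nrow(exposures)) stop("k exceeds the number of samples")
  hc <- hclust(dist(exposures), method = "ward.D")
  cl <- cutree(hc, k = k)
  groups <- factor(paste0("SG", cl), levels = paste0("SG", seq_len(k)))
  names(groups) <- rownames(exposures)
  list(groups = groups, hclust = hc)
}

#' Timing of mutational signatures (early vs late deconvolution)
#'
#' Splits each sample's mutations at CCF 0.8, deconvolutes the early and late
#' subsets separately (samples with fewer than `min_side` mutations on either
#' side are excluded), and tests each signature's early-vs-late exposure
#' change with a two-sided paired Wilcoxon signed-rank test, BH-adjusted.
#'
#' @param maf_ccf MAF-like data.frame with `sample_id`, `context96` and `ccf`
#'   columns (e.g. the `mutations` element of [clonality_pipeline()]).
#' @param catalog K x 96 signature matrix.
#' @param min_side minimum mutations per side (default 20).
#' @param zero_threshold passed to [deconvolute()].
#' @return List: `early`, `late` (exposure matrices over eligible samples)
#'   and `tests` (data.frame signature, delta, p, q) or NULL when fewer than
#'   two samples are eligible.
#' @export
timing_of_signatures <- function(maf_ccf, catalog, min_side = 20,
                                 zero_threshold = 0.06) {
  stop_if_missing_cols(maf_ccf, c("sample_id", "context96", "ccf"),
                       "CCF-annotated mutation table")
  early <- maf_ccf[maf_ccf$ccf >= 0.8, ]
  late <- maf_ccf[maf_ccf$ccf < 0.8, ]
  ids <- unique(maf_ccf$sample_id)
  n_early <- table(factor(early$sample_id, levels = ids))
  n_late <- table(factor(late$sample_id, levels = ids))
  eligible <- ids[n_early >= min_side & n_late >= min_side]
  if (length(eligible) == 0)
    stop("no sample has >= ", min_side, " early and late mutations")
  E <- fit_exposures(count_contexts(early[early$sample_id %in% eligible, ],
                                    samples = eligible),
                     catalog, zero_threshold)$exposures
  L <- fit_exposures(count_contexts(late[late$sample_id %in% eligible, ],
                                    samples = eligible),
                     catalog, zero_threshold)$exposures
  if (length(eligible) < 2) {
    warning("only one eligible sample; paired test skipped")
    return(list(early = E, late = L, tests = NULL))
  }
  tests <- do.call(rbind, lapply(colnames(E), function(sig) {
    d <- L[, sig] - E[, sig]
    p <- if (all(d == 0)) 1 else
      suppressWarnings(wilcox.test(E[, sig], L[, sig], paired = TRUE)$p.value)
    data.frame(signature = sig, delta = mean(d), p = p,
               stringsAsFactors = FALSE)
  }))
  tests$q <- bh_adjust(tests$p)
  list(early = E, late = L, tests = tests)
}
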