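#' Filter somatic mutation calls by read support
#'
#' Retains calls with total depth >= 10, at least 3 alternate reads and a
#' variant allele frequency of at least 0.05. Row order is preserved.
#'
#' @param maf MAF-like data.frame with at least `t_depth` and `t_alt_count`.
#' @param min_depth,min_alt,min_vaf thresholds (defaults 10, 3, 0.05).
#' @return The filtered data.frame.
#' @export
filter_mutations <- function(maf, min_depth = 10, min_alt = 3, min_vaf = 0.05) {
  stop_if_missing_cols(maf, c("t_depth", "t_alt_count"), "mutation table")
  if (any(maf$t_alt_count > maf$t_depth))
    stop("alt count exceeds depth")
  vaf <- ifelse(maf$t_depth > 0, maf$t_alt_count / maf$t_depth, 0)
  keep <- maf$t_depth >= min_depth & maf$t_alt_count >= min_alt & vaf >= min_vaf
  maf[keep, , drop = FALSE]
}

#' Expected variant allele frequency under the purity/copy-number model
#'
#' VAF = purity * CCF / (CN_normal * (1 - purity) + purity * CN_mutation),
#' clamped to \[0, 1\]. `cn_mutation` is the mutation-bearing local tumor copy
#' number (mutation multiplicity 1); `cn_normal` is 2 for autosomes and for
#' the female X, 1 for the male X.
#'
#' @param ccf cancer cell fraction in \[0, 1\].
#' @param purity tumor purity in (0, 1\].
#' @param cn_normal germline copy number (1 or 2).
#' @param cn_mutation local tumor copy number (>= 1).
#' @return Expected VAF, vectorized over inputs.
#' @export
expected_vaf <- function(ccf, purity, cn_normal = 2, cn_mutation = 2) {
  stopifnot(all(purity > 0), all(purity <= 1), all(cn_mutation >= 1))
  v <- purity * ccf / (cn_normal * (1 - purity) + purity * cn_mutation)
  pmin(pmax(v, 0), 1)
}

# binomial deviance of a candidate CCF for one mutation
ccf_deviance <- function(ccf, alt, depth, purity, cn_normal, cn_mutation) {
  p <- expected_vaf(ccf, purity, cn_normal, cn_mutation)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * dbinom(alt, depth, p, log = TRUE)
}

# germline copy number at a locus: 2 for autosomes and female X, 1 for male X
cn_normal_at <- function(chrom, sex) {
  is_x <- toupper(sub("^chr", "", chrom)) == "X"
  ifelse(is_x & tolower(sex) %in% c("male", "m"), 1L, 2L)
}

#' Estimate cancer cell fraction for one mutation
#'
#' Minimizes the binomial deviance -2 log Binom(alt | depth, expected VAF)
#' over CCF in \[0, 1\] (Brent's method, with both interval endpoints checked
#' explicitly). Timing is classified as "early" when CCF >= 0.8, "late"
#' otherwise. A mutation-multiplicity diagnostic
#' m = clamp(round(vaf/purity * (purity*CN_t + (1-purity)*CN_n)), 1, CN_t)
#' is reported but not used in the estimate.
#'
#' @param alt,depth alternate and total read counts.
#' @param purity tumor purity in (0, 1\].
#' @param local_cn local integer tumor copy number (>= 1).
#' @param chrom chromosome name (X triggers the sex-specific CN_normal rule).
#' @param sex "male" or "female"; only used for chromosome X.
#' @return A one-row data.frame: `ccf`, `cn_normal`, `cn_mutation`, `timing`,
#'   `deviance_at_optimum`, `multiplicity_hint`.
#' @export
estimate_ccf <- function(alt, depth, purity, local_cn,
                         chrom = "chr1", sex = "female") {
  stopifnot(depth > 0, alt <= depth, local_cn >= 1)
  cn_n <- cn_normal_at(chrom, sex)
  cn_m <- local_cn
  f <- function(ccf) ccf_deviance(ccf, alt, depth, purity, cn_n, cn_m)
  opt <- optimize(f, interval = c(0, 1), tol = 1e-8)
  vaf <- alt / depth
  # the analytic inverse of the VAF formula is the exact minimizer whenever
  # it falls inside [0, 1]; keep it and the boundaries as exact candidates
  mle <- min(max(vaf * (cn_n * (1 - purity) + purity * cn_m) / purity, 0), 1)
  cand <- c(mle, 0, 1, opt$minimum)
  dev <- vapply(cand, f, numeric(1))
  ccf <- cand[dev <= min(dev) + 1e-9][1]   # exact candidates take precedence
  mult <- round(vaf / purity * (purity * cn_m + (1 - purity) * cn_n))
  mult <- min(max(mult, 1), cn_m)
  data.frame(
    ccf = ccf,
    cn_normal = cn_n,
    cn_mutation = cn_m,
    timing = ifelse(ccf >= 0.8, "early", "late"),
    deviance_at_optimum = f(ccf),
    multiplicity_hint = mult,
    stringsAsFactors = FALSE)
}

# local integer tumor copy number of each mutation from the sample's segments
local_cn_lookup <- function(maf, seg, default_cn = 2L) {
  cn <- rep(default_cn, nrow(maf))
  if (is.null(seg) || nrow(seg) == 0) return(cn)
  for (i in seq_len(nrow(maf))) {
    hit <- seg$sample_id == maf$sample_id[i] & seg$chrom == maf$chrom[i] &
      seg$start <= maf$pos[i] & seg$end >= maf$pos[i]
    if (any(hit)) cn[i] <- seg$integer_cn[which(hit)[1]]
  }
  cn
}

#' Estimate CCFs for all mutations of one or more samples
#'
#' Applies [filter_mutations()], looks up the local copy number of each
#' mutation from the segment table, and runs [estimate_ccf()] per mutation.
#'
#' @param maf MAF-like data.frame (`sample_id`, `chrom`, `pos`, `t_depth`,
#'   `t_alt_count`, ...).
#' @param profiles data.frame with `sample_id`, `purity` and optionally `sex`.
#' @param seg segment table (`sample_id`, `chrom`, `start`, `end`,
#'   `integer_cn`) or NULL for an all-diploid assumption.
#' @return The filtered MAF with appended columns `ccf`, `timing`,
#'   `cn_mutation`, `cn_normal`, `deviance_at_optimum`, `multiplicity_hint`.
#' @export
estimate_ccf_cohort <- function(maf, profiles, seg = NULL) {
  stop_if_missing_cols(profiles, c("sample_id", "purity"), "sample profiles")
  maf <- filter_mutations(maf)
  if (nrow(maf) == 0) {
    maf$ccf <- numeric(0); maf$timing <- character(0)
    return(maf)
  }
  pr <- profiles[match(maf$sample_id, profiles$sample_id), ]
  if (anyNA(pr$purity)) stop("missing purity for some samples in the MAF")
  sex <- if ("sex" %in% names(pr)) pr$sex else rep("female", nrow(pr))
  cn <- local_cn_lookup(maf, seg)
  est <- lapply(seq_len(nrow(maf)), function(i)
    estimate_ccf(maf$t_alt_count[i], maf$t_depth[i], pr$purity[i],
                 max(cn[i], 1L), chrom = maf$chrom[i], sex = sex[i]))
  est <- do.call(rbind, est)
  cbind(maf, est)
}

# 1-D Gaussian mixture by EM with deterministic quantile initialization and a
# variance floor (clamped clonal CCFs form a point mass at 1.0)
em_gmm1d <- function(x, k, var_floor = 2.5e-3, max_iter = 300, tol = 1e-9) {
  n <- length(x)
  mu <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k, type = 7))
  sig2 <- rep(max(var(x) / k^2, var_floor), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * dnorm(x, mu[j], sqrt(sig2[j])), numeric(n))
    tot <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / pmax(nk, 1e-12)
    sig2 <- pmax(colSums(r * (x - rep(mu, each = n))^2) / pmax(nk, 1e-12),
                 var_floor)
    if (ll - ll_old < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(loglik = ll, mu = mu, sig2 = sig2, w = w,
       assignment = max.col(r), bic = -2 * ll + (3 * k - 1) * log(n))
}

#' Cluster per-mutation CCFs into subclones
#'
#' Fits a one-dimensional Gaussian mixture by EM for k = 1..`max_k` with
#' deterministic quantile initialization and a small variance floor (the
#' clonal cluster of clamped CCFs is a point mass at 1), selects k by BIC,
#' then merges clusters carrying fewer than `min_size` mutations into the
#' nearest remaining cluster. The procedure is fully deterministic.
#'
#' @param ccf numeric vector of CCF estimates.
#' @param max_k maximum number of clusters considered (default 5).
#' @param min_size minimum mutations per cluster (default 2).
#' @param var_floor lower bound on per-cluster variance (default 2.5e-3,
#'   i.e. sigma >= 0.05, matching CCF measurement noise at ~100-200x depth).
#' @return List with `assignment` (integer per mutation), `means`, `counts`
#'   and `n_clusters`.
#' @importFrom stats dnorm
#' @export
cluster_subclones <- function(ccf, max_k = 5, min_size = 2, var_floor = 2.5e-3) {
  n <- length(ccf)
  if (n < 5) {
    warning("fewer than 5 mutations; returning a single-cluster model")
    return(list(assignment = rep(1L, n), means = mean(ccf),
                counts = n, n_clusters = 1L))
  }
  if (sd(ccf) < 1e-8) {
    return(list(assignment = rep(1L, n), means = mean(ccf),
                counts = n, n_clusters = 1L))
  }
  fits <- lapply(seq_len(min(max_k, n - 1)), function(k)
    em_gmm1d(ccf, k, var_floor = var_floor))
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  cl <- fit$assignment
  means <- vapply(seq_len(max(cl)), function(j)
    if (any(cl == j)) mean(ccf[cl == j]) else NA_real_, numeric(1))
  # merge undersized clusters into the nearest-by-mean neighbour
  repeat {
    counts <- tabulate(cl, nbins = max(cl))
    small <- which(counts > 0 & counts < min_size)
    if (length(small) == 0 || sum(counts > 0) == 1) break
    s <- small[1]
    others <- setdiff(which(counts > 0), s)
    target <- others[which.min(abs(means[others] - means[s]))]
    cl[cl == s] <- target
    means[target] <- mean(ccf[cl == target])
    means[s] <- NA
  }
  keep <- sort(unique(cl))
  cl <- match(cl, keep)
  means <- as.numeric(tapply(ccf, cl, mean))
  counts <- as.integer(table(cl))
  list(assignment = cl, means = pmin(pmax(means, 0), 1),
       counts = counts, n_clusters = length(keep))
}

#' Intra-tumor heterogeneity metrics
#'
#' * `plm`: fraction of mutations with CCF < 0.8 (percentage of late
#'   mutations).
#' * `math_score`: 100 x 1.4826 x median absolute deviation of the VAFs
#'   divided by their median (the MATH score).
#' * `shannon`: -sum p_i log p_i over subclones. By default p_i is the
#'   fraction of mutations assigned to cluster i; `shannon_weights =
#'   "mean_ccf"` instead normalizes the cluster mean CCFs to proportions.
#'
#' @param ccf per-mutation CCF estimates.
#' @param vaf per-mutation variant allele frequencies.
#' @param model subclone model from [cluster_subclones()].
#' @param shannon_weights "counts" (default) or "mean_ccf".
#' @return List with `plm`, `math_score`, `shannon`.
#' @export
ith_metrics <- function(ccf, vaf, model, shannon_weights = c("counts", "mean_ccf")) {
  shannon_weights <- match.arg(shannon_weights)
  stopifnot(length(ccf) > 0, length(vaf) > 0)
  med <- median(vaf)
  if (med == 0) stop("median VAF is zero; MATH score undefined")
  plm <- mean(ccf < 0.8)
  math <- 100 * mad(vaf, constant = 1.4826) / med
  p <- if (shannon_weights == "counts") {
    model$counts / sum(model$counts)
  } else {
    model$means / sum(model$means)
  }
  p <- p[p > 0]
  shannon <- -sum(p * log(p))
  list(plm = plm, math_score = math, shannon = shannon)
}

#' Per-sample clonality and heterogeneity summary
#'
#' Runs CCF estimation, subclone clustering and ITH metrics for every sample
#' in a cohort MAF.
#'
#' @inheritParams estimate_ccf_cohort
#' @param min_mutations samples with fewer retained mutations are skipped.
#' @return List with `mutations` (per-mutation CCF table) and `samples`
#'   (per-sample data.frame: plm, math_score, shannon, n_clusters,
#'   n_mutations).
#' @export
clonality_pipeline <- function(maf, profiles, seg = NULL, min_mutations = 5) {
  mut <- estimate_ccf_cohort(maf, profiles, seg)
  ids <- unique(mut$sample_id)
  rows <- lapply(ids, function(id) {
    m <- mut[mut$sample_id == id, ]
    if (nrow(m) < min_mutations) return(NULL)
    model <- cluster_subclones(m$ccf)
    ith <- ith_metrics(m$ccf, m$t_alt_count / m$t_depth, model)
    data.frame(sample_id = id, plm = ith$plm, math_score = ith$math_score,
               shannon = ith$shannon, n_clusters = model$n_clusters,
               n_mutations = nrow(m), stringsAsFactors = FALSE)
  })
  list(mutations = mut, samples = do.call(rbind, rows))
}
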