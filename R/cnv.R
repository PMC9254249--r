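#' Genome instability index
#'
#' GII is the fraction of the covered genome whose integer copy number
#' differs from the sample's median ploidy, where the median ploidy is the
#' base-pair-length-weighted median of the segment copy numbers (half-mass
#' ties broken toward 2). A whole-genome-doubled sample with a uniform copy
#' number therefore has GII 0: instability is relative to the median.
#'
#' @param seg segment table for one or more samples (`sample_id`, `chrom`,
#'   `start`, `end`, `integer_cn`; 1-based inclusive coordinates).
#' @return data.frame with `sample_id`, `median_ploidy`, `gii`.
#' @export
genome_instability_index <- function(seg) {
  stop_if_missing_cols(seg, c("sample_id", "chrom", "start", "end", "integer_cn"),
                       "segment table")
  if (nrow(seg) == 0) stop("empty segment table")
  out <- lapply(split(seg, seg$sample_id), function(s) {
    len <- s$end - s$start + 1
    if (sum(len) <= 0) stop("segments cover zero base pairs")
    mp <- weighted_median(s$integer_cn, len, tie_to = 2)
    data.frame(sample_id = s$sample_id[1], median_ploidy = mp,
               gii = sum(len[s$integer_cn != mp]) / sum(len),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Arm-level copy-number calls
#'
#' For every sample and arm, computes the fraction of the arm's length whose
#' integer copy number deviates from the rounded median ploidy by at least
#' `dev_threshold` copies in each direction (uncovered base pairs count as
#' neutral). An arm is called "amp" ("del") when at least `frac_threshold` of
#' its length is gained (lost); otherwise "neutral".
#'
#' @param seg segment table (see [genome_instability_index()]).
#' @param arms arm table (default [default_arm_table()]).
#' @param dev_threshold minimum copy-number deviation (default 1 copy,
#'   i.e. 0.5 rounded up on the integer scale).
#' @param frac_threshold minimum fraction of arm length (default 0.5).
#' @return data.frame: `sample_id`, `arm`, `call`, `mean_dev` (bp-weighted
#'   mean deviation from rounded median ploidy), `mean_cn`, `frac_amp`,
#'   `frac_del`.
#' @export
arm_calls <- function(seg, arms = default_arm_table(),
                      dev_threshold = 1, frac_threshold = 0.5) {
  gii <- genome_instability_index(seg)
  n_arm <- nrow(arms)
  arm_len <- arms$end - arms$start + 1
  per_sample <- lapply(seq_len(nrow(gii)), function(si) {
    sid <- gii$sample_id[si]
    base <- round(gii$median_ploidy[si])
    s <- seg[seg$sample_id == sid, , drop = FALSE]
    # overlap length of every segment with every arm (segments x arms)
    same <- outer(s$chrom, arms$chrom, "==")
    ov <- pmax(outer(s$end, arms$end, pmin) - outer(s$start, arms$start, pmax) + 1,
               0) * same
    dev <- s$integer_cn - base
    cov <- colSums(ov)
    frac_amp <- colSums(ov * (dev >= dev_threshold)) / arm_len
    frac_del <- colSums(ov * (dev <= -dev_threshold)) / arm_len
    uncovered <- cov == 0
    if (any(uncovered))
      warning("arm(s) ", paste(arms$arm[uncovered], collapse = ", "),
              " have no overlapping segments in ", sid, "; called neutral")
    call <- ifelse(frac_amp >= frac_threshold, "amp",
                   ifelse(frac_del >= frac_threshold, "del", "neutral"))
    data.frame(
      sample_id = sid, arm = arms$arm, call = call,
      mean_dev = colSums(ov * dev) / arm_len,
      mean_cn = ifelse(uncovered, NA_real_,
                       colSums(ov * s$integer_cn) / pmax(cov, 1)),
      frac_amp = frac_amp, frac_del = frac_del,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_sample)
  rownames(out) <- NULL
  out
}

#' Arm-level SCNA score
#'
#' Counts the altered (non-neutral) arms per sample, split by sign. The
#' optional magnitude-weighted variant sums |mean deviation| over altered
#' arms instead of counting them.
#'
#' @param calls output of [arm_calls()].
#' @param weight "count" (default) or "magnitude".
#' @return data.frame: `sample_id`, `n_amp`, `n_del`, `arm_scna_score`.
#' @export
arm_scna_score <- function(calls, weight = c("count", "magnitude")) {
  weight <- match.arg(weight)
  out <- lapply(split(calls, calls$sample_id), function(x) {
    amp <- x$call == "amp"; del <- x$call == "del"
    score <- if (weight == "count") sum(amp) + sum(del)
             else sum(abs(x$mean_dev[amp | del]))
    data.frame(sample_id = x$sample_id[1], n_amp = sum(amp), n_del = sum(del),
               arm_scna_score = score, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare arm-alteration frequencies between two cohorts
#'
#' Per arm, a two-sided Fisher's exact test on the 2 x 2 table of altered
#' (amp or del) versus cohort, BH-adjusted across arms.
#'
#' @param calls output of [arm_calls()] for both cohorts.
#' @param cohorts named vector/factor mapping `sample_id` to cohort label.
#' @param fdr significance cutoff on q (default 0.1).
#' @return data.frame per arm: frequencies per cohort, `odds_ratio`, `p`,
#'   `q`, `significant`.
#' @export
compare_arm_frequencies <- function(calls, cohorts, fdr = 0.1) {
  co <- factor(cohorts[calls$sample_id])
  if (nlevels(co) != 2) stop("exactly two cohorts are required")
  if (min(table(cohorts)) < 2) stop("each cohort needs at least 2 samples")
  lv <- levels(co)
  altered <- calls$call != "neutral"
  out <- do.call(rbind, lapply(split(seq_len(nrow(calls)), calls$arm), function(i) {
    tab <- table(factor(altered[i], levels = c(TRUE, FALSE)), co[i])
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
         else min(fisher.test(tab)$p.value, 1)
    data.frame(arm = calls$arm[i[1]],
               freq_1 = mean(altered[i][co[i] == lv[1]]),
               freq_2 = mean(altered[i][co[i] == lv[2]]),
               p = p, stringsAsFactors = FALSE)
  }))
  names(out)[2:3] <- paste0("freq_", lv)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < fdr
  rownames(out) <- NULL
  out
}

#' Arm copy number vs gene expression correlation map
#'
#' Spearman correlation of each arm's per-sample mean copy number with each
#' gene's expression, with a t-approximation p-value, BH-adjusted over the
#' whole map. Constant expression rows and constant arms are skipped.
#'
#' @param calls output of [arm_calls()] (uses `mean_cn`).
#' @param expr genes x samples expression matrix.
#' @param fdr significance cutoff (default 0.1).
#' @return List: `rho`, `q` (genes x arms matrices) and `significant`
#'   (logical matrix at `fdr`).
#' @export
cnv_expression_correlation <- function(calls, expr, fdr = 0.1) {
  arms <- unique(calls$arm)
  samples <- intersect(colnames(expr), unique(calls$sample_id))
  if (length(samples) < 5) stop("need >= 5 matched samples")
  cn <- sapply(arms, function(a) {
    x <- calls[calls$arm == a, ]
    x$mean_cn[match(samples, x$sample_id)]
  })
  expr <- expr[, samples, drop = FALSE]
  keep <- apply(expr, 1, sd) > 0
  expr <- expr[keep, , drop = FALSE]
  n <- length(samples)
  rx <- t(apply(expr, 1, rank))
  ry <- apply(cn, 2, rank)
  rho <- cor(t(rx), ry)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  q <- matrix(bh_adjust(as.numeric(p)), nrow = nrow(p), dimnames = dimnames(p))
  list(rho = rho, q = q, significant = q < fdr)
}
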