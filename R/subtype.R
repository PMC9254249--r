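#' Low-count filter and most-variable-gene selection
#'
#' Optionally removes lowly expressed genes (those without at least
#' `min_count` counts in at least `min_patients` patients, judged on the raw
#' count matrix), then ranks the remaining genes by median absolute deviation
#' of the normalized values and keeps the top `n` (ties broken by gene
#' identifier).
#'
#' @param expr genes x samples normalized (log-scale) matrix with rownames.
#' @param n number of genes to keep (default 3000).
#' @param counts optional raw count matrix aligned with `expr` for the
#'   low-count filter; NULL skips the filter.
#' @param min_count,min_patients low-count filter thresholds (5 and 10).
#' @return The subset of `expr` restricted to the selected genes.
#' @export
select_variable_genes <- function(expr, n = 3000, counts = NULL,
                                  min_count = 5, min_patients = 10) {
  if (!is.null(counts)) {
    keep <- rowSums(counts >= min_count) >= min_patients
    expr <- expr[keep, , drop = FALSE]
  }
  if (n > nrow(expr)) stop("n exceeds the number of available genes")
  m <- apply(expr, 1, mad)
  ord <- order(-m, rownames(expr))
  expr[sort(ord[seq_len(n)]), , drop = FALSE]
}

#' Single NMF run with Brunet (KL-divergence) multiplicative updates
#'
#' Factorizes the nonnegative matrix V (genes x samples) as W H, minimizing
#' the generalized Kullback-Leibler divergence D(V || WH) by the standard
#' multiplicative updates. The objective is non-increasing across updates.
#'
#' @param V nonnegative matrix.
#' @param k factorization rank.
#' @param seed RNG seed for the random initialization.
#' @param max_iter,tol stopping rule (relative objective change).
#' @return List: `W`, `H`, `objective` (trace over iterations), `labels`
#'   (per-sample argmax of H).
#' @export
nmf_brunet <- function(V, k, seed = 1, max_iter = 500, tol = 1e-5) {
  if (any(V < 0)) stop("NMF requires a nonnegative matrix")
  if (k < 1 || k > min(dim(V))) stop("invalid rank")
  eps <- .Machine$double.eps
  n <- nrow(V); m <- ncol(V)
  init <- with_seed(seed, list(W = matrix(runif(n * k), n, k),
                               H = matrix(runif(k * m), k, m)))
  W <- init$W; H <- init$H
  kl <- function(WH) sum(V * log((V + eps) / (WH + eps)) - V + WH)
  obj <- numeric(0)
  WH <- W %*% H
  prev <- kl(WH)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V / (WH + eps))) / (colSums(W) + eps)
    WH <- W %*% H
    W <- W * ((V / (WH + eps)) %*% t(H)) / matrix(rowSums(H) + eps, n, k,
                                                  byrow = TRUE)
    WH <- W %*% H
    cur <- kl(WH)
    obj <- c(obj, cur)
    if (abs(prev - cur) < tol * abs(prev)) break
    prev <- cur
  }
  # put W on a common column scale before reading sample assignments off H
  d <- colSums(W)
  list(W = W, H = H, objective = obj,
       labels = apply(H * d, 2, which.max))
}

consensus_metrics <- function(consensus, k) {
  d <- as.dist(1 - consensus)
  hc <- hclust(d, method = "average")
  coph <- suppressWarnings(cor(cophenetic(hc), d))
  if (is.na(coph)) coph <- 1   # zero-variance consensus: perfectly stable
  labels <- cutree(hc, k = k)
  sil <- if (length(unique(labels)) < 2) 0 else
    mean(cluster::silhouette(labels, dmatrix = 1 - consensus)[, "sil_width"])
  list(cophenetic = coph, silhouette = sil, labels = labels)
}

#' Consensus NMF subtype discovery
#'
#' For each candidate rank, runs `n_runs` randomly initialized Brunet NMF
#' factorizations, aggregates per-run sample assignments into a consensus
#' (co-assignment frequency) matrix, and scores rank stability by the
#' cophenetic correlation of the consensus dendrogram and the mean silhouette
#' width on 1 - consensus. The chosen rank is the largest one whose
#' cophenetic correlation and silhouette are both within `tie_window` of
#' their respective maxima. Final labels come from average-linkage
#' hierarchical clustering of the chosen consensus matrix; per-subtype
#' templates are the top `n_template` genes by one-vs-rest Cohen's d
#' (positive effect sizes only).
#'
#' @param expr nonnegative genes x samples matrix (e.g. from
#'   [select_variable_genes()]).
#' @param ranks candidate ranks (default 2:6).
#' @param n_runs NMF restarts per rank (default 200; use 20 for a fast
#'   profile).
#' @param seed master seed; each run gets a derived seed.
#' @param n_template template genes per subtype (default 100).
#' @param tie_window rank-selection tolerance on both metrics (default 0.05).
#' @param max_iter,tol passed to [nmf_brunet()].
#' @return List of class `subtype_model`: `k`, `labels` (named integer),
#'   `consensus`, `templates` (list of gene vectors), `metrics` (per-rank
#'   data.frame), `consensus_by_rank`.
#' @export
nmf_consensus <- function(expr, ranks = 2:6, n_runs = 200, seed = 1,
                          n_template = 100, tie_window = 0.05,
                          max_iter = 500, tol = 1e-5) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  m <- ncol(expr)
  metrics <- data.frame(rank = ranks, cophenetic = NA_real_,
                        silhouette = NA_real_)
  cons_list <- list()
  seeds <- derive_seeds(seed, length(ranks) * n_runs)
  si <- 0
  for (ri in seq_along(ranks)) {
    k <- ranks[ri]
    C <- matrix(0, m, m)
    for (r in seq_len(n_runs)) {
      si <- si + 1
      lab <- nmf_brunet(expr, k, seed = seeds[si],
                        max_iter = max_iter, tol = tol)$labels
      C <- C + outer(lab, lab, "==")
    }
    C <- C / n_runs
    dimnames(C) <- list(colnames(expr), colnames(expr))
    cons_list[[as.character(k)]] <- C
    cm <- consensus_metrics(C, k)
    metrics$cophenetic[ri] <- cm$cophenetic
    metrics$silhouette[ri] <- cm$silhouette
  }
  ok <- metrics$cophenetic >= max(metrics$cophenetic) - tie_window &
        metrics$silhouette >= max(metrics$silhouette) - tie_window
  k <- if (any(ok)) max(metrics$rank[ok]) else
    metrics$rank[which.max(metrics$cophenetic + metrics$silhouette)]
  C <- cons_list[[as.character(k)]]
  labels <- consensus_metrics(C, k)$labels
  names(labels) <- colnames(expr)
  templates <- subtype_templates(expr, labels, n_template)
  structure(list(k = k, labels = labels, consensus = C,
                 templates = templates, metrics = metrics,
                 consensus_by_rank = cons_list),
            class = "subtype_model")
}

# top-n one-vs-rest up-regulated genes (Cohen's d, positive effects only)
subtype_templates <- function(expr, labels, n_template = 100) {
  ks <- sort(unique(labels))
  out <- lapply(ks, function(k) {
    a <- expr[, labels == k, drop = FALSE]
    b <- expr[, labels != k, drop = FALSE]
    if (ncol(b) == 0) return(character(0))
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- apply(a, 1, var); vb <- apply(b, 1, var)
    na <- ncol(a); nb <- ncol(b)
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / pmax(na + nb - 2, 1))
    d <- (ma - mb) / pmax(sp, 1e-8)
    pos <- d > 0
    genes <- rownames(expr)[pos][order(-d[pos], rownames(expr)[pos])]
    head(genes, n_template)
  })
  names(out) <- paste0("S", ks)
  out
}

#' Nearest-template prediction
#'
#' Row-standardizes the expression matrix (z-score per gene across samples),
#' correlates each sample's z-profile over the union of template genes with
#' each template's binary membership vector, and assigns the highest-
#' correlation template. Significance is assessed per sample by permuting the
#' sample's values over the template-gene universe (`n_perm` draws, seeded),
#' and p-values are BH-adjusted across samples; samples with q >= `fdr` are
#' labelled "NS".
#'
#' @param expr genes x samples matrix.
#' @param templates named list of template gene vectors.
#' @param n_perm permutations per sample (default 1000).
#' @param seed RNG seed for the permutations.
#' @param fdr confident-assignment cutoff (default 0.1).
#' @return data.frame: `sample_id`, `nearest`, `subtype` (nearest or "NS"),
#'   `corr`, `p`, `q`.
#' @export
ntp_assign <- function(expr, templates, n_perm = 1000, seed = 1, fdr = 0.1) {
  universe <- sort(unique(unlist(templates)))
  present <- universe[universe %in% rownames(expr)]
  if (length(present) < 0.5 * length(universe))
    stop("more than 50% of template genes are absent from the matrix")
  mu <- rowMeans(expr); sdv <- apply(expr, 1, sd)
  z <- (expr - mu) / ifelse(sdv > 0, sdv, 1)
  z <- z[present, , drop = FALSE]
  Tm <- sapply(templates, function(g) as.numeric(present %in% g))
  Tm <- scale(Tm)   # correlation via standardized indicator vectors
  n_g <- length(present)
  corr_all <- crossprod(scale(z), Tm) / (n_g - 1)
  nearest_i <- apply(corr_all, 1, which.max)
  corr <- corr_all[cbind(seq_len(ncol(z)), nearest_i)]
  perm_idx <- with_seed(seed, replicate(n_perm, sample.int(n_g)))
  p <- vapply(seq_len(ncol(z)), function(j) {
    zs <- scale(z[, j])[, 1]
    perm_corr <- crossprod(matrix(zs[perm_idx], n_g, n_perm),
                           Tm[, nearest_i[j]]) / (n_g - 1)
    (1 + sum(perm_corr >= corr[j])) / (1 + n_perm)
  }, numeric(1))
  q <- bh_adjust(p)
  data.frame(sample_id = colnames(expr),
             nearest = names(templates)[nearest_i],
             subtype = ifelse(q < fdr, names(templates)[nearest_i], "NS"),
             corr = corr, p = p, q = q,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-cohort subtype correspondence by mutual nearest-template prediction
#'
#' Assigns cohort B samples to cohort A templates and vice versa, scores
#' every subtype pair (i, j) by the geometric mean of the two confident
#' cross-assignment rates (fraction of A-subtype-i samples confidently
#' assigned to B template j, and of B-subtype-j samples to A template i), and
#' extracts a one-to-one matching greedily by descending score, keeping pairs
#' with score >= `min_score`. Subtypes left unmatched are reported as
#' cohort-specific.
#'
#' @param model_a,model_b fitted [nmf_consensus()] models.
#' @param expr_a,expr_b the corresponding expression matrices.
#' @param min_score minimum correspondence score for a match (default 0.25).
#' @param n_perm,seed,fdr passed to [ntp_assign()].
#' @return List: `score` matrix (A subtypes x B subtypes), `matches`
#'   data.frame, `a_specific`, `b_specific`.
#' @export
subtype_correspondence <- function(model_a, model_b, expr_a, expr_b,
                                   min_score = 0.25, n_perm = 1000,
                                   seed = 1, fdr = 0.1) {
  b_on_a <- ntp_assign(expr_b, model_a$templates, n_perm, seed, fdr)
  a_on_b <- ntp_assign(expr_a, model_b$templates, n_perm, seed + 1, fdr)
  subs_a <- names(model_a$templates); subs_b <- names(model_b$templates)
  lab_a <- paste0("S", model_a$labels[colnames(expr_a)])
  lab_b <- paste0("S", model_b$labels[colnames(expr_b)])
  S <- matrix(0, length(subs_a), length(subs_b),
              dimnames = list(subs_a, subs_b))
  for (i in subs_a) for (j in subs_b) {
    r1 <- mean(b_on_a$subtype[lab_b == j] == i)   # B_j samples -> A template i
    r2 <- mean(a_on_b$subtype[lab_a == i] == j)   # A_i samples -> B template j
    S[i, j] <- sqrt(r1 * r2)
  }
  matches <- data.frame(subtype_a = character(0), subtype_b = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  Sw <- S
  repeat {
    if (all(Sw < min_score)) break
    ij <- which(Sw == max(Sw), arr.ind = TRUE)[1, ]
    matches <- rbind(matches, data.frame(
      subtype_a = rownames(Sw)[ij[1]], subtype_b = colnames(Sw)[ij[2]],
      score = Sw[ij[1], ij[2]], stringsAsFactors = FALSE))
    Sw[ij[1], ] <- -Inf; Sw[, ij[2]] <- -Inf
  }
  list(score = S, matches = matches,
       a_specific = setdiff(subs_a, matches$subtype_a),
       b_specific = setdiff(subs_b, matches$subtype_b))
}

#' Gene-set activity score
#'
#' Mean per-gene z-score (computed across samples) over the member genes; a
#' rank-free stand-in for pathway-level activity used for immune-class,
#' MDSC and GEP style features. Constant genes get z = 0.
#'
#' @param expr genes x samples matrix.
#' @param genes character vector of member genes.
#' @param min_genes minimum members required in the matrix (default 3).
#' @return Named numeric vector of per-sample scores.
#' @export
gene_set_score <- function(expr, genes, min_genes = 3) {
  present <- intersect(genes, rownames(expr))
  if (length(present) < min_genes)
    stop("fewer than ", min_genes, " member genes present")
  x <- expr[present, , drop = FALSE]
  sdv <- apply(x, 1, sd)
  z <- (x - rowMeans(x)) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  colMeans(z)
}
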