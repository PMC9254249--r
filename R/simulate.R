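#' Configuration for the synthetic two-cohort generator
#'
#' Builds and validates the parameter set for [simulate_cohorts()]. The
#' defaults encode the cohort contrasts the pipeline is designed to detect:
#' cohort A carries a higher tumor mutation burden (`tmb_shift`), a more
#' frequent planted arm deletion ("16q", coupled to its A-specific "P2"
#' transcriptomic subtype), a higher overall arm-alteration rate, a different
#' mutational-signature composition (more aristolochic-acid- and
#' liver-signature-like patients) and a fourth transcriptomic subtype absent
#' from cohort B. Survival is generated from an exponential proportional-
#' hazards model on `hazard_coefs`.
#'
#' @param n_a,n_b patients per cohort (defaults 150).
#' @param seed integer RNG seed.
#' @param depth_mean mean sequencing depth; depths are negative binomial with
#'   dispersion `depth_dispersion`.
#' @param depth_dispersion negative-binomial size parameter (default 8).
#' @param purity_range tumor purity interval in (0, 1].
#' @param tmb_mean mean somatic mutation count per patient in cohort B.
#' @param tmb_shift multiplicative TMB factor for cohort A (default 1.6).
#' @param arm_del_freq_a,arm_del_freq_b marginal probability of the planted
#'   "16q" deletion per cohort (defaults 0.4 and 0.1).
#' @param subtype_props_a,subtype_props_b subtype mixing proportions (4 for
#'   cohort A: P1, P2, P3, P4; 3 for cohort B: P1, P3, P4 -- "P2" is
#'   A-specific). Each must sum to 1.
#' @param n_genes expression genes (default 1000; at least 320).
#' @param hazard_coefs named log-hazard coefficients: `subtype_p2`, `mdsc`,
#'   `driver` (TP53), `scna` (per altered arm).
#' @param archetype_probs_a,archetype_probs_b mixing over the four signature
#'   exposure archetypes (clock-like, smoking, aristolochic acid, liver).
#' @param arm_alt_rate_a,arm_alt_rate_b per-arm alteration probability for
#'   the non-planted arms.
#' @param subtype_shift log-scale up-regulation of each subtype's gene
#'   program (default 2.5, about 3 residual standard deviations).
#' @param coding_frac fraction of mutations flagged coding (default 0.9).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_a = 150, n_b = 150, seed = 1,
                       depth_mean = 100, depth_dispersion = 20,
                       purity_range = c(0.55, 0.95),
                       tmb_mean = 60, tmb_shift = 1.6,
                       arm_del_freq_a = 0.4, arm_del_freq_b = 0.1,
                       subtype_props_a = c(P1 = 0.30, P2 = 0.30, P3 = 0.20, P4 = 0.20),
                       subtype_props_b = c(P1 = 0.40, P3 = 0.35, P4 = 0.25),
                       n_genes = 1000,
                       hazard_coefs = c(subtype_p2 = 0.9, mdsc = 0.5,
                                        driver = 0.7, scna = 0.06),
                       archetype_probs_a = c(0.20, 0.15, 0.35, 0.30),
                       archetype_probs_b = c(0.50, 0.30, 0.10, 0.10),
                       arm_alt_rate_a = 0.12, arm_alt_rate_b = 0.06,
                       subtype_shift = 2.5, coding_frac = 0.9) {
  if (n_a < 0 || n_b < 0 || n_a + n_b == 0)
    stop("cohort sizes must be non-negative and not both zero")
  if (length(subtype_props_a) != 4 || abs(sum(subtype_props_a) - 1) > 1e-8)
    stop("subtype_props_a must be 4 proportions summing to 1")
  if (length(subtype_props_b) != 3 || abs(sum(subtype_props_b) - 1) > 1e-8)
    stop("subtype_props_b must be 3 proportions summing to 1")
  if (purity_range[1] <= 0 || purity_range[2] > 1 ||
      purity_range[1] > purity_range[2])
    stop("purity_range must satisfy 0 < low <= high <= 1")
  for (f in c(arm_del_freq_a, arm_del_freq_b, arm_alt_rate_a, arm_alt_rate_b,
              coding_frac))
    if (f < 0 || f > 1) stop("frequencies must lie in [0, 1]")
  if (n_genes < 320) stop("n_genes must be at least 320")
  structure(as.list(environment()), class = "sim_config")
}

#' Null variant of the generator configuration
#'
#' Flattens every cohort contrast (TMB shift 1, equal arm frequencies, equal
#' signature composition, equal driver frequencies) for type-I-error
#' calibration runs. The structural asymmetry (cohort A still has 4 subtypes)
#' is retained.
#'
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_null <- function(...) {
  cfg <- sim_config(tmb_shift = 1,
                    arm_del_freq_a = 0.25, arm_del_freq_b = 0.25,
                    archetype_probs_a = c(0.35, 0.22, 0.22, 0.21),
                    archetype_probs_b = c(0.35, 0.22, 0.22, 0.21),
                    arm_alt_rate_a = 0.09, arm_alt_rate_b = 0.09, ...)
  cfg$null_drivers <- TRUE
  cfg
}

#' Curated liver-cancer driver gene list
#'
#' The 12 recurrently mutated driver genes planted by the synthetic-cohort
#' generator, mirroring well-known hepatocellular-carcinoma drivers. Used as
#' the default curated driver list for the feature table (driver discovery
#' is out of scope; the list is an input).
#'
#' @return Character vector of 12 gene symbols.
#' @export
hcc_driver_genes <- function() driver_table()$gene

# driver genes: per-cohort frequencies and fixed loci on the toy genome.
# AXIN1 sits on 16p and its frequency is boosted when 16q is deleted.
driver_table <- function(null_drivers = FALSE) {
  d <- data.frame(
    gene   = c("TP53", "CTNNB1", "AXIN1", "ARID1A", "ARID2", "RB1",
               "ALB", "TSC2", "NFE2L2", "KEAP1", "RPS6KA3", "BAP1"),
    chrom  = c("chr17", "chr3", "chr16", "chr1", "chr5", "chr6",
               "chr4", "chr16", "chr2", "chr2", "chr7", "chr3"),
    pos    = c(20000L, 30000L, 15000L, 50000L, 40000L, 60000L,
               70000L, 40000L, 25000L, 90000L, 35000L, 110000L),
    freq_a = c(0.45, 0.18, 0.08, 0.10, 0.07, 0.06,
               0.12, 0.05, 0.05, 0.05, 0.06, 0.05),
    freq_b = c(0.25, 0.35, 0.08, 0.10, 0.07, 0.06,
               0.12, 0.05, 0.05, 0.05, 0.06, 0.05),
    stringsAsFactors = FALSE)
  if (null_drivers) d$freq_a <- d$freq_b <- (d$freq_a + d$freq_b) / 2
  d
}

# the four signature-exposure archetypes over the bundled 10-signature catalog
exposure_archetypes <- function(catalog) {
  sig <- rownames(catalog)
  arch <- list(
    clock   = c(SBS1 = .18, SBS5 = .60, SBS4 = .08, SBS12 = .07, SBS16 = .07),
    smoking = c(SBS4 = .42, SBS5 = .38, SBS1 = .10, SBS18 = .10),
    aa      = c(SBS22 = .55, SBS5 = .25, SBS1 = .10, SBS4 = .10),
    liver   = c(SBS12 = .32, SBS16 = .30, SBS5 = .23, SBS1 = .15))
  M <- matrix(0, length(arch), length(sig), dimnames = list(names(arch), sig))
  for (i in seq_along(arch)) M[i, names(arch[[i]])] <- arch[[i]]
  M / rowSums(M)
}

# designated gene sets of the synthetic expression design
sim_gene_sets <- function(genes) {
  list(proliferation = genes[1:50],    metabolism = genes[51:100],
       inflammation  = genes[101:150], myc_upr    = genes[151:200],
       trans_del16   = genes[201:240], mdsc       = genes[241:260],
       gep_immune    = genes[261:280])
}

#' Simulate two labelled tumor cohorts with planted ground truth
#'
#' Generates, per patient: purity; 1-4 subclones (one clonal cluster pinned
#' at CCF 1); mutation counts from a negative-binomial TMB model (cohort A
#' scaled by `tmb_shift`); trinucleotide contexts drawn from the patient's
#' true signature mixture; read depths (negative binomial around
#' `depth_mean`) and alternate counts drawn binomially from the expected VAF
#' given purity, local copy number and clone CCF (mutation multiplicity 1);
#' integer copy-number segments tiling the 22-arm miniature genome with
#' cohort-specific alteration probabilities and the planted "16q" deletion
#' coupled to subtype P2 in cohort A; a block-structured expression matrix
#' (subtype programs, cis copy-number dosage, a trans-effect of the 16q
#' deletion, an MDSC-like program, Gaussian noise); and exponential
#' proportional-hazards survival with uniform censoring calibrated to ~30%.
#'
#' @param config a [sim_config()].
#' @return List of class `cohort_bundle`: `maf`, `seg`, `expression`
#'   (genes x samples matrix), `clinical`, `truth` (ground-truth list),
#'   `gene_sets`, `config`.
#' @export
simulate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohorts_impl(config))
}

simulate_cohorts_impl <- function(cfg) {
  arms <- default_arm_table()
  catalog <- sig_catalog_default()
  ctx <- sbs_contexts()
  arch <- exposure_archetypes(catalog)
  drv <- driver_table(isTRUE(cfg$null_drivers))
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  gsets <- sim_gene_sets(genes)

  n_tot <- cfg$n_a + cfg$n_b
  ids <- c(sprintf("A%03d", seq_len(cfg$n_a)), sprintf("B%03d", seq_len(cfg$n_b)))
  cohort <- rep(c("A", "B"), c(cfg$n_a, cfg$n_b))

  # ---- per-sample latent state -------------------------------------------
  purity <- runif(n_tot, cfg$purity_range[1], cfg$purity_range[2])
  subtype <- character(n_tot)
  subtype[cohort == "A"] <- sample(names(cfg$subtype_props_a), cfg$n_a,
                                   TRUE, cfg$subtype_props_a)
  subtype[cohort == "B"] <- sample(names(cfg$subtype_props_b), cfg$n_b,
                                   TRUE, cfg$subtype_props_b)
  arch_idx <- integer(n_tot)
  arch_idx[cohort == "A"] <- sample(4, cfg$n_a, TRUE, cfg$archetype_probs_a)
  arch_idx[cohort == "B"] <- sample(4, cfg$n_b, TRUE, cfg$archetype_probs_b)
  exposures <- t(vapply(seq_len(n_tot), function(i) {
    e <- arch[arch_idx[i], ] + rgamma(ncol(arch), shape = 0.6, rate = 12)
    e / sum(e)
  }, numeric(ncol(arch))))
  rownames(exposures) <- ids

  # planted 16q deletion: marginal frequency per cohort, concentrated on P2
  # within cohort A (which is the only cohort carrying P2)
  del16 <- logical(n_tot)
  for (co in c("A", "B")) {
    f <- if (co == "A") cfg$arm_del_freq_a else cfg$arm_del_freq_b
    in_co <- which(cohort == co)
    if (length(in_co) == 0) next
    p2 <- subtype[in_co] == "P2"
    pi2 <- mean(p2)
    if (pi2 > 0 && f > 0) {
      x <- min(2.5 * f, 1, f / pi2)               # P(del | P2)
      y <- max((f - pi2 * x) / (1 - pi2), 0)      # P(del | not P2)
      pr <- ifelse(p2, x, y)
    } else pr <- rep(f, length(in_co))
    del16[in_co] <- runif(length(in_co)) < pr
  }

  # ---- copy-number segments and somatic mutations -------------------------
  n_arm <- nrow(arms)
  arm_len <- arms$end - arms$start + 1
  arm_prob <- arm_len / sum(arm_len)
  j16 <- which(arms$arm == "16q")
  j8 <- which(arms$arm == "8q")
  arm_truth <- matrix("neutral", n_tot, n_arm, dimnames = list(ids, arms$arm))
  arm_cn_mean <- matrix(2, n_tot, n_arm, dimnames = list(ids, arms$arm))
  # driver loci mapped to arms once
  drv_arm <- vapply(seq_len(nrow(drv)), function(g)
    which(arms$chrom == drv$chrom[g] & arms$start <= drv$pos[g] &
            arms$end >= drv$pos[g]), integer(1))

  # ---- drivers -------------------------------------------------------------
  drv_mat <- matrix(0L, n_tot, nrow(drv), dimnames = list(ids, drv$gene))
  for (g in seq_len(nrow(drv))) {
    f <- ifelse(cohort == "A", drv$freq_a[g], drv$freq_b[g])
    if (drv$gene[g] == "AXIN1") f <- ifelse(del16, 0.35, 0.08)
    drv_mat[, g] <- as.integer(runif(n_tot) < f)
  }

  seg_acc <- vector("list", n_tot)
  maf_acc <- vector("list", n_tot)
  truth_acc <- vector("list", n_tot)
  clone_rows <- vector("list", n_tot)
  n_clones <- integer(n_tot)
  for (i in seq_len(n_tot)) {
    rate <- if (cohort[i] == "A") cfg$arm_alt_rate_a else cfg$arm_alt_rate_b
    # arm copy numbers: planted 16q deletion, amplification-prone 8q,
    # background alterations at the cohort rate
    u_alt <- runif(n_arm); u_dir <- runif(n_arm)
    amp_cn <- ifelse(runif(n_arm) < 0.8, 3L, 4L)
    cn <- rep(2L, n_arm)
    altered <- u_alt < rate
    cn[altered] <- ifelse(u_dir[altered] < 0.55, 1L, amp_cn[altered])
    cn[j8] <- if (u_alt[j8] < rate + 0.10) amp_cn[j8] else 2L
    cn[j16] <- if (del16[i]) 1L else 2L
    arm_truth[i, ] <- ifelse(cn > 2L, "amp", ifelse(cn < 2L, "del", "neutral"))
    # occasional sub-arm event too short to qualify as an arm-level call
    part <- cn == 2L & runif(n_arm) < 0.05
    cut <- as.integer(floor(arms$start + 0.4 * (arms$end - arms$start)))
    sub_cn <- ifelse(runif(n_arm) < 0.5, 1L, 3L)
    idx <- rep(seq_len(n_arm), times = 1L + part)
    second <- duplicated(idx)
    first_split <- part[idx] & !second
    seg_acc[[i]] <- list(
      sample_id = rep(ids[i], length(idx)),
      chrom = arms$chrom[idx],
      start = ifelse(second, cut[idx] + 1L, arms$start[idx]),
      end = ifelse(first_split, cut[idx], arms$end[idx]),
      integer_cn = ifelse(first_split, sub_cn[idx],
                          ifelse(second, 2L, cn[idx])))
    frac_cut <- (cut - arms$start + 1) / arm_len
    arm_cn_mean[i, ] <- ifelse(part, sub_cn * frac_cut + 2 * (1 - frac_cut), cn)

    # subclone structure and mutation burden
    k <- sample(1:4, 1, prob = c(.25, .30, .25, .20))
    ccfs <- 1
    if (k > 1) ccfs <- c(1, sort(runif(k - 1, 0.15, 0.70), decreasing = TRUE))
    w <- c(1.3, rgamma(k - 1, shape = 1) + 0.3)
    mu <- cfg$tmb_mean * if (cohort[i] == "A") cfg$tmb_shift else 1
    n_mut <- max(rnbinom(1, mu = mu, size = 6), 15)
    clone <- rep(seq_len(k), as.integer(rmultinom(1, n_mut, w)))
    arm_i <- sample(n_arm, n_mut, TRUE, arm_prob)
    pos <- arms$start[arm_i] + floor(runif(n_mut) * arm_len[arm_i])
    local_cn <- ifelse(part[arm_i] & pos <= cut[arm_i], sub_cn[arm_i],
                       ifelse(part[arm_i], 2L, cn[arm_i]))
    local_cn <- pmax(local_cn, 1L)   # homozygous-deletion guard
    vaf <- expected_vaf(ccfs[clone], purity[i], 2, local_cn)
    depth <- rnbinom(n_mut, mu = cfg$depth_mean, size = cfg$depth_dispersion) + 1L
    alt <- rbinom(n_mut, depth, vaf)
    context <- sample(ctx, n_mut, TRUE,
                      prob = as.numeric(exposures[i, ] %*% catalog))
    # clonal coding driver mutations on top of the background burden
    hit <- which(drv_mat[i, ] == 1L)
    d_cn <- pmax(ifelse(part[drv_arm[hit]] & drv$pos[hit] <= cut[drv_arm[hit]],
                        sub_cn[drv_arm[hit]],
                        ifelse(part[drv_arm[hit]], 2L, cn[drv_arm[hit]])), 1L)
    d_depth <- rnbinom(length(hit), mu = cfg$depth_mean,
                       size = cfg$depth_dispersion) + 1L
    d_alt <- rbinom(length(hit), d_depth, expected_vaf(1, purity[i], 2, d_cn))
    d_ctx <- sample(ctx, length(hit), TRUE,
                    prob = as.numeric(exposures[i, ] %*% catalog))
    all_ctx <- c(context, d_ctx)
    maf_acc[[i]] <- list(
      sample_id = rep(ids[i], n_mut + length(hit)),
      chrom = c(arms$chrom[arm_i], drv$chrom[hit]),
      pos = c(pos, drv$pos[hit]),
      ref = substr(all_ctx, 3, 3),
      alt = substr(all_ctx, 5, 5),
      t_depth = c(depth, d_depth),
      t_alt_count = c(alt, d_alt),
      context96 = all_ctx,
      coding = c(as.integer(runif(n_mut) < cfg$coding_frac),
                 rep(1L, length(hit))),
      gene = c(paste0("G", sub("^chr", "", arms$chrom[arm_i]), "_",
                      pos %/% 5000L),
               drv$gene[hit]))
    truth_acc[[i]] <- list(
      sample_id = rep(ids[i], n_mut + length(hit)),
      chrom = c(arms$chrom[arm_i], drv$chrom[hit]),
      pos = c(pos, drv$pos[hit]),
      clone = c(clone, rep(1L, length(hit))),
      true_ccf = c(ccfs[clone], rep(1, length(hit))))
    clone_rows[[i]] <- data.frame(sample_id = ids[i], clone = seq_len(k),
                                  ccf = ccfs, n_mut = tabulate(clone, k),
                                  stringsAsFactors = FALSE)
    n_clones[i] <- k
  }
  cat_field <- function(acc, f) unlist(lapply(acc, `[[`, f), use.names = FALSE)
  seg <- data.frame(sample_id = cat_field(seg_acc, "sample_id"),
                    chrom = cat_field(seg_acc, "chrom"),
                    start = cat_field(seg_acc, "start"),
                    end = cat_field(seg_acc, "end"),
                    integer_cn = cat_field(seg_acc, "integer_cn"),
                    stringsAsFactors = FALSE)
  maf <- data.frame(sample_id = cat_field(maf_acc, "sample_id"),
                    chrom = cat_field(maf_acc, "chrom"),
                    pos = cat_field(maf_acc, "pos"),
                    ref = cat_field(maf_acc, "ref"),
                    alt = cat_field(maf_acc, "alt"),
                    t_depth = cat_field(maf_acc, "t_depth"),
                    t_alt_count = cat_field(maf_acc, "t_alt_count"),
                    context96 = cat_field(maf_acc, "context96"),
                    coding = cat_field(maf_acc, "coding"),
                    gene = cat_field(maf_acc, "gene"),
                    stringsAsFactors = FALSE)
  mut_truth_df <- data.frame(sample_id = cat_field(truth_acc, "sample_id"),
                             chrom = cat_field(truth_acc, "chrom"),
                             pos = cat_field(truth_acc, "pos"),
                             clone = cat_field(truth_acc, "clone"),
                             true_ccf = cat_field(truth_acc, "true_ccf"),
                             stringsAsFactors = FALSE)
  scna_true <- rowSums(arm_truth != "neutral")

  # ---- expression ---------------------------------------------------------
  prog_of <- c(P1 = "proliferation", P2 = "metabolism",
               P3 = "inflammation", P4 = "myc_upr")
  # home arm per gene for the cis dosage effect; designed sets stay off chr16
  non16 <- which(!arms$arm %in% c("16p", "16q"))
  home <- integer(cfg$n_genes)
  home[1:300] <- rep(non16, length.out = 300)
  if (cfg$n_genes > 300)
    home[301:cfg$n_genes] <- rep(seq_len(nrow(arms)),
                                 length.out = cfg$n_genes - 300)
  mdsc_latent <- 0.9 * del16 + rnorm(n_tot, 0, 0.4)
  immune_latent <- -0.06 * scna_true + rnorm(n_tot, 0, 0.3)
  expr <- matrix(rnorm(cfg$n_genes * n_tot, 5, 0.5), cfg$n_genes, n_tot,
                 dimnames = list(genes, ids))
  for (p in names(prog_of)) {
    rows <- match(gsets[[prog_of[p]]], genes)
    expr[rows, subtype == p] <- expr[rows, subtype == p] + cfg$subtype_shift
  }
  expr[match(gsets$trans_del16, genes), del16] <-
    expr[match(gsets$trans_del16, genes), del16] - 1.2
  expr[match(gsets$mdsc, genes), ] <-
    expr[match(gsets$mdsc, genes), ] + rep(mdsc_latent, each = 20)
  expr[match(gsets$gep_immune, genes), ] <-
    expr[match(gsets$gep_immune, genes), ] + rep(immune_latent, each = 20)
  expr <- expr + 0.45 * (t(arm_cn_mean)[home, ] - 2)
  expr <- expr + matrix(rnorm(cfg$n_genes * n_tot, 0, 0.6), cfg$n_genes, n_tot)
  expr <- pmax(expr, 0)

  # ---- survival -----------------------------------------------------------
  hc <- cfg$hazard_coefs
  lp <- hc["subtype_p2"] * (subtype == "P2") + hc["mdsc"] * mdsc_latent +
    hc["driver"] * drv_mat[, "TP53"] + hc["scna"] * scna_true
  lp <- as.numeric(lp - mean(lp))
  lambda0 <- 0.02
  t_event <- rexp(n_tot, rate = lambda0 * exp(lp))
  c_max <- 3.3 / lambda0   # uniform censoring tuned to ~30% at mean hazard
  t_cens <- runif(n_tot, 0, c_max)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)

  ploidy <- as.numeric(arm_cn_mean %*% arm_len / sum(arm_len))

  clinical <- data.frame(
    sample_id = ids, cohort = cohort,
    age = round(rnorm(n_tot, 60, 10)),
    sex = sample(c("male", "female"), n_tot, TRUE, c(.7, .3)),
    viral_status = ifelse(cohort == "A",
                          sample(c("HBV", "HCV", "none"), n_tot, TRUE, c(.55, .10, .35)),
                          sample(c("HBV", "HCV", "none"), n_tot, TRUE, c(.15, .30, .55))),
    stage = sample(c("I", "II", "III", "IV"), n_tot, TRUE, c(.35, .3, .2, .15)),
    grade = sample(c("G1", "G2", "G3"), n_tot, TRUE, c(.3, .5, .2)),
    purity = purity, ploidy = ploidy,
    os_time = os_time, os_event = os_event,
    stringsAsFactors = FALSE)

  truth <- list(
    samples = data.frame(
      sample_id = ids, cohort = cohort, purity = purity, subtype = subtype,
      archetype = rownames(arch)[arch_idx], del16 = del16,
      scna_count = as.integer(scna_true), mdsc_latent = mdsc_latent,
      lp = lp, n_clones = n_clones, stringsAsFactors = FALSE),
    clones = do.call(rbind, clone_rows),
    mutations = mut_truth_df,
    exposures = exposures,
    arm_alterations = arm_truth,
    drivers = drv_mat)
  rownames(truth$clones) <- rownames(truth$mutations) <- NULL

  structure(list(maf = maf, seg = seg, expression = expr,
                 clinical = clinical, truth = truth, gene_sets = gsets,
                 config = cfg),
            class = "cohort_bundle")
}
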