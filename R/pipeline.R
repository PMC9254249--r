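#' Run the full molecular pipeline and assemble the survival feature table
#'
#' Convenience composition of the per-module steps on a two-cohort bundle
#' (simulated or read from disk): CCF estimation, subclone clustering and ITH
#' metrics; SBS-96 deconvolution with the 2%/20% retention rule; genome
#' instability, arm calls and arm-level SCNA scores; per-cohort consensus-NMF
#' subtypes with cross-cohort correspondence; gene-set activity scores
#' (MDSC-like and immune/GEP-like sets from the bundle); driver event matrix
#' with the hypermutation and 1%-frequency filters; and the 44-feature-style
#' table via [build_feature_table()].
#'
#' @param bundle a `cohort_bundle` from [simulate_cohorts()] or
#'   [read_fixture()].
#' @param ranks,n_runs,n_var_genes consensus-NMF settings (defaults 2:6,
#'   20 restarts, 300 most-variable genes).
#' @param driver_genes curated driver gene list for the driver feature
#'   block (default [hcc_driver_genes()]); driver discovery itself is out of
#'   scope and treated as an input, as with literature-curated driver lists.
#' @param n_perm NTP permutations for the correspondence step.
#' @param seed master seed for the NMF restarts and NTP permutations.
#' @return List: `features` (feature table with `categories` attribute),
#'   `clonality`, `exposures`, `arm_calls`, `scna`, `gii`, `models` (per-
#'   cohort subtype models), `correspondence`, `subtype_labels`.
#' @export
integrative_features <- function(bundle, ranks = 2:6, n_runs = 20,
                                 n_var_genes = 300,
                                 driver_genes = hcc_driver_genes(),
                                 n_perm = 500, seed = 1) {
  cl <- bundle$clinical
  prof <- cl[, c("sample_id", "purity", "sex")]

  clon <- clonality_pipeline(bundle$maf, prof, bundle$seg)

  counts <- count_contexts(bundle$maf, samples = cl$sample_id)
  nonzero <- rowSums(counts) > 0
  ret <- iterative_retention(counts[nonzero, , drop = FALSE],
                             sig_catalog_default())
  exposures <- matrix(NA_real_, nrow(cl), ncol(ret$exposures),
                      dimnames = list(cl$sample_id, colnames(ret$exposures)))
  exposures[rownames(ret$exposures), ] <- ret$exposures

  calls <- arm_calls(bundle$seg)
  scna <- arm_scna_score(calls)
  gii <- genome_instability_index(bundle$seg)
  cnv_events <- matrix(0L, nrow(cl), length(unique(calls$arm)),
                       dimnames = list(cl$sample_id, unique(calls$arm)))
  altered <- calls[calls$call != "neutral", ]
  cnv_events[cbind(altered$sample_id, altered$arm)] <- 1L

  filt <- apply_cohort_filters(bundle$maf, cl)
  drv_cols <- intersect(colnames(filt$events), driver_genes)
  filt$events <- filt$events[, drv_cols, drop = FALSE]

  cohorts <- unique(cl$cohort)
  models <- list(); labels <- setNames(rep(NA_character_, nrow(cl)), cl$sample_id)
  for (i in seq_along(cohorts)) {
    ids <- cl$sample_id[cl$cohort == cohorts[i]]
    v <- select_variable_genes(bundle$expression[, ids, drop = FALSE],
                               n = min(n_var_genes, nrow(bundle$expression)))
    models[[cohorts[i]]] <- nmf_consensus(v, ranks = ranks, n_runs = n_runs,
                                          seed = seed + i)
    labels[ids] <- paste0(cohorts[i], ".S", models[[cohorts[i]]]$labels[ids])
  }
  correspondence <- if (length(cohorts) == 2) {
    ids_a <- cl$sample_id[cl$cohort == cohorts[1]]
    ids_b <- cl$sample_id[cl$cohort == cohorts[2]]
    subtype_correspondence(models[[cohorts[1]]], models[[cohorts[2]]],
                           bundle$expression[, ids_a],
                           bundle$expression[, ids_b],
                           n_perm = n_perm, seed = seed)
  } else NULL

  mdsc <- gene_set_score(bundle$expression, bundle$gene_sets$mdsc)
  gep <- gene_set_score(bundle$expression, bundle$gene_sets$gep_immune)
  tmb <- as.integer(table(factor(bundle$maf$sample_id[bundle$maf$coding == 1],
                                 levels = cl$sample_id)))

  molecular <- data.frame(
    sample_id = cl$sample_id,
    purity = cl$purity, ploidy = cl$ploidy,
    subtype = labels[cl$sample_id],
    tmb = tmb,
    scna = scna$arm_scna_score[match(cl$sample_id, scna$sample_id)],
    gii = gii$gii[match(cl$sample_id, gii$sample_id)],
    mdsc_score = mdsc[cl$sample_id],
    gep_score = gep[cl$sample_id],
    stringsAsFactors = FALSE)

  ith <- clon$samples
  missing_ith <- setdiff(cl$sample_id, ith$sample_id)
  if (length(missing_ith) > 0)
    ith <- rbind(ith, data.frame(sample_id = missing_ith, plm = NA, math_score = NA,
                                 shannon = NA, n_clusters = NA, n_mutations = NA))

  drivers <- filt$events
  missing_drv <- setdiff(cl$sample_id, rownames(drivers))
  if (length(missing_drv) > 0) {
    pad <- matrix(0L, length(missing_drv), ncol(drivers),
                  dimnames = list(missing_drv, colnames(drivers)))
    drivers <- rbind(drivers, pad)
  }

  features <- build_feature_table(
    clinical = cl,
    clinical_features = c("sex", "age", "stage", "viral_status", "grade"),
    molecular = molecular,
    exposures = exposures,
    cnv_events = cnv_events,
    drivers = drivers,
    ith = ith)

  list(features = features, clonality = clon, exposures = exposures,
       arm_calls = calls, scna = scna, gii = gii, models = models,
       correspondence = correspondence, subtype_labels = labels)
}
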