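#' Read a MAF-like mutation TSV
#'
#' Required columns: `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `t_depth`, `t_alt_count`, `context96`, `coding`; extra columns (e.g.
#' `gene`) are preserved.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_maf <- function(path) {
  maf <- read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(maf, c("sample_id", "chrom", "pos", "ref", "alt",
                              "t_depth", "t_alt_count", "context96", "coding"),
                       "MAF")
  maf
}

#' Read a SEG copy-number TSV
#'
#' Columns: `sample_id`, `chrom`, `start`, `end` (1-based inclusive),
#' `integer_cn`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_seg <- function(path) {
  seg <- read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(seg, c("sample_id", "chrom", "start", "end", "integer_cn"),
                       "SEG")
  seg
}

#' Read a genes x samples expression TSV
#'
#' First column holds gene identifiers; remaining columns are samples.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a clinical/survival TSV
#' @param path TSV path (needs at least `sample_id` and `cohort`).
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  cl <- read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(cl, c("sample_id", "cohort"), "clinical table")
  cl
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a simulated cohort bundle to disk
#'
#' Writes `maf.tsv`, `seg.tsv`, `expression.tsv`, `clinical.tsv` and
#' `truth.json` (ground truth, gene sets and the generator configuration)
#' into `out_dir`. The files round-trip losslessly through [read_fixture()].
#'
#' @param bundle a `cohort_bundle` from [simulate_cohorts()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- file.path(out_dir, c("maf.tsv", "seg.tsv", "expression.tsv",
                                "clinical.tsv", "truth.json"))
  write_tsv(bundle$maf, paths[1])
  write_tsv(bundle$seg, paths[2])
  expr_df <- data.frame(gene = rownames(bundle$expression), bundle$expression,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(expr_df, paths[3])
  write_tsv(bundle$clinical, paths[4])
  truth <- bundle$truth
  truth$exposures <- list(samples = rownames(truth$exposures),
                          signatures = colnames(truth$exposures),
                          values = unname(truth$exposures))
  truth$arm_alterations <- list(samples = rownames(bundle$truth$arm_alterations),
                                arms = colnames(bundle$truth$arm_alterations),
                                values = unname(bundle$truth$arm_alterations))
  truth$drivers <- list(samples = rownames(bundle$truth$drivers),
                        genes = colnames(bundle$truth$drivers),
                        values = unname(bundle$truth$drivers))
  cfg <- bundle$config
  class(cfg) <- NULL
  jsonlite::write_json(list(truth = truth, gene_sets = bundle$gene_sets,
                            config = cfg),
                       paths[5], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

json_matrix <- function(x, mode = "double") {
  m <- do.call(rbind, lapply(x$values, unlist))
  if (is.null(m)) m <- matrix(vector(mode, 0), 0, length(x$arms %||% x$genes %||% x$signatures))
  dimnames(m) <- list(unlist(x$samples),
                      unlist(x$signatures %||% x$arms %||% x$genes))
  m
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir the fixture directory.
#' @return A `cohort_bundle`.
#' @export
read_fixture <- function(dir) {
  maf <- read_maf(file.path(dir, "maf.tsv"))
  seg <- read_seg(file.path(dir, "seg.tsv"))
  expr <- read_expression(file.path(dir, "expression.tsv"))
  clinical <- read_clinical(file.path(dir, "clinical.tsv"))
  js <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth <- js$truth
  truth$exposures <- local({
    m <- truth$exposures$values
    dimnames(m) <- list(truth$exposures$samples, truth$exposures$signatures)
    m
  })
  truth$arm_alterations <- local({
    m <- truth$arm_alterations$values
    dimnames(m) <- list(truth$arm_alterations$samples, truth$arm_alterations$arms)
    m
  })
  truth$drivers <- local({
    m <- truth$drivers$values
    storage.mode(m) <- "integer"
    dimnames(m) <- list(truth$drivers$samples, truth$drivers$genes)
    m
  })
  cfg <- js$config
  class(cfg) <- "sim_config"
  structure(list(maf = maf, seg = seg, expression = expr, clinical = clinical,
                 truth = truth, gene_sets = js$gene_sets, config = cfg),
            class = "cohort_bundle")
}
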