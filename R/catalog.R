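#' Bundled single-base-substitution signature catalog
#'
#' A synthetic catalog of 10 signatures over the 96 trinucleotide contexts,
#' constructed deterministically (no RNG state is touched). The rows are
#' labelled with the names of signatures commonly active in liver cancer
#' (clock-like SBS1/SBS5, smoking SBS4, MSI-associated SBS6, liver-associated
#' SBS12/SBS16, reactive-oxygen SBS18, aristolochic-acid SBS22, aflatoxin
#' SBS24, SBS29) and each row mimics the dominant substitution class and
#' flanking-base preference of its namesake, but the numeric profiles are
#' synthetic stand-ins, not redistributed COSMIC data. A user-supplied
#' COSMIC-format catalog can be read with [read_catalog()].
#'
#' @return A 10 x 96 matrix; rows sum to 1, rownames are signature names,
#'   colnames are [sbs_contexts()].
#' @export
sig_catalog_default <- function() {
  ctx <- sbs_contexts()
  classes <- rep(c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"), each = 16)
  f5 <- substr(ctx, 1, 1)
  f3 <- substr(ctx, 7, 7)

  # per-signature: class weights over the 6 substitution types plus an
  # optional flank constraint concentrating mass within the dominant class
  spec <- list(
    SBS1  = list(w = c(.04, .03, .80, .03, .07, .03), dom = "C>T", mask = f3 == "G"),
    SBS4  = list(w = c(.65, .10, .12, .04, .06, .03), dom = "C>A", mask = NULL),
    SBS5  = list(w = c(.14, .09, .26, .09, .31, .11), dom = NULL,  mask = NULL),
    SBS6  = list(w = c(.08, .04, .62, .04, .18, .04), dom = "C>T", mask = f5 == "G"),
    SBS12 = list(w = c(.05, .04, .08, .05, .72, .06), dom = "T>C", mask = NULL),
    SBS16 = list(w = c(.06, .04, .08, .06, .70, .06), dom = "T>C", mask = f5 == "A"),
    SBS18 = list(w = c(.64, .08, .10, .05, .08, .05), dom = "C>A", mask = f5 == "T"),
    SBS22 = list(w = c(.05, .03, .06, .78, .05, .03), dom = "T>A", mask = NULL),
    SBS24 = list(w = c(.58, .06, .20, .04, .08, .04), dom = "C>A", mask = f3 == "C"),
    SBS29 = list(w = c(.52, .16, .10, .12, .06, .04), dom = "C>A", mask = f5 == "C")
  )

  M <- matrix(0, nrow = length(spec), ncol = 96,
              dimnames = list(names(spec), ctx))
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    prof <- numeric(96)
    # deterministic flank modulation, distinct per signature and class
    for (ci in seq_along(unique(classes))) {
      cls <- unique(classes)[ci]
      idx <- which(classes == cls)
      mod <- lcg_stream(16, seed = 7919L * i + 131L * ci)^2 + 0.05
      prof[idx] <- s$w[ci] * mod / sum(mod)
    }
    if (!is.null(s$mask)) {
      # concentrate 85% of the dominant class's mass on the preferred flank
      idx <- which(classes == s$dom)
      inmask <- s$mask[idx]
      cls_mass <- sum(prof[idx])
      p_in <- prof[idx] * ifelse(inmask, 1, 0)
      p_out <- prof[idx] * ifelse(inmask, 0, 1)
      prof[idx] <- 0.85 * cls_mass * p_in / sum(p_in) +
                   0.15 * cls_mass * p_out / sum(p_out)
    }
    M[i, ] <- prof / sum(prof)
  }
  M
}

#' Read a signature catalog TSV
#'
#' Accepts the COSMIC file layout: first column holds context labels
#' (96 rows, signatures in columns) or signature names (rows = signatures,
#' 96 context columns); orientation is detected from the labels.
#'
#' @param path TSV path.
#' @return K x 96 matrix with unit row sums.
#' @export
read_catalog <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lab <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  ctx <- sbs_contexts()
  if (all(lab %in% ctx)) {           # contexts in rows (COSMIC layout)
    rownames(mat) <- lab
    mat <- t(mat[ctx, , drop = FALSE])
  } else {                           # signatures in rows
    rownames(mat) <- lab
    if (!all(ctx %in% colnames(mat)))
      stop("catalog columns do not match the 96 canonical contexts")
    mat <- mat[, ctx, drop = FALSE]
  }
  storage.mode(mat) <- "double"
  sums <- rowSums(mat)
  if (any(abs(sums - 1) > 1e-6)) mat <- mat / sums
  mat
}

#' Write a signature catalog TSV (signatures in rows)
#' @param catalog K x 96 matrix.
#' @param path output path.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(signature = rownames(catalog), catalog,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
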