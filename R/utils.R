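# internal helpers shared across modules

# weighted median of integer values; exact half-mass ties broken toward `tie_to`
weighted_median <- function(x, w, tie_to = 2) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  half <- sum(w) / 2
  i <- which(cw >= half)[1L]
  if (isTRUE(all.equal(cw[i], half)) && i < length(x)) {
    cand <- c(x[i], x[i + 1L])
    return(cand[which.min(abs(cand - tie_to))])
  }
  x[i]
}

# deterministic pseudo-random stream (LCG) used only to build the bundled
# signature catalog, so package data never touches the user's RNG
lcg_stream <- function(n, seed) {
  m <- 2147483647; a <- 48271
  s <- (seed %% m)
  if (s == 0) s <- 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (a * s) %% m
    out[i] <- s / m
  }
  out
}

# run an expression with a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# derive a sub-seed stream from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_missing_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
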