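# shared fixtures, memoized so expensive objects are built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small two-cohort bundle for fast structural tests
small_bundle <- function() {
  cached("small", simulate_cohorts(sim_config(n_a = 30, n_b = 30, seed = 101,
                                              n_genes = 320)))
}

# full-size bundle at the default study conditions
default_bundle <- function() {
  cached("default", simulate_cohorts(sim_config(seed = 7)))
}

with_seed_local <- function(seed, expr) withr::with_seed(seed, expr)

# brute-force Harrell's c over all ordered pairs, written independently of
# concordance_index (vectorized outer comparisons rather than a loop)
cindex_oracle <- function(risk, time, event) {
  shorter <- outer(time, time, "<")                       # i fails before j
  comparable <- shorter & matrix(event == 1, length(time), length(time))
  conc <- sum(comparable & outer(risk, risk, ">")) +
    0.5 * sum(comparable & outer(risk, risk, "=="))
  conc / sum(comparable)
}

# two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; n1 <- a + c; tot <- a + b + c + d
  lo <- max(0, n1 - (tot - m1)); hi <- min(m1, n1)
  probs <- dhyper(lo:hi, m1, tot - m1, n1)
  p_obs <- dhyper(a, m1, tot - m1, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# grid-search deviance oracle for the CCF estimator
ccf_grid_oracle <- function(alt, depth, purity, cn_normal = 2, cn_mutation = 2,
                            step = 1e-3) {
  grid <- seq(0, 1, by = step)
  vaf <- purity * grid / (cn_normal * (1 - purity) + purity * cn_mutation)
  vaf <- pmin(pmax(vaf, 1e-12), 1 - 1e-12)
  dev <- -2 * dbinom(alt, depth, vaf, log = TRUE)
  grid[which.min(dev)]
}

# adjusted Rand index for label-recovery checks
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# planted 3-block nonnegative expression matrix for NMF tests
planted_blocks <- function(n_per = 20, n_genes = 150, shift = 2, seed = 5,
                           n_blocks = 3) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_blocks * n_per, 5, 1), n_genes, n_blocks * n_per)
  gsz <- floor(n_genes / (2 * n_blocks))
  for (b in seq_len(n_blocks)) {
    rows <- ((b - 1) * gsz + 1):(b * gsz)
    cols <- ((b - 1) * n_per + 1):(b * n_per)
    m[rows, cols] <- m[rows, cols] + shift
  }
  dimnames(m) <- list(sprintf("G%04d", seq_len(n_genes)),
                      sprintf("S%03d", seq_len(n_blocks * n_per)))
  list(expr = pmax(m, 0), labels = rep(seq_len(n_blocks), each = n_per))
}
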