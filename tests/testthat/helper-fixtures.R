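# build a genotype_matrix directly from a dosage matrix
make_genotypes <- function(dosages, chrom = "1", pos = NULL, ids = NULL,
                           sex = NULL) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 10000L
  if (is.null(ids)) ids <- sprintf("rs%05d", seq_len(m))
  if (is.null(sex)) sex <- rep(c("male", "female"),
                               length.out = nrow(dosages))
  structure(list(
    dosages = dosages,
    variants = data.frame(id = ids, chrom = rep_len(chrom, m), pos = pos,
                          a1 = "A", a2 = "G",
                          freq = colMeans(dosages) / 2,
                          block = seq_len(m), stringsAsFactors = FALSE),
    sex = sex), class = "genotype_matrix")
}

# minimal sumstats from a z vector
make_sumstats <- function(z, n = 10000, pos = NULL, chrom = "1",
                          freq = 0.3, a1 = "A", a2 = "G", beta_scale = 0.1,
                          ids = NULL, ...) {
  m <- length(z)
  if (is.null(pos)) pos <- seq_len(m) * 10000L
  if (is.null(ids)) ids <- sprintf("rs%05d", seq_len(m))
  se <- rep_len(beta_scale, m)
  sumstats(data.frame(
    id = ids, chrom = rep_len(chrom, m), pos = pos,
    a1 = rep_len(a1, m), a2 = rep_len(a2, m), freq = rep_len(freq, m),
    beta = z * se, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)), n = rep_len(n, m),
    stringsAsFactors = FALSE), ...)
}

# dosage columns with a target pairwise correlation structure:
# col j = sqrt(r2) * base + sqrt(1 - r2) * noise, mapped to [0, 2]
make_correlated_dosages <- function(n, r2_to_first, seed = 1) {
  set.seed(seed)
  base <- stats::rnorm(n)
  X <- vapply(r2_to_first, function(r2) {
    r <- sqrt(r2)
    r * base + sqrt(1 - r2) * stats::rnorm(n)
  }, numeric(n))
  1 + X / max(abs(X))      # affine map into (0, 2): correlations unchanged
}

# standard small LD panel + liability phenotypes for reuse
sim_small_study <- function(n = 5000, blocks = 50, block_size = 10,
                            rho = 0.5, h2 = 0.2, K = 0.09, seed = 1,
                            ...) {
  G <- simulate_ld_reference(n = n, blocks = blocks,
                             block_size = block_size, rho = rho,
                             maf_range = c(0.1, 0.5), seed = seed)
  p <- liability_params(h2_liab = h2, K_m = K, K_f = K,
                        seed = seed + 1000L, ...)
  phen <- simulate_liability_phenotypes(G, p)
  list(G = G, phen = phen, params = p)
}

# mr_instruments builder for estimator tests
make_instruments <- function(beta_exp, beta_out, se_exp = 0.02,
                             se_out = 0.02, n_exp = 5e4, n_out = 5e4) {
  k <- length(beta_exp)
  out <- data.frame(
    id = paste0("iv", seq_len(k)),
    beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
    beta_out = beta_out, se_out = rep_len(se_out, k),
    n_exp = rep_len(n_exp, k), n_out = rep_len(n_out, k),
    z_exp = beta_exp / rep_len(se_exp, k),
    z_out = beta_out / rep_len(se_out, k),
    reason = "kept", stringsAsFactors = FALSE)
  class(out) <- c("mr_instruments", "data.frame")
  out
}
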