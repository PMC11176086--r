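test_that("LD scores match closed-form expectations", {
  # independent variants: ld score ~ 1 after the small-sample adjustment
  G0 <- simulate_ld_reference(n = 4000, blocks = 50, block_size = 1,
                              rho = 0, maf_range = c(0.2, 0.4), seed = 1)
  sc0 <- compute_ld_scores(G0)
  expect_equal(mean(sc0$ldscore), 1, tolerance = 0.02)

  # a block of m identical columns has ld score m
  set.seed(2)
  col <- rbinom(3000, 2, 0.3)
  Gd <- make_genotypes(cbind(col, col, col, col))
  scd <- compute_ld_scores(Gd)
  expect_equal(scd$ldscore, rep(4, 4), tolerance = 1e-6)

  # AR(1) interior variant: ell ~ 1 + 2 rho^2 / (1 - rho^2)
  rho <- 0.6
  G1 <- simulate_ld_reference(n = 20000, blocks = 40, block_size = 11,
                              rho = rho, maf_range = c(0.25, 0.35), seed = 3)
  sc1 <- compute_ld_scores(G1, window_kb = 2000)
  interior <- which(seq_len(440) %% 11 == 6)   # middle of each block
  expect_equal(mean(sc1$ldscore[interior]),
               1 + 2 * rho^2 / (1 - rho^2), tolerance = 0.05)

  expect_error(compute_ld_scores(make_genotypes(matrix(0:1, 2, 3))),
               "at least 3")
})

test_that("two-step regression algebra: constant chi2 shift moves only the intercept", {
  set.seed(4)
  study <- sim_small_study(n = 8000, blocks = 100, seed = 5)
  ss <- run_single_snp_gwas(study$G, study$phen)
  sc <- compute_ld_scores(study$G)
  h <- ldsc_h2(ss, sc, weight_iters = 1)
  ss_shift <- ss
  shift <- 0.5
  ss_shift$z <- sqrt(ss$z^2 + shift) * sign(ss$z)
  ss_shift$p <- 2 * pnorm(-abs(ss_shift$z))
  ss_shift$beta <- ss_shift$z * ss_shift$se
  h2 <- ldsc_h2(ss_shift, sc, weight_iters = 1)
  expect_equal(h2$intercept, h$intercept + shift, tolerance = 1e-6)
  expect_equal(h2$h2_obs, h$h2_obs, tolerance = 1e-6)
})

test_that("a null trait yields h2 near 0 and intercept near 1", {
  study <- sim_small_study(n = 10000, blocks = 100, h2 = 0, seed = 6)
  ss <- run_single_snp_gwas(study$G, study$phen)
  sc <- compute_ld_scores(study$G)
  h <- ldsc_h2(ss, sc)
  expect_lt(abs(h$h2_obs), 2 * h$h2_se)
  expect_lt(abs(h$intercept - 1), 2 * h$intercept_se)
  expect_error(ldsc_h2(ss, transform(sc, ldscore = 1)), "constant")
})

test_that("population stratification raises the intercept, not the slope", {
  G <- simulate_ld_reference(n = 15000, blocks = 100,
                             block_size = 10, rho = c(0, 0.3, 0.6, 0.9),
                             maf_range = c(0.1, 0.5), seed = 7, fst = 0.005)
  base <- liability_params(h2_liab = 0.1, seed = 8)
  strat <- liability_params(h2_liab = 0.1, strat_shift = 0.3, seed = 8)
  sc <- compute_ld_scores(G)
  h0 <- ldsc_h2(run_single_snp_gwas(G, simulate_liability_phenotypes(G, base)), sc)
  h1 <- ldsc_h2(run_single_snp_gwas(G, simulate_liability_phenotypes(G, strat)), sc)
  expect_gt(h1$intercept, h0$intercept)
  # the slope-based h2 moves less than a naive mean-chi2 estimator would
  naive0 <- (h0$mean_chi2 - 1) * h0$M / h0$N
  naive1 <- (h1$mean_chi2 - 1) * h1$M / h1$N
  expect_lt(abs(h1$h2_obs - h0$h2_obs), abs(naive1 - naive0))
})

test_that("liability transform matches closed forms and is well behaved", {
  expect_equal(liability_transform(0, 0.09, 0.27), 0)
  expect_equal(liability_transform(1, 0.5, 0.5), pi / 2, tolerance = 1e-6)
  # independent numeric evaluation at K = 0.09, P = 0.27
  K <- 0.09; P <- 0.27
  mult <- K^2 * (1 - K)^2 / (P * (1 - P) * dnorm(qnorm(1 - K))^2)
  expect_equal(liability_transform(1, K, P), mult, tolerance = 1e-12)
  # linear in h2_obs
  expect_equal(liability_transform(0.4, K, P),
               2 * liability_transform(0.2, K, P), tolerance = 1e-12)
  # continuous in K (numeric derivative stays bounded)
  eps <- 1e-6
  d1 <- (liability_transform(1, K + eps, P) -
           liability_transform(1, K - eps, P)) / (2 * eps)
  d2 <- (liability_transform(1, K + 2 * eps, P) -
           liability_transform(1, K - 2 * eps, P)) / (4 * eps)
  expect_equal(d1, d2, tolerance = 1e-3)
  expect_error(liability_transform(0.5, 0, 0.5))
})

test_that("genetic correlation recovers truth for shared architectures", {
  # two traits with effect correlation ~ 0.7 on one panel, plus
  # self-correlation and independence checks
  G <- simulate_ld_reference(n = 12000, blocks = 100, block_size = 10,
                             rho = c(0, 0.3, 0.6, 0.9),
                             maf_range = c(0.1, 0.5), seed = 9)
  sc <- compute_ld_scores(G)
  m <- ncol(G$dosages)
  mk <- function(eff, seed) {
    p <- liability_params(h2_liab = 0.3, seed = seed)
    run_single_snp_gwas(
      G, simulate_liability_phenotypes(G, p, effects = eff),
      trait = "liability")
  }
  # three replicate trait pairs per architecture; test the mean estimate
  rgs <- sapply(1:3, function(r) {
    set.seed(10 + r)
    e1 <- rnorm(m)
    e2 <- 0.7 * e1 + sqrt(1 - 0.49) * rnorm(m)
    e3 <- rnorm(m)
    s1 <- mk(e1, 20 + r); s2 <- mk(e2, 40 + r); s3 <- mk(e3, 60 + r)
    c(self = ldsc_rg(s1, s1, sc)$rg,
      shared = ldsc_rg(s1, s2, sc)$rg,
      shared_se = ldsc_rg(s1, s2, sc)$se,
      indep = ldsc_rg(s1, s3, sc)$rg)
  })
  expect_lt(abs(mean(rgs["self", ]) - 1), 0.05)
  se_mean <- mean(rgs["shared_se", ]) / sqrt(3)
  expect_lt(abs(mean(rgs["shared", ]) - 0.7), 2.5 * se_mean)
  expect_lt(abs(mean(rgs["indep", ])), 0.2)
})

test_that("liability-scale recovery holds across an h2-by-prevalence grid", {
  # one panel reused across the grid; phenotypes and effects are redrawn
  G <- simulate_ld_reference(n = 20000, blocks = 500, block_size = 4,
                             rho = c(0, 0.5, 0.8, 0.9),
                             maf_range = c(0.1, 0.5), seed = 71)
  ref <- make_genotypes(G$dosages[1:4000, ], sex = G$sex[1:4000])
  ref$variants <- G$variants
  sc <- compute_ld_scores(ref, window_kb = 1000)
  grid <- expand.grid(h2 = c(0.1, 0.2, 0.3), K = c(0.05, 0.09))
  errs <- unlist(lapply(seq_len(nrow(grid)), function(g) {
    vapply(1:10, function(r) {
      p <- liability_params(h2_liab = grid$h2[g], K_m = grid$K[g],
                            K_f = grid$K[g], seed = 100 * g + r,
                            m_causal = 2000)
      ph <- simulate_liability_phenotypes(G, p)
      ss <- run_single_snp_gwas(G, ph)
      h <- ldsc_h2(ss, sc, M = 2000, K = grid$K[g],
                   P = mean(ph$case_status))
      abs(h$h2_liab - grid$h2[g])
    }, numeric(1))
  }))
  expect_lt(median(errs), 0.05)
})

test_that("two-sample and one-sample Z-tests match the normal tail", {
  eq <- estimate_diff_ztest(0.2, 0.05, 0.2, 0.05)
  expect_equal(eq$z, 0); expect_equal(eq$p, 1)
  # est vs 0 with a degenerate second se reduces to est/se
  expect_equal(estimate_diff_ztest(0.5, 0.25, 0, 1e-12)$z, 2,
               tolerance = 1e-6)
  expect_equal(estimate_diff_ztest(0.5, 0.25, 0, 1e-12)$p, 0.0455,
               tolerance = 1e-3)
  v1 <- estimate_diff_ztest(1.3, 0.15, kind = "vs_one")
  expect_equal(v1$z, 2, tolerance = 1e-9)
})

test_that("chromosome X heritability algebra and error states", {
  expect_equal(xchr_h2(1, 1e5, 1000)$h2, 0)
  expect_equal(xchr_h2(1.35, 1e5, 1000)$h2, 0.0035, tolerance = 1e-12)
  neg <- xchr_h2(0.9, 1e5, 1000)
  expect_lt(neg$h2, 0)
  expect_identical(neg$flag, "negative")
  expect_error(xchr_rg(rnorm(100) * 0.1, rnorm(100)), "exceed 1")
})

test_that("X-linked simulation recovers h2 and split-half rg near 1", {
  # one X-linked trait measured in two random halves of one population
  G <- simulate_ld_reference(n = 16000, blocks = 60, block_size = 10,
                             rho = c(0.2, 0.5, 0.8), maf_range = c(0.1, 0.5),
                             seed = 14, chrom = "X")
  p <- liability_params(h2_liab = 0.3, seed = 15)
  ph <- simulate_liability_phenotypes(G, p)
  set.seed(16)
  half <- sample(c(TRUE, FALSE), 16000, replace = TRUE)
  sub <- function(sel) make_genotypes(G$dosages[sel, ], chrom = "X",
                                      sex = G$sex[sel])
  ssa <- run_single_snp_gwas(sub(half), ph[half, ], trait = "liability")
  ssb <- run_single_snp_gwas(sub(!half), ph[!half, ], trait = "liability")
  sc <- compute_ld_scores(G, window_kb = 2000)
  meff <- effective_m(sc)
  h <- xchr_h2(mean(ssa$z^2, na.rm = TRUE), mean(ssa$n), meff)
  # observed-scale truth for a quantitative liability trait is h2_liab
  expect_lt(abs(h$h2 - 0.3), 0.1)
  rg <- xchr_rg(ssa$z, ssb$z)
  expect_gt(rg$rg, 0.85)

  # genetically independent traits on the same panel: rg ~ 0
  p2 <- liability_params(h2_liab = 0.3, seed = 17)
  set.seed(18)
  ph2 <- simulate_liability_phenotypes(G, p2, effects = rnorm(600))
  ssc <- run_single_snp_gwas(sub(half), ph2[half, ], trait = "liability")
  rg0 <- xchr_rg(ssa$z, ssc$z)
  expect_lt(abs(rg0$rg), 0.25)
})

test_that("heritability reports serialize to a readable TSV row", {
  study <- sim_small_study(n = 4000, blocks = 60, seed = 99)
  ss <- run_single_snp_gwas(study$G, study$phen)
  sc <- compute_ld_scores(study$G)
  h <- ldsc_h2(ss, sc, K = 0.09, P = mean(study$phen$case_status))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_h2_report(h, path)
  d <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(d$H2_OBS, h$h2_obs, tolerance = 1e-9)
  expect_equal(d$INTERCEPT, h$intercept, tolerance = 1e-9)
})

test_that("LD scores round-trip through the TSV format", {
  sc <- data.frame(id = c("a", "b"), chrom = c("1", "X"), pos = c(1L, 2L),
                   ldscore = c(1.5, 2.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_scores(sc, path)
  expect_equal(read_ld_scores(path), sc)
})
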