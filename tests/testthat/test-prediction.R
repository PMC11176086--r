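test_that("PRS equals the brute-force weighted sum", {
  set.seed(1)
  n <- 100; m <- 216
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m,
                dimnames = list(NULL, paste0("w", 1:m)))
  wt <- data.frame(id = paste0("w", 1:m), weight = rnorm(m),
                   freq = rep(0.3, m))
  prs <- compute_prs(dos, wt)
  oracle <- numeric(n)
  for (i in 1:n) for (j in 1:m)
    oracle[i] <- oracle[i] + wt$weight[j] * dos[i, wt$id[j]]
  expect_equal(as.numeric(prs), oracle, tolerance = 1e-12)

  # degenerate cases
  wt0 <- wt; wt0$weight <- 0
  expect_equal(as.numeric(compute_prs(dos, wt0)), rep(0, n))
  expect_equal(as.numeric(compute_prs(matrix(2, 1, 1,
                                             dimnames = list(NULL, "s")),
                                      data.frame(id = "s", weight = 0.2))),
               0.4)
})

test_that("missing dosages impute to 2f and heavy missingness is flagged", {
  dos <- matrix(c(NA, 2, NA, NA), 2, 2,
                dimnames = list(NULL, c("a", "b")))
  wt <- data.frame(id = c("a", "b"), weight = c(1, 1),
                   freq = c(0.25, 0.4))
  prs <- compute_prs(dos, wt)
  expect_equal(as.numeric(prs), c(0.5 + 0.8, 2 + 0.8))
  expect_equal(attr(prs, "n_imputed"), 3L)
  expect_identical(attr(prs, "flagged"), c(TRUE, TRUE))
  expect_error(compute_prs(dos, data.frame(id = "zz", weight = 1)),
               "absent")
})

demo_table <- function() {
  data.frame(
    SEX = rep(c("male", "female"), each = 3),
    AGE_LO = rep(c(20, 40, 60), 2), AGE_HI = rep(c(40, 60, 80), 2),
    PROPORTION = c(0.18, 0.17, 0.15, 0.18, 0.17, 0.15),
    CUM_INCIDENCE = c(0.02, 0.05, 0.10, 0.04, 0.10, 0.18))
}

make_cohort <- function(n = 6000, seed = 2) {
  set.seed(seed)
  sex <- sample(rep(c("male", "female"), length.out = n))
  prs <- rnorm(n)
  liab <- 0.5 * prs + rnorm(n)
  case <- as.integer(liab > qnorm(0.7))
  age <- runif(n, 20, 80)
  onset <- ifelse(case == 1, pmin(age, runif(n, 10, 75)), NA)
  structure(data.frame(case_status = case, sex = sex, age = age,
                       onset_age = onset, prs = prs,
                       stringsAsFactors = FALSE),
            class = c("phenotype_table", "data.frame"))
}

test_that("resampling matches the demographic pyramid and incidence curve", {
  cohort <- make_cohort()
  dem <- demo_table()
  pop <- resample_population(cohort, dem, target_n = 1e5,
                             prs = cohort$prs, seed = 3)
  # age-sex pyramid: multinomial goodness of fit
  bin <- cut(pop$age, c(20, 40, 60, 80), right = FALSE)
  obs <- as.vector(table(pop$sex, bin))
  key <- expand.grid(sex = sort(unique(pop$sex)), bin = levels(bin))
  expected <- dem$PROPORTION[match(paste(key$sex, sub("\\[(\\d+),.*", "\\1", key$bin)),
                                   paste(dem$SEX, dem$AGE_LO))]
  gof <- chisq.test(obs, p = expected / sum(expected))
  expect_gt(gof$p.value, 0.01)
  # prevalence per stratum tracks the incidence curve
  for (s in seq_len(nrow(dem))) {
    sel <- pop$sex == dem$SEX[s] & pop$age >= dem$AGE_LO[s] &
      pop$age < dem$AGE_HI[s]
    K <- dem$CUM_INCIDENCE[s]
    tol <- qnorm(0.9995) * sqrt(K * (1 - K) / sum(sel))
    expect_lt(abs(mean(pop$case_status[sel]) - K), tol)
  }
  # onset never exceeds current age; folds partition everyone
  expect_true(all(pop$onset_age[pop$case_status == 1] <=
                    pop$age[pop$case_status == 1] + 1e-9))
  expect_true(all(pop$fold %in% 1:10))
})

test_that("the bundled synthetic demography table loads and resamples", {
  path <- system.file("extdata", "demography_synthetic.tsv",
                      package = "gwamakit")
  dem <- read_demography(path)
  expect_setequal(names(dem), c("SEX", "AGE_LO", "AGE_HI", "PROPORTION",
                                "CUM_INCIDENCE"))
  pop <- resample_population(make_cohort(2000), dem, 1000, seed = 12)
  expect_equal(nrow(pop), 1000L)
})

test_that("single-stratum demography draws only from that stratum", {
  cohort <- make_cohort(2000)
  dem <- data.frame(SEX = "female", AGE_LO = 40, AGE_HI = 60,
                    PROPORTION = 1, CUM_INCIDENCE = 0.1)
  pop <- resample_population(cohort, dem, 500, seed = 4)
  expect_true(all(pop$sex == "female"))
  expect_true(all(pop$age >= 40 & pop$age < 60))
  # empty stratum errors by name
  dem_bad <- data.frame(SEX = "other", AGE_LO = 0, AGE_HI = 10,
                        PROPORTION = 1, CUM_INCIDENCE = 0.1)
  expect_error(resample_population(cohort, dem_bad, 10, seed = 5), "other")
})

test_that("resampled PRS distribution matches the source per stratum", {
  cohort <- make_cohort(8000)
  pop <- resample_population(cohort, demo_table(), 4e4,
                             prs = cohort$prs, seed = 6)
  for (s in c("male", "female")) for (cls in 0:1) {
    a <- pop$prs[pop$sex == s & pop$case_status == cls]
    b <- cohort$prs[cohort$sex == s & cohort$case_status == cls]
    ks <- suppressWarnings(ks.test(a, b))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("five-year landmark labels follow the window rules", {
  pop <- data.frame(age = c(60, 70, 70, 70, 52),
                    onset_age = c(53, NA, 58, 62, NA))
  lab <- five_year_labels(pop, landmark_age = 55)
  idx <- attr(lab, "index")
  # onset at 58 (3 y after landmark) -> 1; onset at 62 (7 y after) -> 0
  expect_equal(lab[idx == 3], 1L)
  expect_equal(lab[idx == 4], 0L)
  # prevalent case (onset 53) excluded; early censoring (age 52) excluded
  expect_false(1 %in% idx)
  expect_false(5 %in% idx)
  # disease-free with full follow-up -> 0
  expect_equal(lab[idx == 2], 0L)
  expect_error(five_year_labels(pop, 200), "at risk")
})

test_that("classifier metrics match hand counts and the null", {
  # perfect separation makes the univariate OR refit degenerate (warns)
  perfect <- suppressWarnings(
    evaluate_classifier(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), n_boot = 0))
  expect_equal(perfect$auc, 1)
  hand <- evaluate_classifier(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0),
                              n_boot = 0)
  expect_equal(hand$auc, 0.75)
  set.seed(7)
  null <- evaluate_classifier(runif(1e4), rbinom(1e4, 1, 0.3), n_boot = 50)
  expect_gt(null$auc, 0.48); expect_lt(null$auc, 0.52)
  expect_error(evaluate_classifier(1:3, c(1, 1, 1)), "both classes")
})

test_that("interaction GLM recovers null and non-null coefficients", {
  set.seed(8)
  n <- 20000
  pop <- data.frame(prs = rnorm(n),
                    sex = sample(c("male", "female"), n, TRUE),
                    age = runif(n, 20, 80))
  pop$case_status <- rbinom(n, 1, plogis(-2 + 0.5 * pop$prs))
  f <- fit_interaction_glm(pop)
  cf <- f$coefficients
  inter <- grep(":", rownames(cf))
  expect_true(all(abs(cf[inter, 1]) < 2.6 * cf[inter, 2]))
  expect_lt(abs(cf["prs", 1] - 0.5), 2.6 * cf["prs", 2])

  # constant PRS is inestimable
  pop0 <- pop; pop0$prs <- 1
  expect_error(fit_interaction_glm(pop0), "constant")
})

test_that("OR per sd is exp(beta1 * sd) at the reference stratum", {
  set.seed(9)
  n <- 5000
  pop <- data.frame(prs = rnorm(n, 0, 2),
                    sex = sample(c("male", "female"), n, TRUE),
                    age = runif(n, 20, 80))
  pop$case_status <- rbinom(n, 1, plogis(-1.5 + 0.3 * pop$prs))
  f <- fit_interaction_glm(pop)
  o <- or_per_sd(f, sex = "male")
  expect_equal(o$or, exp(coef(f$fit)["prs"] * sd(pop$prs)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Nagelkerke formula matches hand evaluations and guards nesting", {
  expect_equal(nagelkerke_r2(-60, -50, 100),
               (1 - exp(-0.2)) / (1 - exp(-1.2)), tolerance = 1e-12)
  expect_equal(nagelkerke_r2(-5, -5, 50), 0)
  expect_equal(nagelkerke_r2(-5, 0, 50), 1)   # perfect model
  expect_error(nagelkerke_r2(-4, -5, 50), "nesting")
})

test_that("interaction share follows its floor rule", {
  expect_equal(interaction_variance_share(0.2, 0.2), 0)
  expect_equal(interaction_variance_share(0.22, 0.36),
               (0.36 - 0.22) / 0.36, tolerance = 1e-12)
  expect_warning(sh <- interaction_variance_share(0.3, 0.2), "floored")
  expect_equal(sh, 0)
  expect_error(interaction_variance_share(0.1, 0), "undefined")
})

test_that("cross-validated metrics are invariant to row order", {
  set.seed(10)
  n <- 3000
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + X[, 1]))
  m1 <- cv_evaluate(X, y, glm_learner(), folds = 5, seed = 11)
  perm <- sample.int(n)
  m2 <- cv_evaluate(X[perm, ], y[perm], glm_learner(), folds = 5,
                    seed = 11)
  expect_equal(m1$auc, m2$auc, tolerance = 1e-12)
  expect_equal(m1$nagelkerke, m2$nagelkerke, tolerance = 1e-12)
})
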