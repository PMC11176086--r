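#' Simulate an LD reference panel of genotype dosages
#'
#' Generates an individuals-by-variants dosage matrix with a block-diagonal
#' linkage-disequilibrium structure. Within a block, haplotype alleles follow
#' a first-order Markov "copy" process: the allele at variant \eqn{j+1} is a
#' copy of the allele at variant \eqn{j} with probability \code{rho} and a
#' fresh Bernoulli(MAF) draw otherwise, so the genotype correlation between
#' variants \eqn{j} and \eqn{k} of the same block is \eqn{\rho^{|j-k|}}
#' (an AR(1) profile) while marginal allele frequencies stay exact. Blocks
#' are mutually independent. The minor allele frequency is drawn once per
#' block from \code{maf_range} so that the within-block copy process keeps
#' the marginal frequency of every variant at the block MAF.
#'
#' On chromosome X (\code{chrom = "X"}), males carry a single haplotype and
#' their dosages are coded 0/2 (no dosage compensation), females 0/1/2.
#'
#' @param n Number of individuals (>= 2).
#' @param blocks Number of independent LD blocks.
#' @param block_size Variants per block (>= 1).
#' @param rho Adjacent-variant haplotype copying probability in [0, 1);
#'   a scalar or a vector recycled over blocks (variable LD strength
#'   across blocks widens the LD score distribution, as in real genomes).
#' @param maf_range Length-2 numeric interval in (0, 0.5]; block MAFs are
#'   drawn uniformly from it.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param chrom Chromosome label for all variants (default \code{"1"});
#'   \code{"X"} switches to sex-aware haploid male coding.
#' @param sex Optional character vector of length \code{n} with values
#'   \code{"male"}/\code{"female"}; defaults to an even random split.
#' @param bp_spacing Base-pair distance between consecutive variants
#'   (default 10000).
#' @param fst Optional differentiation between two equal-sized
#'   subpopulations: per variant, subpopulation allele frequencies are
#'   \eqn{f \pm \delta_j} with \eqn{\delta_j \sim N(0, fst\,f(1-f))},
#'   independent of local LD (default 0 = one panmictic population).
#'
#' @return An object of class \code{genotype_matrix}: a list with
#'   \code{dosages} (n x m integer matrix), \code{variants} (data.frame with
#'   id, chrom, pos, a1, a2, freq, block), \code{sex} and \code{subpop}
#'   (1/2 per individual).
#' @export
simulate_ld_reference <- function(n, blocks, block_size, rho, maf_range,
                                  seed = 1L, chrom = "1", sex = NULL,
                                  bp_spacing = 10000L, fst = 0) {
  stopifnot(n >= 2, block_size >= 1, blocks >= 1)
  if (length(maf_range) != 2 || diff(range(maf_range)) < 0 ||
      min(maf_range) <= 0 || max(maf_range) > 0.5)
    stop("'maf_range' must be a non-empty interval within (0, 0.5]")
  if (any(rho < 0) || any(rho >= 1)) stop("'rho' must be in [0, 1)")
  set.seed(seed)
  if (is.null(sex)) sex <- sample(rep(c("male", "female"), length.out = n))
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  is_x <- identical(chrom, "X")
  male <- sex == "male"

  m <- blocks * block_size
  dos <- matrix(0L, n, m)
  mafs <- stats::runif(blocks, maf_range[1], maf_range[2])
  rho_b <- rep_len(rho, blocks)
  subpop <- rep_len(1:2, n)
  fvar <- rep(mafs, each = block_size)
  if (fst > 0) {
    # per-variant drift between the two subpopulations, independent of LD
    delta <- stats::rnorm(m, 0, sqrt(fst * fvar * (1 - fvar)))
    fsub <- cbind(pmin(pmax(fvar + delta, 0.01), 0.99),
                  pmin(pmax(fvar - delta, 0.01), 0.99))
  } else {
    fsub <- cbind(fvar, fvar)
  }

  # all blocks of a chunk advance their copy chains in lock-step, so the
  # sequential loop is only over within-block offsets; one uniform per
  # entry: u < rho copies the previous allele, and conditional on no copy,
  # (u - rho)/(1 - rho) is again uniform(0,1) and supplies the fresh
  # Bernoulli(f) draw
  sim_chunk_haps <- function(n_hap, fmat, r_blocks) {
    nb <- nrow(fmat)
    rcol <- rep(r_blocks, each = n_hap)
    H <- matrix(0L, n_hap, nb * block_size)
    first <- seq(1L, nb * block_size, by = block_size)
    H[, first] <- as.integer(stats::runif(n_hap * nb) <
                               rep(fmat[, 1], each = n_hap))
    if (block_size > 1) for (k in 2:block_size) {
      cols <- first + (k - 1L)
      fcol <- rep(fmat[, k], each = n_hap)
      u <- stats::runif(n_hap * nb)
      val <- as.integer((u - rcol) / (1 - rcol) < fcol)
      copy <- u < rcol
      prev <- H[, cols - 1L, drop = FALSE]
      val[copy] <- prev[copy]
      H[, cols] <- val
    }
    H
  }

  chunk_blocks <- max(1L, ceiling(2e7 / (n * block_size)))
  for (cs in seq(1L, blocks, by = chunk_blocks)) {
    bset <- cs:min(blocks, cs + chunk_blocks - 1L)
    cols <- ((bset[1] - 1L) * block_size + 1L):(bset[length(bset)] * block_size)
    for (sp in 1:2) {
      fmat <- matrix(fsub[cols, sp], length(bset), block_size, byrow = TRUE)
      rows_sp <- subpop == sp
      if (!is_x) {
        dos[rows_sp, cols] <-
          sim_chunk_haps(sum(rows_sp), fmat, rho_b[bset]) +
          sim_chunk_haps(sum(rows_sp), fmat, rho_b[bset])
      } else {
        fem <- rows_sp & !male
        mal <- rows_sp & male
        dos[fem, cols] <- sim_chunk_haps(sum(fem), fmat, rho_b[bset]) +
          sim_chunk_haps(sum(fem), fmat, rho_b[bset])
        dos[mal, cols] <- 2L * sim_chunk_haps(sum(mal), fmat, rho_b[bset])
      }
    }
  }

  variants <- data.frame(
    id = sprintf("rs%05d", seq_len(m)),
    chrom = chrom,
    pos = as.integer(seq_len(m)) * bp_spacing,
    a1 = "A", a2 = "G",
    freq = rep(mafs, each = block_size),
    block = rep(seq_len(blocks), each = block_size),
    stringsAsFactors = FALSE
  )
  structure(list(dosages = dos, variants = variants, sex = sex,
                 subpop = subpop),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "variants on chromosome",
      paste(unique(x$variants$chrom), collapse = ","), "\n")
  invisible(x)
}

#' Liability-model simulation parameters
#'
#' Bundles the parameters of the liability-threshold phenotype generator:
#' liability-scale heritability, number of causal variants, sex-specific
#' population prevalences, an optional environmental exposure with a main
#' effect and sex-specific gene-by-environment interaction coefficients, and
#' an optional per-subpopulation stratification shift.
#'
#' The female-to-male interaction ratio \code{c_f / c_m} is the quantity the
#' gene-by-environment comparison module estimates.
#'
#' @param h2_liab Liability-scale heritability in [0, 1).
#' @param m_causal Number of causal variants.
#' @param K_m,K_f Male and female population prevalence in (0, 1).
#' @param exposure_kind One of \code{"none"}, \code{"binary"},
#'   \code{"continuous"}. Binary exposure is Bernoulli(q_sex); continuous is
#'   Normal(q_sex, 1).
#' @param q_m,q_f Exposure rate (binary) or mean (continuous) per sex.
#' @param c_E Main environmental effect on liability.
#' @param c_m,c_f Sex-specific interaction coefficients multiplying
#'   (genetic score x exposure).
#' @param strat_shift Optional liability offset applied to a random half of
#'   individuals (crude population stratification / confounding).
#' @param seed Integer seed used by [simulate_liability_phenotypes()].
#'
#' @return A list of class \code{liability_params}.
#' @export
liability_params <- function(h2_liab = 0.2, m_causal = NULL,
                             K_m = 0.09, K_f = 0.09,
                             exposure_kind = c("none", "binary", "continuous"),
                             q_m = 0, q_f = 0, c_E = 0, c_m = 0, c_f = 0,
                             strat_shift = 0, seed = 1L) {
  exposure_kind <- match.arg(exposure_kind)
  stopifnot(h2_liab >= 0, h2_liab < 1,
            K_m > 0, K_m < 1, K_f > 0, K_f < 1)
  structure(list(h2_liab = h2_liab, m_causal = m_causal, K_m = K_m, K_f = K_f,
                 exposure_kind = exposure_kind, q_m = q_m, q_f = q_f,
                 c_E = c_E, c_m = c_m, c_f = c_f,
                 strat_shift = strat_shift, seed = as.integer(seed)),
            class = "liability_params")
}

# expected mean / variance of the exposure for one sex
.exposure_moments <- function(kind, q) {
  switch(kind,
         none = c(mean = 0, var = 0),
         binary = c(mean = q, var = q * (1 - q)),
         continuous = c(mean = q, var = 1))
}

#' Simulate liability-threshold phenotypes on a genotype panel
#'
#' Constructs a latent liability
#' \deqn{L = a S + c_E E + c_{sex} (S \times E) + \epsilon,}
#' where \eqn{S} is the empirically standardized causal polygenic score,
#' \eqn{a = \sqrt{h^2_{liab}}}, \eqn{E} the exposure and \eqn{\epsilon}
#' Gaussian residual noise whose variance is chosen so the total liability
#' variance is 1 in expectation (within each sex; realized variance is
#' checked by tests, not forced). The liability is centred per sex at its
#' expected mean so that case status (liability above
#' \eqn{\Phi^{-1}(1 - K_{sex})}) has prevalence \eqn{K_{sex}}.
#'
#' Ages are drawn uniformly on [20, 80]; onset ages for prevalent cases come
#' from a truncated normal (mean 45, sd 15) further truncated at [5, age].
#'
#' @param G A \code{genotype_matrix}.
#' @param params A [liability_params()] object.
#' @param effects Optional per-causal-variant allelic effect sizes (recycled
#'   to \code{m_causal}); defaults to iid standard normal draws. Passing the
#'   same effects to two panels gives a shared architecture.
#' @param causal_idx Optional indices of causal variants; defaults to the
#'   first \code{m_causal} columns.
#'
#' @return A data.frame of class \code{phenotype_table} with columns
#'   \code{case_status}, \code{liability}, \code{genetic_score},
#'   \code{exposure}, \code{sex}, \code{age}, \code{onset_age} (NA for
#'   controls). Attributes \code{causal_idx} and \code{effects} record the
#'   realized architecture.
#' @export
simulate_liability_phenotypes <- function(G, params, effects = NULL,
                                          causal_idx = NULL) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(params, "liability_params"))
  n <- nrow(G$dosages)
  m <- ncol(G$dosages)
  m_causal <- if (is.null(params$m_causal)) m else params$m_causal
  if (m_causal > m) stop("m_causal exceeds the number of variants")
  set.seed(params$seed)
  if (is.null(causal_idx)) causal_idx <- seq_len(m_causal)
  if (is.null(effects)) effects <- stats::rnorm(m_causal)
  effects <- rep_len(effects, m_causal)

  raw <- as.vector(G$dosages[, causal_idx, drop = FALSE] %*% effects)
  sd_raw <- stats::sd(raw)
  S <- if (sd_raw > 0) (raw - mean(raw)) / sd_raw else raw * 0
  a <- sqrt(params$h2_liab)

  sex <- G$sex
  male <- sex == "male"
  q <- ifelse(male, params$q_m, params$q_f)
  E <- switch(params$exposure_kind,
              none = numeric(n),
              binary = stats::rbinom(n, 1L, q),
              continuous = stats::rnorm(n, q, 1))
  c_sex <- ifelse(male, params$c_m, params$c_f)

  # per-sex expected variance of the systematic part; residual tops up to 1
  liab <- numeric(n)
  resid_sd <- numeric(n)
  for (s in c("male", "female")) {
    idx <- sex == s
    if (!any(idx)) next
    mom <- .exposure_moments(params$exposure_kind,
                             if (s == "male") params$q_m else params$q_f)
    cs <- if (s == "male") params$c_m else params$c_f
    v_sys <- a^2 + params$c_E^2 * mom["var"] +
      cs^2 * (mom["var"] + mom["mean"]^2) +
      2 * a * cs * mom["mean"]
    if (v_sys >= 1)
      stop(sprintf(
        "systematic liability variance %.3f >= 1 for %s; shrink h2_liab or environmental effects",
        v_sys, s))
    resid_sd[idx] <- sqrt(1 - v_sys)
    # centre at the expected mean so the threshold matches the prevalence
    mu <- params$c_E * mom["mean"]
    liab[idx] <- a * S[idx] + params$c_E * E[idx] +
      cs * S[idx] * E[idx] - mu
  }
  liab <- liab + stats::rnorm(n, 0, resid_sd)
  if (params$strat_shift != 0) {
    # confounding: liability differs between the panel's subpopulations
    sp <- if (!is.null(G$subpop)) G$subpop else rep_len(1:2, n)
    liab <- liab + params$strat_shift * (sp == 2) - params$strat_shift / 2
  }

  thr <- ifelse(male, stats::qnorm(1 - params$K_m), stats::qnorm(1 - params$K_f))
  case <- as.integer(liab > thr)
  age <- stats::runif(n, 20, 80)
  onset <- rep(NA_real_, n)
  ci <- which(case == 1L)
  if (length(ci)) onset[ci] <- .rtruncnorm(length(ci), 45, 15, 5, age[ci])

  out <- data.frame(case_status = case, liability = liab, genetic_score = S,
                    exposure = E, sex = sex, age = age, onset_age = onset,
                    stringsAsFactors = FALSE)
  attr(out, "causal_idx") <- causal_idx
  attr(out, "effects") <- effects
  class(out) <- c("phenotype_table", "data.frame")
  out
}

# truncated normal via inverse-CDF; vectorized bounds
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  hi <- pmax(hi, lo + 1e-8)
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Per-variant association scan (single-SNP GWAS)
#'
#' Runs an additive-model association test of each variant against the
#' phenotype with covariate adjustment. For binary case status the standard
#' GWAS score test is used: a covariate-only logistic null model is fitted
#' once, dosages are residualized against the covariates under the null
#' weights, and per-variant score statistics give Z, an effect estimate
#' \eqn{\hat\beta = U/V} and \eqn{se = 1/\sqrt{V}}. For quantitative
#' phenotypes (the latent liability) exact least-squares algebra is used on
#' covariate-residualized phenotype and dosages.
#'
#' Monomorphic variants are flagged (all association fields NA,
#' \code{flag = "monomorphic"}) rather than silently dropped.
#'
#' @param G A \code{genotype_matrix}.
#' @param phen A \code{phenotype_table} (or any data.frame with the needed
#'   column).
#' @param covariates Optional numeric matrix/data.frame of covariates
#'   (an intercept is always included; sex is not added automatically).
#' @param trait Column of \code{phen} to analyse: \code{"case_status"}
#'   (logistic score test) or \code{"liability"} (linear model).
#' @param cohort,sex_stratum Labels stored on the output.
#'
#' @return A \code{sumstats} data.frame (see [sumstats()]).
#' @export
run_single_snp_gwas <- function(G, phen, covariates = NULL,
                                trait = c("case_status", "liability"),
                                cohort = "sim", sex_stratum = "pooled") {
  stopifnot(inherits(G, "genotype_matrix"))
  trait <- match.arg(trait)
  y <- phen[[trait]]
  n <- length(y)
  stopifnot(n == nrow(G$dosages))
  X <- G$dosages
  binary <- trait == "case_status"
  if (binary && (sum(y == 1L) < 2 || sum(y == 0L) < 2))
    stop("need at least 2 cases and 2 controls")

  C <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) C <- cbind(C, as.matrix(covariates))

  if (binary) {
    null_fit <- stats::glm.fit(C, y, family = stats::binomial())
    p0 <- null_fit$fitted.values
    w <- p0 * (1 - p0)
    # residualize each dosage column against covariates under null weights
    CW <- C * w
    M <- solve(crossprod(C, CW), t(CW))      # q x n projector core
    Xres <- X - C %*% (M %*% X)
    U <- as.vector(crossprod(X, y - p0))
    V <- as.vector(colSums(Xres^2 * w))
    ok <- V > 1e-12
    beta <- ifelse(ok, U / V, NA_real_)
    se <- ifelse(ok, 1 / sqrt(V), NA_real_)
  } else {
    Mc <- solve(crossprod(C), t(C))
    yres <- y - C %*% (Mc %*% y)
    Xres <- X - C %*% (Mc %*% X)
    sxx <- colSums(Xres^2)
    ok <- sxx > 1e-12
    beta <- as.vector(crossprod(Xres, yres)) / ifelse(ok, sxx, NA_real_)
    df <- n - ncol(C) - 1
    rss <- sum(yres^2) - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / df / sxx)
    se[!ok] <- NA_real_
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  fr <- colMeans(X) / 2
  out <- data.frame(
    id = G$variants$id, chrom = G$variants$chrom, pos = G$variants$pos,
    a1 = G$variants$a1, a2 = G$variants$a2, freq = fr,
    beta = beta, se = se, z = z, p = p,
    n = n,
    n_case = if (binary) sum(y == 1L) else NA_integer_,
    n_control = if (binary) sum(y == 0L) else NA_integer_,
    flag = ifelse(ok, "", "monomorphic"),
    stringsAsFactors = FALSE
  )
  sumstats(out, cohort = cohort, sex_stratum = sex_stratum)
}
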