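#' Specification of a sex-stratified gene-environment simulation model
#'
#' @param model One of \code{"no_gxe"}, \code{"gxe_binary"},
#'   \code{"gxe_continuous"}. \code{no_gxe} forces c_m = c_f = 0.
#' @param params Base [liability_params()]; its exposure kind is overridden
#'   to match \code{model}.
#' @param n_per_sex Individuals simulated per sex.
#' @param m_variants Number of variants on the panel.
#' @param replicates Replicate count for repeated simulation.
#' @return list of class \code{gxe_model_spec}.
#' @export
gxe_model_spec <- function(model = c("no_gxe", "gxe_binary", "gxe_continuous"),
                           params = liability_params(),
                           n_per_sex = 20000, m_variants = 1000,
                           replicates = 1) {
  model <- match.arg(model)
  params$exposure_kind <- switch(model, no_gxe = params$exposure_kind,
                                 gxe_binary = "binary",
                                 gxe_continuous = "continuous")
  if (model == "no_gxe") { params$c_m <- 0; params$c_f <- 0 }
  structure(list(model = model, params = params, n_per_sex = n_per_sex,
                 m_variants = m_variants, replicates = replicates),
            class = "gxe_model_spec")
}

# simulate one sex-stratified study on a (possibly pre-built) panel and
# return per-sex sumstats; shared architecture = shared `effects`
.simulate_strata <- function(spec, seed, panel = NULL, effects = NULL) {
  p <- spec$params
  m <- spec$m_variants
  if (is.null(panel)) {
    panel <- simulate_ld_reference(
      n = 2 * spec$n_per_sex, blocks = max(1, m %/% 10), block_size = 10,
      rho = 0.5, maf_range = c(0.1, 0.5), seed = seed,
      sex = rep(c("male", "female"), each = spec$n_per_sex))
  }
  p$seed <- seed + 1L
  p$m_causal <- ncol(panel$dosages)
  if (is.null(effects)) {
    set.seed(seed + 2L)
    effects <- stats::rnorm(p$m_causal)
  }
  phen <- simulate_liability_phenotypes(panel, p, effects = effects)
  male <- panel$sex == "male"
  sub <- function(sel, stratum) {
    g <- structure(list(dosages = panel$dosages[sel, , drop = FALSE],
                        variants = panel$variants, sex = panel$sex[sel]),
                   class = "genotype_matrix")
    run_single_snp_gwas(g, phen[sel, , drop = FALSE],
                        sex_stratum = stratum)
  }
  list(male = sub(male, "male"), female = sub(!male, "female"),
       phen = phen, panel = panel)
}

#' Simulate a sex-stratified GWAS and estimate the heritability triple
#'
#' Generates a genotype panel shared between the sexes, applies sex-specific
#' exposure and interaction terms to a common polygenic architecture, runs a
#' per-sex association scan, and estimates observed-scale male and female
#' heritability and the cross-sex genetic correlation. Estimation uses
#' either full LD score regression ([ldsc_h2()] / [ldsc_rg()]) or the fast
#' mean-chi-squared / Z-product estimators ([xchr_h2()] / [xchr_rg()]).
#'
#' @param spec A [gxe_model_spec()].
#' @param seed Integer seed.
#' @param estimator "ldsc" or "mean_chi2".
#' @param scores Optional precomputed LD scores (saves time across calls).
#' @param panel,effects Optional pre-built panel / architecture.
#' @return list(male, female, h2_m, h2_m_se, h2_f, h2_f_se, rg, rg_se).
#'   With the mean_chi2 estimator the ses are NA.
#' @export
simulate_sex_stratified_study <- function(spec, seed = 1L,
                                          estimator = c("ldsc", "mean_chi2"),
                                          scores = NULL, panel = NULL,
                                          effects = NULL) {
  estimator <- match.arg(estimator)
  sim <- .simulate_strata(spec, seed, panel = panel, effects = effects)
  if (is.null(scores)) {
    # LD scores from a subsample of the panel for speed
    nref <- min(nrow(sim$panel$dosages), 4000)
    ref <- structure(list(dosages = sim$panel$dosages[seq_len(nref), ,
                                                      drop = FALSE],
                          variants = sim$panel$variants,
                          sex = sim$panel$sex[seq_len(nref)]),
                     class = "genotype_matrix")
    scores <- compute_ld_scores(ref, window_kb = 2000)
  }
  if (estimator == "ldsc") {
    hm <- ldsc_h2(sim$male, scores, maf_min = 0)
    hf <- ldsc_h2(sim$female, scores, maf_min = 0)
    rg <- ldsc_rg(sim$male, sim$female, scores)
    out <- list(h2_m = hm$h2_obs, h2_m_se = hm$h2_se,
                h2_f = hf$h2_obs, h2_f_se = hf$h2_se,
                rg = rg$rg, rg_se = rg$se)
  } else {
    meff <- effective_m(scores)
    hm <- xchr_h2(mean(sim$male$z^2, na.rm = TRUE),
                  mean(sim$male$n), meff)
    hf <- xchr_h2(mean(sim$female$z^2, na.rm = TRUE),
                  mean(sim$female$n), meff)
    rg <- tryCatch(xchr_rg(sim$male$z, sim$female$z)$rg,
                   error = function(e) NA_real_)
    out <- list(h2_m = hm$h2, h2_m_se = NA_real_,
                h2_f = hf$h2, h2_f_se = NA_real_,
                rg = rg, rg_se = NA_real_)
  }
  c(list(male = sim$male, female = sim$female), out)
}

#' Observed summary triple for model comparison
#'
#' @param h2_m,h2_m_se,h2_f,h2_f_se,rg,rg_se The target male/female
#'   heritabilities and cross-sex genetic correlation with standard errors.
#' @return list of class \code{observed_summaries}.
#' @export
observed_summaries <- function(h2_m, h2_m_se, h2_f, h2_f_se, rg, rg_se) {
  stopifnot(h2_m_se > 0, h2_f_se > 0, rg_se > 0)
  structure(list(h2_m = h2_m, h2_m_se = h2_m_se, h2_f = h2_f,
                 h2_f_se = h2_f_se, rg = rg, rg_se = rg_se),
            class = "observed_summaries")
}

#' Approximate Bayesian computation model comparison
#'
#' For each candidate model, parameters are drawn from uniform priors,
#' a sex-stratified study is simulated (one shared genotype panel per run,
#' fast mean-chi-squared summaries), and a draw is accepted when the
#' standardized distance
#' \deqn{d = \sqrt{\sum_s \left((T_s - T_s^{obs})/se_s^{obs}\right)^2}}
#' over the triple (h2_m, h2_f, rg) falls below \code{tolerance}. The
#' marginal likelihood of a model is approximated by its acceptance rate
#' (the kernel mass is common across models and cancels in Bayes factors);
#' models with zero acceptances are floored at 1/(n_draws + 1) and flagged.
#'
#' @param obs An [observed_summaries()] triple.
#' @param models Named list (>= 2) of [gxe_model_spec()] objects.
#' @param priors Named list of c(lo, hi) prior ranges for any of
#'   \code{h2_liab, c_E, c_m, c_f, q}; parameters not listed stay at the
#'   spec's values. \code{q} sets both q_m and q_f.
#' @param n_draws Prior draws per model (>= 100).
#' @param tolerance Acceptance distance; if NULL, the 10% quantile of the
#'   pooled simulated distances (shared across models).
#' @param seed Integer seed; identical seeds give identical accepted sets.
#' @return Object of class \code{abc_comparison}: per-model acceptance
#'   counts, log marginal likelihoods, log10 Bayes factors vs the first
#'   model (with Monte-Carlo se), accepted parameter draws.
#' @export
abc_model_comparison <- function(obs, models, priors = list(),
                                 n_draws = 500, tolerance = NULL,
                                 seed = 1L) {
  stopifnot(inherits(obs, "observed_summaries"),
            length(models) >= 2, n_draws >= 100)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, character(1), "model")

  draws <- list(); dists <- list()
  for (mi in seq_along(models)) {
    spec <- models[[mi]]
    set.seed(seed + 1000L * mi)
    # one shared panel per model keeps per-draw cost at the phenotype step
    panel <- simulate_ld_reference(
      n = 2 * spec$n_per_sex, blocks = max(1, spec$m_variants %/% 10),
      block_size = 10, rho = 0.5, maf_range = c(0.1, 0.5),
      seed = seed + 1000L * mi,
      sex = rep(c("male", "female"), each = spec$n_per_sex))
    nref <- min(nrow(panel$dosages), 4000)
    scores <- compute_ld_scores(structure(
      list(dosages = panel$dosages[seq_len(nref), , drop = FALSE],
           variants = panel$variants, sex = panel$sex[seq_len(nref)]),
      class = "genotype_matrix"), window_kb = 2000)
    par_draws <- matrix(NA_real_, n_draws, 5,
                        dimnames = list(NULL,
                                        c("h2_liab", "c_E", "c_m", "c_f", "q")))
    dvec <- numeric(n_draws)
    for (it in seq_len(n_draws)) {
      p <- spec$params
      for (nm in names(priors)) {
        val <- stats::runif(1, priors[[nm]][1], priors[[nm]][2])
        if (nm == "q") { p$q_m <- val; p$q_f <- val }
        else p[[nm]] <- val
      }
      if (spec$model == "no_gxe") { p$c_m <- 0; p$c_f <- 0 }
      par_draws[it, ] <- c(p$h2_liab, p$c_E, p$c_m, p$c_f, p$q_f)
      sp <- spec; sp$params <- p
      sm <- tryCatch(
        simulate_sex_stratified_study(sp, seed = seed + 1000L * mi + it,
                                      estimator = "mean_chi2",
                                      scores = scores, panel = panel),
        error = function(e) NULL)
      dvec[it] <- if (is.null(sm) || !is.finite(sm$rg)) Inf else
        sqrt(((sm$h2_m - obs$h2_m) / obs$h2_m_se)^2 +
               ((sm$h2_f - obs$h2_f) / obs$h2_f_se)^2 +
               ((sm$rg - obs$rg) / obs$rg_se)^2)
    }
    draws[[mi]] <- par_draws
    dists[[mi]] <- dvec
  }
  if (is.null(tolerance))
    tolerance <- stats::quantile(unlist(dists)[is.finite(unlist(dists))],
                                 0.1)
  acc <- lapply(dists, function(d) d < tolerance)
  n_acc <- vapply(acc, sum, integer(1))
  lik <- pmax(n_acc, 0) / n_draws
  floored <- lik == 0
  lik[floored] <- 1 / (n_draws + 1)
  log10_bf <- log10(lik) - log10(lik[1])
  # binomial MC se on log10 scale (delta method)
  mc_se <- sqrt(pmax(lik * (1 - lik), 1 / n_draws^2) / n_draws) /
    (lik * log(10))
  structure(list(models = names(models), n_draws = n_draws,
                 tolerance = unname(tolerance), n_accepted = n_acc,
                 log_marginal = log(lik), log10_bf = log10_bf,
                 mc_se_log10 = mc_se, floored = floored,
                 accepted_draws = lapply(seq_along(models), function(i)
                   draws[[i]][acc[[i]], , drop = FALSE]),
                 distances = dists, seed = seed),
            class = "abc_comparison")
}

#' @export
print.abc_comparison <- function(x, ...) {
  cat("ABC model comparison (", x$n_draws, "draws/model, tolerance",
      sprintf("%.3f", x$tolerance), ")\n")
  for (i in seq_along(x$models))
    cat(sprintf("  %-16s accepted %4d  log10 BF vs %s: %+.3f%s\n",
                x$models[i], x$n_accepted[i], x$models[1],
                x$log10_bf[i], if (x$floored[i]) " [floored]" else ""))
  invisible(x)
}

#' Posterior ratio of female to male interaction coefficients
#'
#' From the accepted draws of the winning (or a chosen) model, the ratio
#' c_f / c_m is summarized by its posterior median and a percentile
#' interval. When the accepted posterior puts mass on c_m = 0 the ratio is
#' unbounded and a one-sided lower bound on c_f / c_m is reported instead.
#'
#' @param comparison An \code{abc_comparison}.
#' @param model Model name or index (default: highest acceptance count).
#' @param level Interval level (default 0.95).
#' @return list(kind = "ratio"/"one_sided", ratio, ci / lower).
#' @export
estimate_rgxe_ratio <- function(comparison, model = NULL, level = 0.95) {
  stopifnot(inherits(comparison, "abc_comparison"))
  i <- if (is.null(model)) which.max(comparison$n_accepted)
       else if (is.character(model)) match(model, comparison$models)
       else model
  d <- comparison$accepted_draws[[i]]
  if (!nrow(d)) stop("no accepted draws for model ", comparison$models[i])
  a <- (1 - level) / 2
  if (any(d[, "c_m"] == 0)) {
    pos <- d[d[, "c_m"] > 0, , drop = FALSE]
    lower <- if (nrow(pos)) unname(stats::quantile(
      pos[, "c_f"] / pos[, "c_m"], a)) else Inf
    return(list(kind = "one_sided", lower = lower,
                prop_cm_zero = mean(d[, "c_m"] == 0)))
  }
  r <- d[, "c_f"] / d[, "c_m"]
  list(kind = "ratio", ratio = unname(stats::median(r)),
       ci = unname(stats::quantile(r, c(a, 1 - a))), level = level)
}
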