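#' Age bin factor in 20-year bins
#' @param age Numeric ages.
#' @param width Bin width in years (default 20).
#' @return Factor of bins such as \code{[20,40)}.
#' @export
age_bins <- function(age, width = 20) {
  lo <- floor(min(age) / width) * width
  hi <- ceiling(max(age) / width + 1e-9) * width
  cut(age, seq(lo, hi, by = width), right = FALSE)
}

#' Fit the PRS x sex x age interaction logistic model
#'
#' Maximum-likelihood logistic regression of case status on PRS, sex, age
#' (as 20-year-bin dummies), all their pairwise interactions and the
#' three-way interaction, plus optional principal-component covariates:
#' \deqn{logit P(case) = \beta_0 + \beta_1 PRS + \beta_2 sex +
#'   \beta_3 age + \beta_4 PRS{\times}sex + \beta_5 PRS{\times}age +
#'   \beta_6 sex{\times}age + \beta_7 PRS{\times}sex{\times}age +
#'   \gamma PC.}
#' With more than two age bins each age term expands into one coefficient
#' per non-reference bin. Quasi-complete separation and inestimable terms
#' (e.g. a constant PRS) are rejected with a diagnostic.
#'
#' @param pop data.frame with case_status, prs, sex, age.
#' @param pcs Optional matrix of principal components (columns named or
#'   numbered PC1...).
#' @param age_width Age bin width (default 20).
#' @return Object of class \code{interaction_glm}: the glm fit plus a
#'   coefficient table and the model log-likelihood.
#' @export
fit_interaction_glm <- function(pop, pcs = NULL, age_width = 20) {
  d <- data.frame(y = pop$case_status,
                  prs = pop$prs,
                  sex = as.integer(pop$sex == "female"),
                  ageb = age_bins(pop$age, age_width))
  if (stats::sd(d$prs) == 0) stop("PRS is constant: effect inestimable")
  form <- y ~ prs * sex * ageb
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    d <- cbind(d, pcs)
    form <- stats::as.formula(paste("y ~ prs * sex * ageb +",
                                    paste(colnames(pcs), collapse = " + ")))
  }
  fit <- stats::glm(form, family = stats::binomial(), data = d)
  if (!fit$converged) stop("logistic fit did not converge")
  cf <- summary(fit)$coefficients
  if (any(!is.finite(cf[, 2])) || any(cf[, 2] > 100))
    stop("quasi-complete separation suspected: unstable standard errors")
  if (anyNA(stats::coef(fit)))
    stop("inestimable terms (aliased coefficients): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  structure(list(fit = fit, coefficients = cf,
                 logLik = as.numeric(stats::logLik(fit)),
                 n = nrow(d), prs_sd = stats::sd(d$prs)),
            class = "interaction_glm")
}

#' @export
print.interaction_glm <- function(x, ...) {
  cat("PRS x sex x age interaction logistic model (n =", x$n, ")\n")
  stats::printCoefmat(x$coefficients, digits = 3)
  invisible(x)
}

#' Odds ratio per PRS standard deviation from an interaction fit
#'
#' At the reference stratum (male, reference age bin) the OR per PRS sd is
#' \eqn{\exp(\beta_1 \cdot sd(PRS))}; other strata add the corresponding
#' interaction coefficients.
#'
#' @param fit An \code{interaction_glm}.
#' @param sex "male"/"female"; \code{age_bin} a level of the fitted age
#'   factor (default reference).
#' @param age_bin Age-bin level label or NULL for the reference bin.
#' @return list(or, log_or, se_log_or) on the per-sd scale.
#' @export
or_per_sd <- function(fit, sex = "male", age_bin = NULL) {
  cf <- stats::coef(fit$fit)
  V <- stats::vcov(fit$fit)
  sel <- "prs"
  if (sex == "female") sel <- c(sel, "prs:sex")
  if (!is.null(age_bin)) {
    ab <- paste0("prs:ageb", age_bin)
    sel <- c(sel, ab)
    if (sex == "female") sel <- c(sel, paste0("prs:sex:ageb", age_bin))
  }
  sel <- intersect(sel, names(cf))
  slope <- sum(cf[sel])
  se <- sqrt(sum(V[sel, sel]))
  list(or = exp(slope * fit$prs_sd), log_or = slope * fit$prs_sd,
       se_log_or = se * fit$prs_sd)
}

#' Nagelkerke's pseudo-R-squared between nested models
#'
#' \deqn{R^2 = \frac{1 - (L_0/L_1)^{2/N}}{1 - L_0^{2/N}}}
#' computed from log-likelihoods for numerical stability. \code{L0} is the
#' base model (e.g. covariates only), \code{L1} the richer model; nesting
#' (\eqn{L_0 \le L_1}) is enforced.
#'
#' @param logL0,logL1 Log-likelihoods of the base and full models.
#' @param n Sample size.
#' @return R-squared in [0, 1].
#' @export
nagelkerke_r2 <- function(logL0, logL1, n) {
  if (logL0 > logL1 + 1e-12)
    stop("base model has higher likelihood than the full model: nesting violated")
  if (logL0 > 0 || logL1 > 1e-12) stop("likelihoods must not exceed 1")
  num <- 1 - exp((2 / n) * (logL0 - logL1))
  den <- 1 - exp((2 / n) * logL0)
  if (den == 0) return(0)
  num / den
}
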