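#' Harmonize exposure and outcome summary statistics into MR instruments
#'
#' Instruments are exposure variants with p below \code{p_instr}, greedily
#' pruned to pairwise r-squared below \code{r2_prune} (ascending p) using
#' the LD reference. Outcome effects are aligned to the exposure effect
#' allele: signs flip on allele swaps, strand complements are resolved, and
#' palindromic variants whose allele frequency lies in the ambiguous band
#' [0.42, 0.58] are dropped. Every excluded variant carries a drop-reason
#' code; reason counts always sum to the number of candidate instruments.
#'
#' @param exposure,outcome \code{sumstats} with beta and se.
#' @param ld Optional \code{genotype_matrix} LD reference for pruning
#'   (instruments absent from it are kept, assumed independent).
#' @param p_instr Instrument p-value threshold (default 5e-8).
#' @param r2_prune Pairwise r-squared ceiling (default 0.01).
#' @param ambiguous_band Palindromic frequency band (default c(0.42, 0.58)).
#' @return data.frame of class \code{mr_instruments}: id, beta_exp, se_exp,
#'   beta_out, se_out, n_exp, n_out, reason (kept / ld_pruned /
#'   palindromic_ambiguous / strand_unresolved / missing_in_outcome).
#' @export
harmonize <- function(exposure, outcome, ld = NULL, p_instr = 5e-8,
                      r2_prune = 0.01, ambiguous_band = c(0.42, 0.58)) {
  cand <- which(exposure$p < p_instr)
  cand <- cand[order(exposure$p[cand])]
  reason <- setNames(rep("kept", length(cand)), exposure$id[cand])

  oidx <- match(exposure$id[cand], outcome$id)
  reason[is.na(oidx)] <- "missing_in_outcome"

  comp <- function(x) chartr("ACGT", "TGCA", x)
  sgn <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    if (reason[i] != "kept") next
    e <- exposure[cand[i], ]; o <- outcome[oidx[i], ]
    pal <- e$a1 == comp(e$a2)
    if (pal) {
      f <- e$freq
      if (is.na(f) || (f >= ambiguous_band[1] && f <= ambiguous_band[2])) {
        reason[i] <- "palindromic_ambiguous"; next
      }
    }
    if (e$a1 == o$a1 && e$a2 == o$a2) sgn[i] <- 1
    else if (e$a1 == o$a2 && e$a2 == o$a1) sgn[i] <- -1
    else if (!pal && e$a1 == comp(o$a1) && e$a2 == comp(o$a2)) sgn[i] <- 1
    else if (!pal && e$a1 == comp(o$a2) && e$a2 == comp(o$a1)) sgn[i] <- -1
    else if (pal) {
      # palindromic with unambiguous frequency: orient by frequency
      fo <- o$freq
      if (is.na(fo)) { reason[i] <- "strand_unresolved"; next }
      sgn[i] <- if (abs(e$freq - fo) <= abs(e$freq - (1 - fo))) 1 else -1
    } else { reason[i] <- "strand_unresolved"; next }
  }

  # greedy LD pruning among still-kept instruments (already p-ordered)
  if (!is.null(ld)) {
    ridx <- match(exposure$id[cand], ld$variants$id)
    kept_so_far <- integer(0)
    for (i in seq_along(cand)) {
      if (reason[i] != "kept") next
      if (!is.na(ridx[i]) && length(kept_so_far)) {
        prev <- kept_so_far[!is.na(ridx[kept_so_far])]
        if (length(prev)) {
          r2 <- vapply(prev, function(j)
            .ld_r2(ld, ridx[i], ridx[j]), numeric(1))
          if (any(r2 >= r2_prune, na.rm = TRUE)) {
            reason[i] <- "ld_pruned"; next
          }
        }
      }
      kept_so_far <- c(kept_so_far, i)
    }
  }

  out <- data.frame(
    id = exposure$id[cand],
    beta_exp = exposure$beta[cand], se_exp = exposure$se[cand],
    beta_out = ifelse(reason == "kept", sgn * outcome$beta[oidx], NA_real_),
    se_out = ifelse(reason == "kept", outcome$se[oidx], NA_real_),
    n_exp = exposure$n[cand],
    n_out = ifelse(is.na(oidx), NA_real_, outcome$n[oidx]),
    z_exp = exposure$z[cand],
    z_out = ifelse(reason == "kept", sgn * outcome$z[oidx], NA_real_),
    reason = unname(reason),
    stringsAsFactors = FALSE)
  class(out) <- c("mr_instruments", "data.frame")
  out
}

.kept <- function(instr) instr[instr$reason == "kept", , drop = FALSE]

#' Inverse-variance-weighted MR estimate
#'
#' Weighted zero-intercept regression of outcome betas on exposure betas
#' with weights \eqn{1/se_{out}^2}, equivalent to the IVW average of Wald
#' ratios \eqn{\beta_{out}/\beta_{exp}} with weights
#' \eqn{\beta_{exp}^2/se_{out}^2}. The standard error uses multiplicative
#' random-effects dispersion floored at 1, so it is never smaller than the
#' fixed-effect standard error; Cochran's Q over Wald ratios quantifies
#' instrument heterogeneity. Instruments with zero exposure
#' effect are excluded with a warning.
#'
#' @param instr \code{mr_instruments} (kept rows used; >= 1 needed).
#' @return Object of class \code{mr_result}: method, estimate, se, p, Q,
#'   q_p, n_instruments.
#' @export
ivw <- function(instr) {
  d <- .kept(instr)
  drop0 <- d$beta_exp == 0
  if (any(drop0)) {
    warning(sum(drop0), " instrument(s) with zero exposure effect excluded")
    d <- d[!drop0, , drop = FALSE]
  }
  k <- nrow(d)
  if (k < 1) stop("no usable instruments")
  w <- 1 / d$se_out^2
  a <- sum(w * d$beta_exp * d$beta_out) / sum(w * d$beta_exp^2)
  if (k == 1) {
    se <- abs(d$se_out / d$beta_exp)      # first-order delta method
    Q <- 0; qp <- NA_real_
  } else {
    resid <- d$beta_out - a * d$beta_exp
    sigma2 <- sum(w * resid^2) / (k - 1)
    se <- sqrt(max(sigma2, 1) / sum(w * d$beta_exp^2))
    wr <- d$beta_out / d$beta_exp
    wq <- d$beta_exp^2 / d$se_out^2
    abar <- sum(wq * wr) / sum(wq)
    Q <- sum(wq * (wr - abar)^2)
    qp <- stats::pchisq(Q, k - 1, lower.tail = FALSE)
  }
  structure(list(method = "ivw", estimate = a, se = se,
                 p = 2 * stats::pnorm(-abs(a / se)),
                 Q = Q, q_p = qp, n_instruments = k),
            class = "mr_result")
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights \eqn{1/se_{out}^2}); exposure effects are oriented
#' positive first. The slope is the causal estimate and the intercept the
#' average directional-pleiotropy term, each with a normal-theory p-value
#' under multiplicative random-effects dispersion (floored at 1).
#'
#' @param instr \code{mr_instruments}; >= 3 kept instruments required.
#' @return \code{mr_result} with additional fields intercept,
#'   intercept_se, intercept_p.
#' @export
egger <- function(instr) {
  d <- .kept(instr)
  d <- d[d$beta_exp != 0, , drop = FALSE]
  if (nrow(d) < 3) stop("MR-Egger requires at least 3 instruments")
  flip <- sign(d$beta_exp)
  bx <- d$beta_exp * flip; by <- d$beta_out * flip
  w <- 1 / d$se_out^2
  f <- stats::lm(by ~ bx, weights = w)
  sm <- summary(f)
  disp <- max(1, sm$sigma^2)
  cf <- sm$coefficients
  se_scale <- sqrt(disp) / sm$sigma
  int <- cf[1, 1]; int_se <- cf[1, 2] * se_scale
  slope <- cf[2, 1]; slope_se <- cf[2, 2] * se_scale
  structure(list(method = "egger",
                 estimate = slope, se = slope_se,
                 p = 2 * stats::pnorm(-abs(slope / slope_se)),
                 intercept = int, intercept_se = int_se,
                 intercept_p = 2 * stats::pnorm(-abs(int / int_se)),
                 n_instruments = nrow(d)),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s): estimate %.4f (se %.4f), p = %.3g, %d instruments\n",
              x$method, x$estimate, x$se, x$p, x$n_instruments))
  if (!is.null(x$intercept))
    cat(sprintf("  Egger intercept %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  if (!is.null(x$Q) && is.finite(x$Q))
    cat(sprintf("  heterogeneity Q = %.3f\n", x$Q))
  invisible(x)
}

#' Steiger directionality filter
#'
#' Removes instruments that explain more variance in the outcome than in
#' the exposure, with variance explained approximated as
#' \eqn{r^2 = Z^2 / (Z^2 + N)}. Exact ties are kept (stated convention).
#'
#' @param instr \code{mr_instruments} with per-side Z and N.
#' @return The instruments with failing rows recoded
#'   \code{steiger_removed}; never increases the kept count.
#' @export
steiger_filter <- function(instr) {
  kept <- instr$reason == "kept"
  r2e <- instr$z_exp^2 / (instr$z_exp^2 + instr$n_exp)
  r2o <- instr$z_out^2 / (instr$z_out^2 + instr$n_out)
  fail <- kept & is.finite(r2e) & is.finite(r2o) & (r2o > r2e)
  instr$reason[fail] <- "steiger_removed"
  instr
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, as implemented
#' in \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues > 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}
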