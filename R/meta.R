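#' Estimate the cross-cohort correlation matrix
#'
#' Off-diagonal entries are the Pearson correlations of per-variant Z scores
#' across cohorts, computed on the null subset of variants with |Z| < 1.96
#' in both cohorts (the practice used for cross-trait-intercept style
#' overlap corrections). The result is projected to the nearest positive
#' semi-definite matrix by eigenvalue clipping if needed.
#'
#' @param cohorts List of \code{sumstats} objects.
#' @return k x k correlation matrix of class \code{cohort_correlation}.
#' @export
estimate_cohort_correlation <- function(cohorts) {
  k <- length(cohorts)
  C <- diag(k)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      a <- cohorts[[i]]; b <- cohorts[[j]]
      idx <- match(a$id, b$id)
      ok <- !is.na(idx)
      za <- a$z[ok]; zb <- b$z[idx[ok]]
      null_set <- abs(za) < 1.96 & abs(zb) < 1.96 &
        is.finite(za) & is.finite(zb)
      C[i, j] <- C[j, i] <-
        if (sum(null_set) >= 30) stats::cor(za[null_set], zb[null_set]) else 0
    }
  }
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < 0) {
    C <- ev$vectors %*% diag(pmax(ev$values, 1e-8)) %*% t(ev$vectors)
    C <- stats::cov2cor(C)
  }
  structure(C, class = c("cohort_correlation", "matrix"))
}

# align cohort b to cohort a's effect alleles; returns sign (+1/-1) or NA
.align_alleles <- function(a1, a2, b1, b2, fa, fb) {
  comp <- function(x) chartr("ACGT", "TGCA", x)
  s <- rep(NA_real_, length(a1))
  pal <- a1 == comp(a2)            # palindromic (A/T, C/G)
  same <- a1 == b1 & a2 == b2
  swap <- a1 == b2 & a2 == b1
  csame <- a1 == comp(b1) & a2 == comp(b2)
  cswap <- a1 == comp(b2) & a2 == comp(b1)
  s[same | (csame & !pal)] <- 1
  s[swap | (cswap & !pal)] <- -1
  # palindromic: orient by allele-frequency proximity when informative
  if (any(pal)) {
    pi <- which(pal & (same | swap | csame | cswap))
    for (i in pi) {
      if (is.na(fa[i]) || is.na(fb[i])) { s[i] <- NA; next }
      d_same <- abs(fa[i] - fb[i]); d_flip <- abs(fa[i] - (1 - fb[i]))
      s[i] <- if (min(d_same, d_flip) < 0.2 && abs(d_same - d_flip) > 1e-12) {
        if (d_same < d_flip) 1 else -1
      } else NA
    }
  }
  s
}

#' N-weighted multivariate meta-analysis of Z scores
#'
#' Combines per-cohort Z statistics with weights \eqn{w_i = \sqrt{N_i}},
#' accounting for cross-cohort dependence through a correlation matrix C:
#' \deqn{Z_{meta} = \sum_i w_i Z_i / \sqrt{w^\top C w}.}
#' The effective sample size is
#' \eqn{N_{eff} = (\sum_i N_i)^2 / (w^\top C w)}, which reduces to
#' \eqn{\sum_i N_i} for independent cohorts and to the per-cohort N for
#' fully dependent cohorts of equal size. Variants absent from a cohort
#' contribute weight zero (the weight vector and C are subset per missing
#' pattern). Alleles are aligned to the first cohort; Z signs flip when
#' effect/other alleles are swapped, strand complements are resolved, and
#' palindromic variants are matched by allele-frequency proximity or
#' dropped. Cochran's Q across cohorts is computed from per-cohort beta/se
#' where available.
#'
#' @param cohorts List of \code{sumstats}.
#' @param C Cohort correlation matrix (default identity); must be positive
#'   semi-definite.
#' @return A \code{meta_result} data.frame: id, chrom, pos, a1, a2, freq,
#'   z (meta), p, n_eff, k (cohorts contributing), q, q_df, q_p, plus
#'   per-cohort z columns. Attribute \code{n_dropped} counts variants lost
#'   to unresolvable allele mismatches.
#' @export
nweighted_meta <- function(cohorts, C = diag(length(cohorts))) {
  stopifnot(length(cohorts) >= 1)
  k <- length(cohorts)
  C <- as.matrix(C)
  stopifnot(nrow(C) == k, ncol(C) == k)
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("cohort correlation matrix is not positive semi-definite")

  ref <- cohorts[[1]]
  ids <- ref$id
  Zm <- matrix(NA_real_, length(ids), k)
  Nm <- matrix(NA_real_, length(ids), k)
  Bm <- matrix(NA_real_, length(ids), k)
  Sm <- matrix(NA_real_, length(ids), k)
  n_dropped <- 0L
  for (i in seq_len(k)) {
    b <- cohorts[[i]]
    idx <- match(ids, b$id)
    ok <- !is.na(idx)
    sgn <- rep(NA_real_, length(ids))
    if (i == 1) sgn[ok] <- 1   # the first cohort defines orientation
    else sgn[ok] <- .align_alleles(ref$a1[ok], ref$a2[ok],
                                   b$a1[idx[ok]], b$a2[idx[ok]],
                                   ref$freq[ok], b$freq[idx[ok]])
    n_dropped <- n_dropped + sum(ok & is.na(sgn))
    use <- ok & !is.na(sgn)
    Zm[use, i] <- sgn[use] * b$z[idx[use]]
    Nm[use, i] <- b$n[idx[use]]
    if (all(c("beta", "se") %in% names(b))) {
      Bm[use, i] <- sgn[use] * b$beta[idx[use]]
      Sm[use, i] <- b$se[idx[use]]
    }
  }

  W <- sqrt(Nm)
  W[is.na(Zm)] <- 0
  Z0 <- Zm; Z0[is.na(Zm)] <- 0
  num <- rowSums(W * Z0)
  den2 <- rowSums((W %*% C) * W)     # w' C w per variant
  zmeta <- num / sqrt(den2)
  Nsum <- rowSums(Nm, na.rm = TRUE)
  neff <- Nsum^2 / den2
  kvar <- rowSums(!is.na(Zm))

  q <- q_df <- q_p <- rep(NA_real_, length(ids))
  hasbs <- rowSums(!is.na(Bm) & !is.na(Sm)) >= 2
  for (v in which(hasbs)) {
    use <- !is.na(Bm[v, ]) & !is.na(Sm[v, ])
    ct <- cochran_q(Bm[v, use], Sm[v, use])
    q[v] <- ct$Q; q_df[v] <- ct$df; q_p[v] <- ct$p
  }

  out <- data.frame(id = ids, chrom = ref$chrom, pos = ref$pos,
                    a1 = ref$a1, a2 = ref$a2, freq = ref$freq,
                    z = zmeta, p = 2 * stats::pnorm(-abs(zmeta)),
                    n_eff = neff, k = kvar,
                    q = q, q_df = q_df, q_p = q_p,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) out[[paste0("z_cohort", i)]] <- Zm[, i]
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Genomic-control correction
#'
#' Computes the inflation factor \eqn{\lambda = median(Z^2)/0.4549364} and,
#' when \eqn{\lambda > 1}, divides all squared statistics by it and
#' recomputes p-values. Deflation is never applied (\eqn{\lambda \le 1}
#' leaves the statistics untouched), following the usual meta-analysis
#' convention.
#'
#' @param stats A \code{sumstats} object with >= 100 variants.
#' @return The corrected \code{sumstats}, with attribute \code{lambda}.
#' @export
genomic_control <- function(stats) {
  stopifnot(inherits(stats, "sumstats"), nrow(stats) >= 100)
  z2 <- stats$z^2
  lambda <- stats::median(z2, na.rm = TRUE) / stats::qchisq(0.5, 1)
  if (lambda > 1) {
    stats$z <- stats$z / sqrt(lambda)
    if ("se" %in% names(stats)) stats$se <- stats$se * sqrt(lambda)
    stats$p <- 2 * stats::pnorm(-abs(stats$z))
  }
  attr(stats, "lambda") <- lambda
  stats
}

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_i w_i (\beta_i - \bar\beta)^2} with inverse-variance
#' weights \eqn{w_i = se_i^{-2}} and
#' \eqn{\bar\beta = \sum w_i \beta_i / \sum w_i}; the p-value is the upper
#' tail of a chi-squared distribution with k - 1 degrees of freedom.
#'
#' @param betas,ses Numeric vectors of length k >= 2; all ses > 0.
#' @return list(Q, df, p).
#' @export
cochran_q <- function(betas, ses) {
  k <- length(betas)
  stopifnot(k >= 2, length(ses) == k)
  if (any(ses <= 0)) stop("all standard errors must be > 0")
  w <- 1 / ses^2
  bbar <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - bbar)^2)
  list(Q = Q, df = k - 1L, p = stats::pchisq(Q, k - 1L, lower.tail = FALSE))
}

#' Between-sex effect heterogeneity at lead variants
#'
#' For each lead variant present in both sex strata, Cochran's Q between the
#' male and female effect estimates (df = 1) is computed and flagged against
#' the Bonferroni threshold 0.05 / n_tests.
#'
#' @param lead_ids Character vector of variant ids to test.
#' @param male,female \code{sumstats} for the two strata (beta + se needed).
#' @param n_tests Bonferroni denominator (default 221).
#' @return data.frame with id, beta_m, beta_f, q, p, flagged; attribute
#'   \code{excluded} lists ids missing from a stratum.
#' @export
sex_heterogeneity <- function(lead_ids, male, female, n_tests = 221) {
  im <- match(lead_ids, male$id)
  iff <- match(lead_ids, female$id)
  ok <- !is.na(im) & !is.na(iff)
  excluded <- lead_ids[!ok]
  id <- lead_ids[ok]
  bm <- male$beta[im[ok]]; sm <- male$se[im[ok]]
  bf <- female$beta[iff[ok]]; sf <- female$se[iff[ok]]
  q <- p <- numeric(length(id))
  for (i in seq_along(id)) {
    ct <- cochran_q(c(bm[i], bf[i]), c(sm[i], sf[i]))
    q[i] <- ct$Q; p[i] <- ct$p
  }
  out <- data.frame(id = id, beta_m = bm, beta_f = bf, q = q, p = p,
                    flagged = p <= 0.05 / n_tests,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "threshold") <- 0.05 / n_tests
  out
}
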