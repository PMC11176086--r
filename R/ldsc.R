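#' Compute LD scores from a reference panel
#'
#' The LD score of variant j is \eqn{\ell_j = \sum_k \tilde r^2_{jk}} over
#' variants k on the same chromosome within \code{window_kb} kilobases
#' (including j itself), using the unbiased small-sample adjustment
#' \eqn{\tilde r^2 = r^2 - (1 - r^2)/(n - 2)}.
#'
#' @param ld A \code{genotype_matrix} with n >= 3 individuals.
#' @param window_kb Window half-width in kb (default 1000).
#' @return data.frame: id, chrom, pos, ldscore.
#' @export
compute_ld_scores <- function(ld, window_kb = 1000) {
  n <- nrow(ld$dosages)
  if (n < 3) stop("need at least 3 individuals to adjust r-squared")
  v <- ld$variants
  ell <- numeric(nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    X <- scale(ld$dosages[, idx, drop = FALSE])
    sdz <- attr(X, "scaled:scale")
    R <- crossprod(X) / (n - 1)
    R[!is.finite(R)] <- 0
    r2 <- R^2
    r2adj <- r2 - (1 - r2) / (n - 2)
    inwin <- abs(outer(v$pos[idx], v$pos[idx], "-")) <= window_kb * 1000
    r2adj[!inwin] <- 0
    ell[idx] <- rowSums(r2adj)
    ell[idx][sdz == 0] <- NA_real_
  }
  data.frame(id = v$id, chrom = v$chrom, pos = v$pos, ldscore = ell,
             stringsAsFactors = FALSE)
}

#' LD score regression heritability
#'
#' Fits the LD score regression model
#' \eqn{E[\chi^2_j] = 1 + N a + (N h^2 / M)\, \ell_j} by weighted least
#' squares of \eqn{\chi^2 = Z^2} on \eqn{N \ell_j / M}. A two-step
#' procedure estimates the intercept on variants with \eqn{\chi^2 <}
#' \code{two_step_cut} and then fixes it while the slope (= h2 on the
#' observed scale) is estimated on all variants. Weights combine the
#' over-counting term \eqn{1/\ell_j} with the heteroskedasticity term
#' \eqn{1/\max(1, \hat E[\chi^2_j])^2} and are iterated twice. Standard
#' errors come from a delete-one block jackknife over \code{n_blocks}
#' contiguous blocks in genome order.
#'
#' @param stats A \code{sumstats} with z and n.
#' @param scores LD score table from [compute_ld_scores()].
#' @param M Number of variants the heritability refers to (default: number
#'   of regression variants).
#' @param two_step_cut Chi-squared cut for intercept estimation (default 30).
#' @param n_blocks Jackknife blocks (default 200; reduced if fewer than 10
#'   variants per block are available).
#' @param K,P Optional population prevalence and sample case fraction; when
#'   both are given the liability-scale transform is applied.
#' @param maf_min MAF filter (default 0.01).
#' @param weight_iters Iterations of the weight update (default 2; 1 gives
#'   plain fixed-weight regression, useful for algebraic checks).
#' @return Object of class \code{ldsc_h2}: list with h2_obs, h2_se,
#'   intercept, intercept_se, ratio, mean_chi2, h2_liab, h2_liab_se, M, N,
#'   n_blocks, n_snps.
#' @export
ldsc_h2 <- function(stats, scores, M = NULL, two_step_cut = 30,
                    n_blocks = 200, K = NULL, P = NULL, maf_min = 0.01,
                    weight_iters = 2) {
  idx <- match(stats$id, scores$id)
  ok <- !is.na(idx) & is.finite(stats$z) &
    is.finite(scores$ldscore[idx]) &
    (!is.finite(stats$freq) | (stats$freq > maf_min & stats$freq < 1 - maf_min))
  d <- data.frame(chi2 = stats$z[ok]^2,
                  ell = scores$ldscore[idx[ok]],
                  n = stats$n[ok],
                  chrom = stats$chrom[ok], pos = stats$pos[ok])
  d <- d[order(d$chrom, d$pos), ]
  nv <- nrow(d)
  n_blocks <- max(2L, min(n_blocks, nv %/% 10L))
  if (nv < 2 * n_blocks) stop("too few variants for jackknife")
  if (stats::sd(d$ell) < 1e-12) stop("constant LD scores: model unidentifiable")
  if (is.null(M)) M <- nv
  Nbar <- mean(d$n)
  x <- d$n * d$ell / M
  blocks <- cut(seq_len(nv), n_blocks, labels = FALSE)

  fit_once <- function(keep) {
    chi2 <- d$chi2[keep]; xx <- x[keep]; ell <- d$ell[keep]
    w <- 1 / pmax(ell, 1)
    int <- NA_real_; slope <- 0
    for (it in seq_len(weight_iters)) {
      # step 1: intercept from the sub-threshold variants
      s1 <- chi2 < two_step_cut
      f1 <- stats::lm.wfit(cbind(1, xx[s1]), chi2[s1], w[s1])
      int <- unname(f1$coefficients[1])
      # step 2: slope with the intercept fixed
      slope <- sum(w * xx * (chi2 - int)) / sum(w * xx^2)
      fitted <- pmax(1, int + slope * xx)
      w <- 1 / (pmax(ell, 1) * fitted^2)
    }
    c(h2 = slope, intercept = int)
  }

  full <- fit_once(rep(TRUE, nv))
  jk <- vapply(seq_len(n_blocks), function(b) fit_once(blocks != b),
               numeric(2))
  jk_se <- function(theta_full, theta_del) {
    g <- length(theta_del)
    ps <- g * theta_full - (g - 1) * theta_del
    sqrt(stats::var(ps) / g)
  }
  h2_obs <- unname(full["h2"])
  h2_se <- jk_se(full["h2"], jk[1, ])
  intercept <- unname(full["intercept"])
  int_se <- jk_se(full["intercept"], jk[2, ])
  mean_chi2 <- mean(d$chi2)
  ratio <- if (mean_chi2 > 1) (intercept - 1) / (mean_chi2 - 1) else NA_real_

  h2_liab <- h2_liab_se <- NA_real_
  if (!is.null(K) && !is.null(P)) {
    mult <- liability_transform(1, K, P)
    h2_liab <- h2_obs * mult
    h2_liab_se <- h2_se * mult
  }
  structure(list(h2_obs = h2_obs, h2_se = h2_se,
                 intercept = intercept, intercept_se = int_se,
                 ratio = ratio, mean_chi2 = mean_chi2,
                 h2_liab = h2_liab, h2_liab_se = h2_liab_se,
                 M = M, N = Nbar, K = K, P = P,
                 n_blocks = n_blocks, n_snps = nv),
            class = "ldsc_h2")
}

#' @export
print.ldsc_h2 <- function(x, ...) {
  cat("LD score regression heritability\n")
  cat(sprintf("  observed-scale h2: %.4f (se %.4f)\n", x$h2_obs, x$h2_se))
  if (is.finite(x$h2_liab))
    cat(sprintf("  liability-scale h2: %.4f (se %.4f)  [K=%.3g, P=%.3g]\n",
                x$h2_liab, x$h2_liab_se, x$K, x$P))
  cat(sprintf("  intercept: %.4f (se %.4f); mean chi2 %.4f; ratio %s\n",
              x$intercept, x$intercept_se, x$mean_chi2,
              ifelse(is.na(x$ratio), "NA", sprintf("%.3f", x$ratio))))
  cat(sprintf("  %d SNPs, M = %d, mean N = %.0f, %d jackknife blocks\n",
              x$n_snps, x$M, x$N, x$n_blocks))
  invisible(x)
}

#' Observed-to-liability scale transform for heritability
#'
#' \deqn{h^2_{liab} = h^2_{obs} \frac{K^2 (1-K)^2}{P(1-P)\, z^2}}
#' with K the population prevalence, P the sample case fraction and z the
#' standard-normal density at the liability threshold
#' \eqn{\Phi^{-1}(1 - K)}.
#'
#' @param h2_obs Observed-scale estimate.
#' @param K,P Population prevalence and sample case fraction, in (0,1).
#' @return Liability-scale heritability.
#' @export
liability_transform <- function(h2_obs, K, P) {
  stopifnot(K > 0, K < 1, P > 0, P < 1)
  z <- stats::dnorm(stats::qnorm(1 - K))
  h2_obs * K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
}

#' LD score regression genetic correlation
#'
#' Regresses the Z-score product of two traits on
#' \eqn{\sqrt{N_1 N_2}\,\ell_j / M}: the slope estimates the genetic
#' covariance and the free intercept absorbs sample overlap. The genetic
#' correlation is \eqn{r_g = cov_g / \sqrt{h^2_1 h^2_2}} with the two
#' heritabilities estimated by [ldsc_h2()] on the shared variant set; the
#' standard error is a delete-one block jackknife of the full ratio.
#'
#' @param stats1,stats2 \code{sumstats} for the two traits.
#' @param scores LD score table.
#' @param M Variant count for scaling (default: shared variants).
#' @param n_blocks Jackknife blocks (default 200, reduced as needed).
#' @return list(rg, se, covg, h2_1, h2_2) of class \code{ldsc_rg};
#'   rg is NA with flag "undefined" when either h2 <= 0.
#' @export
ldsc_rg <- function(stats1, stats2, scores, M = NULL, n_blocks = 200) {
  j <- match(stats1$id, stats2$id)
  ok <- !is.na(j)
  s1 <- stats1[ok, ]; s2 <- stats2[j[ok], ]
  k <- match(s1$id, scores$id)
  ok2 <- !is.na(k) & is.finite(s1$z) & is.finite(s2$z) &
    is.finite(scores$ldscore[k])
  d <- data.frame(z1 = s1$z[ok2], z2 = s2$z[ok2],
                  n1 = s1$n[ok2], n2 = s2$n[ok2],
                  ell = scores$ldscore[k[ok2]],
                  chrom = s1$chrom[ok2], pos = s1$pos[ok2])
  d <- d[order(d$chrom, d$pos), ]
  nv <- nrow(d)
  if (is.null(M)) M <- nv
  n_blocks <- max(2L, min(n_blocks, nv %/% 10L))
  blocks <- cut(seq_len(nv), n_blocks, labels = FALSE)

  rg_of <- function(keep) {
    dd <- d[keep, ]
    w <- 1 / pmax(dd$ell, 1)
    x <- sqrt(dd$n1 * dd$n2) * dd$ell / M
    f <- stats::lm.wfit(cbind(1, x), dd$z1 * dd$z2, w)
    covg <- unname(f$coefficients[2])
    h2 <- function(z, n) {
      xx <- n * dd$ell / M
      ff <- stats::lm.wfit(cbind(1, xx), z^2, w)
      unname(ff$coefficients[2])
    }
    h1 <- h2(dd$z1, dd$n1); h2b <- h2(dd$z2, dd$n2)
    if (h1 <= 0 || h2b <= 0) return(NA_real_)
    covg / sqrt(h1 * h2b)
  }
  rg_full <- rg_of(rep(TRUE, nv))
  if (is.na(rg_full))
    return(structure(list(rg = NA_real_, se = NA_real_,
                          flag = "undefined: non-positive h2"),
                     class = "ldsc_rg"))
  jk <- vapply(seq_len(n_blocks), function(b) rg_of(blocks != b), numeric(1))
  jk <- jk[is.finite(jk)]
  g <- length(jk)
  ps <- g * rg_full - (g - 1) * jk
  structure(list(rg = rg_full, se = sqrt(stats::var(ps) / g),
                 n_snps = nv, flag = ""),
            class = "ldsc_rg")
}

#' @export
print.ldsc_rg <- function(x, ...) {
  if (nzchar(x$flag)) cat("genetic correlation:", x$flag, "\n")
  else cat(sprintf("genetic correlation rg = %.4f (se %.4f), %d SNPs\n",
                   x$rg, x$se, x$n_snps))
  invisible(x)
}

#' Z-test for the difference of two estimates (or of one estimate vs 1)
#'
#' two_sample: \eqn{z = (est_1 - est_2)/\sqrt{se_1^2 + se_2^2}};
#' vs_one: \eqn{z = (est_1 - 1)/se_1}. Two-sided normal p-value.
#'
#' @param est1,se1 First estimate and its standard error.
#' @param est2,se2 Second estimate (ignored for vs_one).
#' @param kind "two_sample" or "vs_one".
#' @return list(z, p).
#' @export
estimate_diff_ztest <- function(est1, se1, est2 = NULL, se2 = NULL,
                                kind = c("two_sample", "vs_one")) {
  kind <- match.arg(kind)
  stopifnot(se1 > 0)
  z <- if (kind == "two_sample") {
    stopifnot(se2 > 0)
    (est1 - est2) / sqrt(se1^2 + se2^2)
  } else (est1 - 1) / se1
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Chromosome X heritability from the mean chi-squared statistic
#'
#' Uses \eqn{E[\chi^2] \approx 1 + N h^2 / M_{eff}} so that
#' \eqn{h^2 = (\bar\chi^2 - 1) M_{eff} / N}. Negative values are reported
#' as-is with a flag.
#'
#' @param mean_chi2 Mean chi-squared across the region's variants.
#' @param N GWAS sample size.
#' @param M_eff Effective number of loci in the region (see
#'   [effective_m()]).
#' @return list(h2, flag).
#' @export
xchr_h2 <- function(mean_chi2, N, M_eff) {
  stopifnot(N > 0, M_eff > 0)
  h2 <- (mean_chi2 - 1) * M_eff / N
  list(h2 = h2, flag = if (h2 < 0) "negative" else "")
}

#' Effective number of loci in a region
#'
#' Estimated as M / mean(LD score): perfectly correlated variants count
#' once, independent variants count fully.
#'
#' @param scores LD score table for the region.
#' @return Scalar M_eff.
#' @export
effective_m <- function(scores) {
  ell <- scores$ldscore[is.finite(scores$ldscore)]
  length(ell) / mean(ell)
}

#' Cross-sex genetic correlation from Z-score products
#'
#' \deqn{\hat r_g = \overline{Z_m Z_f} /
#'   \sqrt{(\bar\chi^2_f - 1)(\bar\chi^2_m - 1)},}
#' valid for independent male and female samples. Requires both mean
#' chi-squared statistics to exceed 1; the reported value is clipped to
#' [-1, 1] with the raw value retained.
#'
#' @param z_male,z_female Aligned per-variant Z scores for the two strata.
#' @return list(rg, rg_raw, mean_chi2_m, mean_chi2_f).
#' @export
xchr_rg <- function(z_male, z_female) {
  stopifnot(length(z_male) == length(z_female))
  ok <- is.finite(z_male) & is.finite(z_female)
  cm <- mean(z_male[ok]^2); cf <- mean(z_female[ok]^2)
  if (cm <= 1 || cf <= 1)
    stop("mean chi-squared must exceed 1 in both strata; rg undefined")
  raw <- mean(z_male[ok] * z_female[ok]) / sqrt((cf - 1) * (cm - 1))
  list(rg = max(-1, min(1, raw)), rg_raw = raw,
       mean_chi2_m = cm, mean_chi2_f = cf)
}

#' Write a heritability estimate as a machine-readable TSV row
#'
#' One row with the fields of the estimate (observed and liability scale,
#' intercept, ratio, mean chi-squared, M, N, SNP and block counts).
#'
#' @param x An \code{ldsc_h2} object.
#' @param path Output file.
#' @export
write_h2_report <- function(x, path) {
  stopifnot(inherits(x, "ldsc_h2"))
  d <- data.frame(H2_OBS = x$h2_obs, H2_OBS_SE = x$h2_se,
                  H2_LIAB = x$h2_liab, H2_LIAB_SE = x$h2_liab_se,
                  INTERCEPT = x$intercept, INTERCEPT_SE = x$intercept_se,
                  RATIO = x$ratio, MEAN_CHI2 = x$mean_chi2,
                  M = x$M, N = x$N, N_SNPS = x$n_snps,
                  N_BLOCKS = x$n_blocks)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read LD scores as tab-separated text (ID, CHR, BP, L2)
#' @param scores LD score table.
#' @param path File path.
#' @rdname write_ld_scores
#' @export
write_ld_scores <- function(scores, path) {
  d <- scores[c("id", "chrom", "pos", "ldscore")]
  names(d) <- c("ID", "CHR", "BP", "L2")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ld_scores
#' @export
read_ld_scores <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  data.frame(id = d$ID, chrom = as.character(d$CHR), pos = d$BP,
             ldscore = d$L2, stringsAsFactors = FALSE)
}
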