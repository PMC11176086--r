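# squared correlation between two dosage columns of an LD reference
.ld_r2 <- function(ld, i, j) {
  suppressWarnings(stats::cor(ld$dosages[, i], ld$dosages[, j]))^2
}

#' Greedy LD clumping of meta-analysis results
#'
#' PLINK-style clumping: index candidates are variants with p < \code{p1},
#' taken greedily in ascending p (ties broken by chromosome then position).
#' Variants with p < \code{p2}, on the same chromosome within \code{kb}
#' kilobases of the index and with r-squared above \code{r2_thresh} to it
#' are absorbed into the clump. Each variant belongs to at most one clump.
#'
#' @param meta A \code{meta_result} (or any data.frame with id, chrom, pos,
#'   p columns).
#' @param ld A \code{genotype_matrix} LD reference covering the variants
#'   (uncovered variants are reported via attribute \code{uncovered}).
#' @param r2_thresh,kb,p1,p2 Clumping parameters (defaults 0.05, 500,
#'   5e-8, 1e-5).
#' @return list of clumps; each clump is a list(index, members, chrom,
#'   start, end) where members includes the index. Attribute
#'   \code{uncovered} lists variant ids missing from the reference.
#' @export
ld_clump <- function(meta, ld, r2_thresh = 0.05, kb = 500,
                     p1 = 5e-8, p2 = 1e-5) {
  ref_idx <- match(meta$id, ld$variants$id)
  uncovered <- meta$id[is.na(ref_idx)]
  ord <- order(meta$p, meta$chrom, meta$pos)
  assigned <- rep(FALSE, nrow(meta))
  clumps <- list()
  for (v in ord) {
    if (assigned[v] || is.na(meta$p[v]) || meta$p[v] >= p1) next
    if (is.na(ref_idx[v])) next
    cand <- which(!assigned & meta$chrom == meta$chrom[v] &
                    abs(meta$pos - meta$pos[v]) <= kb * 1000 &
                    meta$p < p2 & !is.na(ref_idx))
    cand <- setdiff(cand, v)
    keep <- cand[vapply(cand, function(j)
      isTRUE(.ld_r2(ld, ref_idx[v], ref_idx[j]) > r2_thresh), logical(1))]
    members <- c(v, keep)
    assigned[members] <- TRUE
    clumps[[length(clumps) + 1L]] <- list(
      index = meta$id[v],
      members = meta$id[members],
      chrom = meta$chrom[v],
      start = min(meta$pos[members]),
      end = max(meta$pos[members]))
  }
  attr(clumps, "uncovered") <- uncovered
  clumps
}

#' Merge clumps into genomic risk loci
#'
#' Two clumps merge iff they lie on the same chromosome and either their
#' member spans overlap or the gap between the spans is below
#' \code{gap_kb} kilobases; merging is applied to transitive closure.
#'
#' @param clumps Output of [ld_clump()].
#' @param gap_kb Maximum span gap in kb (default 500).
#' @return list of loci: list(chrom, start, end, index, members); loci on a
#'   chromosome have pairwise-disjoint spans.
#' @export
merge_loci <- function(clumps, gap_kb = 500) {
  if (!length(clumps)) return(list())
  ch <- vapply(clumps, `[[`, character(1), "chrom")
  st <- vapply(clumps, `[[`, numeric(1), "start")
  en <- vapply(clumps, `[[`, numeric(1), "end")
  n <- length(clumps)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || ch[i] != ch[j]) next
    gap <- max(st[i], st[j]) - min(en[i], en[j])
    if (gap < gap_kb * 1000) {         # overlap gives gap <= 0
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), roots), function(grp) {
    mem <- unlist(lapply(clumps[grp], `[[`, "members"))
    idxs <- vapply(clumps[grp], `[[`, character(1), "index")
    list(chrom = ch[grp[1]], start = min(st[grp]), end = max(en[grp]),
         index = idxs[1], members = mem)
  })
}

#' Write loci as a BED-like tab-separated table
#'
#' Spans are written 0-based half-open (CHR, START-1, END, INDEX_ID);
#' internally loci are 1-based inclusive.
#'
#' @param loci Output of [merge_loci()].
#' @param path Output file.
#' @export
write_loci <- function(loci, path) {
  d <- data.frame(
    CHR = vapply(loci, `[[`, character(1), "chrom"),
    START = vapply(loci, `[[`, numeric(1), "start") - 1,
    END = vapply(loci, `[[`, numeric(1), "end"),
    INDEX_ID = vapply(loci, `[[`, character(1), "index"))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Stepwise conditional selection of independent lead signals
#'
#' Forward selection on summary statistics in the style of conditional and
#' joint (COJO) analysis, using the standardized-genotype approximation: a
#' variant's standardized marginal effect is \eqn{b_j = z_j/\sqrt{N_j}},
#' and for a selected set S the joint effects are
#' \eqn{b_J = R_{SS}^{-1} b_S} with R the LD correlation matrix from the
#' reference. The candidate with the smallest conditional p-value
#' \deqn{z_{j|S} = (z_j - R_{jS} R_{SS}^{-1} z_S)/
#'   \sqrt{1 - R_{jS} R_{SS}^{-1} R_{Sj}}}
#' enters while its conditional p is below \code{p_thresh} and its
#' r-squared with every already-selected variant within \code{window_mb}
#' megabases stays below \code{colinearity}. Variants outside the window of
#' a selected variant are treated as uncorrelated with it.
#'
#' @param meta A \code{meta_result}-like data.frame (id, chrom, pos, z,
#'   n_eff or n, p).
#' @param ld A \code{genotype_matrix} LD reference.
#' @param p_thresh Genome-wide threshold for entry (default 5e-8).
#' @param window_mb LD window in megabases (default 10).
#' @param colinearity Maximum allowed r-squared with selected variants
#'   (default 0.9).
#' @return data.frame of lead signals: id, chrom, pos, joint_beta
#'   (standardized scale), joint_se, joint_p, entry_order.
#' @export
stepwise_joint_selection <- function(meta, ld, p_thresh = 5e-8,
                                     window_mb = 10, colinearity = 0.9) {
  N <- if ("n_eff" %in% names(meta)) meta$n_eff else meta$n
  ref_idx <- match(meta$id, ld$variants$id)
  usable <- which(!is.na(ref_idx) & is.finite(meta$z) & is.finite(N))
  if (!length(usable)) return(.empty_leads())

  Xs <- scale(ld$dosages[, ref_idx[usable], drop = FALSE])
  R_of <- function(i, j) {  # correlation between usable-index i and j
    same_chr <- meta$chrom[usable[i]] == meta$chrom[usable[j]]
    near <- abs(meta$pos[usable[i]] - meta$pos[usable[j]]) <=
      window_mb * 1e6
    if (!same_chr || !near) return(0)
    mean(Xs[, i] * Xs[, j], na.rm = TRUE)
  }

  z <- meta$z[usable]
  sel <- integer(0)
  repeat {
    cand <- setdiff(seq_along(usable), sel)
    if (!length(cand)) break
    if (!length(sel)) {
      zc <- z[cand]
    } else {
      Rss <- outer(sel, sel, Vectorize(R_of))
      diag(Rss) <- 1
      ok_solve <- TRUE
      Rinv <- tryCatch(solve(Rss), error = function(e) { ok_solve <<- FALSE; NULL })
      if (!ok_solve) break
      zc <- vapply(cand, function(j) {
        rjs <- vapply(sel, function(s) R_of(j, s), numeric(1))
        if (any(rjs^2 >= colinearity)) return(0)  # blocked by colinearity
        denom <- 1 - drop(rjs %*% Rinv %*% rjs)
        if (denom <= 1e-8) return(0)
        (z[j] - drop(rjs %*% Rinv %*% z[sel])) / sqrt(denom)
      }, numeric(1))
    }
    pc <- 2 * stats::pnorm(-abs(zc))
    best <- which.min(pc)
    if (pc[best] >= p_thresh) break
    sel <- c(sel, cand[best])
  }
  if (!length(sel)) return(.empty_leads())

  Rss <- outer(sel, sel, Vectorize(R_of)); diag(Rss) <- 1
  Rinv <- solve(Rss)
  b_marg <- z[sel] / sqrt(N[usable[sel]])
  b_joint <- drop(Rinv %*% b_marg)
  se_joint <- sqrt(diag(Rinv) / N[usable[sel]])
  zj <- b_joint / se_joint
  data.frame(id = meta$id[usable[sel]],
             chrom = meta$chrom[usable[sel]],
             pos = meta$pos[usable[sel]],
             joint_beta = b_joint, joint_se = se_joint,
             joint_p = 2 * stats::pnorm(-abs(zj)),
             entry_order = seq_along(sel),
             stringsAsFactors = FALSE)
}

.empty_leads <- function() {
  data.frame(id = character(0), chrom = character(0), pos = numeric(0),
             joint_beta = numeric(0), joint_se = numeric(0),
             joint_p = numeric(0), entry_order = integer(0),
             stringsAsFactors = FALSE)
}
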