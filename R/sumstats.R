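#' GWAS summary-statistics table
#'
#' Validates and classes a per-variant association table. Required columns:
#' \code{id, chrom, pos, a1, a2, freq, p, n} plus \code{beta}+\code{se}
#' and/or \code{z}. Alleles are upper-cased; \code{z} is checked against
#' \code{beta/se} where both are present.
#'
#' @param x data.frame of per-variant statistics.
#' @param cohort,trait,sex_stratum Metadata labels attached as attributes.
#' @return \code{x} with class \code{c("sumstats","data.frame")}.
#' @export
sumstats <- function(x, cohort = "cohort", trait = "trait",
                     sex_stratum = c("pooled", "male", "female")) {
  sex_stratum <- match.arg(sex_stratum)
  need <- c("id", "chrom", "pos", "a1", "a2", "freq", "p", "n")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (!("z" %in% names(x)) && !all(c("beta", "se") %in% names(x)))
    stop("need either 'z' or both 'beta' and 'se'")
  x$a1 <- toupper(x$a1); x$a2 <- toupper(x$a2)
  if (!("z" %in% names(x))) x$z <- x$beta / x$se
  ok <- is.finite(x$z) & is.finite(x$p)
  if (any(ok & (x$p <= 0 | x$p > 1)))
    stop("p-values must lie in (0, 1]")
  if (all(c("beta", "se") %in% names(x))) {
    both <- ok & is.finite(x$beta) & is.finite(x$se) & x$se > 0
    bad <- both & abs(x$z - x$beta / x$se) >
      1e-6 * pmax(1, abs(x$z))
    if (any(bad)) stop(sum(bad), " variant(s) violate z = beta/se")
  }
  if (anyDuplicated(x$id)) stop("duplicate variant ids")
  attr(x, "cohort") <- cohort
  attr(x, "trait") <- trait
  attr(x, "sex_stratum") <- sex_stratum
  class(x) <- unique(c("sumstats", class(x)))
  x
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats: %d variants | cohort=%s trait=%s stratum=%s\n",
              nrow(x), attr(x, "cohort"), attr(x, "trait"),
              attr(x, "sex_stratum")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# canonical file header <-> internal names
.ss_cols <- c(ID = "id", CHR = "chrom", BP = "pos", A1 = "a1", A2 = "a2",
              FRQ = "freq", BETA = "beta", SE = "se", Z = "z", P = "p",
              N = "n", N_CASE = "n_case", N_CONTROL = "n_control")

#' Read / write summary statistics as tab-separated text
#'
#' The on-disk dialect is a tab-separated table with header columns
#' ID, CHR, BP, A1, A2, FRQ, BETA, SE, Z, P, N (N_CASE/N_CONTROL optional).
#' BETA+SE or Z must be present alongside N and P. Round-trips are lossless
#' for all populated fields; p-values in scientific notation are parsed as
#' doubles (1e-300 does not underflow to 0).
#'
#' @param path File path.
#' @rdname read_sumstats
#' @return \code{read_sumstats}: a \code{sumstats} data.frame.
#' @export
read_sumstats <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  req <- c("ID", "CHR", "BP", "A1", "A2", "P")
  miss <- setdiff(req, hdr)
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (!("Z" %in% hdr) && !all(c("BETA", "SE") %in% hdr))
    stop("missing required column(s): BETA/SE or Z")
  if (!any(c("N", "SE") %in% hdr))
    stop("missing required column(s): SE or N")
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = NA, stringsAsFactors = FALSE,
                         check.names = FALSE, comment.char = "")
  if (!is.numeric(d$P)) {
    suppressWarnings(pv <- as.numeric(d$P))
    bad <- is.na(pv) & !is.na(d$P)
    if (any(bad))
      stop("non-numeric p value at line ", which(bad)[1] + 1L)
    d$P <- pv
  }
  keep <- intersect(names(.ss_cols), names(d))
  d <- d[keep]
  names(d) <- .ss_cols[keep]
  d$id <- as.character(d$id)
  d$chrom <- as.character(d$chrom)
  if (!("freq" %in% names(d))) d$freq <- NA_real_
  if (!("n" %in% names(d))) d$n <- NA_real_
  sumstats(d)
}

#' @param x A \code{sumstats} object.
#' @rdname read_sumstats
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  keep <- .ss_cols[.ss_cols %in% names(x)]
  d <- as.data.frame(x)[, keep, drop = FALSE]
  names(d) <- names(keep)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
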