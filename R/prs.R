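#' Polygenic risk score from dosages and weights
#'
#' \eqn{PRS_i = \sum_j w_j g_{ij}} over the weight file's variants. Missing
#' dosages are imputed to twice the weight table's allele frequency (when
#' provided) and counted; individuals with more than 10% of weighted
#' variants missing are flagged.
#'
#' @param dosages n x m matrix with variant ids as column names (NA =
#'   missing).
#' @param weights data.frame with columns id, weight and optionally freq.
#' @return Numeric PRS vector with attributes \code{n_imputed} (total
#'   imputed entries) and \code{flagged} (logical per individual).
#' @export
compute_prs <- function(dosages, weights) {
  miss <- setdiff(weights$id, colnames(dosages))
  if (length(miss)) stop("weight ids absent from dosages: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  X <- dosages[, weights$id, drop = FALSE]
  na <- is.na(X)
  n_imp <- sum(na)
  if (n_imp) {
    if (is.null(weights$freq)) stop("missing dosages need 'freq' in weights")
    fill <- matrix(2 * weights$freq, nrow(X), ncol(X), byrow = TRUE)
    X[na] <- fill[na]
  }
  prs <- as.vector(X %*% weights$weight)
  structure(prs, n_imputed = n_imp,
            flagged = rowMeans(na) > 0.10)
}

#' Read a PRS weights file (TSV: ID, A1, WEIGHT[, FRQ])
#' @param path File path.
#' @return data.frame with id, a1, weight, freq.
#' @export
read_prs_weights <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  data.frame(id = d$ID, a1 = d$A1, weight = d$WEIGHT,
             freq = if ("FRQ" %in% names(d)) d$FRQ else NA_real_,
             stringsAsFactors = FALSE)
}

#' Resample a case-control cohort into a demography-matched population
#'
#' Draws \code{target_n} individuals with replacement from a source cohort
#' so that (i) the age-sex pyramid matches the demography table's stratum
#' proportions and (ii) the probability of being a prevalent case given age
#' and sex follows the stratum's cumulative incidence. Each synthetic
#' individual receives an age uniform within its stratum's bin, case status
#' Bernoulli(stratum incidence), the dosage/PRS/PC profile of a randomly
#' chosen source individual of the same sex and case status, and (for
#' cases) an onset age resampled from the source cases' onset distribution
#' conditioned on onset <= current age.
#'
#' @param cohort A \code{phenotype_table} (needs case_status, sex, age,
#'   onset_age).
#' @param dosages Optional matrix aligned to \code{cohort} rows; resampled
#'   alongside.
#' @param prs Optional per-individual PRS vector, resampled alongside.
#' @param demography data.frame with columns SEX, AGE_LO, AGE_HI,
#'   PROPORTION, CUM_INCIDENCE covering every stratum.
#' @param target_n Output population size.
#' @param seed Integer seed.
#' @param folds Number of cross-validation folds to assign (default 10,
#'   stratified by case status).
#' @return data.frame of class \code{simulated_population} with sex, age,
#'   case_status, onset_age, prs, source_row, fold; attribute
#'   \code{dosages} when given.
#' @export
resample_population <- function(cohort, demography, target_n,
                                dosages = NULL, prs = NULL, seed = 1L,
                                folds = 10L) {
  req <- c("SEX", "AGE_LO", "AGE_HI", "PROPORTION", "CUM_INCIDENCE")
  stopifnot(all(req %in% names(demography)))
  set.seed(seed)
  dem <- demography
  dem$PROPORTION <- dem$PROPORTION / sum(dem$PROPORTION)
  counts <- as.vector(stats::rmultinom(1, target_n, dem$PROPORTION))

  rows <- list()
  for (s in seq_len(nrow(dem))) {
    ns <- counts[s]
    if (!ns) next
    sex_s <- dem$SEX[s]
    src_case <- which(cohort$sex == sex_s & cohort$case_status == 1L)
    src_ctrl <- which(cohort$sex == sex_s & cohort$case_status == 0L)
    if (!length(src_case) || !length(src_ctrl))
      stop(sprintf("no source individuals for stratum %s [%g,%g)",
                   sex_s, dem$AGE_LO[s], dem$AGE_HI[s]))
    age <- stats::runif(ns, dem$AGE_LO[s], dem$AGE_HI[s])
    case <- stats::rbinom(ns, 1L, dem$CUM_INCIDENCE[s])
    src <- ifelse(case == 1L,
                  sample(src_case, ns, replace = TRUE),
                  sample(src_ctrl, ns, replace = TRUE))
    onset <- rep(NA_real_, ns)
    ci <- which(case == 1L)
    if (length(ci)) {
      pool <- cohort$onset_age[src_case]
      pool <- pool[is.finite(pool)]
      onset[ci] <- vapply(age[ci], function(a) {
        elig <- pool[pool <= a]
        if (length(elig)) sample(elig, 1) else stats::runif(1, 5, a)
      }, numeric(1))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sex = sex_s, age = age, case_status = case, onset_age = onset,
      source_row = src, stringsAsFactors = FALSE)
  }
  pop <- do.call(rbind, rows)
  pop <- pop[sample.int(nrow(pop)), , drop = FALSE]
  rownames(pop) <- NULL
  if (!is.null(prs)) pop$prs <- prs[pop$source_row]
  # stratified fold assignment
  pop$fold <- NA_integer_
  for (cls in unique(pop$case_status)) {
    i <- which(pop$case_status == cls)
    pop$fold[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  if (!is.null(dosages))
    attr(pop, "dosages") <- dosages[pop$source_row, , drop = FALSE]
  class(pop) <- c("simulated_population", "data.frame")
  pop
}

#' Read a demography table (TSV: SEX, AGE_LO, AGE_HI, PROPORTION,
#' CUM_INCIDENCE)
#' @param path File path.
#' @return data.frame.
#' @export
read_demography <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Five-year landmark labels for time-to-event prediction
#'
#' At landmark age L, individuals already affected (onset <= L) are
#' excluded; the label is 1 iff onset falls in (L, L + 5]. Individuals
#' whose current age censors them before L + 5 without an event in the
#' window are excluded (documented choice: no partial follow-up).
#'
#' @param pop A \code{simulated_population} (age, onset_age).
#' @param landmark_age Landmark L in years.
#' @return Integer labels with attribute \code{index} (rows of \code{pop}
#'   retained); errors if nobody is at risk.
#' @export
five_year_labels <- function(pop, landmark_age) {
  onset <- pop$onset_age
  has_onset <- is.finite(onset)
  prevalent <- has_onset & onset <= landmark_age
  event_in_window <- has_onset & onset > landmark_age &
    onset <= landmark_age + 5
  censored_early <- !event_in_window & pop$age < landmark_age + 5
  keep <- !prevalent & !censored_early
  if (!any(keep)) stop("no individuals at risk at landmark ", landmark_age)
  labels <- as.integer(event_in_window[keep])
  attr(labels, "index") <- which(keep)
  labels
}
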