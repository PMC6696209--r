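#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1) for single measurements, computed from the two-way ANOVA
#' decomposition of an n-subjects-by-k-sessions matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with MSR the
#' between-subject, MSC the between-session and MSE the residual mean
#' square.
#'
#' @param pairs numeric matrix, subjects in rows, sessions (usually
#'   test/retest, k = 2) in columns; complete rows only.
#' @return The ICC(2,1) estimate.
#' @export
icc_two_way <- function(pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) >= 2)
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  n <- nrow(pairs); k <- ncol(pairs)
  if (n < 3) stop("at least 3 complete subject rows are required")
  gm <- mean(pairs)
  sst <- sum((pairs - gm)^2)
  if (sst == 0) stop("zero total variance: ICC undefined")
  ssr <- k * sum((rowMeans(pairs) - gm)^2)
  ssc <- n * sum((colMeans(pairs) - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)`: the within-subject measurement noise on
#' the measure's own scale.
#'
#' @param sd sample standard deviation of the measure (conventionally
#'   pooled over test and retest observations).
#' @param icc intraclass correlation, at most 1.
#' @return SEM in measure units.
#' @export
#' @examples
#' sem(10, 0.75)  # 5
sem <- function(sd, icc) {
  stopifnot(sd >= 0)
  if (any(icc > 1)) stop("icc must not exceed 1")
  sd * sqrt(1 - icc)
}

#' Minimal detectable change at 95% confidence
#'
#' `MDC = SEM * 1.96 * sqrt(2)`: the smallest change between two
#' sessions exceeding measurement error with 95% confidence.
#'
#' @param sem_value standard error of measurement (nonnegative).
#' @return MDC in measure units.
#' @export
#' @examples
#' mdc(1)  # 2.7719...
mdc <- function(sem_value) {
  if (any(sem_value < 0)) stop("sem must be nonnegative")
  sem_value * 1.96 * sqrt(2)
}

#' Test-retest reliability report for selected measures
#'
#' Pairs each subject's test and retest values and reports, per
#' measure: ICC(2,1), the SD pooled over all test and retest
#' observations, SEM and MDC.
#'
#' @param test,retest `measure_table`s of the same measures; subjects
#'   are paired by row order after restricting `test` to the groups
#'   present in `retest` (conventionally the PD group only).
#' @param ids measures to report (default: all of `retest`).
#' @return Data frame with `measure_id`, `icc`, `sd_pooled`, `sem`,
#'   `mdc`, `n_pairs`.
#' @export
reliability_table <- function(test, retest, ids = measure_ids(retest)) {
  stopifnot(all(ids %in% measure_ids(test)))
  groups <- unique(as.character(retest$group))
  t_rows <- which(as.character(test$group) %in% groups)
  if (length(t_rows) != nrow(retest$values))
    stop("test and retest tables pair different numbers of subjects")
  rows <- lapply(ids, function(id) {
    m <- cbind(test$values[t_rows, id], retest$values[, id])
    m <- m[stats::complete.cases(m), , drop = FALSE]
    icc <- icc_two_way(m)
    sd_pooled <- stats::sd(c(m))
    s <- sem(sd_pooled, min(icc, 1))
    data.frame(measure_id = id, icc = icc, sd_pooled = sd_pooled,
               sem = s, mdc = mdc(s), n_pairs = nrow(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
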