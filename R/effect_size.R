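#' Standardized mean difference between two groups
#'
#' Computes `(mean1 - mean2) / S`.  Two denominators are available:
#'
#' * `"paper"`: `S = sqrt[(SD1^2/n1 + SD2^2/n2) * (n1*n2/(n1+n2))]`,
#'   which reduces to the classical pooled SD when `n1 = n2`;
#' * `"cohen_pooled"`: Cohen's pooled SD,
#'   `S = sqrt[((n1-1)SD1^2 + (n2-1)SD2^2) / (n1+n2-2)]`.
#'
#' The two variants coincide at equal group sizes with equal SDs and
#' differ by a few percent otherwise.
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (here: PD).
#' @param mean2,sd2,n2 summary statistics of group 2 (here: controls).
#' @param variant denominator, `"paper"` (default) or `"cohen_pooled"`.
#' @return The signed SMD.
#' @export
#' @examples
#' smd(1, 1, 50, 0, 1, 50)   # 1
smd <- function(mean1, sd1, n1, mean2, sd2, n2,
                variant = c("paper", "cohen_pooled")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  s <- switch(variant,
    paper = sqrt((sd1^2 / n1 + sd2^2 / n2) * (n1 * n2 / (n1 + n2))),
    cohen_pooled = sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) /
                          (n1 + n2 - 2)))
  if (s == 0) stop("degenerate denominator: both group SDs are zero")
  (mean1 - mean2) / s
}

#' Qualitative magnitude of an SMD
#'
#' Conventional benchmarks: 0.20 small, 0.50 moderate, 0.80 large
#' (applied to the absolute value).
#'
#' @param smd signed or absolute SMD (vectorized).
#' @return Factor with levels `negligible`, `small`, `moderate`,
#'   `large`.
#' @export
classify_smd <- function(smd) {
  a <- abs(smd)
  cut(a, breaks = c(-Inf, 0.20, 0.50, 0.80, Inf), right = FALSE,
      labels = c("negligible", "small", "moderate", "large"))
}

#' Per-measure effect sizes of a table or ensemble
#'
#' For a complete `measure_table`, computes group means, SDs, sizes and
#' the SMD for every measure.  For an `imputed_ensemble`, the
#' statistics are pooled (averaged element-wise) over the completed
#' datasets.
#'
#' @param x a complete `measure_table` or an `imputed_ensemble`.
#' @param variant SMD denominator, see [smd()].
#' @return Data frame with one row per measure: `measure_id`,
#'   `mean_pd`, `mean_hc`, `sd_pd`, `sd_hc`, `n_pd`, `n_hc`, `smd`,
#'   `abs_smd`.
#' @export
effect_size_table <- function(x, variant = c("paper", "cohen_pooled")) {
  variant <- match.arg(variant)
  if (inherits(x, "imputed_ensemble")) {
    pooled <- pool_over_ensemble(function(tb) {
      es <- effect_size_table(tb, variant)
      as.matrix(es[, c("mean_pd", "mean_hc", "sd_pd", "sd_hc", "smd")])
    }, x)
    first <- effect_size_table(x$datasets[[1]], variant)
    out <- data.frame(measure_id = first$measure_id, pooled$mean,
                      n_pd = first$n_pd, n_hc = first$n_hc)
    out$abs_smd <- abs(out$smd)
    rownames(out) <- NULL
    return(out[, c("measure_id", "mean_pd", "mean_hc", "sd_pd", "sd_hc",
                   "n_pd", "n_hc", "smd", "abs_smd")])
  }
  stopifnot(inherits(x, "measure_table"))
  if (anyNA(x$values))
    stop("effect_size_table needs complete data; impute first")
  pd <- x$group == "PD"
  v_pd <- x$values[pd, , drop = FALSE]
  v_hc <- x$values[!pd, , drop = FALSE]
  mean_pd <- colMeans(v_pd); mean_hc <- colMeans(v_hc)
  sd_pd <- apply(v_pd, 2, stats::sd); sd_hc <- apply(v_hc, 2, stats::sd)
  d <- mapply(smd, mean_pd, sd_pd, sum(pd), mean_hc, sd_hc, sum(!pd),
              MoreArgs = list(variant = variant))
  data.frame(measure_id = measure_ids(x),
             mean_pd = mean_pd, mean_hc = mean_hc,
             sd_pd = sd_pd, sd_hc = sd_hc,
             n_pd = sum(pd), n_hc = sum(!pd),
             smd = d, abs_smd = abs(d), row.names = NULL)
}

#' Filter measures by absolute SMD
#'
#' Retains the measures whose absolute SMD strictly exceeds the
#' sensitivity threshold, sorted by decreasing absolute SMD.  The
#' absolute value is used because the direction of the parkinsonian
#' deficit differs across measures.
#'
#' @param x a complete `measure_table`, an `imputed_ensemble`, or a
#'   data frame as returned by [effect_size_table()].
#' @param threshold positive sensitivity threshold (default 0.5,
#'   a moderate effect).
#' @param variant SMD denominator, see [smd()].
#' @return The [effect_size_table()] rows passing the threshold with an
#'   added logical column `passes_threshold` (all `TRUE`), sorted by
#'   `abs_smd` descending; the full table is attached as attribute
#'   `"all_measures"`.
#' @export
filter_by_smd <- function(x, threshold = 0.5,
                          variant = c("paper", "cohen_pooled")) {
  stopifnot(threshold > 0 || (threshold == 0))
  if (!is.data.frame(x)) x <- effect_size_table(x, match.arg(variant))
  x$passes_threshold <- x$abs_smd > threshold
  kept <- x[x$passes_threshold, , drop = FALSE]
  kept <- kept[order(kept$abs_smd, decreasing = TRUE), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "all_measures") <- x
  kept
}
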