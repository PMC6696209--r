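#' Associations between selected measures and clinical scales
#'
#' Spearman rank correlation of each selected measure with each
#' clinical scale.  Scales administered to both groups (Mini-BEST, ABC)
#' are correlated over the pooled cohort; disease-specific scales
#' (PDQ-39, MDS-UPDRS) over the PD group only.  P-values are adjusted
#' for multiplicity with the Benjamini-Hochberg false-discovery-rate
#' step-up, applied separately within each scale's family of tests, and
#' flagged significant at `p_adjusted < alpha`.
#'
#' @param measures a complete `measure_table`.
#' @param clinical data frame with `subject_id`, `group`, and one
#'   column per scale; `NA` where a scale was not administered.
#' @param selected_ids measures to test.
#' @param alpha significance level on the adjusted p-value
#'   (default 0.01).
#' @param scales scale columns to use (default: every column after
#'   `subject_id`/`group`).
#' @param pooled_scales scales evaluated on the pooled cohort; all
#'   others are PD-only.
#' @return Data frame of class `association_report`: one row per
#'   (measure, scale) with `rho`, `p_raw`, `p_adjusted`, `significant`,
#'   `cohort_used`, `n`.
#' @export
associate_clinical <- function(measures, clinical, selected_ids,
                               alpha = 0.01, scales = NULL,
                               pooled_scales = c("MiniBEST", "ABC")) {
  stopifnot(inherits(measures, "measure_table"),
            alpha > 0, alpha < 1,
            all(selected_ids %in% measure_ids(measures)))
  if (is.null(scales))
    scales <- setdiff(names(clinical), c("subject_id", "group"))
  idx <- match(measures$subject_id, clinical$subject_id)
  if (anyNA(idx)) stop("clinical table is missing some subjects")
  clinical <- clinical[idx, , drop = FALSE]
  pd <- measures$group == "PD"
  out <- list()
  for (s in scales) {
    use_all <- s %in% pooled_scales
    rows <- if (use_all) rep(TRUE, length(pd)) else pd
    y <- clinical[[s]][rows]
    ok <- !is.na(y)
    if (sum(ok & pd[rows]) < 3)
      stop("scale '", s, "' has fewer than 3 non-missing PD values")
    res <- lapply(selected_ids, function(id) {
      x <- measures$values[rows, id][ok]
      ct <- suppressWarnings(
        stats::cor.test(x, y[ok], method = "spearman", exact = FALSE))
      data.frame(measure_id = id, scale = s,
                 rho = unname(ct$estimate), p_raw = ct$p.value,
                 cohort_used = if (use_all) "all" else "PD_only",
                 n = sum(ok))
    })
    fam <- do.call(rbind, res)
    fam$p_adjusted <- stats::p.adjust(fam$p_raw, method = "BH")
    fam$significant <- fam$p_adjusted < alpha
    out[[s]] <- fam
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  rep <- rep[, c("measure_id", "scale", "rho", "p_raw", "p_adjusted",
                 "significant", "cohort_used", "n")]
  class(rep) <- c("association_report", "data.frame")
  attr(rep, "alpha") <- alpha
  rep
}

#' @export
print.association_report <- function(x, ...) {
  cat("<association_report> ", length(unique(x$measure_id)), " measures x ",
      length(unique(x$scale)), " scales; ",
      sum(x$significant), " significant at BH-adjusted p < ",
      attr(x, "alpha"), "\n", sep = "")
  invisible(as.data.frame(x))
}
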