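#' Remove tasks with excessive missingness
#'
#' A task whose overall fraction of missing cells exceeds the threshold
#' in the PD group or in the pooled cohort (the default trigger) is
#' removed wholesale: all of its measures are dropped from the table and
#' the catalogue.
#'
#' @param table a `measure_table`.
#' @param cat matching `measure_catalogue`.
#' @param threshold missingness fraction in `(0, 1)` above which a task
#'   is removed; values at or below the threshold are kept.
#' @param trigger which rate must exceed the threshold: `"pooled"`
#'   (either the pooled-cohort rate or the PD rate, the default) or
#'   `"both_groups"` (both group rates).
#' @return A list with elements `table`, `catalogue` (both reduced) and
#'   `removed_tasks` (data frame log with the offending rates).
#' @export
drop_high_missing_tasks <- function(table, cat, threshold = 0.20,
                                    trigger = c("pooled", "both_groups")) {
  stopifnot(threshold > 0, threshold < 1)
  trigger <- match.arg(trigger)
  mt <- missingness_by_task(table, cat)
  hit <- switch(trigger,
                pooled = mt$frac_all > threshold | mt$frac_pd > threshold,
                both_groups = mt$frac_pd > threshold & mt$frac_hc > threshold)
  removed <- mt[hit, , drop = FALSE]
  out_cat <- cat
  out_tab <- table
  for (tk in removed$task) {
    out_cat <- drop_task(out_cat, tk)
  }
  if (nrow(removed)) {
    out_tab <- subset_measures(table, out_cat$measure_id)
  }
  list(table = out_tab, catalogue = out_cat, removed_tasks = removed)
}

#' Worst-case single-value imputation (categories A and D)
#'
#' Subjects who fell during a task or produced no detectable
#' anticipatory adjustment are presumed more impaired than anyone who
#' completed it.  Each such cell is replaced by the worst observed value
#' of the measure over the pooled cohort, pushed a further two observed
#' standard deviations into the impaired direction: `max + 2*SD` when
#' higher values are worse, `min - 2*SD` when lower values are worse.
#' All imputed cells of a measure receive the same anchor value, so this
#' track is deterministic.
#'
#' @param table a `measure_table`.
#' @param cat matching `measure_catalogue` providing the impairment
#'   direction of each measure.
#' @return The completed-for-A/D `measure_table` (other missing cells
#'   untouched), with an attribute `"worst_case_anchors"` recording the
#'   anchor used per imputed measure.
#' @export
impute_worst_case <- function(table, cat) {
  check_table_catalogue(table, cat)
  dir <- stats::setNames(cat$impairment_direction, cat$measure_id)
  values <- table$values
  miss <- table$miss_code
  anchors <- c()
  for (id in measure_ids(table)) {
    cells <- miss[, id] %in% .worst_case_codes
    if (!any(cells)) next
    obs <- values[!is.na(values[, id]), id]
    if (length(obs) < 2)
      stop("cannot impute measure '", id,
           "': fewer than 2 observed values (SD undefined)")
    s <- stats::sd(obs)
    anchor <- if (dir[id] == "higher_is_worse") max(obs) + 2 * s
              else min(obs) - 2 * s
    values[cells, id] <- anchor
    miss[cells, id] <- "Observed"
    anchors[id] <- anchor
  }
  out <- measure_table(values, table$group, table$subject_id, miss)
  attr(out, "worst_case_anchors") <- anchors
  out
}

## one chained-equations sweep over the columns with missing cells;
## predictive-mean-matching draws with a Bayesian-ish coefficient
## perturbation.  predictors: group indicator + the `n_pred` columns
## most correlated with the target (computed on the current completed
## data).
.pmm_sweep <- function(values, miss_idx, group_num, n_pred, donors) {
  for (id in names(miss_idx)) {
    rows <- miss_idx[[id]]
    y_obs_rows <- setdiff(seq_len(nrow(values)), rows)
    others <- setdiff(colnames(values), id)
    cors <- abs(suppressWarnings(
      stats::cor(values[, others, drop = FALSE], values[, id])))
    cors[is.na(cors)] <- 0
    top <- others[order(cors, decreasing = TRUE)][seq_len(min(n_pred,
                                                              length(others)))]
    X <- cbind(1, group_num, values[, top, drop = FALSE])
    fit <- stats::lm.fit(X[y_obs_rows, , drop = FALSE], values[y_obs_rows, id])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    sigma <- sqrt(sum(fit$residuals^2) /
                    max(1, length(y_obs_rows) - sum(!is.na(fit$coefficients))))
    # perturb coefficients to propagate estimation uncertainty between
    # imputed datasets
    beta_star <- beta + stats::rnorm(length(beta)) * sigma /
      sqrt(pmax(colSums(X[y_obs_rows, , drop = FALSE]^2), 1))
    pred_obs <- drop(X[y_obs_rows, , drop = FALSE] %*% beta_star)
    pred_mis <- drop(X[rows, , drop = FALSE] %*% beta_star)
    for (r in seq_along(rows)) {
      d <- order(abs(pred_obs - pred_mis[r]))[seq_len(min(donors,
                                                          length(pred_obs)))]
      values[rows[r], id] <- values[y_obs_rows[d[sample.int(length(d), 1)]], id]
    }
  }
  values
}

#' Multiple imputation by chained equations (categories B, C and E)
#'
#' Completes the randomly missing cells with `m` stochastic draws using
#' chained equations with predictive-mean-matching: each incomplete
#' measure is regressed on the group label and its most-correlated
#' companion measures, coefficients are perturbed, and each missing cell
#' receives the observed value of a donor whose prediction is closest.
#' Cells already completed by the worst-case track (categories A/D) are
#' identical across all `m` datasets.
#'
#' @param table a `measure_table`; any remaining `A_Fall`/`D_NoAPA`
#'   cells must have been imputed first (see [impute_worst_case()]).
#' @param m number of completed datasets (default 25).
#' @param seed integer seed; the full ensemble is reproducible from it.
#' @param n_iter chained-equation sweeps per dataset (default 10).
#' @param n_pred number of companion-measure predictors (default 5).
#' @param donors donor-pool size for predictive mean matching
#'   (default 5).
#' @return An object of class `imputed_ensemble`: a list with
#'   `datasets` (list of `m` complete `measure_table`s) and `provenance`
#'   (data frame of imputed cells and their track).
#' @export
impute_multiple <- function(table, m = 25, seed = 1L, n_iter = 10,
                            n_pred = 5, donors = 5) {
  stopifnot(m >= 1)
  if (any(table$miss_code %in% .worst_case_codes))
    stop("worst-case cells (categories A/D) present: run ",
         "impute_worst_case() before multiple imputation")
  values0 <- table$values
  entirely_missing <- colSums(!is.na(values0)) == 0
  if (any(entirely_missing))
    stop("measure entirely missing: ",
         paste(colnames(values0)[entirely_missing], collapse = ", "))
  miss_idx <- lapply(as.data.frame(is.na(values0)), which)
  miss_idx <- miss_idx[vapply(miss_idx, length, 1L) > 0]
  group_num <- as.numeric(table$group == "PD")
  set.seed(seed)
  obs_complete <- matrix("Observed", nrow(values0), ncol(values0),
                         dimnames = dimnames(values0))
  datasets <- vector("list", m)
  for (k in seq_len(m)) {
    vals <- values0
    # initialize missing cells at the observed column mean
    for (id in names(miss_idx)) {
      vals[miss_idx[[id]], id] <- mean(values0[, id], na.rm = TRUE)
    }
    if (length(miss_idx)) {
      for (it in seq_len(n_iter)) {
        vals <- .pmm_sweep(vals, miss_idx, group_num, n_pred, donors)
      }
    }
    datasets[[k]] <- measure_table(vals, table$group, table$subject_id,
                                   obs_complete)
  }
  prov <- do.call(rbind, lapply(names(miss_idx), function(id) {
    data.frame(measure_id = id, row = miss_idx[[id]],
               code = table$miss_code[miss_idx[[id]], id],
               track = "multiple_imputation")
  }))
  structure(list(datasets = datasets, provenance = prov, seed = seed),
            class = "imputed_ensemble")
}

#' @export
print.imputed_ensemble <- function(x, ...) {
  cat("<imputed_ensemble> m = ", length(x$datasets), " completed datasets, ",
      if (is.null(x$provenance)) 0 else nrow(x$provenance),
      " stochastically imputed cells\n", sep = "")
  invisible(x)
}

#' Pool a statistic over an imputed ensemble
#'
#' Applies `stat_fn` to every completed dataset and returns the
#' element-wise mean (the pooled analysis) together with the
#' across-dataset SD as a between-imputation diagnostic.
#'
#' @param stat_fn function mapping a complete `measure_table` to a
#'   numeric vector/matrix of fixed shape.
#' @param ensemble an `imputed_ensemble`.
#' @return List with `mean` and `sd`, each shaped like one `stat_fn`
#'   result.
#' @export
pool_over_ensemble <- function(stat_fn, ensemble) {
  stopifnot(inherits(ensemble, "imputed_ensemble"))
  res <- lapply(ensemble$datasets, stat_fn)
  shapes <- vapply(res, function(r) paste(dim(r) %||% length(r),
                                          collapse = "x"), "")
  if (length(unique(shapes)) != 1)
    stop("stat_fn returned results of differing shape across datasets")
  arr <- simplify2array(res)
  nd <- length(dim(arr))
  if (nd <= 1) {
    list(mean = mean(arr), sd = stats::sd(arr))
  } else {
    m <- apply(arr, seq_len(nd - 1), mean)
    s <- apply(arr, seq_len(nd - 1), stats::sd)
    list(mean = m, sd = s)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
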