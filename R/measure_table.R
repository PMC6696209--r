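.miss_codes <- c("Observed", "A_Fall", "B_Skip", "C_NotUsable",
                 "D_NoAPA", "E_Noisy")

# categories imputed by the worst-case single-value track: subjects who
# fell (A) or produced no detectable anticipatory adjustment (D) are
# presumed most impaired
.worst_case_codes <- c("A_Fall", "D_NoAPA")
.mi_codes <- c("B_Skip", "C_NotUsable", "E_Noisy")

#' Subjects-by-measures table with missingness categories
#'
#' Container for one testing session: a numeric matrix of measure values
#' (rows = subjects, columns = measures matching a catalogue), the group
#' label of each subject (`PD` or `HC`), and a parallel character matrix
#' of per-cell missingness category codes.  Every missing value carries
#' a non-`Observed` code and vice versa.
#'
#' Missingness categories: `A_Fall` (subject fell during the task),
#' `B_Skip` (task skipped for fatigue/time), `C_NotUsable` (technical
#' problems with the raw sensor data), `D_NoAPA` (no detectable
#' anticipatory postural adjustment), `E_Noisy` (baseline too noisy for
#' the detection algorithm).
#'
#' @param values numeric matrix, subjects x measures, `NA` for missing
#'   cells; column names are measure ids.
#' @param group character/factor of `"PD"`/`"HC"`, one per subject.
#' @param subject_id character vector of unique subject ids.
#' @param miss_code character matrix of codes, same shape as `values`;
#'   if omitted, all-`Observed` is assumed (no `NA`s allowed then).
#' @return An object of class `measure_table`.
#' @export
measure_table <- function(values, group, subject_id = rownames(values),
                          miss_code = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(subject_id)) subject_id <- sprintf("S%03d", seq_len(n))
  group <- factor(as.character(group), levels = c("PD", "HC"))
  stopifnot(length(group) == n, !anyNA(group),
            length(subject_id) == n, !anyDuplicated(subject_id),
            !is.null(colnames(values)))
  if (is.null(miss_code)) {
    miss_code <- matrix("Observed", n, ncol(values),
                        dimnames = dimnames(values))
  }
  miss_code <- as.matrix(miss_code)
  stopifnot(identical(dim(miss_code), dim(values)))
  if (!all(miss_code %in% .miss_codes))
    stop("unknown missingness code: ",
         paste(unique(setdiff(miss_code, .miss_codes)), collapse = ", "))
  dimnames(miss_code) <- dimnames(values)
  if (!identical(unname(is.na(values)), unname(miss_code != "Observed")))
    stop("miss_code inconsistent with NA pattern: every missing value ",
         "must carry a non-Observed code and every observed value the ",
         "code 'Observed'")
  rownames(values) <- rownames(miss_code) <- subject_id
  structure(list(subject_id = subject_id, group = group,
                 values = values, miss_code = miss_code),
            class = "measure_table")
}

#' @export
print.measure_table <- function(x, ...) {
  cat("<measure_table> ", nrow(x$values), " subjects (",
      sum(x$group == "PD"), " PD / ", sum(x$group == "HC"), " HC) x ",
      ncol(x$values), " measures; ",
      sum(is.na(x$values)), " missing cells\n", sep = "")
  invisible(x)
}

#' Measure ids of a table
#' @param table a `measure_table`.
#' @return Character vector of column ids.
#' @export
measure_ids <- function(table) colnames(table$values)

#' Restrict a table to a subset of measures
#' @param table a `measure_table`.
#' @param ids measure ids to keep (order preserved as given).
#' @return A `measure_table` with only those columns.
#' @export
subset_measures <- function(table, ids) {
  stopifnot(all(ids %in% measure_ids(table)))
  measure_table(table$values[, ids, drop = FALSE], table$group,
                table$subject_id, table$miss_code[, ids, drop = FALSE])
}

#' Check that a table's columns match a catalogue
#' @keywords internal
check_table_catalogue <- function(table, cat) {
  if (!setequal(measure_ids(table), cat$measure_id))
    stop("measure_table columns do not match catalogue measure ids")
  invisible(TRUE)
}

#' Per-(task, group) missingness fractions
#'
#' @param table a `measure_table`.
#' @param cat matching `measure_catalogue`.
#' @return Data frame with columns `task`, `frac_pd`, `frac_hc`,
#'   `frac_all`: the fraction of missing cells among all cells of that
#'   task's measures, by group and pooled.
#' @export
missingness_by_task <- function(table, cat) {
  check_table_catalogue(table, cat)
  tasks <- unique(as.character(cat$task))
  rows <- lapply(tasks, function(tk) {
    ids <- cat$measure_id[cat$task == tk]
    v <- table$values[, ids, drop = FALSE]
    pd <- table$group == "PD"
    data.frame(task = tk,
               frac_pd = mean(is.na(v[pd, , drop = FALSE])),
               frac_hc = mean(is.na(v[!pd, , drop = FALSE])),
               frac_all = mean(is.na(v)))
  })
  do.call(rbind, rows)
}

#' Write / read a measure table as a CSV pair
#'
#' The values go to `path`, the per-cell missingness codes to a parallel
#' CSV with suffix `_misscodes` (same shape).  First two columns are
#' `subject_id` and `group`.
#'
#' @param table a `measure_table`.
#' @param path CSV path for the values.
#' @return `write_measure_table`: paths, invisibly.
#'   `read_measure_table`: a `measure_table`.
#' @export
write_measure_table <- function(table, path) {
  df <- data.frame(subject_id = table$subject_id,
                   group = as.character(table$group),
                   table$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  mpath <- sub("(\\.csv)?$", "_misscodes.csv", path)
  mdf <- data.frame(subject_id = table$subject_id,
                    group = as.character(table$group),
                    table$miss_code, check.names = FALSE)
  utils::write.csv(mdf, mpath, row.names = FALSE)
  invisible(c(values = path, miss_code = mpath))
}

#' @rdname write_measure_table
#' @export
read_measure_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mpath <- sub("(\\.csv)?$", "_misscodes.csv", path)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  miss <- NULL
  if (file.exists(mpath)) {
    mdf <- utils::read.csv(mpath, check.names = FALSE)
    miss <- as.matrix(mdf[, -(1:2), drop = FALSE])
  }
  measure_table(vals, df$group, df$subject_id, miss)
}
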