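#' Measure catalogue
#'
#' The full battery comprises 93 objective balance measures across five
#' domains of postural control: quiet-stance sway (Sway), anticipatory
#' postural adjustments before step initiation (APA), automatic postural
#' responses to a push-and-release perturbation (APR), walking measures
#' (Gait, including derived dual-task-cost measures) and limits of
#' stability (LOS).  A catalogue is a data frame with one row per
#' measure descriptor.
#'
#' @name catalogue
#' @keywords internal
NULL

.domains <- c("Sway", "APA", "APR", "Gait", "LOS")

.tasks <- c("EOFirm", "ECFirm", "EOFoam", "ECFoam",
            "ISAW_stand_ST", "ISAW_stand_DT",
            "Gait_ST", "Gait_DT", "Gait_DC",
            "APA_ST", "APA_DT", "PushRelease", "LOS")

.dual_task_tasks <- c("ISAW_stand_DT", "Gait_DT", "APA_DT")

#' Construct a measure catalogue
#'
#' @param base_name character vector of base measure names.
#' @param domain balance domain, one of `"Sway"`, `"APA"`, `"APR"`,
#'   `"Gait"`, `"LOS"`.
#' @param task task/condition under which the measure is collected.
#' @param impairment_direction `"higher_is_worse"` or `"lower_is_worse"`:
#'   the direction in which disease moves the measure, used by
#'   worst-case imputation.
#' @param is_derived logical; `TRUE` only for dual-task-cost measures.
#'
#' @return A data frame of class `measure_catalogue` with columns
#'   `measure_id`, `base_name`, `domain`, `task`, `is_dual_task`,
#'   `is_derived`, `impairment_direction`, ordered by
#'   (domain, task, base_name).
#' @export
new_catalogue <- function(base_name, domain, task, impairment_direction,
                          is_derived = FALSE) {
  stopifnot(length(base_name) == length(domain),
            length(base_name) == length(task),
            length(base_name) == length(impairment_direction))
  if (!all(domain %in% .domains))
    stop("unknown domain: ", paste(setdiff(domain, .domains), collapse = ", "))
  if (!all(task %in% .tasks))
    stop("unknown task: ", paste(setdiff(task, .tasks), collapse = ", "))
  if (!all(impairment_direction %in% c("higher_is_worse", "lower_is_worse")))
    stop("impairment_direction must be 'higher_is_worse' or 'lower_is_worse'")
  is_derived <- rep_len(is_derived, length(base_name))
  if (any(is_derived & task != "Gait_DC"))
    stop("derived (dual-task-cost) measures must have task 'Gait_DC'")
  cat <- data.frame(
    measure_id = paste(task, base_name, sep = "."),
    base_name = base_name,
    domain = factor(domain, levels = .domains),
    task = factor(task, levels = .tasks),
    is_dual_task = task %in% .dual_task_tasks,
    is_derived = is_derived,
    impairment_direction = impairment_direction,
    stringsAsFactors = FALSE
  )
  cat <- cat[order(cat$domain, cat$task, cat$base_name), , drop = FALSE]
  rownames(cat) <- NULL
  if (anyDuplicated(cat$measure_id))
    stop("duplicate measure_id in catalogue")
  class(cat) <- c("measure_catalogue", "data.frame")
  cat
}

#' Build the default 93-measure catalogue
#'
#' Seven sway measures instantiated under six standing tasks (42), twelve
#' gait measures under single- and dual-task walking (24) plus five
#' derived dual-task-cost measures, six anticipatory-postural-adjustment
#' measures under single- and dual-task step initiation (12), seven
#' push-and-release stepping-response measures, and three
#' limits-of-stability measures: 93 in total.
#'
#' Impairment directions encode the direction of the parkinsonian
#' deficit: larger sway amplitude, longer latencies and times, and more
#' steps are worse; larger range of motion, speed, length, and lean
#' range are better (so smaller is worse).
#'
#' @return A `measure_catalogue` with 93 rows.
#' @export
#' @examples
#' cat <- build_default_catalogue()
#' nrow(cat)           # 93
#' table(cat$domain)
build_default_catalogue <- function() {
  sway_base <- c(RMS_ML = "higher_is_worse",
                 RMS_AP = "higher_is_worse",
                 Jerk_ML = "higher_is_worse",
                 Jerk_AP = "higher_is_worse",
                 Sway_area = "higher_is_worse",
                 Mean_velocity = "higher_is_worse",
                 Frequency_dispersion = "higher_is_worse")
  sway_tasks <- c("EOFirm", "ECFirm", "EOFoam", "ECFoam",
                  "ISAW_stand_ST", "ISAW_stand_DT")
  gait_base <- c(Gait_speed = "lower_is_worse",
                 Stride_length = "lower_is_worse",
                 Foot_strike_angle = "lower_is_worse",
                 Toe_off_angle = "lower_is_worse",
                 Arm_ROM = "lower_is_worse",
                 Trunk_ROM = "lower_is_worse",
                 Turn_velocity = "lower_is_worse",
                 Turn_duration = "higher_is_worse",
                 Turn_steps = "higher_is_worse",
                 Stance_time = "higher_is_worse",
                 Double_support_time = "higher_is_worse",
                 Gait_cycle_SD = "higher_is_worse")
  # dual-task cost is signed percent change; for speed/length measures a
  # more negative cost is worse, for time measures a larger cost is worse
  dc_base <- c(DC_Gait_speed = "lower_is_worse",
               DC_Stride_length = "lower_is_worse",
               DC_Stance_time = "higher_is_worse",
               DC_Double_support_time = "higher_is_worse",
               DC_Gait_cycle_SD = "higher_is_worse")
  apa_base <- c(Peak_accel_ML = "lower_is_worse",
                Peak_accel_AP = "lower_is_worse",
                APA_duration = "higher_is_worse",
                First_step_ROM = "lower_is_worse",
                First_step_duration = "higher_is_worse",
                First_step_velocity = "lower_is_worse")
  apr_base <- c(Step_latency = "higher_is_worse",
                First_step_length = "lower_is_worse",
                First_step_velocity = "lower_is_worse",
                Time_to_stability = "higher_is_worse",
                Num_recovery_steps = "higher_is_worse",
                Trunk_displacement = "higher_is_worse",
                Step_duration = "higher_is_worse")
  los_base <- c(Forward_range = "lower_is_worse",
                Backward_range = "lower_is_worse",
                Total_range = "lower_is_worse")

  blocks <- list(
    list(base = sway_base, domain = "Sway", tasks = sway_tasks),
    list(base = gait_base, domain = "Gait", tasks = c("Gait_ST", "Gait_DT")),
    list(base = dc_base, domain = "Gait", tasks = "Gait_DC", derived = TRUE),
    list(base = apa_base, domain = "APA", tasks = c("APA_ST", "APA_DT")),
    list(base = apr_base, domain = "APR", tasks = "PushRelease"),
    list(base = los_base, domain = "LOS", tasks = "LOS")
  )
  parts <- lapply(blocks, function(b) {
    grid <- expand.grid(base = names(b$base), task = b$tasks,
                        stringsAsFactors = FALSE)
    data.frame(base_name = grid$base,
               domain = b$domain,
               task = grid$task,
               impairment_direction = unname(b$base[grid$base]),
               is_derived = isTRUE(b$derived),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  new_catalogue(all$base_name, all$domain, all$task,
                all$impairment_direction, all$is_derived)
}

#' Remove all measures of one task from a catalogue
#'
#' @param cat a `measure_catalogue`.
#' @param task a single task name present in the task taxonomy.
#' @return The catalogue without descriptors of that task; the input is
#'   unchanged.
#' @export
#' @examples
#' nrow(drop_task(build_default_catalogue(), "ECFoam"))  # 86
drop_task <- function(cat, task) {
  stopifnot(inherits(cat, "measure_catalogue"), length(task) == 1L)
  if (!task %in% .tasks)
    stop("unknown task: '", task, "'")
  out <- cat[cat$task != task, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dual-task cost of a gait measure
#'
#' Percent change of a measure from single-task (ST) to cognitive
#' dual-task (DT) walking: `100 * (dt - st) / st`.  The cost is signed;
#' for speed-like measures a more negative cost indicates greater
#' dual-task interference.
#'
#' @param st_value measure value under single task (nonzero).
#' @param dt_value measure value under dual task.
#' @return Dual-task cost in percent.
#' @export
#' @examples
#' dual_task_cost(100, 75)  # -25
dual_task_cost <- function(st_value, dt_value) {
  stopifnot(is.numeric(st_value), is.numeric(dt_value))
  if (any(st_value == 0))
    stop("undefined dual-task cost: single-task value is zero")
  100 * (dt_value - st_value) / st_value
}

#' @export
print.measure_catalogue <- function(x, ...) {
  cat("<measure_catalogue> ", nrow(x), " measures\n", sep = "")
  print(table(domain = x$domain))
  invisible(x)
}

#' Write a catalogue to CSV
#'
#' @param cat a `measure_catalogue`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_catalogue_csv <- function(cat, path) {
  utils::write.csv(as.data.frame(cat), path, row.names = FALSE)
  invisible(path)
}
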