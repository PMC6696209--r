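#' Synthetic-cohort configuration
#'
#' Describes the statistical structure of a simulated cohort: group
#' sizes, the per-measure planted standardized mean difference (SMD)
#' between PD and controls, within-domain and cross-domain correlation
#' structure, planted redundant measure pairs, per-(task, group)
#' missingness with category codes, per-measure retest reliability
#' (ICC), and clinical-scale models driven by a latent impairment
#' factor.
#'
#' The generative model is a Gaussian factor model.  Each subject
#' carries a latent impairment factor `f = z + mu_latent * 1[PD]` with
#' `z ~ N(0,1)`.  A measure's standardized signal loads
#' `sqrt(cross_block_correlation)` on `z`, `sqrt(block - cross)` on a
#' domain factor, and the remainder on unique noise, so that within-
#' domain correlation is `block_correlation[domain]` and cross-domain
#' correlation is `cross_block_correlation`.  Planted redundant
#' measures are a `rho`-mixture of their partner's signal with fresh
#' noise.  The group effect enters as a mean shift equal to the planted
#' SMD (within-group SD is 1), signed by the measure's impairment
#' direction.
#'
#' @param n_pd,n_hc group sizes.
#' @param catalogue a `measure_catalogue`.
#' @param smd_profile named numeric vector, measure_id -> planted
#'   absolute SMD; ids absent from the vector default to 0.
#' @param block_correlation named numeric, domain -> within-domain
#'   correlation in `[0, 1)`.
#' @param cross_block_correlation common correlation across domains;
#'   must not exceed any within-domain value.
#' @param redundancy data frame with columns `redundant_id`,
#'   `partner_id`, `rho`: planted high-correlation pairs.
#' @param missingness_spec data frame with columns `task`, `group`,
#'   `rate`, `category`; category `A_Fall`/`D_NoAPA` masks are applied
#'   to the most-impaired subjects first (informative missingness),
#'   `B_Skip`/`C_NotUsable`/`E_Noisy` completely at random.
#' @param retest_icc named numeric, measure_id -> planted test-retest
#'   ICC in `(0, 1]`; `retest_icc_default` fills the rest.
#' @param retest_icc_default default planted ICC.
#' @param clinical_loading named list of clinical-scale models, each a
#'   list with `intercept`, `slope` (on the latent factor), `noise_sd`,
#'   `min`, `max`, `pd_only`.
#' @param mu_latent mean shift of the latent impairment factor in PD.
#' @param seed integer seed making generation reproducible.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_pd = 144, n_hc = 79,
                         catalogue = build_default_catalogue(),
                         smd_profile = numeric(0),
                         block_correlation = c(Sway = 0.25, APA = 0.25,
                                               APR = 0.25, Gait = 0.25,
                                               LOS = 0.25),
                         cross_block_correlation = 0.15,
                         redundancy = NULL,
                         missingness_spec = NULL,
                         retest_icc = numeric(0),
                         retest_icc_default = 0.85,
                         clinical_loading = default_clinical_loading(),
                         mu_latent = 1.5,
                         seed = 1L) {
  stopifnot(inherits(catalogue, "measure_catalogue"),
            n_pd >= 2, n_hc >= 2)
  ids <- catalogue$measure_id
  prof <- stats::setNames(numeric(length(ids)), ids)
  if (length(smd_profile)) {
    bad <- setdiff(names(smd_profile), ids)
    if (length(bad)) stop("smd_profile names not in catalogue: ",
                          paste(bad, collapse = ", "))
    prof[names(smd_profile)] <- smd_profile
  }
  if (!all(.domains %in% names(block_correlation)))
    stop("block_correlation must name every domain")
  if (any(block_correlation < 0 | block_correlation >= 1))
    stop("block correlations must lie in [0, 1)")
  if (cross_block_correlation < 0 ||
      cross_block_correlation > min(block_correlation))
    stop("non-positive-definite block structure: cross-domain ",
         "correlation must lie in [0, min(within-domain)]")
  if (is.null(redundancy))
    redundancy <- data.frame(redundant_id = character(0),
                             partner_id = character(0), rho = numeric(0))
  stopifnot(all(c("redundant_id", "partner_id", "rho") %in%
                  names(redundancy)))
  if (nrow(redundancy)) {
    stopifnot(all(redundancy$redundant_id %in% ids),
              all(redundancy$partner_id %in% ids),
              all(abs(redundancy$rho) < 1),
              !anyDuplicated(redundancy$redundant_id))
    # chains (a redundant measure anchoring a further twin) are allowed,
    # cycles are not: generation needs a topological order
    if (is.null(.redundancy_order(redundancy)))
      stop("redundancy pairs form a cycle")
  }
  if (is.null(missingness_spec))
    missingness_spec <- data.frame(task = character(0), group = character(0),
                                   rate = numeric(0), category = character(0))
  stopifnot(all(c("task", "group", "rate", "category") %in%
                  names(missingness_spec)))
  if (nrow(missingness_spec)) {
    stopifnot(all(missingness_spec$task %in% as.character(catalogue$task)),
              all(missingness_spec$group %in% c("PD", "HC")),
              all(missingness_spec$rate >= 0 & missingness_spec$rate <= 1),
              all(missingness_spec$category %in% setdiff(.miss_codes,
                                                         "Observed")))
  }
  icc <- stats::setNames(rep(retest_icc_default, length(ids)), ids)
  if (length(retest_icc)) {
    bad <- setdiff(names(retest_icc), ids)
    if (length(bad)) stop("retest_icc names not in catalogue: ",
                          paste(bad, collapse = ", "))
    icc[names(retest_icc)] <- retest_icc
  }
  if (any(icc <= 0 | icc > 1)) stop("retest ICCs must lie in (0, 1]")
  structure(list(n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
                 catalogue = catalogue, smd_profile = prof,
                 block_correlation = block_correlation,
                 cross_block_correlation = cross_block_correlation,
                 redundancy = redundancy,
                 missingness_spec = missingness_spec,
                 retest_icc = icc,
                 clinical_loading = clinical_loading,
                 mu_latent = mu_latent, seed = as.integer(seed)),
            class = "synth_config")
}

## topological order of redundancy rows (partners before their twins);
## NULL if the pair graph has a cycle
.redundancy_order <- function(redundancy) {
  remaining <- seq_len(nrow(redundancy))
  done <- setdiff(unique(redundancy$partner_id), redundancy$redundant_id)
  order <- integer(0)
  while (length(remaining)) {
    ready <- remaining[!(redundancy$partner_id[remaining] %in%
                           redundancy$redundant_id) |
                         redundancy$partner_id[remaining] %in% done]
    if (!length(ready)) return(NULL)
    order <- c(order, ready)
    done <- c(done, redundancy$redundant_id[ready])
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Default clinical-scale generative models
#'
#' Scales are a linear function of the latent impairment factor plus
#' Gaussian noise, truncated to each instrument's natural range:
#' Mini-BEST 0-28 and ABC 0-100 (administered to both groups, lower is
#' worse), PDQ-39 total and mobility sub-score 0-100, MDS-UPDRS total
#' 0-260, Part II 0-52 and Part III 0-132 (PD only, higher is worse).
#' Intercepts and slopes are set so group summaries resemble a typical
#' moderate-severity PD cohort.
#'
#' @return Named list of scale models.
#' @export
default_clinical_loading <- function() {
  list(
    MiniBEST      = list(intercept = 24, slope = -3.5, noise_sd = 1.5,
                         min = 0, max = 28,  pd_only = FALSE),
    ABC           = list(intercept = 96, slope = -9,   noise_sd = 3,
                         min = 0, max = 100, pd_only = FALSE),
    PDQ39_total   = list(intercept = 8,  slope = 6,    noise_sd = 5,
                         min = 0, max = 100, pd_only = TRUE),
    PDQ39_mobility = list(intercept = 5, slope = 8,    noise_sd = 6,
                         min = 0, max = 100, pd_only = TRUE),
    UPDRS_total   = list(intercept = 45, slope = 16,   noise_sd = 8,
                         min = 0, max = 260, pd_only = TRUE),
    UPDRS_II      = list(intercept = 4,  slope = 6,    noise_sd = 3,
                         min = 0, max = 52,  pd_only = TRUE),
    UPDRS_III     = list(intercept = 25, slope = 10,   noise_sd = 6,
                         min = 0, max = 132, pd_only = TRUE)
  )
}

#' Default study configuration
#'
#' The configuration emulating the study cohort the pipeline was
#' designed around: 144 PD and 79 control subjects over the default
#' 93-measure catalogue.
#'
#' Planted structure:
#' * 44 sensitive measures (absolute SMD 1.0-1.32) distributed
#'   Gait (15) > APA (12) > Sway (10) > APR (7), with the four headline
#'   measures (turn velocity, foot-strike angle, arm ROM in single-task
#'   gait; first-step ROM at step initiation) at the top; all LOS and
#'   eyes-closed-foam sway measures are planted null, as are the
#'   remaining 49 measures.
#' * 20 of the 44 sensitive measures are planted redundant (pairwise
#'   latent correlation 0.85 with a more-sensitive or single-task
#'   partner): 9 dual-task twins and 11 smaller-SMD twins, leaving 24
#'   planted-independent sensitive measures.
#' * Missingness: eyes-closed foam stance 38.9% PD / 11.4% HC (falls,
#'   informative); eyes-open foam 13.9% / 2.5% (falls); push-and-release
#'   13.9% PD split between falls and unusable data, 1.3% HC unusable;
#'   dual-task step initiation 12.5% PD split between no-APA and noisy
#'   baseline, 5.1% HC noisy baseline.
#' * Retest ICCs 0.95 / 0.97 / 0.96 / 0.82 for the four headline
#'   measures, 0.85 elsewhere.
#'
#' @param seed integer seed stored in the configuration.
#' @return A `synth_config`.
#' @export
default_study_config <- function(seed = 1L) {
  smd <- c(
    ## Gait, single task
    Gait_ST.Gait_speed = 1.27, Gait_ST.Stride_length = 1.00,
    Gait_ST.Foot_strike_angle = 1.31, Gait_ST.Toe_off_angle = 1.00,
    Gait_ST.Arm_ROM = 1.28, Gait_ST.Trunk_ROM = 1.00,
    Gait_ST.Turn_velocity = 1.32, Gait_ST.Turn_duration = 1.00,
    Gait_ST.Double_support_time = 1.26, Gait_ST.Gait_cycle_SD = 1.00,
    ## Gait, dual task (sensitive twins of the strongest single-task ones)
    Gait_DT.Gait_speed = 1.08, Gait_DT.Foot_strike_angle = 1.10,
    Gait_DT.Arm_ROM = 1.06,
    ## Gait, dual-task cost
    Gait_DC.DC_Gait_speed = 1.05, Gait_DC.DC_Stride_length = 1.03,
    ## APA, single task
    APA_ST.First_step_ROM = 1.28, APA_ST.Peak_accel_ML = 1.22,
    APA_ST.Peak_accel_AP = 1.15, APA_ST.APA_duration = 1.10,
    APA_ST.First_step_duration = 1.08, APA_ST.First_step_velocity = 1.18,
    ## APA, dual task
    APA_DT.First_step_ROM = 1.15, APA_DT.Peak_accel_ML = 1.09,
    APA_DT.Peak_accel_AP = 1.02, APA_DT.APA_duration = 1.00,
    APA_DT.First_step_duration = 1.00, APA_DT.First_step_velocity = 1.05,
    ## Sway
    EOFoam.RMS_ML = 1.25, EOFoam.RMS_AP = 1.24, EOFoam.Mean_velocity = 1.27,
    EOFoam.Jerk_ML = 1.00, EOFoam.Jerk_AP = 1.00, EOFoam.Sway_area = 1.00,
    EOFoam.Frequency_dispersion = 1.02,
    EOFirm.RMS_ML = 1.24, EOFirm.RMS_AP = 1.00, ECFirm.RMS_ML = 1.00,
    ## APR (push and release)
    PushRelease.Step_latency = 1.26, PushRelease.First_step_length = 1.24,
    PushRelease.First_step_velocity = 1.00,
    PushRelease.Time_to_stability = 1.00,
    PushRelease.Num_recovery_steps = 1.02,
    PushRelease.Trunk_displacement = 1.01, PushRelease.Step_duration = 1.04
  )
  redundancy <- rbind(
    ## dual-task twins of single-task measures (pruning rule 2 territory)
    data.frame(redundant_id = c("Gait_DT.Gait_speed",
                                "Gait_DT.Foot_strike_angle",
                                "Gait_DT.Arm_ROM",
                                "APA_DT.First_step_ROM",
                                "APA_DT.Peak_accel_ML",
                                "APA_DT.Peak_accel_AP",
                                "APA_DT.APA_duration",
                                "APA_DT.First_step_duration",
                                "APA_DT.First_step_velocity"),
               partner_id = c("Gait_ST.Gait_speed",
                              "Gait_ST.Foot_strike_angle",
                              "Gait_ST.Arm_ROM",
                              "APA_ST.First_step_ROM",
                              "APA_ST.Peak_accel_ML",
                              "APA_ST.Peak_accel_AP",
                              "APA_ST.APA_duration",
                              "APA_ST.First_step_duration",
                              "APA_ST.First_step_velocity"),
               rho = 0.85),
    ## smaller-SMD twins within a task (pruning rule 1 territory)
    data.frame(redundant_id = c("Gait_ST.Stride_length",
                                "Gait_ST.Toe_off_angle",
                                "Gait_ST.Trunk_ROM",
                                "Gait_ST.Turn_duration",
                                "Gait_ST.Gait_cycle_SD",
                                "EOFoam.Jerk_ML",
                                "EOFoam.Jerk_AP",
                                "EOFoam.Sway_area",
                                "ECFirm.RMS_ML",
                                "PushRelease.First_step_velocity",
                                "PushRelease.Time_to_stability"),
               partner_id = c("Gait_ST.Gait_speed",
                              "Gait_ST.Foot_strike_angle",
                              "Gait_ST.Arm_ROM",
                              "Gait_ST.Turn_velocity",
                              "Gait_ST.Double_support_time",
                              "EOFoam.RMS_ML",
                              "EOFoam.RMS_AP",
                              "EOFoam.Mean_velocity",
                              "EOFirm.RMS_ML",
                              "PushRelease.First_step_length",
                              "PushRelease.Step_latency"),
               rho = 0.85)
  )
  missingness <- data.frame(
    task = c("ECFoam", "ECFoam", "EOFoam", "EOFoam",
             "PushRelease", "PushRelease", "PushRelease",
             "APA_DT", "APA_DT", "APA_DT"),
    group = c("PD", "HC", "PD", "HC", "PD", "PD", "HC",
              "PD", "PD", "HC"),
    rate = c(0.389, 0.114, 0.139, 0.025, 0.070, 0.069, 0.013,
             0.063, 0.062, 0.051),
    category = c("A_Fall", "A_Fall", "A_Fall", "A_Fall",
                 "A_Fall", "C_NotUsable", "C_NotUsable",
                 "D_NoAPA", "E_Noisy", "E_Noisy")
  )
  retest_icc <- c(Gait_ST.Turn_velocity = 0.95,
                  Gait_ST.Foot_strike_angle = 0.97,
                  Gait_ST.Arm_ROM = 0.96,
                  APA_ST.First_step_ROM = 0.82)
  synth_config(n_pd = 144, n_hc = 79,
               smd_profile = smd, redundancy = redundancy,
               missingness_spec = missingness, retest_icc = retest_icc,
               seed = seed)
}

#' Planted sensitive / independent measure sets of a configuration
#'
#' @param cfg a `synth_config`.
#' @param threshold SMD threshold defining "sensitive".
#' @return `planted_sensitive()`: ids with planted |SMD| above the
#'   threshold. `planted_independent()`: the planted-sensitive ids that
#'   are not planted as redundant twins.
#' @export
planted_sensitive <- function(cfg, threshold = 0.5) {
  names(cfg$smd_profile)[abs(cfg$smd_profile) > threshold]
}

#' @rdname planted_sensitive
#' @export
planted_independent <- function(cfg, threshold = 0.5) {
  setdiff(planted_sensitive(cfg, threshold), cfg$redundancy$redundant_id)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> ", x$n_pd, " PD + ", x$n_hc, " HC, ",
      nrow(x$catalogue), " measures; ",
      sum(x$smd_profile > 0), " planted sensitive (",
      nrow(x$redundancy), " redundant pairs), seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}
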