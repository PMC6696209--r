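#' Generate a synthetic cohort
#'
#' Draws a test-session measure table, a retest table (PD subjects
#' only), and a clinical-scale table from the generative model described
#' in [synth_config()], then imposes the configured missingness.  The
#' result is fully reproducible from `cfg$seed`.
#'
#' Informative missingness (`A_Fall`, `D_NoAPA`) masks the
#' most-impaired subjects of a group first (largest latent impairment
#' factor); the random categories (`B_Skip`, `C_NotUsable`, `E_Noisy`)
#' mask completely at random among the not-yet-masked subjects of the
#' task.
#'
#' @param cfg a `synth_config`.
#' @return A list of class `synth_cohort` with elements `table`
#'   (`measure_table`, test session, with missingness), `retest_table`
#'   (`measure_table`, PD subjects, complete), `clinical` (data frame,
#'   one row per subject; PD-only scales are `NA` for controls), and
#'   `truth` (the config plus the signed per-measure mean shifts and
#'   each subject's latent factor).
#' @export
#' @examples
#' coh <- generate_cohort(default_study_config(seed = 7))
#' coh$table
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  cat <- cfg$catalogue
  ids <- cat$measure_id
  p <- length(ids)
  n <- cfg$n_pd + cfg$n_hc
  group <- factor(rep(c("PD", "HC"), c(cfg$n_pd, cfg$n_hc)),
                  levels = c("PD", "HC"))
  subject_id <- sprintf("S%03d", seq_len(n))
  is_pd <- group == "PD"

  ## latent structure
  z <- stats::rnorm(n)                       # centred impairment factor
  f <- z + cfg$mu_latent * is_pd             # impairment factor
  u <- matrix(stats::rnorm(n * length(.domains)), n,
              dimnames = list(NULL, .domains))
  b <- sqrt(cfg$cross_block_correlation)
  c_d <- sqrt(cfg$block_correlation[.domains] - cfg$cross_block_correlation)
  w_d <- sqrt(1 - cfg$block_correlation[.domains])
  eps <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, ids))

  ## standardized within-group signals (variance 1); redundant measures
  ## are built from their partner's signal afterwards
  dom <- as.character(cat$domain)
  signal <- matrix(0, n, p, dimnames = list(NULL, ids))
  redundant <- ids %in% cfg$redundancy$redundant_id
  for (j in seq_len(p)) {
    if (redundant[j]) next
    d <- dom[j]
    signal[, j] <- b * z + c_d[d] * u[, d] + w_d[d] * eps[, j]
  }
  if (nrow(cfg$redundancy)) {
    for (k in .redundancy_order(cfg$redundancy)) {
      r <- cfg$redundancy$redundant_id[k]
      pt <- cfg$redundancy$partner_id[k]
      rho <- cfg$redundancy$rho[k]
      signal[, r] <- rho * signal[, pt] + sqrt(1 - rho^2) * eps[, r]
    }
  }

  ## orient by impairment direction and add the planted group shift
  sgn <- ifelse(cat$impairment_direction == "higher_is_worse", 1, -1)
  delta_signed <- sgn * cfg$smd_profile[ids]
  values <- sweep(signal, 2, sgn, `*`) +
    outer(as.numeric(is_pd), delta_signed)

  ## retest session for PD subjects: same planted mean, signal carried
  ## over with weight icc plus fresh noise, so the population ICC(2,1)
  ## equals the planted value
  icc <- cfg$retest_icc[ids]
  eta <- matrix(stats::rnorm(cfg$n_pd * p), cfg$n_pd, p)
  sig_pd <- signal[is_pd, , drop = FALSE]
  retest_sig <- sweep(sig_pd, 2, icc, `*`) +
    sweep(eta, 2, sqrt(1 - icc^2), `*`)
  retest_values <- sweep(retest_sig, 2, sgn, `*`) +
    matrix(delta_signed, cfg$n_pd, p, byrow = TRUE)
  colnames(retest_values) <- ids

  ## clinical scales from the latent impairment factor
  clinical <- data.frame(subject_id = subject_id,
                         group = as.character(group))
  for (s in names(cfg$clinical_loading)) {
    m <- cfg$clinical_loading[[s]]
    val <- m$intercept + m$slope * f + stats::rnorm(n, sd = m$noise_sd)
    val <- pmin(pmax(val, m$min), m$max)
    if (isTRUE(m$pd_only)) val[!is_pd] <- NA_real_
    clinical[[s]] <- val
  }

  ## impose missingness task-wise: a masked subject loses every measure
  ## of the task
  miss_code <- matrix("Observed", n, p, dimnames = list(NULL, ids))
  ms <- cfg$missingness_spec
  if (nrow(ms)) {
    # informative categories claim the most-impaired subjects before the
    # random categories draw from the remainder
    ms <- ms[order(!(ms$category %in% .worst_case_codes)), , drop = FALSE]
    for (k in seq_len(nrow(ms))) {
      g_idx <- which(group == ms$group[k])
      cols <- which(as.character(cat$task) == ms$task[k])
      n_mask <- round(ms$rate[k] * length(g_idx))
      if (n_mask == 0 || !length(cols)) next
      already <- miss_code[g_idx, cols[1]] != "Observed"
      avail <- g_idx[!already]
      n_mask <- min(n_mask, length(avail))
      if (ms$category[k] %in% .worst_case_codes) {
        pick <- avail[order(f[avail], decreasing = TRUE)][seq_len(n_mask)]
      } else {
        pick <- avail[sample.int(length(avail), n_mask)]
      }
      miss_code[pick, cols] <- ms$category[k]
    }
  }
  values[miss_code != "Observed"] <- NA_real_

  table <- measure_table(values, group, subject_id, miss_code)
  retest_table <- measure_table(retest_values, group[is_pd],
                                paste0(subject_id[is_pd], "_retest"))
  structure(list(table = table, retest_table = retest_table,
                 clinical = clinical,
                 truth = list(config = cfg, delta_signed = delta_signed,
                              latent = f)),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort>\n  test session: ")
  print(x$table)
  cat("  retest (PD): ", nrow(x$retest_table$values), " subjects\n",
      "  clinical scales: ",
      paste(setdiff(names(x$clinical), c("subject_id", "group")),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write the three cohort tables as CSV files
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "measures_test.csv")
  p2 <- file.path(dir, "measures_retest.csv")
  p3 <- file.path(dir, "clinical.csv")
  write_measure_table(cohort$table, p1)
  write_measure_table(cohort$retest_table, p2)
  utils::write.csv(cohort$clinical, p3, row.names = FALSE)
  truth <- list(delta_signed = as.list(cohort$truth$delta_signed),
                seed = cohort$truth$config$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(test = p1, retest = p2, clinical = p3))
}
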