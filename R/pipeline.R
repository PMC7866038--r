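#' Estimate eTSCC for every patient in a cohort
#'
#' Runs the full estimation chain per patient: the two-compartment PK model
#' gives the regimen-averaged plasma 5-FU concentration from BSA-based
#' dosing; three-phase CT Hounsfield units give the blood volume fraction
#' surrogate; the transport model scales plasma exposure by the duty cycle,
#' CEA-normalized tumor burden and BVF into the estimated tumor-site
#' concentration.
#'
#' @param cohort Patient table with columns `patient_id`, `bsa`, `bolus`,
#'   `infusion`, `delta_t`, `n_cycles`, `t_span`, `cea` (and optionally
#'   `trg` plus clinical covariates, which are carried through).
#' @param ct Long-format CT ROI table (see [perfusion_from_ct()]).
#' @param cea_ref Reference CEA (ng/mL); default 13.4.
#' @param grid_step PK output grid spacing (h).
#' @param method PK solution path: `"analytic"` (closed form, default) or
#'   `"numeric"` (ODE integration).
#' @return Tibble with one row per included patient: `patient_id`,
#'   `sigma_dbar`, `duty`, `bvf`, `sigma_T_B`, `sigma_T` (all on the ug/mL
#'   scale where applicable) plus carried-through columns.  Patients that
#'   could not be processed are recorded in `attr(, "exclusions")` with a
#'   reason code (`no_perfusion`, `pk_failure`) instead of crashing the
#'   run.
#' @examples
#' fx <- fixture_cohort()
#' est <- estimate_cohort(fx$cohort, fx$ct)
#' head(est[, c("patient_id", "sigma_dbar", "duty", "bvf", "sigma_T")])
#' @export
estimate_cohort <- function(cohort, ct, cea_ref = 13.4, grid_step = 0.1,
                            method = c("analytic", "numeric")) {
  method <- match.arg(method)
  cohort <- as_tibble(cohort)
  needed <- c("patient_id", "bsa", "bolus", "infusion", "delta_t",
              "n_cycles", "t_span", "cea")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste("cohort is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  perf <- perfusion_from_ct(ct)
  exclusions <- tibble(patient_id = character(), reason = character())
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    pv <- perf[perf$patient_id == row$patient_id, ]
    if (nrow(pv) == 0) {
      exclusions <<- bind_rows(exclusions,
                               tibble(patient_id = row$patient_id,
                                      reason = "no_perfusion"))
      return(NULL)
    }
    est <- tryCatch({
      p <- pk_params(v_ml = blood_volume(row$bsa))
      r <- regimen(bolus = row$bolus, infusion = row$infusion,
                   delta_t = row$delta_t, bsa = row$bsa,
                   n_cycles = row$n_cycles, t_span = row$t_span)
      profs <- simulate_regimen(p, r, grid_step = grid_step, method = method)
      exp_sum <- exposure_summary(profs, r)
      s_tb <- fkill0_surrogate(exp_sum$sigma_dbar, row$n_cycles, row$delta_t,
                               row$t_span, row$cea, cea_ref = cea_ref)
      mutate(row,
             sigma_dbar = exp_sum$sigma_dbar,
             duty = duty_cycle(row$n_cycles, row$delta_t, row$t_span),
             bvf = pv$bvf, bvf_clamped = pv$bvf_clamped,
             sigma_T_B = s_tb,
             sigma_T = etscc(s_tb, pv$bvf))
    }, error = function(e) {
      exclusions <<- bind_rows(exclusions,
                               tibble(patient_id = row$patient_id,
                                      reason = "pk_failure"))
      NULL
    })
    est
  })
  out <- bind_rows(rows)
  attr(out, "exclusions") <- exclusions
  out
}

#' Classify a cohort of eTSCC estimates into responders and non-responders
#'
#' Thin wrapper chaining [classifier_report()] and [loocv()] on the output
#' of [estimate_cohort()]: the eTSCC becomes the score and TRG supplies the
#' labels.
#'
#' @param estimates Output of [estimate_cohort()]; must carry `sigma_T` and
#'   `trg`.
#' @param responder_max_trg Highest TRG counted as responder; default 2.
#' @return List with `report` ([classifier_report()] object) and `cv`
#'   ([loocv()] object).
#' @export
classify_cohort <- function(estimates, responder_max_trg = 2) {
  if (!all(c("sigma_T", "trg") %in% names(estimates))) {
    abort("estimates must have `sigma_T` and `trg` columns")
  }
  scores <- labeled_scores(
    tibble(patient_id = estimates$patient_id, score = estimates$sigma_T,
           trg = estimates$trg),
    responder_max_trg
  )
  list(report = classifier_report(scores), cv = loocv(scores))
}

#' Read a regimen description from a YAML file
#'
#' Expected keys: `bolus_mg_per_m2`, `infusion_mg_per_m2`,
#' `infusion_hours`, `cycles`, `span_days`, `interval_days`.
#'
#' @param path YAML file path.
#' @param bsa Body surface area (m^2) to pair with the regimen.
#' @return A [regimen()] object.
#' @export
read_regimen_yaml <- function(path, bsa) {
  y <- yaml::read_yaml(path)
  regimen(bolus = y$bolus_mg_per_m2, infusion = y$infusion_mg_per_m2,
          delta_t = y$infusion_hours, bsa = bsa, n_cycles = y$cycles,
          t_span = y$span_days * 24, cycle_interval = y$interval_days * 24)
}

#' Export a concentration profile as CSV
#'
#' @param profile An `etscc_profile` tibble.
#' @param path Output CSV path (columns `time_h`, `sigma_B`, `sigma_P`).
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Run the whole estimation and classification pipeline from files
#'
#' Reads the cohort and CT ROI CSV tables, estimates per-patient eTSCC,
#' classifies responders, and writes the per-patient results CSV
#' (`estimates.csv`), a JSON report (`report.json`: threshold, AUC,
#' accuracies, LOOCV summary, exclusions) and a plain-text log to the
#' output directory.  Per-patient failures are logged and excluded with a
#' reason code, never fatal.  Outputs are deterministic for a given input.
#'
#' @param cohort_csv,ct_csv Input CSV paths (cohort table; long CT ROI
#'   table).
#' @param out_dir Output directory, created if absent.
#' @param cea_ref,responder_max_trg,grid_step Passed to the pipeline
#'   stages.
#' @param quiet Suppress stderr log messages.
#' @return Invisibly, a list with `estimates`, `classification`,
#'   `exclusions` and the output paths.
#' @export
run_pipeline <- function(cohort_csv, ct_csv, out_dir,
                         cea_ref = 13.4, responder_max_trg = 2,
                         grid_step = 0.1, quiet = FALSE) {
  for (f in c(cohort_csv, ct_csv)) {
    if (!file.exists(f)) abort(paste("input file not found:", f))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character()
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  say("reading cohort: ", cohort_csv)
  cohort <- as_tibble(read.csv(cohort_csv, stringsAsFactors = FALSE))
  say("reading CT ROI table: ", ct_csv)
  ct <- as_tibble(read.csv(ct_csv, stringsAsFactors = FALSE))
  say("estimating eTSCC for ", nrow(cohort), " patients")
  est <- estimate_cohort(cohort, ct, cea_ref = cea_ref,
                         grid_step = grid_step)
  excl <- attr(est, "exclusions")
  for (i in seq_len(nrow(excl))) {
    say("excluded ", excl$patient_id[i], ": ", excl$reason[i])
  }
  est_path <- file.path(out_dir, "estimates.csv")
  write.csv(as.data.frame(est), est_path, row.names = FALSE)
  say("wrote ", est_path)

  cls <- NULL
  report_path <- file.path(out_dir, "report.json")
  if ("trg" %in% names(est) && nrow(est) >= 3 &&
      length(unique(est$trg <= responder_max_trg)) == 2) {
    cls <- classify_cohort(est, responder_max_trg = responder_max_trg)
    report <- list(
      n_included = nrow(est),
      n_excluded = nrow(excl),
      threshold_ug_ml = cls$report$threshold,
      auc = cls$report$auc,
      accuracy_responders_pct = cls$report$accuracy_responders,
      accuracy_nonresponders_pct = cls$report$accuracy_nonresponders,
      pooled_accuracy_pct = cls$report$pooled_accuracy,
      loocv = list(mean_auc = cls$cv$mean_auc, sd_auc = cls$cv$sd_auc,
                   pooled_accuracy_pct = cls$cv$pooled_accuracy),
      exclusions = as.list(setNames(excl$reason, excl$patient_id))
    )
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
    say("wrote ", report_path)
    roc_path <- file.path(out_dir, "roc.csv")
    write.csv(as.data.frame(cls$report$roc), roc_path, row.names = FALSE)
    ccd_path <- file.path(out_dir, "ccd.csv")
    write.csv(as.data.frame(cls$report$ccd), ccd_path, row.names = FALSE)
    say("wrote ", roc_path, " and ", ccd_path)
  } else {
    say("classification skipped: needs TRG labels in both classes")
  }
  writeLines(log_lines, log_path)
  invisible(list(estimates = est, classification = cls, exclusions = excl,
                 paths = list(estimates = est_path, report = report_path,
                              log = log_path)))
}

#' Write a generated cohort to CSV files
#'
#' @param cohort_bundle List with `cohort` and `ct` tibbles, as returned by
#'   [generate_cohort()] or [fixture_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the two file paths (`cohort.csv`, `ct_roi.csv`).
#' @export
write_cohort_csv <- function(cohort_bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(dir, "cohort.csv")
  ct_path <- file.path(dir, "ct_roi.csv")
  write.csv(as.data.frame(cohort_bundle$cohort), cohort_path,
            row.names = FALSE)
  write.csv(as.data.frame(cohort_bundle$ct), ct_path, row.names = FALSE)
  invisible(c(cohort = cohort_path, ct = ct_path))
}
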