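#' Contrast enhancement curve from three-phase CT Hounsfield units
#'
#' Converts mean ROI Hounsfield units measured in the non-contrast,
#' arterial and portal-venous phases into an enhancement curve: the change
#' in HU relative to the non-contrast baseline, anchored at (0, 0).
#'
#' @param hu Numeric length-3: mean HU in the non-contrast, arterial and
#'   portal-venous phases.
#' @param phase_times Seconds from contrast injection for the three phases;
#'   strictly increasing, first element 0 (baseline).  Default `c(0, 35, 70)`,
#'   standard three-phase liver CT timing.
#' @return Tibble with columns `time_s`, `delta_hu`.  Negative enhancement
#'   (ROI darker post-contrast) is retained with a warning.
#' @examples
#' enhancement_curve(c(50, 120, 110))
#' @export
enhancement_curve <- function(hu, phase_times = c(0, 35, 70)) {
  if (length(hu) != 3 || any(!is.finite(hu))) {
    abort("hu must be three finite values (non-contrast, arterial, portal-venous)")
  }
  if (length(phase_times) != 3 || phase_times[1] != 0 ||
      any(diff(phase_times) <= 0)) {
    abort("phase_times must be strictly increasing with baseline at 0")
  }
  delta <- hu - hu[1]
  if (any(delta < 0)) {
    warn("negative contrast enhancement in at least one phase; retained as-is")
  }
  tibble(time_s = phase_times, delta_hu = delta)
}

#' Blood volume fraction surrogate from tumor and liver enhancement
#'
#' The tumor blood volume fraction (BVF) is approximated by the ratio of
#' the areas under the tumor and surrounding-liver contrast enhancement
#' curves, AUC_tumor / AUC_liver (trapezoidal rule over the three phases).
#' Tumor perfusion normalized to healthy liver in this way serves as a
#' perfusion surrogate; colorectal liver metastases are hypovascular, so
#' values are expected well below 1.  Ratios above 1 are clamped to 1 and
#' flagged rather than rejected, since the transport model's domain is
#' 0 <= BVF <= 1.
#'
#' @param tumor_hu,liver_hu Length-3 mean HU vectors (non-contrast,
#'   arterial, portal-venous) for the tumor ROI and the liver ROI.
#' @param phase_times Shared phase times; see [enhancement_curve()].
#' @return One-row tibble: `auc_tumor`, `auc_liver` (HU.s), `bvf_raw`,
#'   `bvf` (clamped to `[0, 1]`), `bvf_clamped` (logical QC flag).
#' @examples
#' # hand trapezoid: liver AUC 3500, tumor AUC 1400 -> bvf 0.4
#' bvf_estimate(tumor_hu = c(40, 68, 64), liver_hu = c(55, 125, 115))
#' @export
bvf_estimate <- function(tumor_hu, liver_hu, phase_times = c(0, 35, 70)) {
  ct <- enhancement_curve(tumor_hu, phase_times)
  cl_ <- enhancement_curve(liver_hu, phase_times)
  trap <- function(x) sum(diff(x$time_s) *
                            (head(x$delta_hu, -1) + tail(x$delta_hu, -1)) / 2)
  auc_t <- trap(ct)
  auc_l <- trap(cl_)
  if (!is.finite(auc_l) || auc_l <= 0) {
    abort("invalid reference: liver enhancement AUC must be positive")
  }
  raw <- auc_t / auc_l
  clamped <- raw < 0 || raw > 1
  if (raw > 1) {
    warn("tumor enhancement exceeds liver reference (bvf > 1); clamped to 1")
  }
  tibble(auc_tumor = auc_t, auc_liver = auc_l, bvf_raw = raw,
         bvf = min(max(raw, 0), 1), bvf_clamped = clamped)
}

#' Per-patient BVF from a long-format CT ROI table
#'
#' @param ct Tibble/data frame with columns `patient_id`, `site`
#'   (`"tumor"`/`"liver"`), `phase` (`"noncontrast"`, `"arterial"`,
#'   `"portal"`), `time_s`, `mean_hu` (optionally `sd_hu`).
#' @return Tibble with one row per patient having complete tumor and liver
#'   triplets: `patient_id`, `auc_tumor`, `auc_liver`, `bvf_raw`, `bvf`,
#'   `bvf_clamped`.  Patients with incomplete CT rows are dropped (the
#'   pipeline records them as exclusions).
#' @export
perfusion_from_ct <- function(ct) {
  needed <- c("patient_id", "site", "phase", "time_s", "mean_hu")
  if (!all(needed %in% names(ct))) {
    abort(paste("CT table must have columns:", paste(needed, collapse = ", ")))
  }
  phase_order <- c("noncontrast", "arterial", "portal")
  ct <- as_tibble(ct) %>%
    mutate(phase = factor(.data$phase, levels = phase_order)) %>%
    filter(!is.na(.data$phase))
  complete_ids <- ct %>%
    group_by(.data$patient_id) %>%
    summarise(ok = dplyr::n_distinct(paste(.data$site, .data$phase)) == 6L,
              .groups = "drop") %>%
    filter(.data$ok) %>%
    pull(.data$patient_id)
  purrr::map_dfr(complete_ids, function(pid) {
    sub <- ct %>% filter(.data$patient_id == pid) %>% arrange(.data$phase)
    tum <- sub %>% filter(.data$site == "tumor")
    liv <- sub %>% filter(.data$site == "liver")
    out <- bvf_estimate(tum$mean_hu, liv$mean_hu, phase_times = tum$time_s)
    mutate(out, patient_id = pid, .before = 1)
  })
}
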