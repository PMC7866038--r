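#' Configuration of the synthetic cohort generator
#'
#' Defines the statistical structure the generator emulates: lesion sizes
#' uniform over the cohort's observed 1-10 cm range; serum CEA linear in
#' size with truncated Gaussian noise; blood volume fraction declining
#' linearly in size (hypovascular regime, clamped to (0, 1)); TRG drawn
#' from a cumulative-logit ordinal model on log eTSCC so that higher
#' tumor-site concentration gives a lower (better) grade.
#'
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; one seed drives the whole generator stream.
#' @param size_range Largest-lesion size range (cm).
#' @param cea_intercept,cea_slope,cea_noise_sd CEA (ng/mL) = intercept +
#'   slope * size + N(0, sd^2), truncated positive.
#' @param perf_intercept,perf_slope,perf_noise_sd BVF = intercept -
#'   slope * size + N(0, sd^2), clamped to (0, 1).
#' @param trg_link_slope Slope of the ordinal link on log eTSCC.
#' @param trg_link_cutpoints Four cutpoints alpha_i of
#'   P(TRG <= i) = plogis(alpha_i + slope * log eTSCC); defaults solve the
#'   cohort TRG mix at the typical regimen.
#' @param trg_noise_sd SD of Gaussian noise added to log eTSCC inside the
#'   link; 0 gives a deterministic-link cohort, large values decouple TRG
#'   from eTSCC.
#' @param regimen_mix Named proportions for FOLFOX / FOLFIRI / combination
#'   regimens; must sum to 1.
#' @param cycle_interval,washout_h Cycle spacing and post-chemo interval to
#'   surgery (h); treatment span is `n_cycles * cycle_interval + washout_h`.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n = 33, seed = 1, size_range = c(1, 10),
                          cea_intercept = 1, cea_slope = 3, cea_noise_sd = 3,
                          perf_intercept = 0.5, perf_slope = 0.04,
                          perf_noise_sd = 0.05,
                          trg_link_slope = 2,
                          trg_link_cutpoints = c(4.09, 5.33, 6.53, 8.34),
                          trg_noise_sd = 0,
                          regimen_mix = c(FOLFOX = 25 / 33, FOLFIRI = 1 / 33,
                                          combination = 7 / 33),
                          cycle_interval = 336, washout_h = 672) {
  if (n < 1) abort("n must be >= 1")
  if (abs(sum(regimen_mix) - 1) > 1e-8) abort("regimen_mix must sum to 1")
  if (cea_noise_sd < 0 || perf_noise_sd < 0 || trg_noise_sd < 0) {
    abort("noise SDs must be non-negative")
  }
  if (length(trg_link_cutpoints) != 4 || is.unsorted(trg_link_cutpoints)) {
    abort("trg_link_cutpoints must be four non-decreasing values")
  }
  structure(as.list(environment()), class = "cohort_config")
}

# Regimen-average plasma concentration for one patient (identical cycles,
# closed-form profile, trapezoidal AUC over [0, delta_t]).
sigma_dbar_one <- function(bsa, bolus = 400, infusion = 2400, delta_t = 46,
                           grid_step = 0.1) {
  p <- pk_params(v_ml = blood_volume(bsa))
  r <- regimen(bolus = bolus, infusion = infusion, delta_t = delta_t,
               bsa = bsa, n_cycles = 1, t_span = delta_t,
               cycle_interval = delta_t)
  auc_trapezoid(analytic_cycle(p, r, grid_step = grid_step)) / delta_t
}

draw_truncated <- function(n, mean_vec, sd, lower) {
  x <- mean_vec + rnorm(n, 0, sd)
  clamped <- x <= lower
  for (i in which(clamped)) {
    for (try in 1:50) {
      x[i] <- mean_vec[i] + rnorm(1, 0, sd)
      if (x[i] > lower) break
    }
    if (x[i] <= lower) x[i] <- lower
  }
  list(x = x, n_clamped = sum(clamped))
}

ct_rows_for <- function(id, bvf, liver_art, liver_pv,
                        liver_base = 55, tumor_base = 40) {
  # tumor enhancement is bvf times the liver enhancement per phase, so the
  # enhancement AUC ratio reproduces bvf exactly
  tibble(
    patient_id = rep(id, 6),
    site = rep(c("liver", "tumor"), each = 3),
    phase = rep(c("noncontrast", "arterial", "portal"), 2),
    time_s = rep(c(0, 35, 70), 2),
    mean_hu = c(liver_base, liver_base + liver_art, liver_base + liver_pv,
                tumor_base, tumor_base + bvf * liver_art,
                tumor_base + bvf * liver_pv),
    sd_hu = rep(c(12, 10), each = 3)
  )
}

#' Generate a synthetic patient cohort
#'
#' Draws a cohort under a [cohort_config()]: clinical covariates with the
#' study population's category frequencies, lesion size, CEA and BVF with
#' the configured linear couplings, per-patient CT Hounsfield-unit rows
#' back-computed so the enhancement-AUC ratio reproduces the latent BVF
#' exactly, and TRG drawn from the ordinal link on log eTSCC.
#' Reproducible: the same config (including seed) always returns the same
#' cohort.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (one row per patient; includes generator
#'   ground truth `bvf_true` and `etscc_true`, which the estimation
#'   pipeline does not read) and `ct` (long-format CT ROI table).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n
  id <- sprintf("S%04d", seq_len(n))
  age <- 42 + round(41 * stats::rbeta(n, 1.5, 2.5))
  gender <- sample(c("male", "female"), n, replace = TRUE,
                   prob = c(20, 13) / 33)
  primary_site <- sample(c("right colon", "left colon", "rectum"), n,
                         replace = TRUE, prob = c(12, 12, 9) / 33)
  presentation <- sample(c("synchronous", "metachronous"), n, replace = TRUE,
                         prob = c(29, 4) / 33)
  extrahepatic <- runif(n) < 11 / 33
  lesion_count <- sample(1:5, n, replace = TRUE,
                         prob = c(0.30, 0.30, 0.20, 0.12, 0.08))
  bsa <- pmin(pmax(rnorm(n, 1.8, 0.2), 1.4), 2.4)
  size <- runif(n, config$size_range[1], config$size_range[2])

  cea_draw <- draw_truncated(n, config$cea_intercept + config$cea_slope * size,
                             config$cea_noise_sd, lower = 0.5)
  if (cea_draw$n_clamped > n / 2) {
    abort("infeasible CEA config: more than half the draws required truncation")
  }
  cea <- cea_draw$x

  bvf_raw <- config$perf_intercept - config$perf_slope * size +
    rnorm(n, 0, config$perf_noise_sd)
  bvf_clamps <- sum(bvf_raw <= 0.01 | bvf_raw >= 0.99)
  if (bvf_clamps > n / 2) {
    abort("infeasible perfusion config: more than half the BVF draws clamp")
  }
  bvf <- pmin(pmax(bvf_raw, 0.01), 0.99)

  regimen_label <- sample(names(config$regimen_mix), n, replace = TRUE,
                          prob = config$regimen_mix)
  n_cycles <- sample(1:9, n, replace = TRUE,
                     prob = c(0.05, 0.12, 0.20, 0.25, 0.15, 0.10,
                              0.06, 0.04, 0.03))
  t_span <- n_cycles * config$cycle_interval + config$washout_h

  sigma_dbar <- vapply(bsa, sigma_dbar_one, numeric(1))
  s_tb <- sigma_dbar * duty_cycle(n_cycles, 46, t_span) * (13.4 / cea)
  etscc_true <- s_tb * bvf

  # latent cumulative-logit draw: P(TRG <= i) = plogis(alpha_i + eta)
  eta <- config$trg_link_slope *
    (log(etscc_true) + rnorm(n, 0, config$trg_noise_sd))
  w <- -eta + rlogis(n)
  trg <- 1L + vapply(w, function(wi) sum(wi > config$trg_link_cutpoints),
                     integer(1))

  liver_art <- 70 + rnorm(n, 0, 5)
  liver_pv <- 60 + rnorm(n, 0, 4)
  ct <- purrr::map_dfr(seq_len(n), function(i) {
    ct_rows_for(id[i], bvf[i], liver_art[i], liver_pv[i])
  })

  cohort <- tibble(
    patient_id = id, age = age, gender = gender,
    primary_site = primary_site, presentation = presentation,
    extrahepatic = extrahepatic, lesion_count = lesion_count,
    bsa = bsa, size = size, cea = cea,
    regimen = regimen_label, bolus = 400, infusion = 2400, delta_t = 46,
    n_cycles = n_cycles, t_span = t_span, trg = trg,
    bvf_true = bvf, etscc_true = etscc_true
  )
  list(cohort = cohort, ct = ct)
}

# fixed bijective scramble of 1..n (multiplier coprime with n + 1)
fixed_perm <- function(n, mult) order((seq_len(n) * mult) %% (n + 1))

#' Deterministic 33-patient reference cohort
#'
#' A fixed cohort whose marginals reproduce the study population exactly:
#' 20 male / 13 female; primary site 12 right colon / 12 left colon /
#' 9 rectum; 29 synchronous presentations; 11 with extrahepatic disease;
#' TRG counts 2/4/8/13/6 for grades 1-5; regimens 25 FOLFOX / 1 FOLFIRI /
#' 7 combinations; medians age 57 (42-83), 2 lesions (1-5), largest lesion
#' 3.2 cm (1-10), CEA 13.4 ng/mL (1-97), 4 cycles (1-9).  CEA increases
#' with lesion size and BVF decreases with it; TRG is assigned by eTSCC
#' rank (larger eTSCC, lower grade) with exactly the marginal counts above.
#'
#' @return List with `cohort` and `ct` tibbles, as [generate_cohort()].
#' @seealso [fixture_audit()] for the automated marginal check.
#' @export
fixture_cohort <- function() {
  n <- 33
  id <- sprintf("F%04d", seq_len(n))
  ages_sorted <- c(42, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 55,
                   56, 56, 57, 58, 59, 60, 61, 62, 63, 64, 66, 68, 70, 72,
                   74, 76, 78, 80, 83)
  age <- ages_sorted[fixed_perm(n, 7)]
  gender <- rep("male", n)
  gender[c(2, 5, 8, 10, 13, 16, 18, 21, 24, 26, 29, 31, 33)] <- "female"
  primary_site <- c(rep(c("right colon", "left colon", "rectum"), 9),
                    rep(c("right colon", "left colon"), 3))
  presentation <- rep("synchronous", n)
  presentation[c(4, 12, 20, 28)] <- "metachronous"
  extrahepatic <- seq_len(n) %in% seq(3, 33, by = 3)
  lesion_count <- rep(c(1L, 2L, 3L, 4L, 5L), c(9, 9, 7, 5, 3))[fixed_perm(n, 13)]
  size <- c(1.0, 1.2, 1.4, 1.6, 1.8, 2.0, 2.2, 2.4, 2.5, 2.6, 2.7, 2.8,
            2.9, 3.0, 3.0, 3.1, 3.2, 3.4, 3.6, 3.8, 4.0, 4.3, 4.6, 5.0,
            5.4, 5.8, 6.2, 6.7, 7.2, 7.8, 8.5, 9.2, 10.0)
  cea <- c(1.0, 2.1, 3.5, 4.2, 5.0, 5.8, 6.5, 7.3, 8.1, 9.0, 9.8, 10.5,
           11.2, 12.0, 12.6, 13.0, 13.4, 14.5, 16.0, 18.2, 21.0, 24.5,
           28.3, 33.0, 38.5, 44.0, 50.5, 57.8, 66.0, 74.5, 82.0, 90.0,
           97.0)
  bvf <- 0.48 - 0.038 * size
  bsa <- rep_len(c(1.6, 1.7, 1.8, 1.9, 2.0), n)
  n_cycles <- rep(1:9, c(1, 4, 6, 10, 5, 3, 2, 1, 1))[fixed_perm(n, 21)]
  t_span <- n_cycles * 336 + 672
  regimen_label <- rep("FOLFOX", n)
  regimen_label[15] <- "FOLFIRI"
  regimen_label[c(3, 7, 11, 19, 23, 27, 31)] <- "combination"

  sigma_dbar <- vapply(bsa, sigma_dbar_one, numeric(1))
  etscc_true <- sigma_dbar * duty_cycle(n_cycles, 46, t_span) *
    (13.4 / cea) * bvf
  trg <- integer(n)
  trg[order(etscc_true, decreasing = TRUE)] <- rep(1:5, c(2, 4, 8, 13, 6))

  ct <- purrr::map_dfr(seq_len(n), function(i) {
    ct_rows_for(id[i], bvf[i], liver_art = 70, liver_pv = 60)
  })
  cohort <- tibble(
    patient_id = id, age = age, gender = gender,
    primary_site = primary_site, presentation = presentation,
    extrahepatic = extrahepatic, lesion_count = lesion_count,
    bsa = bsa, size = size, cea = cea,
    regimen = regimen_label, bolus = 400, infusion = 2400, delta_t = 46,
    n_cycles = n_cycles, t_span = t_span, trg = trg,
    bvf_true = bvf, etscc_true = etscc_true
  )
  list(cohort = cohort, ct = ct)
}

#' Audit the reference cohort against its marginal targets
#'
#' @param cohort The `cohort` tibble from [fixture_cohort()].
#' @return Tibble with one row per marginal check: `check`, `target`,
#'   `actual`, `pass`.  All rows pass for the shipped fixture.
#' @export
fixture_audit <- function(cohort = fixture_cohort()$cohort) {
  chk <- function(check, target, actual) {
    tibble(check = check, target = target, actual = actual,
           pass = isTRUE(all.equal(target, actual, tolerance = 1e-9)))
  }
  bind_rows(
    chk("n patients", 33, nrow(cohort)),
    chk("male count", 20, sum(cohort$gender == "male")),
    chk("female count", 13, sum(cohort$gender == "female")),
    chk("right colon", 12, sum(cohort$primary_site == "right colon")),
    chk("left colon", 12, sum(cohort$primary_site == "left colon")),
    chk("rectum", 9, sum(cohort$primary_site == "rectum")),
    chk("synchronous", 29, sum(cohort$presentation == "synchronous")),
    chk("extrahepatic", 11, sum(cohort$extrahepatic)),
    chk("TRG1", 2, sum(cohort$trg == 1)),
    chk("TRG2", 4, sum(cohort$trg == 2)),
    chk("TRG3", 8, sum(cohort$trg == 3)),
    chk("TRG4", 13, sum(cohort$trg == 4)),
    chk("TRG5", 6, sum(cohort$trg == 5)),
    chk("FOLFOX", 25, sum(cohort$regimen == "FOLFOX")),
    chk("FOLFIRI", 1, sum(cohort$regimen == "FOLFIRI")),
    chk("combination", 7, sum(cohort$regimen == "combination")),
    chk("median age", 57, median(cohort$age)),
    chk("age min", 42, min(cohort$age)),
    chk("age max", 83, max(cohort$age)),
    chk("median lesions", 2, median(cohort$lesion_count)),
    chk("lesions range low", 1, min(cohort$lesion_count)),
    chk("lesions range high", 5, max(cohort$lesion_count)),
    chk("median size", 3.2, median(cohort$size)),
    chk("size min", 1, min(cohort$size)),
    chk("size max", 10, max(cohort$size)),
    chk("median CEA", 13.4, median(cohort$cea)),
    chk("CEA min", 1, min(cohort$cea)),
    chk("CEA max", 97, max(cohort$cea)),
    chk("median cycles", 4, median(cohort$n_cycles)),
    chk("cycles min", 1, min(cohort$n_cycles)),
    chk("cycles max", 9, max(cohort$n_cycles))
  )
}
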