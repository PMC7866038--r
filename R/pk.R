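#' Two-compartment 5-FU pharmacokinetic parameters
#'
#' Rate constants and clearance of the linear two-compartment model of
#' systemic 5-fluorouracil disposition, together with the patient blood
#' volume.  Defaults are literature values for 5-FU; the blood volume is
#' usually derived from body surface area with [blood_volume()].
#'
#' @param k12 Central-to-peripheral first-order transfer rate (1/h).
#' @param k21 Peripheral-to-central first-order transfer rate (1/h).
#' @param cl Clearance of 5-FU from the central compartment (L/h).
#' @param v_ml Blood volume (mL).
#'
#' @return An object of class `pk_params`: a named list with the four
#'   components, volume additionally carried in litres (`v_l`).
#' @examples
#' pk_params(v_ml = blood_volume(1.8))
#' @export
pk_params <- function(k12 = 5.35, k21 = 5.69, cl = 65.3, v_ml) {
  vals <- c(k12 = k12, k21 = k21, cl = cl, v_ml = v_ml)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all PK parameters (k12, k21, cl, v_ml) must be finite and strictly positive")
  }
  structure(
    list(k12 = k12, k21 = k21, cl = cl, v_ml = v_ml, v_l = v_ml / 1000),
    class = "pk_params"
  )
}

#' Blood volume from body surface area
#'
#' Empirical linear relation between body surface area and total blood
#' volume, V = (3.29 BSA - 1.229) * 1000 mL.
#'
#' @param bsa Body surface area (m^2); must exceed 1.229/3.29 so the
#'   volume is positive.
#' @return Blood volume in mL.
#' @examples
#' blood_volume(1.8) # 4693 mL
#' @export
blood_volume <- function(bsa) {
  v <- (3.29 * bsa - 1.229) * 1000
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("invalid BSA: blood volume (3.29*BSA - 1.229) L must be positive")
  }
  v
}

#' Chemotherapy regimen description
#'
#' Describes the 5-FU component of a FOLFOX/FOLFIRI-style regimen: an
#' intravenous bolus at dose `bolus` mg per m^2 BSA followed immediately by
#' an infusion of `infusion` mg per m^2 BSA spread over `delta_t` hours,
#' repeated for `n_cycles` cycles over a treatment span of `t_span` hours.
#'
#' @param bolus Bolus dose D (mg per m^2 BSA).
#' @param infusion Infusion dose R (mg per m^2 BSA).
#' @param delta_t Infusion/cycle duration (h); FOLFOX default 46 h.
#' @param bsa Body surface area (m^2).
#' @param n_cycles Number of chemotherapy cycles (integer >= 1).
#' @param t_span Treatment span from first cycle to surgery (h).  Defaults
#'   to `n_cycles * cycle_interval`.
#' @param cycle_interval Time between cycle starts (h); default 336 h
#'   (14-day FOLFOX cadence).
#'
#' @return An object of class `regimen` (named list).
#' @examples
#' regimen(bsa = 1.8, n_cycles = 6, t_span = 2016)
#' @export
regimen <- function(bolus = 400, infusion = 2400, delta_t = 46, bsa,
                    n_cycles = 1, t_span = n_cycles * cycle_interval,
                    cycle_interval = 336) {
  if (bolus < 0 || infusion < 0) abort("doses must be non-negative")
  if (bolus == 0 && infusion == 0) abort("bolus and infusion doses cannot both be zero")
  if (delta_t <= 0) abort("delta_t must be positive")
  if (delta_t > cycle_interval) abort("delta_t cannot exceed cycle_interval")
  if (n_cycles < 1 || n_cycles != round(n_cycles)) abort("n_cycles must be an integer >= 1")
  if (t_span <= 0) abort("t_span must be positive")
  if (n_cycles * cycle_interval > t_span) {
    warn("n_cycles * cycle_interval exceeds t_span; duty cycle may be overestimated")
  }
  blood_volume(bsa) # validates BSA
  structure(
    list(bolus = bolus, infusion = infusion, delta_t = delta_t, bsa = bsa,
         n_cycles = as.integer(n_cycles), t_span = t_span,
         cycle_interval = cycle_interval),
    class = "regimen"
  )
}

# System matrix, forcing and initial state of the central/peripheral ODEs.
# Concentrations are carried in mg/L (numerically identical to ug/mL);
# volume is used in litres so that dose (mg) / V (L) is mg/L.
pk_system <- function(params, reg) {
  v <- params$v_l
  A <- matrix(c(-(params$k12 + params$cl / v), params$k21,
                params$k12, -params$k21),
              nrow = 2, byrow = TRUE)
  list(
    A = A,
    forcing = c(reg$infusion * reg$bsa / (reg$delta_t * v), 0),
    x0 = c(reg$bolus * reg$bsa / v, 0)
  )
}

# Output grid for one integration segment: tenfold refinement over the
# first hour resolves the fast (~20/h) mode so trapezoidal AUCs of the
# bolus spike stay accurate at the default step.
segment_grid <- function(t0, t1, step) {
  knee <- min(t0 + 1, t1)
  unique(c(seq(t0, knee, by = step / 10),
           seq(knee, t1, by = step), t1))
}

new_profile <- function(times, sB, sP) {
  structure(
    tibble(time_h = times, sigma_B = sB, sigma_P = sP),
    class = c("etscc_profile", "tbl_df", "tbl", "data.frame")
  )
}

#' Numerically simulate one chemotherapy cycle
#'
#' Integrates the two-compartment ODE system for the blood (`sigma_B`) and
#' peripheral (`sigma_P`) 5-FU concentrations over one cycle: the bolus
#' enters as the initial condition sigma_B(0) = D*BSA/V and the infusion as a
#' constant zero-order input R*BSA/(delta_t*V) active on `[0, delta_t]`.
#'
#' @param params A [pk_params()] object.
#' @param reg A [regimen()] object.
#' @param grid_step Output grid spacing (h); default 0.1.
#' @param t_max End of the simulated window (h); defaults to `delta_t`.
#'   When larger, the infusion switches off at `delta_t` and washout is
#'   simulated to `t_max`.
#' @param atol Absolute solver tolerance; default 1e-9.
#'
#' @return A tibble of class `etscc_profile` with columns `time_h`,
#'   `sigma_B`, `sigma_P` (concentrations in ug/mL, i.e. mg/L).
#' @seealso [analytic_cycle()] for the closed-form solution.
#' @examples
#' p <- pk_params(v_ml = blood_volume(1.8))
#' r <- regimen(bsa = 1.8)
#' prof <- simulate_cycle(p, r)
#' head(prof)
#' @export
simulate_cycle <- function(params, reg, grid_step = 0.1,
                           t_max = reg$delta_t, atol = 1e-9) {
  stopifnot(inherits(params, "pk_params"), inherits(reg, "regimen"))
  if (t_max < reg$delta_t) abort("grid must cover [0, delta_t] at least")
  sys <- pk_system(params, reg)
  deriv <- function(t, y, parms) {
    list(as.vector(parms$A %*% y + parms$b))
  }
  solve_seg <- function(times, y0, b) {
    deSolve::lsoda(y = y0, times = times, func = deriv,
                   parms = list(A = sys$A, b = b),
                   rtol = 1e-10, atol = atol)
  }
  grid1 <- segment_grid(0, reg$delta_t, grid_step)
  out1 <- solve_seg(grid1, sys$x0, sys$forcing)
  times <- out1[, 1]; sB <- out1[, 2]; sP <- out1[, 3]
  if (t_max > reg$delta_t) {
    grid2 <- segment_grid(reg$delta_t, t_max, grid_step)
    y1 <- c(sB[length(sB)], sP[length(sP)])
    out2 <- solve_seg(grid2, y1, c(0, 0))
    times <- c(times, out2[-1, 1])
    sB <- c(sB, out2[-1, 2])
    sP <- c(sP, out2[-1, 3])
  }
  if (min(sB, sP) < -1e-6 * max(abs(sB))) {
    abort("integration failure: concentrations went negative beyond solver tolerance")
  }
  new_profile(times, pmax(sB, 0), pmax(sP, 0))
}

# exp(A t) x applied columnwise over a time vector via eigendecomposition;
# falls back to scaling-and-squaring (Matrix::expm) near-degenerate spectra.
expAt_apply <- function(A, x, times) {
  eg <- eigen(A)
  if (abs(eg$values[1] - eg$values[2]) >
      1e-8 * max(abs(eg$values), 1e-12)) {
    Vi <- solve(eg$vectors)
    z <- Vi %*% x
    E <- exp(outer(eg$values, times)) # 2 x length(times)
    Re(eg$vectors %*% (E * as.vector(z)))
  } else {
    vapply(times, function(t) as.vector(Matrix::expm(A * t) %*% x),
           numeric(2))
  }
}

#' Closed-form solution of one chemotherapy cycle
#'
#' Exact bi-exponential solution of the constant-coefficient linear
#' two-compartment system with constant infusion forcing,
#' x(t) = e^(At) (x0 + A^-1 b) - A^-1 b, evaluated by eigendecomposition.
#' Used as the independent oracle for [simulate_cycle()] and as the fast
#' path when estimating whole cohorts.
#'
#' @inheritParams simulate_cycle
#' @return A tibble of class `etscc_profile` (`time_h`, `sigma_B`, `sigma_P`).
#' @examples
#' p <- pk_params(v_ml = blood_volume(1.8))
#' analytic_cycle(p, regimen(bsa = 1.8), grid_step = 2)
#' @export
analytic_cycle <- function(params, reg, grid_step = 0.1, t_max = reg$delta_t) {
  stopifnot(inherits(params, "pk_params"), inherits(reg, "regimen"))
  if (t_max < reg$delta_t) abort("grid must cover [0, delta_t] at least")
  sys <- pk_system(params, reg)
  xss <- -solve(sys$A, sys$forcing) # steady state of the forced system
  grid1 <- segment_grid(0, reg$delta_t, grid_step)
  X1 <- expAt_apply(sys$A, sys$x0 - xss, grid1) + xss
  times <- grid1; sB <- X1[1, ]; sP <- X1[2, ]
  if (t_max > reg$delta_t) {
    grid2 <- segment_grid(reg$delta_t, t_max, grid_step)
    y1 <- c(sB[length(sB)], sP[length(sP)])
    X2 <- expAt_apply(sys$A, y1, grid2 - reg$delta_t)
    keep <- -1
    times <- c(times, grid2[keep])
    sB <- c(sB, X2[1, ][keep])
    sP <- c(sP, X2[2, ][keep])
  }
  new_profile(times, pmax(sB, 0), pmax(sP, 0))
}

#' Trapezoidal area under a concentration profile
#'
#' @param profile An `etscc_profile` tibble (or any data frame with
#'   `time_h` and the value column).
#' @param window Length-2 numeric `[t0, t1]` inside the stored grid;
#'   default the full grid.  Endpoints off the grid are linearly
#'   interpolated.
#' @param value Column to integrate; default `"sigma_B"`.
#' @return AUC in ug.h/mL; non-negative for non-negative profiles.
#' @examples
#' auc_trapezoid(tibble::tibble(time_h = c(0, 1), sigma_B = c(0, 2))) # 1
#' @export
auc_trapezoid <- function(profile, window = NULL, value = "sigma_B") {
  t <- profile$time_h
  y <- profile[[value]]
  if (is.null(window)) window <- range(t)
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("window must be an increasing [t0, t1] pair")
  }
  if (window[1] < min(t) - 1e-9 || window[2] > max(t) + 1e-9) {
    abort("window must lie within the stored time grid")
  }
  keep <- t > window[1] & t < window[2]
  tt <- c(window[1], t[keep], window[2])
  yy <- c(stats::approx(t, y, xout = window[1])$y, y[keep],
          stats::approx(t, y, xout = window[2])$y)
  sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
}

#' Simulate a full multi-cycle regimen
#'
#' Each cycle restarts from a drug-free state (14-day cycle spacing washes
#' out essentially all drug given a terminal half-life well under an hour),
#' so identical cycles are computed once and replicated.
#'
#' @inheritParams simulate_cycle
#' @param method `"analytic"` (default) or `"numeric"`.
#' @return A list of `n_cycles` `etscc_profile` tibbles.
#' @export
simulate_regimen <- function(params, reg, grid_step = 0.1,
                             method = c("analytic", "numeric")) {
  method <- match.arg(method)
  one <- switch(method,
    analytic = analytic_cycle(params, reg, grid_step = grid_step),
    numeric = simulate_cycle(params, reg, grid_step = grid_step)
  )
  rep(list(one), reg$n_cycles)
}

#' Per-cycle and regimen-averaged 5-FU exposure
#'
#' Computes the per-cycle AUC by the trapezoidal rule, the per-cycle
#' time-averaged blood concentration AUC_i/delta_t, and the regimen average
#' sum(AUC_i)/(N delta_t) -- identically the mean of the per-cycle
#' averages.
#'
#' @param profiles List of per-cycle `etscc_profile` tibbles (length N).
#' @param reg The [regimen()] the profiles were simulated under.
#' @return An object of class `exposure_summary`: list with
#'   `auc_per_cycle`, `sigma_bar_i` (both length N), `sigma_dbar`,
#'   `n_cycles`, `delta_t`.  [tidy()] gives the per-cycle tibble,
#'   [glance()] the one-row summary.
#' @examples
#' p <- pk_params(v_ml = blood_volume(1.8))
#' r <- regimen(bsa = 1.8, n_cycles = 2)
#' glance(exposure_summary(simulate_regimen(p, r), r))
#' @export
exposure_summary <- function(profiles, reg) {
  if (length(profiles) < 1) abort("at least one per-cycle profile is required")
  auc <- vapply(profiles, auc_trapezoid, numeric(1),
                window = c(0, reg$delta_t))
  sigma_bar <- auc / reg$delta_t
  structure(
    list(auc_per_cycle = auc,
         sigma_bar_i = sigma_bar,
         sigma_dbar = sum(auc) / (length(auc) * reg$delta_t),
         n_cycles = length(auc), delta_t = reg$delta_t),
    class = "exposure_summary"
  )
}

#' @exportS3Method generics::tidy
tidy.exposure_summary <- function(x, ...) {
  tibble(cycle = seq_len(x$n_cycles),
         auc = x$auc_per_cycle,
         sigma_bar = x$sigma_bar_i)
}

#' @exportS3Method generics::glance
glance.exposure_summary <- function(x, ...) {
  tibble(n_cycles = x$n_cycles, delta_t = x$delta_t,
         total_auc = sum(x$auc_per_cycle), sigma_dbar = x$sigma_dbar)
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat("5-FU exposure over", x$n_cycles, "cycle(s) of", x$delta_t, "h\n")
  cat("  per-cycle AUC (ug.h/mL):",
      paste(signif(x$auc_per_cycle, 5), collapse = ", "), "\n")
  cat("  regimen-average concentration sigma_dbar:",
      signif(x$sigma_dbar, 5), "ug/mL\n")
  invisible(x)
}
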