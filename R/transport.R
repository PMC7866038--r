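#' Geometric penalty factor of diffusion-limited drug penetration
#'
#' For a cylindrical vessel of radius `r_b` feeding tissue with drug
#' diffusion penetration distance `L`, the kill fraction in the
#' well-perfused limit carries the geometric factor
#' 2 K1(rho) / (rho K0(rho)) with rho = r_b/L, where K0 and K1 are
#' modified Bessel functions of the second kind.
#'
#' @param rho Vessel-radius to penetration-distance ratio r_b/L (> 0).
#' @return The dimensionless penalty factor (vectorized over `rho`).
#' @examples
#' penalty_factor(1)   # 2 K1(1)/K0(1)
#' penalty_factor(0.1) # ~81.2
#' @export
penalty_factor <- function(rho) {
  if (any(!is.finite(rho)) || any(rho <= 0)) abort("rho must be positive")
  # exponent-scaled ratio: the e^rho factors cancel, avoiding underflow of
  # both Bessel functions at large rho
  2 * besselK(rho, 1, expon.scaled = TRUE) /
    (rho * besselK(rho, 0, expon.scaled = TRUE))
}

#' Transport model parameters
#'
#' @param r_b Average blood vessel cross-sectional radius (um); default 10.
#' @param L Drug diffusion penetration distance in tumor tissue (um);
#'   default 100.
#' @param bvf Blood volume fraction, in `[0, 1]`.
#' @param fkill0 In-vitro kill fraction at the tumor-vascular drug
#'   concentration, in `[0, 1]`.
#' @return Object of class `transport_params`.
#' @export
transport_params <- function(r_b = 10, L = 100, bvf, fkill0 = 1) {
  if (r_b <= 0 || L <= 0) abort("r_b and L must be positive")
  if (any(bvf < 0 | bvf > 1)) abort("bvf must lie in [0, 1]")
  if (any(fkill0 < 0 | fkill0 > 1)) abort("fkill0 must lie in [0, 1]")
  structure(list(r_b = r_b, L = L, rho = r_b / L, bvf = bvf, fkill0 = fkill0),
            class = "transport_params")
}

#' Fraction of tumor killed: full cylindrical-geometry solution
#'
#' Closed-form solution of the steady diffusion equation around a vessel of
#' radius `r_b` in a tumor of blood volume fraction BVF:
#' fkill = 2 fkill0 BVF (sqrt(BVF) K1(rho) - K1(rho/sqrt(BVF))) /
#' (sqrt(BVF) rho K0(rho) (1 - BVF)).  Transport barriers make
#' fkill <= fkill0; the limits BVF -> 0 and BVF -> 1 give 0 and fkill0.
#'
#' @param p A [transport_params()] object (`bvf` may be vectorized).
#' @return Kill fraction(s) in `[0, fkill0]`.
#' @seealso [fkill_approx()] for the small-BVF linearization.
#' @export
fkill_full <- function(p) {
  stopifnot(inherits(p, "transport_params"))
  rho <- p$rho
  vapply(seq_along(p$bvf), function(i) {
    b <- p$bvf[i]
    f0 <- if (length(p$fkill0) > 1) p$fkill0[i] else p$fkill0
    if (b == 0) return(0)
    if (b >= 1 - 1e-9) return(f0) # limiting value; formula is 0/0 at bvf = 1
    sb <- sqrt(b)
    2 * f0 * b * (sb * besselK(rho, 1) - besselK(rho / sb, 1)) /
      (sb * rho * besselK(rho, 0) * (1 - b))
  }, numeric(1))
}

#' Fraction of tumor killed: hypovascular (small-BVF) approximation
#'
#' First-order expansion of [fkill_full()] around BVF = 0 under the
#' normalization convention in which the constant geometric
#' [penalty_factor()] is absorbed: fkill ~ fkill0 * BVF.
#'
#' @inheritParams fkill_full
#' @return fkill0 * bvf.
#' @export
fkill_approx <- function(p) {
  stopifnot(inherits(p, "transport_params"))
  p$fkill0 * p$bvf
}

#' Duty cycle of a chemotherapy course
#'
#' Fraction of the treatment span during which drug is being infused:
#' lambda * delta_t = N * delta_t / t.
#'
#' @param n_cycles Number of cycles N.
#' @param delta_t Cycle infusion duration (h).
#' @param t_span Treatment span (h).
#' @return Dimensionless duty cycle (vectorized).
#' @export
duty_cycle <- function(n_cycles, delta_t, t_span) {
  if (any(t_span <= 0)) abort("t_span must be positive")
  if (any(n_cycles < 1)) abort("n_cycles must be >= 1")
  n_cycles * delta_t / t_span
}

#' Tumor-vascular time-averaged concentration (fkill0 surrogate)
#'
#' The clinical surrogate for the in-vitro kill fraction fkill0 is the
#' time-averaged 5-FU concentration in the tumor vasculature over the whole
#' course: the regimen-averaged plasma concentration scaled by the duty
#' cycle N*delta_t/t and by tumor burden through serum CEA,
#' sigma_T_B = sigma_dbar * (N delta_t / t) * (cea_ref / cea).  Dividing by
#' CEA normalized to a reference level keeps the result on the plasma
#' concentration scale (ug/mL).
#'
#' @param sigma_dbar Regimen-averaged plasma concentration (ug/mL).
#' @param n_cycles,delta_t,t_span Regimen: cycles, cycle duration (h),
#'   treatment span (h).
#' @param cea Serum carcinoembryonic antigen (ng/mL), tumor-burden
#'   surrogate; must be positive.
#' @param cea_ref Reference CEA (ng/mL) making the burden factor
#'   dimensionless; default 13.4, the study-population median at
#'   presentation.
#' @return sigma_T_B in ug/mL (vectorized).  Warns when the duty cycle
#'   exceeds 1.
#' @examples
#' fkill0_surrogate(1.5, n_cycles = 6, delta_t = 46, t_span = 2016,
#'                  cea = 13.4) # 1.5 * 276/2016 = 0.2054
#' @export
fkill0_surrogate <- function(sigma_dbar, n_cycles, delta_t, t_span,
                             cea, cea_ref = 13.4) {
  if (any(cea <= 0) || cea_ref <= 0) abort("cea and cea_ref must be positive")
  duty <- duty_cycle(n_cycles, delta_t, t_span)
  if (any(duty > 1)) {
    warn("duty cycle N*delta_t/t exceeds 1 for at least one patient")
  }
  sigma_dbar * duty * (cea_ref / cea)
}

#' Estimated tumor-site chemotherapy concentration (eTSCC)
#'
#' In the hypovascular regime the time-averaged extravascular tumor
#' concentration is the tumor-vascular concentration attenuated by the
#' blood volume fraction: sigma_T = sigma_T_B * BVF.
#'
#' @param sigma_T_B Tumor-vascular time-averaged concentration (ug/mL),
#'   from [fkill0_surrogate()].
#' @param bvf Blood volume fraction in `[0, 1]`.
#' @return eTSCC in ug/mL (vectorized); never exceeds `sigma_T_B`.
#' @examples
#' etscc(0.2054, bvf = 0.4) # 0.0822
#' @export
etscc <- function(sigma_T_B, bvf) {
  if (any(bvf < 0 | bvf > 1)) abort("bvf must lie in [0, 1]")
  if (any(sigma_T_B < 0)) abort("sigma_T_B must be non-negative")
  sigma_T_B * bvf
}
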