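# shared test helpers: small data constructors and independent oracles

default_pk <- function(bsa = 1.8) pk_params(v_ml = blood_volume(bsa))

folfox_regimen <- function(bsa = 1.8, n_cycles = 1,
                           t_span = n_cycles * 336) {
  regimen(bsa = bsa, n_cycles = n_cycles, t_span = t_span)
}

# random labeled score set; integer scores give ties
random_scores <- function(n, tie_prone = FALSE) {
  score <- if (tie_prone) sample(1:6, n, replace = TRUE) + 0 else rnorm(n)
  responder <- runif(n) < 0.4
  if (all(responder) || !any(responder)) responder[1:2] <- c(TRUE, FALSE)
  tibble::tibble(score = score, responder = responder)
}

# concordance (Mann-Whitney) AUC with half credit for ties -- independent
# of the package's trapezoid path
rank_auc <- function(data) {
  x <- data$score[data$responder]
  y <- data$score[!data$responder]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# brute-force accuracy-maximizing cut: evaluates the rule score > t on a
# dense set of candidate cuts (all interval midpoints plus the outer ones)
brute_best_accuracy <- function(data) {
  u <- sort(unique(data$score))
  cand <- c(u[1] - 1, (head(u, -1) + tail(u, -1)) / 2, u[length(u)] + 1, u)
  max(vapply(cand, function(t) mean((data$score > t) == data$responder),
             numeric(1)))
}

# modified Bessel K of order nu by quadrature of the integral
# representation K_nu(x) = int_0^Inf exp(-x cosh t) cosh(nu t) dt
bessel_k_quad <- function(x, nu) {
  stats::integrate(function(t) exp(-x * cosh(t)) * cosh(nu * t),
                   0, 30, rel.tol = 1e-12)$value
}
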