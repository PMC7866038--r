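#' Proportional-odds model of TRG on clinical covariates
#'
#' Cumulative-logit ordinal regression of Tumor Regression Grade on six
#' pre-treatment clinical covariates, parameterized as
#' log(P(TRG <= i) / P(TRG > i)) = alpha_i + sum_j beta_j X_j.
#' Fitting is by maximum likelihood ([MASS::polr()]); since polr models
#' logit P(Y <= i) = zeta_i - eta, the reported coefficients are
#' alpha_i = zeta_i and beta_j = -(polr coefficient), with Wald p-values.
#' Under this parameterization the intercepts are monotone non-decreasing
#' in i.
#'
#' Categorical covariates are coded as indicators with reference levels
#' female (gender), metachronous (presentation), no extrahepatic disease,
#' and right colon (primary site).
#'
#' @param cohort Data frame with columns `trg` (1-5, spanning at least two
#'   observed levels) and the covariates in `covariates`.
#' @param covariates Character vector of covariate columns; default the six
#'   study covariates `age`, `gender`, `presentation`, `lesion_count`,
#'   `extrahepatic`, `primary_site`.
#' @return Object of class `etscc_ordinal` wrapping the polr fit; [tidy()]
#'   returns term/estimate/std.error/statistic/p.value with a `type` column
#'   separating intercepts from coefficients.
#' @export
ordinal_fit <- function(cohort,
                        covariates = c("age", "gender", "presentation",
                                       "lesion_count", "extrahepatic",
                                       "primary_site")) {
  cohort <- as_tibble(cohort)
  missing_cols <- setdiff(c("trg", covariates), names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste("cohort is missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (length(unique(cohort$trg)) < 2) {
    abort("TRG must span at least two observed grades")
  }
  d <- cohort[, c("trg", covariates), drop = FALSE]
  d$trg <- factor(d$trg, levels = sort(unique(d$trg)), ordered = TRUE)
  ref <- c(gender = "female", presentation = "metachronous",
           primary_site = "right colon")
  for (v in covariates) {
    if (is.character(d[[v]]) || is.factor(d[[v]])) {
      d[[v]] <- factor(d[[v]])
      if (v %in% names(ref) && ref[[v]] %in% levels(d[[v]])) {
        d[[v]] <- stats::relevel(d[[v]], ref = ref[[v]])
      }
    }
    if (is.logical(d[[v]])) d[[v]] <- as.numeric(d[[v]])
  }
  form <- stats::as.formula(
    paste("trg ~", if (length(covariates)) paste(covariates, collapse = " + ")
          else "1"))
  mm <- stats::model.matrix(form, data = d)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    abort(paste("rank-deficient design; collinear columns:",
                paste(bad, collapse = ", ")))
  }
  fit <- MASS::polr(form, data = d, Hess = TRUE)
  ctab <- summary(fit)$coefficients
  n_beta <- length(fit$coefficients)
  terms_ <- rownames(ctab)
  is_int <- seq_len(nrow(ctab)) > n_beta
  est <- ifelse(is_int, ctab[, 1], -ctab[, 1]) # recover Eq-form signs
  se <- ctab[, 2]
  stat <- est / se
  tidy_tbl <- tibble(
    term = ifelse(is_int, paste0("alpha_", sub("\\|.*", "", terms_)), terms_),
    type = ifelse(is_int, "intercept", "coefficient"),
    estimate = est, std.error = se, statistic = stat,
    p.value = 2 * pnorm(-abs(stat))
  )
  structure(list(fit = fit, tidy = tidy_tbl, n = nrow(d)),
            class = "etscc_ordinal")
}

#' @exportS3Method generics::tidy
tidy.etscc_ordinal <- function(x, ...) x$tidy

#' @exportS3Method generics::glance
glance.etscc_ordinal <- function(x, ...) {
  tibble(n = x$n, deviance = x$fit$deviance, aic = stats::AIC(x$fit),
         n_intercepts = sum(x$tidy$type == "intercept"),
         n_coefficients = sum(x$tidy$type == "coefficient"))
}

#' @export
print.etscc_ordinal <- function(x, ...) {
  cat("Proportional-odds model of TRG,", x$n, "patients\n")
  print(x$tidy)
  invisible(x)
}
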