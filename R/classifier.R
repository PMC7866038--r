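#' Label patients as responders from TRG
#'
#' Tumor Regression Grade runs from 1 (complete pathologic response) to 5
#' (no response).  Responders are defined as TRG <= `responder_max_trg`
#' (default 2), the split under which the study cohort's per-class
#' accuracies correspond to 6 responders vs 27 non-responders.
#'
#' @param data Data frame with a `score` column (eTSCC, ug/mL) and either a
#'   `trg` column (integer 1-5) or a `label`/`responder` column.
#' @param responder_max_trg Highest TRG counted as responder; default 2.
#' @return Tibble with `patient_id`, `score`, `responder` (logical) and
#'   `label` (factor `non-responder`/`responder`), plus `trg` if present.
#' @export
labeled_scores <- function(data, responder_max_trg = 2) {
  data <- as_tibble(data)
  if (!"score" %in% names(data)) abort("data must have a `score` column")
  if (!"patient_id" %in% names(data)) {
    data$patient_id <- sprintf("P%04d", seq_len(nrow(data)))
  }
  if ("responder" %in% names(data)) {
    resp <- as.logical(data$responder)
  } else if ("label" %in% names(data)) {
    resp <- as.character(data$label) == "responder"
  } else if ("trg" %in% names(data)) {
    if (!all(data$trg %in% 1:5)) abort("trg must be integers in 1..5")
    resp <- data$trg <= responder_max_trg
  } else {
    abort("data needs one of `trg`, `label` or `responder`")
  }
  out <- tibble(patient_id = data$patient_id, score = data$score,
                responder = resp,
                label = factor(ifelse(resp, "responder", "non-responder"),
                               levels = c("non-responder", "responder")))
  if ("trg" %in% names(data)) out$trg <- data$trg
  out
}

check_two_classes <- function(scores) {
  if (length(unique(scores$responder)) < 2) {
    abort("both responder classes must be present")
  }
}

#' Logistic regression of response on eTSCC
#'
#' Maximum-likelihood univariate logistic fit (iteratively reweighted least
#' squares via [stats::glm()]) of responder status on the eTSCC score.
#' Perfectly separable data produce divergent coefficients; the fit then
#' warns and stops at the iteration cap.
#'
#' @inheritParams labeled_scores
#' @param maxit IRLS iteration cap; default 100.
#' @return Object of class `etscc_logit` wrapping the glm fit; supports
#'   [tidy()] and [glance()].
#' @export
fit_logistic <- function(data, responder_max_trg = 2, maxit = 100) {
  scores <- labeled_scores(data, responder_max_trg)
  check_two_classes(scores)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(responder ~ score, family = binomial(), data = scores,
        control = list(maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated) {
    warn("classes are (quasi-)separable; coefficients capped at the iteration limit")
  }
  structure(list(fit = fit, data = scores, separated = separated),
            class = "etscc_logit")
}

#' @exportS3Method generics::tidy
tidy.etscc_logit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @exportS3Method generics::glance
glance.etscc_logit <- function(x, ...) {
  tibble(n = nrow(x$data), separated = x$separated,
         deviance = x$fit$deviance, aic = x$fit$aic,
         auc = attr(roc_curve(x$data), "auc"))
}

#' Empirical ROC curve and AUC
#'
#' Sweeps every distinct score as a candidate threshold (classification
#' rule: score strictly greater than the threshold means responder) and
#' records sensitivity and specificity.  The AUC is the trapezoidal area,
#' which equals the rank-sum concordance statistic
#' U/(n1 n0) with half credit for ties.
#'
#' @inheritParams labeled_scores
#' @return Tibble of class `etscc_roc` with `threshold`, `sensitivity`,
#'   `specificity`; the AUC is in `attr(, "auc")` (also via [roc_auc()]).
#' @export
roc_curve <- function(data, responder_max_trg = 2) {
  scores <- labeled_scores(data, responder_max_trg)
  check_two_classes(scores)
  s <- scores$score
  pos <- scores$responder
  thr <- c(-Inf, sort(unique(s)))
  sens <- vapply(thr, function(t) mean(s[pos] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!pos] <= t), numeric(1))
  curve <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- -sum(diff(fpr[ord]) * (head(sens[ord], -1) + tail(sens[ord], -1)) / 2)
  auc <- abs(auc)
  structure(curve, auc = auc,
            class = c("etscc_roc", class(curve)))
}

#' @rdname roc_curve
#' @return `roc_auc()` returns the numeric AUC.
#' @export
roc_auc <- function(data, responder_max_trg = 2) {
  attr(roc_curve(data, responder_max_trg), "auc")
}

#' Accuracy-maximizing eTSCC threshold
#'
#' Enumerates every cut interval between adjacent distinct scores (plus the
#' two unbounded end intervals), computes the classification accuracy of
#' the rule "score > threshold is a responder" on each, and returns the
#' midpoint of the lowest accuracy-maximizing interval -- a reproducible
#' tie-break that favors sensitivity.  Unbounded optimal end intervals
#' return the boundary score offset by one unit.
#'
#' @inheritParams labeled_scores
#' @return List: `threshold`, `accuracy` (proportion), `n_optimal`
#'   (number of tied optimal intervals).
#' @export
choose_threshold <- function(data, responder_max_trg = 2) {
  scores <- labeled_scores(data, responder_max_trg)
  s <- scores$score
  pos <- scores$responder
  u <- sort(unique(s))
  # representative cut per interval: below min, at each u_i (covers
  # [u_i, u_{i+1})), i.e. classification changes only at the u_i
  reps <- c(u[1] - 1, u)
  acc <- vapply(reps, function(t) mean((s > t) == pos), numeric(1))
  best <- max(acc)
  idx <- which(acc >= best - 1e-12)
  i <- idx[1] # lowest optimal interval
  threshold <- if (i == 1) {
    u[1] - 1
  } else if (i == length(reps)) {
    u[length(u)] + 1
  } else {
    (u[i - 1] + u[i]) / 2
  }
  list(threshold = threshold, accuracy = best, n_optimal = length(idx))
}

#' Complementary cumulative distribution of scores by class
#'
#' For each responder class, the fraction of patients whose eTSCC exceeds
#' x, evaluated at every observed score.  At the classification threshold
#' the responder CCD is the sensitivity and one minus the non-responder CCD
#' the specificity.
#'
#' @inheritParams labeled_scores
#' @return Tibble with `label`, `x`, `ccd`.
#' @export
ccd <- function(data, responder_max_trg = 2) {
  scores <- labeled_scores(data, responder_max_trg)
  xs <- sort(unique(scores$score))
  purrr::map_dfr(levels(scores$label), function(lv) {
    cls <- scores$score[scores$label == lv]
    if (length(cls) == 0) return(tibble())
    tibble(label = lv, x = xs,
           ccd = vapply(xs, function(x) mean(cls > x), numeric(1)))
  })
}

#' Classification report at a threshold
#'
#' @inheritParams labeled_scores
#' @param threshold eTSCC cut (ug/mL); defaults to the accuracy-maximizing
#'   threshold from [choose_threshold()].
#' @return Object of class `etscc_report`: threshold, AUC, per-class and
#'   pooled accuracies (percent), confusion counts, ROC and CCD tables.
#' @export
classifier_report <- function(data, threshold = NULL, responder_max_trg = 2) {
  scores <- labeled_scores(data, responder_max_trg)
  check_two_classes(scores)
  if (is.null(threshold)) {
    threshold <- choose_threshold(scores)$threshold
  }
  roc <- roc_curve(scores)
  pred <- scores$score > threshold
  n_resp <- sum(scores$responder)
  n_non <- sum(!scores$responder)
  correct_resp <- sum(pred & scores$responder)
  correct_non <- sum(!pred & !scores$responder)
  structure(
    list(threshold = threshold,
         auc = attr(roc, "auc"),
         accuracy_responders = 100 * correct_resp / n_resp,
         accuracy_nonresponders = 100 * correct_non / n_non,
         pooled_accuracy = pooled_accuracy(correct_resp, n_resp,
                                           correct_non, n_non),
         counts = c(correct_resp = correct_resp, n_resp = n_resp,
                    correct_nonresp = correct_non, n_nonresp = n_non),
         roc = roc, ccd = ccd(scores), scores = scores),
    class = "etscc_report"
  )
}

#' @exportS3Method generics::glance
glance.etscc_report <- function(x, ...) {
  tibble(threshold = x$threshold, auc = x$auc,
         accuracy_responders = x$accuracy_responders,
         accuracy_nonresponders = x$accuracy_nonresponders,
         pooled_accuracy = x$pooled_accuracy)
}

#' @exportS3Method generics::tidy
tidy.etscc_report <- function(x, ...) x$ccd

#' @export
print.etscc_report <- function(x, ...) {
  cat("eTSCC responder classification\n")
  cat(sprintf("  threshold: %.4g ug/mL   AUC: %.3f\n", x$threshold, x$auc))
  cat(sprintf("  accuracy: responders %.1f%% (%d/%d), non-responders %.1f%% (%d/%d), pooled %.1f%%\n",
              x$accuracy_responders, x$counts["correct_resp"], x$counts["n_resp"],
              x$accuracy_nonresponders, x$counts["correct_nonresp"],
              x$counts["n_nonresp"], x$pooled_accuracy))
  invisible(x)
}

#' Pooled classification accuracy
#'
#' @param correct_resp,n_resp Correctly classified and total responders.
#' @param correct_nonresp,n_nonresp Same for non-responders.
#' @return Percent accuracy 100 (correct_resp + correct_nonresp) / n.
#' @examples
#' pooled_accuracy(5, 6, 22, 27) # 81.8
#' @export
pooled_accuracy <- function(correct_resp, n_resp, correct_nonresp, n_nonresp) {
  if (n_resp + n_nonresp <= 0) abort("no patients: zero denominator")
  if (correct_resp > n_resp || correct_nonresp > n_nonresp ||
      min(correct_resp, correct_nonresp, n_resp, n_nonresp) < 0) {
    abort("inconsistent confusion counts")
  }
  unname(100 * (correct_resp + correct_nonresp) / (n_resp + n_nonresp))
}

#' Leave-one-out cross-validation of the eTSCC classifier
#'
#' Runs n folds: each fold re-derives the ROC curve and the
#' accuracy-maximizing threshold on the remaining n-1 patients, then
#' classifies the held-out patient.  Held-out predictions are pooled into a
#' confusion summary; fold-wise training AUCs are reported as mean +/- SD.
#' Deterministic: no randomness is involved.
#'
#' @inheritParams labeled_scores
#' @return Object of class `etscc_loocv`: `predictions` (one row per
#'   held-out patient: id, score, label, threshold used, prediction),
#'   `fold_auc`, `mean_auc`, `sd_auc`, pooled and per-class accuracies.
#' @export
loocv <- function(data, responder_max_trg = 2) {
  scores <- labeled_scores(data, responder_max_trg)
  n <- nrow(scores)
  if (n < 3) abort("LOOCV needs at least 3 patients")
  check_two_classes(scores)
  folds <- purrr::map(seq_len(n), function(i) {
    train <- scores[-i, ]
    if (length(unique(train$responder)) < 2) {
      warn(sprintf("fold %d: training set has a single class; using majority rule", i))
      thr <- if (mean(train$responder) > 0.5) -Inf else Inf
      auc_i <- NA_real_
    } else {
      thr <- choose_threshold(train)$threshold
      auc_i <- roc_auc(train)
    }
    tibble(fold = i,
           patient_id = scores$patient_id[i],
           score = scores$score[i],
           responder = scores$responder[i],
           threshold = thr,
           predicted = scores$score[i] > thr,
           train_auc = auc_i)
  })
  pred <- bind_rows(folds)
  correct_resp <- sum(pred$predicted & pred$responder)
  correct_non <- sum(!pred$predicted & !pred$responder)
  n_resp <- sum(pred$responder)
  n_non <- sum(!pred$responder)
  structure(
    list(predictions = pred,
         fold_auc = pred$train_auc,
         mean_auc = mean(pred$train_auc, na.rm = TRUE),
         sd_auc = stats::sd(pred$train_auc, na.rm = TRUE),
         accuracy_responders = 100 * correct_resp / n_resp,
         accuracy_nonresponders = 100 * correct_non / n_non,
         pooled_accuracy = pooled_accuracy(correct_resp, n_resp,
                                           correct_non, n_non)),
    class = "etscc_loocv"
  )
}

#' @exportS3Method generics::tidy
tidy.etscc_loocv <- function(x, ...) x$predictions

#' @exportS3Method generics::glance
glance.etscc_loocv <- function(x, ...) {
  tibble(n = nrow(x$predictions), mean_auc = x$mean_auc, sd_auc = x$sd_auc,
         accuracy_responders = x$accuracy_responders,
         accuracy_nonresponders = x$accuracy_nonresponders,
         pooled_accuracy = x$pooled_accuracy)
}

#' @export
print.etscc_loocv <- function(x, ...) {
  cat("Leave-one-out cross-validation,", nrow(x$predictions), "folds\n")
  cat(sprintf("  training AUC: %.3f +/- %.3f\n", x$mean_auc, x$sd_auc))
  cat(sprintf("  pooled accuracy %.1f%% (responders %.1f%%, non-responders %.1f%%)\n",
              x$pooled_accuracy, x$accuracy_responders,
              x$accuracy_nonresponders))
  invisible(x)
}
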