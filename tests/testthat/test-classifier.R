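test_that("labels derive from TRG with the configurable responder cut", {
  d <- tibble::tibble(score = 1:5, trg = 1:5)
  ls <- labeled_scores(d)
  expect_equal(ls$responder, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  ls3 <- labeled_scores(d, responder_max_trg = 3)
  expect_equal(sum(ls3$responder), 3)
  expect_error(labeled_scores(tibble::tibble(score = 1, trg = 7)), "1..5")
  expect_error(labeled_scores(tibble::tibble(score = 1)), "needs one of")
})

test_that("logistic fit separates, warns on separation, and matches a direct ML oracle", {
  toy <- tibble::tibble(score = c(0.1, 0.2, 0.3, 0.8, 0.9, 1.0),
                        responder = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_warning(fit <- fit_logistic(toy), "separable")
  expect_equal(roc_auc(toy), 1)
  expect_error(fit_logistic(tibble::tibble(score = 1:3,
                                           responder = rep(TRUE, 3))),
               "both")

  # 10-point non-separable set: compare against direct likelihood optimization
  set.seed(11)
  d <- tibble::tibble(score = c(0.2, 0.5, 0.9, 1.3, 1.7, 2.1, 2.4, 2.8, 3.1, 3.5),
                      responder = c(FALSE, TRUE, FALSE, FALSE, TRUE,
                                    FALSE, TRUE, TRUE, FALSE, TRUE))
  fit <- fit_logistic(d)
  nll <- function(par) {
    eta <- par[1] + par[2] * d$score
    -sum(d$responder * eta - log1p(exp(eta)))
  }
  oracle <- stats::optim(c(0, 0), nll, method = "BFGS",
                         control = list(reltol = 1e-14))$par
  expect_equal(unname(coef(fit$fit)), oracle, tolerance = 1e-4)
})

test_that("trapezoidal ROC AUC equals the rank-sum concordance statistic", {
  d <- tibble::tibble(score = c(0.8, 0.9, 0.1, 0.2),
                      responder = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_auc(d), 1)
  set.seed(5)
  for (i in 1:25) {
    d <- random_scores(sample(6:40, 1), tie_prone = (i %% 2 == 0))
    expect_equal(roc_auc(d), rank_auc(d), tolerance = 1e-12)
    flipped <- d
    flipped$responder <- !flipped$responder
    expect_equal(roc_auc(flipped), 1 - roc_auc(d), tolerance = 1e-12)
  }
})

test_that("roc curve is a monotone staircase in [0,1]", {
  set.seed(6)
  roc <- roc_curve(random_scores(30))
  expect_true(all(roc$sensitivity >= 0 & roc$sensitivity <= 1))
  expect_true(all(roc$specificity >= 0 & roc$specificity <= 1))
  expect_true(all(diff(roc$sensitivity) <= 1e-12))
  expect_true(all(diff(roc$specificity) >= -1e-12))
})

test_that("threshold selection maximizes accuracy with the midpoint tie-break", {
  d <- tibble::tibble(score = c(0.8, 0.9, 0.1, 0.2),
                      responder = c(TRUE, TRUE, FALSE, FALSE))
  ct <- choose_threshold(d)
  expect_equal(ct$threshold, 0.5)
  expect_equal(ct$accuracy, 1)

  same <- tibble::tibble(score = rep(2, 7),
                         responder = c(rep(FALSE, 5), TRUE, TRUE))
  expect_equal(choose_threshold(same)$accuracy, 5 / 7)

  set.seed(7)
  for (i in 1:20) {
    d <- random_scores(33, tie_prone = (i %% 2 == 0))
    ct <- choose_threshold(d)
    expect_equal(ct$accuracy, brute_best_accuracy(d), tolerance = 1e-12)
    # returned threshold actually achieves the claimed accuracy
    expect_equal(mean((d$score > ct$threshold) == d$responder), ct$accuracy)
  }
})

test_that("classification by score cut equals classification by fitted probability cut", {
  set.seed(8)
  d <- random_scores(40)
  fit <- suppressWarnings(fit_logistic(d))
  b <- coef(fit$fit)
  thr <- choose_threshold(d)$threshold
  p_thr <- plogis(b[1] + b[2] * thr)
  pred_score <- d$score > thr
  prob <- plogis(b[1] + b[2] * d$score)
  pred_prob <- if (b[2] >= 0) prob > p_thr else prob < p_thr
  expect_equal(pred_prob, pred_score)
})

test_that("CCD is a survival curve consistent with per-class accuracies", {
  set.seed(9)
  d <- random_scores(25)
  tab <- ccd(d)
  surv <- function(lv, x) {
    cls <- d$score[d$responder == (lv == "responder")]
    mean(cls > x)
  }
  expect_equal(surv("responder", min(d$score) - 1), 1)
  expect_equal(surv("responder", max(d$score)), 0)
  expect_true(all(tab$ccd >= 0 & tab$ccd <= 1))
  # counting identity at the chosen threshold
  rep_ <- classifier_report(d)
  expect_equal(surv("responder", rep_$threshold) * 100,
               rep_$accuracy_responders)
  expect_equal((1 - surv("non-responder", rep_$threshold)) * 100,
               rep_$accuracy_nonresponders)
})

test_that("pooled accuracy reproduces the arithmetic identities", {
  expect_equal(round(pooled_accuracy(5, 6, 22, 27), 1), 81.8)
  expect_equal(pooled_accuracy(6, 6, 27, 27), 100)
  expect_equal(round(pooled_accuracy(5, 6, 23, 27), 1), 84.8)
  expect_error(pooled_accuracy(7, 6, 22, 27), "inconsistent")
  expect_error(pooled_accuracy(0, 0, 0, 0), "denominator")
})

test_that("LOOCV holds each patient out exactly once and pools correctly", {
  set.seed(10)
  d <- random_scores(15)
  d$patient_id <- sprintf("X%02d", 1:15)
  cv <- loocv(d)
  expect_equal(nrow(cv$predictions), 15)
  expect_setequal(cv$predictions$patient_id, d$patient_id)
  # deterministic
  cv2 <- loocv(d)
  expect_identical(cv$predictions, cv2$predictions)
  # fold thresholds derive only from the training points
  for (i in c(1, 7, 15)) {
    expect_equal(cv$predictions$threshold[i],
                 choose_threshold(d[-i, ])$threshold)
  }
  # pooled accuracy equals hand-pooled confusion counts
  correct <- cv$predictions$predicted == cv$predictions$responder
  expect_equal(cv$pooled_accuracy, 100 * mean(correct))
  exp_resp <- 100 * mean(correct[cv$predictions$responder])
  expect_equal(cv$accuracy_responders, exp_resp)
  expect_error(loocv(d[1:2, ]), "at least 3")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:5) {
    d <- random_scores(30, tie_prone = TRUE)
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(d$responder, d$score, quiet = TRUE))))
    expect_equal(roc_auc(d), ref, tolerance = 1e-12)
  }
})
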