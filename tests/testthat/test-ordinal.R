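make_ordinal_cohort <- function(n, alpha = c(-2, -1, 0.5, 2),
                                beta = c(age = 0.03, male = -0.4,
                                         synchronous = 0.3,
                                         lesion_count = 0.2,
                                         extrahepatic = -0.5,
                                         left = 0.25, rectum = -0.3)) {
  age <- runif(n, 42, 83)
  gender <- sample(c("female", "male"), n, replace = TRUE)
  presentation <- sample(c("metachronous", "synchronous"), n, replace = TRUE)
  lesion_count <- sample(1:5, n, replace = TRUE)
  extrahepatic <- runif(n) < 0.3
  primary_site <- sample(c("right colon", "left colon", "rectum"), n,
                         replace = TRUE)
  eta <- beta["age"] * age + beta["male"] * (gender == "male") +
    beta["synchronous"] * (presentation == "synchronous") +
    beta["lesion_count"] * lesion_count +
    beta["extrahepatic"] * extrahepatic +
    beta["left"] * (primary_site == "left colon") +
    beta["rectum"] * (primary_site == "rectum")
  # P(TRG <= i) = plogis(alpha_i + eta); latent logistic draw
  w <- -eta + rlogis(n)
  trg <- 1L + vapply(w, function(wi) sum(wi > alpha), integer(1))
  tibble::tibble(age, gender, presentation, lesion_count, extrahepatic,
                 primary_site, trg = trg)
}

test_that("intercept-only cumulative logits equal the empirical proportions", {
  set.seed(21)
  cohort <- make_ordinal_cohort(400)
  fit <- ordinal_fit(cohort, covariates = character(0))
  td <- tidy(fit)
  levs <- sort(unique(cohort$trg))
  cum <- cumsum(table(factor(cohort$trg, levels = levs)))[-length(levs)] /
    nrow(cohort)
  expect_equal(unname(td$estimate[td$type == "intercept"]),
               unname(qlogis(cum)), tolerance = 1e-4)
})

test_that("intercepts are monotone under the cumulative-logit parameterization", {
  set.seed(22)
  cohort <- make_ordinal_cohort(300)
  td <- tidy(ordinal_fit(cohort))
  a <- td$estimate[td$type == "intercept"]
  expect_true(all(diff(a) > 0))
  expect_equal(sum(td$type == "coefficient"), 7) # 6 covariates, 7 columns
})

test_that("rank-deficient designs fail loudly naming the collinear column", {
  set.seed(23)
  cohort <- make_ordinal_cohort(100)
  cohort$dup <- cohort$lesion_count
  expect_error(ordinal_fit(cohort, covariates = c("lesion_count", "dup")),
               "collinear.*dup")
  cohort$flat <- 1
  expect_error(ordinal_fit(cohort, covariates = c("age", "flat")),
               "collinear")
})

test_that("proportional-odds fit recovers known coefficients within 3 SE", {
  set.seed(24)
  alpha <- c(-2, -1, 0.5, 2)
  beta <- c(age = 0.03, male = -0.4, synchronous = 0.3, lesion_count = 0.2,
            extrahepatic = -0.5, left = 0.25, rectum = -0.3)
  cohort <- make_ordinal_cohort(1000, alpha, beta)
  td <- tidy(ordinal_fit(cohort))
  truth <- c(age = unname(beta["age"]),
             gendermale = unname(beta["male"]),
             presentationsynchronous = unname(beta["synchronous"]),
             lesion_count = unname(beta["lesion_count"]),
             extrahepatic = unname(beta["extrahepatic"]),
             `primary_siteleft colon` = unname(beta["left"]),
             primary_siterectum = unname(beta["rectum"]))
  co <- td[td$type == "coefficient", ]
  expect_setequal(co$term, names(truth))
  z <- abs(co$estimate - truth[co$term]) / co$std.error
  expect_true(all(z < 3))
  a <- td$estimate[td$type == "intercept"]
  a_se <- td$std.error[td$type == "intercept"]
  expect_true(all(abs(a - alpha) / a_se < 3))
})

test_that("TRG spanning a single grade is rejected", {
  cohort <- make_ordinal_cohort(50)
  cohort$trg <- 3L
  expect_error(ordinal_fit(cohort), "two observed grades")
})
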