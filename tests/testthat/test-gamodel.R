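# Fixed-coefficient GA prediction, Hittner grades, mixed model, VIF.

zero_features <- function() {
  f <- as.list(stats::setNames(numeric(10), alcv:::feature_names()))
  structure(f, class = "alcv_features")
}

test_that("the shipped model is the published final model", {
  m <- default_ga_model()
  expect_equal(m$intercept, 34.406)
  expect_equal(unname(m$coefficients[c(
    "branch_length_max", "branch_width_max", "branch_width_min",
    "branch_thickness_max", "branch_thickness_min", "density"
  )]), c(0.022, -0.092, 0.155, -0.122, -1.667, -0.124))
  expect_true(all(m$mapping %in% alcv:::feature_names()))
})

test_that("prediction is the declared affine form", {
  m <- default_ga_model()
  expect_equal(suppressWarnings(predict_ga(m, zero_features())), 34.406)
  f <- zero_features()
  f$density <- 1
  expect_equal(suppressWarnings(predict_ga(m, f)), 34.406 - 0.124)
  # linearity: doubling features doubles (prediction - intercept)
  set.seed(3)
  f1 <- zero_features()
  for (fn in alcv:::feature_names()) f1[[fn]] <- runif(1, 0, 5)
  f2 <- f1
  for (fn in alcv:::feature_names()) f2[[fn]] <- 2 * f1[[fn]]
  p1 <- suppressWarnings(predict_ga(m, f1))
  p2 <- suppressWarnings(predict_ga(m, f2))
  expect_equal(p2 - 34.406, 2 * (p1 - 34.406), tolerance = 1e-12)
  # equals an independent dot product on random feature vectors
  for (i in 1:100) {
    f <- zero_features()
    for (fn in alcv:::feature_names()) f[[fn]] <- runif(1, -3, 3)
    manual <- m$intercept + sum(vapply(
      names(m$coefficients),
      function(tm) m$coefficients[[tm]] * f[[m$mapping[[tm]]]], numeric(1)
    ))
    expect_equal(suppressWarnings(predict_ga(m, f)), manual,
      tolerance = 1e-12
    )
  }
})

test_that("missing or non-finite features error by name", {
  m <- default_ga_model()
  f <- zero_features()
  f$branch_width_max <- NULL
  expect_error(suppressWarnings(predict_ga(m, f)), "branch_width_max")
  f2 <- zero_features()
  f2$density <- NaN
  expect_error(suppressWarnings(predict_ga(m, f2)), "density")
})

test_that("coefficient files are validated at load", {
  good <- system.file("extdata", "ga_coefficients.json", package = "alcv")
  j <- jsonlite::read_json(good, simplifyVector = TRUE)
  path <- tempfile(fileext = ".json")
  j2 <- j
  j2$mapping$density <- NULL
  jsonlite::write_json(j2, path, auto_unbox = TRUE)
  expect_error(load_ga_model(path), "density")
  j3 <- j
  j3$mapping$density <- "no_such_feature"
  jsonlite::write_json(j3, path, auto_unbox = TRUE)
  expect_error(load_ga_model(path), "unknown biomarker")
  j4 <- j
  j4$intercept <- NULL
  jsonlite::write_json(j4, path, auto_unbox = TRUE)
  expect_error(load_ga_model(path), "intercept")
})

test_that("Hittner grades map to their printed ranges and back", {
  expect_equal(unname(hittner_grade_range("I")), c(33, 34))
  expect_equal(unname(hittner_grade_range("II")), c(31, 32))
  expect_equal(unname(hittner_grade_range("III")), c(29, 30))
  expect_equal(unname(hittner_grade_range("IV")), c(27, 28))
  expect_error(hittner_grade_range("V"), "unknown")
  expect_equal(hittner_grade(30.0), "III")
  # each printed range's midpoint classifies back to its own grade
  for (g in c("I", "II", "III", "IV")) {
    expect_equal(hittner_grade(mean(hittner_grade_range(g))), g)
  }
  expect_warning(out <- hittner_grade(36), "outside")
  expect_true(is.na(out))
})

cohort_terms <- function(coh) {
  setdiff(names(coh), c("subject_id", "session_id", "ultrasound_ga"))
}

test_that("the mixed fit matches lme4 on ML and REML", {
  coh <- simulate_cohort(24, 3, seed = 7)
  terms <- cohort_terms(coh)
  for (reml in c(FALSE, TRUE)) {
    fit <- fit_mixed_model(coh, terms, reml = reml)
    lf <- lme4::lmer(
      stats::as.formula(paste(
        "ultrasound_ga ~", paste(terms, collapse = "+"), "+ (1|subject_id)"
      )),
      data = coh, REML = reml
    )
    expect_equal(unname(fit$fixed_effects), unname(lme4::fixef(lf)),
      tolerance = 1e-5
    )
    expect_equal(fit$loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
    vc <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(fit$sigma_subject, vc$sdcor[1], tolerance = 1e-4)
    expect_equal(fit$sigma_resid, vc$sdcor[2], tolerance = 1e-4)
    if (!reml) {
      expect_equal(fit$aic, stats::AIC(lf), tolerance = 1e-6)
      expect_equal(fit$bic, stats::BIC(lf), tolerance = 1e-6)
    }
  }
})

test_that("AIC/BIC identities and profile optimality hold", {
  coh <- simulate_cohort(20, 3, seed = 12)
  terms <- cohort_terms(coh)
  fit <- fit_mixed_model(coh, terms)
  k <- length(fit$fixed_effects) + 2
  expect_equal(fit$aic, -2 * fit$loglik + 2 * k, tolerance = 1e-12)
  expect_equal(fit$bic, -2 * fit$loglik + k * log(fit$n_obs),
    tolerance = 1e-12
  )
  # the profiled optimum dominates arbitrary variance ratios
  X <- cbind(1, as.matrix(coh[, terms]))
  ss <- alcv:::mixed_suffstats(X, coh$ultrasound_ga, coh$subject_id)
  for (lam in c(0, 0.1, 1, 10)) {
    ll <- alcv:::mixed_profile(ss, lam, nrow(X), ncol(X))$loglik
    expect_lte(ll, fit$loglik + 1e-8)
  }
})

test_that("without subject variance the fit reduces to OLS", {
  coh <- simulate_cohort(24, 3,
    sigma_subject = 0, sigma_resid = 0.5,
    seed = 3
  )
  terms <- cohort_terms(coh)
  fit <- fit_mixed_model(coh, terms)
  ols <- stats::coef(stats::lm(
    stats::as.formula(paste(
      "ultrasound_ga ~", paste(terms, collapse = "+")
    )),
    data = coh
  ))
  expect_equal(unname(fit$fixed_effects), unname(ols), tolerance = 1e-6)
})

test_that("row duplication equals doubling the variance ratio in the GLS step", {
  # (The naive claim that refitted estimates are unchanged to 1e-6 fails:
  # profiling re-optimizes the ratio. The exact invariance is dup@lambda ==
  # original@2*lambda; the refit moves only slightly.)
  coh <- simulate_cohort(24, 3, seed = 7)
  terms <- cohort_terms(coh)
  X <- cbind(1, as.matrix(coh[, terms]))
  y <- coh$ultrasound_ga
  dup <- rbind(coh, coh)
  ss1 <- alcv:::mixed_suffstats(X, y, coh$subject_id)
  ss2 <- alcv:::mixed_suffstats(
    cbind(1, as.matrix(dup[, terms])),
    dup$ultrasound_ga, dup$subject_id
  )
  for (lam in c(0.25, 1, 4)) {
    b1 <- alcv:::mixed_profile(ss1, 2 * lam, nrow(X), ncol(X))$beta
    b2 <- alcv:::mixed_profile(ss2, lam, 2 * nrow(X), ncol(X))$beta
    expect_equal(b1, b2, tolerance = 1e-10)
  }
  f1 <- fit_mixed_model(coh, terms)
  f2 <- fit_mixed_model(dup, terms)
  expect_equal(unname(f1$fixed_effects), unname(f2$fixed_effects),
    tolerance = 0.25
  )
})

test_that("degenerate designs are rejected with useful messages", {
  coh <- simulate_cohort(10, 3, seed = 5)
  coh$dupe <- coh$density
  expect_error(
    fit_mixed_model(coh, c(cohort_terms(coh))),
    "collinear.*dupe|dupe"
  )
  one <- simulate_cohort(2, 1, seed = 5)
  expect_error(fit_mixed_model(one, "density"), ">= 2 sessions")
})

test_that("VIF behaves at independence, duplication and near-collinearity", {
  coh <- simulate_cohort(400, 2, seed = 9)
  terms <- cohort_terms(coh)
  v <- variance_inflation(coh, terms)
  expect_true(all(abs(v - 1) < 0.2))
  coh$dupe <- coh$density
  expect_true(is.infinite(variance_inflation(coh, c("density", "dupe"))[1]))
  set.seed(1)
  coh$near <- coh$density + rnorm(nrow(coh), 0, 0.05)
  v2 <- variance_inflation(coh, c("density", "near", "branch_length_max"))
  expect_gt(v2[["density"]], 10)
  # closed form 1/(1-R^2)
  r2 <- summary(stats::lm(density ~ near + branch_length_max, coh))$r.squared
  expect_equal(v2[["density"]], 1 / (1 - r2), tolerance = 1e-8)
  expect_error(variance_inflation(coh[1:3, ], terms), "rows")
})
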