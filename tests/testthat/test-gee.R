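# The GEE solver is checked two ways: exact agreement with ordinary
# maximum-likelihood GLM fits when clustering is absent, and agreement with
# an independently computed exchangeable-GEE reference (statsmodels 0.14,
# GEE with Exchangeable covariance) on a fixture regenerated here under a
# fixed seed; the reference numbers were computed once and frozen.

gee_oracle_fixture <- function() {
  set.seed(99)
  np <- 150
  ni <- sample(1:4, np, replace = TRUE)
  id <- rep(1:np, ni); n <- length(id)
  re <- rep(rnorm(np, 0, 0.8), ni)
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.3 + 0.7 * x1 - 0.5 * x2 + re))
  z <- rpois(n, exp(0.2 + 0.4 * x1 + 0.3 * re))
  data.frame(id, x1, x2, y, z)
}

test_that("exchangeable GEE matches the frozen statsmodels reference", {
  d <- gee_oracle_fixture()
  fb <- gee_fit(y ~ x1 + x2, d, id = "id", family = "binomial")
  expect_equal(unname(coef(fb)),
               c(-0.46324750, 0.57361791, -0.43025039), tolerance = 1e-6)
  expect_equal(unname(fb$robust_se),
               c(0.16764012, 0.11307862, 0.21519221), tolerance = 1e-6)
  expect_equal(fb$alpha, 0.05064879, tolerance = 1e-6)
  fp <- gee_fit(z ~ x1, d, id = "id", family = "poisson")
  expect_equal(unname(coef(fp)), c(0.23289639, 0.41041753),
               tolerance = 1e-6)
  expect_equal(unname(fp$robust_se), c(0.05319965, 0.04490388),
               tolerance = 1e-6)
  expect_true(fb$converged && fp$converged)
})

test_that("one record per cluster: exchangeable GEE equals ML logistic", {
  set.seed(31)
  n <- 400
  d <- data.frame(id = 1:n, x1 = rnorm(n), x2 = runif(n))
  d$y <- rbinom(n, 1, plogis(0.2 + 0.9 * d$x1 - 1.2 * d$x2))
  f <- gee_fit(y ~ x1 + x2, d, id = "id", family = "binomial")
  g <- stats::glm(y ~ x1 + x2, stats::binomial, d)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$alpha, 0)   # no within-cluster pairs to estimate from
  # same for the Poisson family
  d$z <- rpois(n, exp(0.1 + 0.5 * d$x1))
  fp <- gee_fit(z ~ x1, d, id = "id", family = "poisson")
  gp <- stats::glm(z ~ x1, stats::poisson, d)
  expect_equal(unname(coef(fp)), unname(coef(gp)), tolerance = 1e-6)
})

test_that("estimates are invariant to row shuffling", {
  d <- gee_oracle_fixture()
  f1 <- gee_fit(y ~ x1 + x2, d, id = "id", family = "binomial")
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  f2 <- gee_fit(y ~ x1 + x2, d2, id = "id", family = "binomial")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(f1$robust_se, f2$robust_se, tolerance = 1e-10)
})

test_that("Wald joint tests: 1-df identity, rank deficiency, calibration", {
  d <- gee_oracle_fixture()
  f <- gee_fit(y ~ x1 + x2, d, id = "id", family = "binomial")
  w <- wald_joint_test(f, "x1")
  expect_equal(w$statistic, (coef(f)[["x1"]] / f$robust_se[["x1"]])^2,
               tolerance = 1e-10)
  expect_equal(w$df, 1)
  # duplicated (collinear) term: rank deficiency is reported
  d$x1b <- d$x1
  suppressWarnings(f2 <- gee_fit(y ~ x1 + x1b + x2, d, id = "id",
                                 family = "binomial"))
  w2 <- wald_joint_test(f2, c("x1", "x2"))
  expect_equal(w2$df, 2)
  expect_error(wald_joint_test(f, "nonexistent"), "match")
  # type-I calibration of the joint test under the null (2 df)
  set.seed(77)
  pvals <- replicate(200, {
    n <- 150
    dd <- data.frame(id = 1:n, x1 = rnorm(n), x2 = rnorm(n))
    dd$y <- rbinom(n, 1, 0.4)   # no effect of x1, x2
    ff <- gee_fit(y ~ x1 + x2, dd, id = "id", family = "binomial")
    wald_joint_test(ff, c("x1", "x2"))$p_value
  })
  rej <- mean(pvals < 0.05)
  expect_gt(rej, 0.01); expect_lt(rej, 0.11)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.001)
})

test_that("predictive margins agree with brute-force standardization", {
  d <- gee_oracle_fixture()
  f <- gee_fit(y ~ x1 + x2, d, id = "id", family = "binomial")
  # intercept-only margin equals the observed outcome mean (independence
  # weighting; exchangeable weighting reweights clusters by size)
  f0 <- gee_fit(y ~ 1, d, id = "id", family = "binomial",
                corstr = "independence")
  m0 <- predict_margins(f0)
  expect_equal(m0$margin, mean(d$y), tolerance = 1e-8)
  # margin equals the average of per-row predicted probabilities
  m1 <- predict_margins(f, list(x2 = 1))
  d1 <- d; d1$x2 <- 1
  eta <- as.matrix(cbind(1, d1$x1, d1$x2)) %*% coef(f)
  expect_equal(m1$margin, mean(plogis(eta)), tolerance = 1e-10)
  expect_gt(m1$se, 0)
  # margins move with the coefficient sign
  m_hi <- predict_margins(f, list(x1 = 2))
  m_lo <- predict_margins(f, list(x1 = -2))
  expect_equal(sign(m_hi$margin - m_lo$margin), sign(coef(f)[["x1"]]))
  expect_error(predict_margins(f, list(bogus = 1)), "unknown covariate")
})

test_that("input validation and degenerate outcomes are rejected", {
  d <- data.frame(id = 1:10, x = rnorm(10), y = c(rep(2, 5), rep(0, 5)))
  expect_error(gee_fit(y ~ x, d, id = "id", family = "binomial"),
               "\\[0, 1\\]")
  d$z <- -1
  expect_error(gee_fit(z ~ x, d, id = "id", family = "poisson"),
               "non-negative")
})

test_that("the marginal model layer runs the four suites on a small cohort", {
  fx <- medium_events()
  ev <- data.table::copy(fx$ev)
  set.seed(3)
  ev[, cluster := sample(0:3, .N, replace = TRUE)]
  pd <- prepare_model_data(ev)
  expect_true(all(c("potassium_imp", "potassium_missing",
                    "max_pre_qt_imp") %in% names(pd)))
  expect_false(anyNA(pd$potassium_imp))

  sp <- model_spec("dilqts", exposure = "alert_fired")
  f <- fit_marginal(sp, pd)
  expect_s3_class(f, "qtcds_gee")
  expect_true(f$converged)
  expect_true("alert_fired" %in% names(coef(f)))

  # deterministic rerun gives an identical fit
  f2 <- fit_marginal(sp, pd)
  expect_identical(coef(f), coef(f2))

  # Poisson family on fractional days
  fl <- fit_marginal(model_spec("los_days"), pd)
  expect_equal(fl$family, "poisson")
  expect_true(fl$converged)

  # action-group suite filters to fired, recorded, non-recoded alerts
  sa <- model_spec("los_days", exposure = "action_group", adjusted = FALSE)
  fa <- fit_marginal(sa, pd)
  expect_lte(fa$n_obs, sum(pd$alert_fired))
  expect_lt(fa$n_obs, nrow(pd))
  expect_true("action_groupcomply" %in% names(coef(fa)))

  # era suite has no alert terms
  suite <- run_analysis_suite(ev, "era", outcomes = c("dilqts", "los_days"))
  expect_named(suite$fits, c("dilqts.none", "los_days.none"))
  expect_false(any(grepl("alert", names(coef(suite$fits$dilqts.none)))))
  expect_true(all(c("estimate", "effect", "lower", "upper") %in%
                    names(suite$table)))
  expect_equal(length(suite$failures), 0L)
})

test_that("medication-alert interaction variant fits and is testable", {
  fx <- medium_events()
  ev <- data.table::copy(fx$ev)
  sp <- model_spec("dilqts", interaction = "icu")
  f <- fit_marginal(sp, ev)
  expect_true(any(grepl("icu.*:alert_fired|alert_fired:icu",
                        names(coef(f)))))
  w <- wald_joint_test(f, ":alert_fired|alert_fired:")
  expect_true(w$p_value >= 0 && w$p_value <= 1)
})
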