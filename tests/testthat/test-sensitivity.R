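test_that("ML mediation recovers noiseless structural coefficients exactly", {
  dat <- make_mediation_data(30, sigma_m = 1, sigma_y = 1, seed = 20)
  # mediator deviation orthogonalized against every regressor, so OLS
  # recovers path a exactly; the outcome lies exactly on its equation
  set.seed(20)
  z <- residuals(lm(rnorm(30) ~ age + female + education + sbp_baseline,
                    data = dat))
  dat$interface_quality <- (5.65 - 0.12 * 59) + 0.12 * dat$age + z
  dat$sbp_change <- 10 - 1.35 * dat$interface_quality - 0.28 * dat$age
  # the exact fit triggers lm's perfect-fit warning by design
  ml <- suppressWarnings(ml_mediation(dat, mediation_spec(seed = 1)))
  expect_equal(ml$a, 0.12, tolerance = 1e-9)
  expect_equal(ml$b, -1.35, tolerance = 1e-9)
  expect_equal(ml$c_prime, -0.28, tolerance = 1e-9)
  expect_equal(ml$indirect, 0.12 * -1.35, tolerance = 1e-9)
  expect_equal(ml$total, ml$direct + ml$indirect)
})

test_that("delta-method variance composes the per-equation variances", {
  dat <- make_mediation_data(80, seed = 21)
  spec <- mediation_spec(seed = 1)
  ml <- ml_mediation(dat, spec)
  fm <- lm(interface_quality ~ age + female + education + sbp_baseline, dat)
  fy <- lm(sbp_change ~ interface_quality + age + female + education +
             sbp_baseline, dat)
  se_a <- coef(summary(fm))["age", "Std. Error"]
  se_b <- coef(summary(fy))["interface_quality", "Std. Error"]
  a <- coef(fm)[["age"]]; b <- coef(fy)[["interface_quality"]]
  expect_equal(ml$se_indirect, sqrt(a^2 * se_b^2 + b^2 * se_a^2),
               tolerance = 1e-12)
  boot_ci <- ml_mediation(dat, spec, ci_method = "bootstrap", n_boot = 2000,
                          seed = 2)
  expect_lt(boot_ci$ci_lower, boot_ci$ci_upper)
})

test_that("ML indirect estimate matches generator truth at n = 1000", {
  dat <- make_mediation_data(1000, seed = 22)
  ml <- ml_mediation(dat, mediation_spec(seed = 1))
  expect_lt(abs(ml$indirect - (0.12 * -1.35)), 3 * ml$se_indirect)
})

test_that("prior sensitivity orders estimates and widths as expected", {
  dat <- make_mediation_data(22, a = 0.12, b = -1.35, seed = 23)
  rep_ <- prior_sensitivity(dat, quick_spec(seed = 23))
  tab <- rep_$rows
  expect_setequal(tab$specification, c("default", "weakened", "skeptical", "ml"))
  ind <- function(s) tab$indirect[tab$specification == s]
  wid <- function(s) tab$width[tab$specification == s]
  expect_lte(abs(ind("skeptical")), abs(ind("default")))
  expect_gte(wid("weakened"), wid("default"))
  expect_true(all(tab$lower <= tab$upper))
  expect_true(all(tab$converged))
  expect_equal(rep_$width_ratio_default_vs_ml, wid("default") / wid("ml"))
})

test_that("pure-noise outcomes give null intervals under every prior", {
  dat <- make_mediation_data(400, a = 0, b = 0, c_prime = 0, seed = 24)
  rep_ <- prior_sensitivity(dat, quick_spec(seed = 24))
  tab <- rep_$rows
  expect_true(all(tab$lower <= 0 & tab$upper >= 0))
})

test_that("leave-one-out flags an injected outlier as most influential", {
  # a 10-sigma outcome shift at the highest-leverage row should dominate the
  # influence ranking; at n = 22 leverage interactions occasionally promote a
  # neighbouring case, so the ranking is asserted across seeds
  top1 <- 0; top2 <- 0
  for (s in 25:44) {
    dat <- make_mediation_data(22, sigma_m = 0.2, sigma_y = 1, seed = s)
    h <- hatvalues(lm(sbp_change ~ interface_quality + age + female +
                        education + sbp_baseline, dat))
    target <- which.max(h)
    dat$sbp_change[target] <- dat$sbp_change[target] + 10 * 1
    loo <- loo_influence(dat, mediation_spec(seed = 1))
    expect_equal(nrow(loo$cases), 22)
    expect_equal(loo$max_abs_deviation, max(abs(loo$cases$deviation)))
    r <- which(loo$cases$omitted_row == target)
    top1 <- top1 + (r == 1)
    top2 <- top2 + (r <= 2)
  }
  expect_gte(top1, 12)
  expect_gte(top2, 18)
})

test_that("duplicating the dataset dilutes every case's influence", {
  dat <- make_mediation_data(20, seed = 26)
  spec <- mediation_spec(seed = 1)
  base <- loo_influence(dat, spec)
  doubled <- rbind(dat, dat)
  doubled$id <- sprintf("S%04d", seq_len(nrow(doubled)))
  dil <- loo_influence(doubled, spec)
  expect_lt(dil$max_abs_deviation, base$max_abs_deviation)
})

test_that("removing either copy of a duplicated case has identical influence", {
  # six case types, each duplicated; by exchangeability the two copies of a
  # type must carry exactly the same leave-one-out deviation
  types <- data.frame(age = c(50, 60, 70, 50, 60, 70),
                      female = c(0, 0, 0, 1, 1, 1),
                      education = c(1, 3, 2, 2, 1, 3),
                      m_extra = c(0.4, -0.7, 1.1, -0.2, 0.9, -1.5))
  base <- types[rep(1:6, each = 2), ]
  base$interface_quality <- 2 + 0.1 * base$age + base$m_extra
  base$sbp_change <- 5 - 1.2 * base$interface_quality - 0.3 * base$age
  base$id <- sprintf("T%02d", seq_len(nrow(base)))
  spec <- mediation_spec(covariates = c("female", "education"), seed = 1)
  loo <- suppressWarnings(loo_influence(base, spec)) # exact-fit lm warnings
  dev <- loo$cases$deviation[order(loo$cases$omitted_row)]
  for (k in 1:6)
    expect_equal(dev[2 * k - 1], dev[2 * k], tolerance = 1e-12)
})

test_that("covariate expansion is inert for noise and fixes confounding", {
  dat <- make_mediation_data(1000, seed = 27)
  dat$noise1 <- rnorm(1000)
  dat$noise2 <- rnorm(1000)
  spec <- mediation_spec(seed = 1)
  ce <- covariate_expansion(dat, spec, extra = c("noise1", "noise2"))
  expect_lt(abs(ce$delta_se_units), 0.5)

  dat$dup_age <- dat$age
  expect_error(covariate_expansion(dat, spec, extra = "dup_age"), "collinear")
  expect_error(covariate_expansion(dat, spec, extra = "absent"), "missing")

  # confounder u raises the mediator and lowers the outcome; omitting it
  # biases the indirect effect away from the truth a*b
  set.seed(28)
  n <- 1000
  u <- rnorm(n)
  conf <- make_mediation_data(n, seed = 28)
  conf$interface_quality <- conf$interface_quality + 0.8 * u
  conf$sbp_change <- conf$sbp_change - 1.35 * 0.8 * u - 6 * u
  conf$u <- u
  truth <- 0.12 * -1.35
  base_fit <- ml_mediation(conf, spec)
  exp_fit <- covariate_expansion(conf, spec, extra = "u")
  expect_lt(abs(exp_fit$expanded_indirect - truth),
            abs(base_fit$indirect - truth))
})
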