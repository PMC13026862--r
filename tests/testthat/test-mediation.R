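test_that("log posterior is maximal at truth for noiseless data", {
  set.seed(2)
  n <- 40
  dat <- data.frame(age = runif(n, 45, 74), female = rbinom(n, 1, 0.5),
                    education = sample(1:3, n, TRUE),
                    sbp_baseline = rnorm(n, 128, 14))
  truth <- list(alpha_m = -1.43, a = 0.12, gamma = c(female = 0, education = 0,
                                                     sbp_baseline = 0),
                sigma_m = 1, alpha_y = 19.5, b = -1.35, c_prime = -0.28,
                delta = c(female = 0, education = 0, sbp_baseline = 0),
                sigma_y = 1)
  dat$interface_quality <- truth$alpha_m + truth$a * dat$age
  dat$sbp_change <- truth$alpha_y + truth$b * dat$interface_quality +
    truth$c_prime * dat$age
  spec <- mediation_spec(prior_set = scale_prior_set(default_prior_set(), 1e6),
                         seed = 1)
  lp0 <- log_posterior(truth, dat, spec)
  for (field in c("a", "b", "c_prime", "alpha_m", "alpha_y")) {
    pert <- truth
    pert[[field]] <- pert[[field]] + 0.05
    expect_lt(log_posterior(pert, dat, spec), lp0)
  }
})

test_that("doubling sigma_y changes the log posterior by the Gaussian closed form", {
  set.seed(3)
  n <- 25
  dat <- make_mediation_data(n, seed = 3)
  spec <- mediation_spec(covariates = c("female", "education", "sbp_baseline"),
                         seed = 1)
  base <- list(alpha_m = 0, a = 0.1, gamma = c(female = 0, education = 0,
                                               sbp_baseline = 0),
               sigma_m = 1, alpha_y = 0, b = -1, c_prime = -0.2,
               delta = c(female = 0, education = 0, sbp_baseline = 0),
               sigma_y = 2)
  doubled <- base; doubled$sigma_y <- 2 * base$sigma_y
  mu_y <- base$alpha_y + base$b * dat$interface_quality +
    base$c_prime * dat$age
  ssr <- sum((dat$sbp_change - mu_y)^2)
  s2 <- base$sigma_y^2
  lik_diff <- -n * log(2) - (ssr / 2) * (1 / (4 * s2) - 1 / s2)
  halft <- function(x) log(2) + dt(x / 10, 3, log = TRUE) - log(10)
  prior_diff <- halft(doubled$sigma_y) - halft(base$sigma_y)
  got <- log_posterior(doubled, dat, spec) - log_posterior(base, dat, spec)
  expect_equal(got, lik_diff + prior_diff, tolerance = 1e-9)
})

test_that("log posterior returns -Inf outside the support, not an error", {
  dat <- make_mediation_data(20, seed = 4)
  spec <- mediation_spec(seed = 1)
  params <- list(alpha_m = 0, a = 0, gamma = c(female = 0, education = 0,
                                               sbp_baseline = 0),
                 sigma_m = -1, alpha_y = 0, b = 0, c_prime = 0,
                 delta = c(female = 0, education = 0, sbp_baseline = 0),
                 sigma_y = 1)
  expect_identical(log_posterior(params, dat, spec), -Inf)
})

test_that("Gibbs draws match the conjugate closed form on a one-point model", {
  # y = beta * x + eps, sigma = 1 known, beta ~ N(0,1), (x, y) = (1, 1):
  # posterior is N(0.5, 0.5)
  d <- bayes_lm_gibbs(matrix(1, 1, 1, dimnames = list(NULL, "x")), y = 1,
                      prior_mean = 0, prior_sd = 1, fixed_sigma = 1,
                      chains = 2, iterations = 3000, warmup = 500, seed = 5)
  draws <- c(d[[1]][, "x"], d[[2]][, "x"])
  n <- length(draws)
  expect_equal(mean(draws), 0.5, tolerance = 3 * sqrt(0.5 / n))
  expect_equal(var(draws), 0.5, tolerance = 3 * 0.5 * sqrt(2 / (n - 1)))
})

test_that("split R-hat flags non-mixing and passes iid chains", {
  set.seed(6)
  good <- list(rnorm(2000), rnorm(2000))
  expect_true(gelman_rubin(good) > 0.99 && gelman_rubin(good) < 1.01)
  bad <- list(rnorm(2000, 0), rnorm(2000, 10))
  expect_gt(gelman_rubin(bad), 2)
  expect_error(gelman_rubin(list(rnorm(100))), "single chain")
})

test_that("ESS matches iid and AR(1) oracles", {
  set.seed(7)
  iid <- list(rnorm(5000), rnorm(5000))
  expect_equal(effective_sample_size(iid), 10000, tolerance = 0.2)
  phi <- 0.9
  n <- 20000
  x <- as.numeric(arima.sim(list(ar = phi), n))
  target <- n * (1 - phi) / (1 + phi)
  expect_equal(effective_sample_size(list(x)), target, tolerance = 0.25)
})

test_that("diagnostics agree with coda on a real fit", {
  dat <- make_mediation_data(50, seed = 8)
  dr <- sample_posterior(quick_spec(seed = 8), dat)
  ch <- split(dr$b, dr$chain)
  mc <- coda::mcmc.list(lapply(ch, coda::mcmc))
  expect_equal(gelman_rubin(ch), as.numeric(coda::gelman.diag(mc)$psrf[1, 1]),
               tolerance = 0.01)
  expect_equal(effective_sample_size(ch), unname(coda::effectiveSize(mc)),
               tolerance = 0.35)
})

test_that("derived effects obey the draw-wise identity on every draw", {
  dat <- make_mediation_data(60, seed = 9)
  dr <- sample_posterior(quick_spec(seed = 9), dat)
  expect_equal(nrow(dr), 2 * (1500 - 500))
  expect_identical(dr$total, dr$c_prime + dr$a * dr$b)
  expect_identical(dr$indirect, dr$a * dr$b)
  expect_identical(dr$direct, dr$c_prime)
  expect_true(all(dr$sigma_m > 0 & dr$sigma_y > 0))
})

test_that("summaries handle degenerate draws and enforce draw minimums", {
  dr <- constant_draws(a = 1, b = 1, c_prime = 0)
  sm <- summarize_mediation(dr)
  ind <- sm$effects[sm$effects$effect == "indirect", ]
  expect_equal(ind$mean, 1)
  expect_equal(c(ind$cri_lower, ind$cri_upper), c(1, 1))
  expect_equal(ind$p_negative, 0)
  expect_equal(sm$proportion_mediated$point, 1)
  expect_error(summarize_mediation(constant_draws(1, 1, 0, n = 500)), "1000")
})

test_that("skeptical priors shrink every path toward zero on paired seeds", {
  dat <- make_mediation_data(22, seed = 10)
  fit <- function(ps) {
    sp <- mediation_spec(prior_set = ps, chains = 4, iterations = 4000,
                         warmup = 1000, seed = 11)
    dr <- sample_posterior(sp, dat)
    colMeans(dr[, c("a", "b", "c_prime")])
  }
  m_def <- fit(default_prior_set())
  m_skep <- fit(skeptical_prior_set())
  expect_true(all(abs(m_skep) <= abs(m_def)))
})

test_that("rank-deficient designs fail with the collinear column named", {
  dat <- make_mediation_data(30, seed = 12)
  dat$dup <- dat$female
  sp <- mediation_spec(covariates = c("female", "dup"), seed = 1)
  expect_error(sample_posterior(sp, dat), "collinear.*dup")
})

test_that("model specification invariants are enforced", {
  expect_error(mediation_spec(warmup = 2500, iterations = 2500), "warmup")
  expect_error(mediation_spec(chains = 1), "2 chains")
  expect_error(mediation_spec(mediator = "x", outcome = "x"), "differ")
  expect_error(mediation_spec(covariates = c("age", "female")), "exposure")
})

test_that("age contrasts scale per-year effects correctly", {
  r <- age_contrast(c(total = -1.0, indirect = -0.5), years = 2)
  expect_equal(r$total_mmhg, 2)
  expect_equal(r$mediated_mmhg, 1)
  expect_equal(r$proportion, 0.5)
  r0 <- age_contrast(c(total = -1.0, indirect = -0.5), years = 0)
  expect_equal(r0$total_mmhg, 0)
  expect_true(is.na(r0$proportion))
  expect_error(age_contrast(c(total = -1, indirect = -0.5), years = -1),
               "non-negative")
})
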