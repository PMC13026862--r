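test_that("identical seed reproduces the dataset and CSV byte-for-byte", {
  cfg <- generator_config(n_participants = 22, seed = 42,
                          missing_item_rate = 0.1)
  t1 <- generate_trial(cfg)
  t2 <- generate_trial(cfg)
  expect_identical(t1, t2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trial(t1, f1); write_trial(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("per-participant streams are order-independent", {
  small <- generate_trial(generator_config(n_participants = 10, seed = 3))
  big <- generate_trial(generator_config(n_participants = 40, seed = 3))
  expect_equal(as.data.frame(small), as.data.frame(big[1:10, ]),
               ignore_attr = TRUE)
})

test_that("CSV round trip preserves fields and missing-item markers", {
  tr <- generate_trial(generator_config(n_participants = 22, seed = 7,
                                        missing_item_rate = 0.15))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path)
  back <- read_trial(path)
  expect_equal(as.data.frame(back), as.data.frame(tr)[, names(back)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(anyNA(back[, sprintf("csuq_%02d", 1:16)]))
})

test_that("malformed files are rejected with cell-level messages", {
  tr <- generate_trial(generator_config(n_participants = 5, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path)
  lines <- readLines(path)
  # corrupt participant 2's csuq_08 to an out-of-range 8
  hdr <- strsplit(lines[1], ",")[[1]]
  col <- which(hdr == "\"csuq_08\"")
  cells <- strsplit(lines[3], ",")[[1]]
  cells[col] <- "8"
  lines[3] <- paste(cells, collapse = ",")
  writeLines(lines, path)
  expect_error(read_trial(path), "row 2.*csuq_08")

  # empty cell becomes a missing item, not an error
  cells[col] <- ""
  lines[3] <- paste(cells, collapse = ",")
  writeLines(lines, path)
  back <- read_trial(path)
  expect_true(is.na(back$csuq_08[2]))

  # missing column is a header error
  writeLines(lines[-1], path)
  expect_error(read_trial(path), "header")
})

test_that("null structure: zero paths give zero association", {
  cfg <- generator_config(n_participants = 2000, seed = 5, path_a = 0,
                          path_b = 0, sigma_mediator = 0.2, sigma_outcome = 0.5)
  tr <- generate_trial(cfg)
  lat <- attr(tr, "latents")
  slope_m <- coef(lm(lat$M ~ tr$age))[2]
  expect_lt(abs(slope_m), 0.01)
  resid_c <- residuals(lm(sbp_change ~ age, data = tr))
  expect_lt(abs(cor(tr$age, resid_c)), 0.05)
})

test_that("OLS on the latent trace recovers the configured paths", {
  cfg <- generator_config(n_participants = 5000, seed = 11)
  tr <- generate_trial(cfg)
  lat <- attr(tr, "latents")
  fm <- summary(lm(lat$M ~ tr$age))$coefficients
  expect_lt(abs(fm["tr$age", "Estimate"] - 0.12), 3 * fm["tr$age", "Std. Error"])
  fy <- summary(lm(tr$sbp_change ~ lat$M + tr$age))$coefficients
  expect_lt(abs(fy["lat$M", "Estimate"] - (-1.35)), 3 * fy["lat$M", "Std. Error"])
  expect_lt(abs(fy["tr$age", "Estimate"] - (-0.28)),
            3 * fy["tr$age", "Std. Error"])
})

test_that("marginal moments match the configured population at scale", {
  tr <- generate_trial(generator_config(n_participants = 10000, seed = 2))
  expect_lt(abs(mean(tr$age) / 59 - 1), 0.02)
  expect_lt(abs(mean(tr$bmi_baseline) / 28.4 - 1), 0.02)
  expect_lt(abs(sd(tr$bmi_baseline) / 3.2 - 1), 0.02)
  expect_lt(abs(mean(tr$sbp_baseline) / 128.5 - 1), 0.02)
  expect_lt(abs(sd(tr$sbp_baseline) / 14.2 - 1), 0.02)
  expect_true(all(tr$age >= 45 & tr$age <= 74))
  expect_lt(abs(mean(tr$female) - 0.86), 0.02)
  expect_lt(abs(mean(tr$education == "primary") - 0.41), 0.02)
})

test_that("latent trace satisfies the structural equations exactly", {
  cfg <- generator_config(n_participants = 200, seed = 13,
                          covariate_effects = list(
                            mediator = c(female = 0.3),
                            outcome = c(education = -1.5)))
  tr <- generate_trial(cfg)
  lat <- attr(tr, "latents")
  ic <- structural_intercepts(cfg)
  edu_ord <- match(tr$education, c("primary", "secondary", "technical_bachelor"))
  m_pred <- ic["alpha_m"] + cfg$path_a * tr$age + 0.3 * tr$female + lat$eps_m
  expect_equal(lat$M, unname(m_pred), tolerance = 1e-12)
  y_pred <- ic["alpha_y"] + cfg$path_b * lat$M + cfg$path_c_prime * tr$age +
    (-1.5) * edu_ord + lat$eps_y
  expect_equal(tr$sbp_change, unname(y_pred), tolerance = 1e-12)
})

test_that("null calibration: a-hat is unbiased across seeds when a = 0", {
  est <- vapply(1:200, function(s) {
    tr <- generate_trial(generator_config(n_participants = 100, seed = s,
                                          path_a = 0))
    lat <- attr(tr, "latents")
    coef(lm(lat$M ~ tr$age))[[2]]
  }, 1.0)
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_participants = 0), "positive")
  expect_error(generator_config(education_probs = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(generator_config(female_prop = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(age_bounds = c(74, 45)), "increasing")
  expect_error(generator_config(sigma_mediator = 0), "positive")
  expect_error(generator_config(
    covariate_effects = list(mediator = c(bogus = 1), outcome = numeric(0))),
    "unknown covariate")
})
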