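# Shared fixtures and independent oracles.

# Continuous-mediator mediation dataset with exact structural ground truth
# (no Likert measurement layer); used for engine/sensitivity oracles.
make_mediation_data <- function(n, a = 0.12, b = -1.35, c_prime = -0.28,
                                sigma_m = 0.7, sigma_y = 9.5, seed = 1) {
  set.seed(seed)
  age <- runif(n, 45, 74)
  female <- rbinom(n, 1, 0.86)
  if (sum(female) < 2) female[1:2] <- 1
  if (sum(1 - female) < 2) female[1:2] <- 0
  education <- sample(1:3, n, replace = TRUE, prob = c(0.41, 0.23, 0.36))
  if (length(unique(education)) == 1) education[1] <- (education[1] %% 3) + 1
  sbp_baseline <- rnorm(n, 128.5, 14.2)
  m <- (5.65 - a * 59) + a * age + rnorm(n, 0, sigma_m)
  y <- (-4.6 - b * 5.65 - c_prime * 59) + b * m + c_prime * age +
    rnorm(n, 0, sigma_y)
  data.frame(id = sprintf("S%04d", seq_len(n)), age = age, female = female,
             education = education, sbp_baseline = sbp_baseline,
             interface_quality = m, sbp_change = y)
}

quick_spec <- function(seed = 1, chains = 2L, iterations = 1500L,
                       warmup = 500L, prior_set = default_prior_set()) {
  mediation_spec(prior_set = prior_set, chains = chains,
                 iterations = iterations, warmup = warmup, seed = seed)
}

# Brute-force Holm step-down oracle, straight from the definition.
holm_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_max <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running_max <- max(running_max, val)
    adj[ord[i]] <- running_max
  }
  adj
}

# Degenerate posterior_draws object with prescribed constant paths.
constant_draws <- function(a, b, c_prime, n = 2000) {
  df <- data.frame(chain = rep(1:2, each = n / 2), a = a, b = b,
                   c_prime = c_prime, alpha_m = 0, alpha_y = 0,
                   sigma_m = 1, sigma_y = 1,
                   indirect = a * b, direct = c_prime,
                   total = c_prime + a * b)
  class(df) <- c("posterior_draws", "data.frame")
  attr(df, "converged") <- TRUE
  df
}
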