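#' Configuration for the synthetic trial generator
#'
#' Builds the parameter set that [generate_trial()] uses to simulate a
#' participant-level mobile-health diabetes cohort with a known linear
#' mediation structure: age drives a latent interface-quality mediator
#' (path `a`), which together with a direct age path (`c'`) drives the
#' 90-day change in systolic blood pressure (path `b` per interface point).
#' Defaults reproduce the study conditions of the trial the package
#' analyses: n = 22, age 59 (SD 8.1) truncated to 45--74 years, 86% female,
#' education mix 41/23/36% (at most primary / secondary / technical or
#' bachelor), baseline clinical moments of the trial population, and a
#' CSUQ item structure with information-quality deficits for the
#' at-most-primary education stratum.
#'
#' @param n_participants number of participants to simulate.
#' @param seed master seed; per-participant streams are derived from it by
#'   counter so records do not depend on generation order.
#' @param age_mean,age_sd,age_bounds age distribution (years); sampled as a
#'   Normal truncated to `age_bounds` by rejection.
#' @param female_prop probability of female sex.
#' @param education_probs length-3 probabilities for education levels
#'   `primary`, `secondary`, `technical_bachelor`; must sum to 1.
#' @param path_a effect of age on the latent interface-quality mediator
#'   (points per year).
#' @param path_b effect of the mediator on systolic blood-pressure change
#'   (mmHg per interface point).
#' @param path_c_prime direct effect of age on systolic blood-pressure
#'   change (mmHg per year).
#' @param path_b_bmi,path_b_hba1c analogous mediator effects on the BMI and
#'   HbA1c changes (kg/m2 and percentage points per interface point).
#' @param covariate_effects named list with numeric named vectors
#'   `mediator` and `outcome`; coefficients of `female` and/or `education`
#'   (ordinal 1--3) entering the corresponding structural equation.
#'   Defaults to no covariate effects.
#' @param person_sd SD of a shared person-level usability factor added to
#'   every dimension latent (including the structural mediator, where it
#'   forms part of the mediator-equation residual). This induces the
#'   positive correlation between CSUQ dimensions that a single overall
#'   score with SD near 0.9 requires; 0 gives independent dimensions.
#' @param sigma_mediator idiosyncratic residual SD of the latent mediator
#'   (interface points); must be positive. The total mediator-equation
#'   residual SD is `sqrt(sigma_mediator^2 + person_sd^2)`.
#' @param sigma_outcome residual SD of the systolic change equation (mmHg);
#'   must be positive.
#' @param interface_mean target marginal mean of the latent mediator at the
#'   mean age; fixes the mediator intercept.
#' @param latent_means means of the latent system-quality,
#'   information-quality and satisfaction dimension scores (1--7 scale).
#' @param latent_sds SDs of those three latents.
#' @param item_noise_sd SD of the per-item noise added to each dimension
#'   latent before Likert discretisation.
#' @param item_education_deficits named numeric vector mapping CSUQ item
#'   index (as character) to a latent-scale shift applied to the
#'   at-most-primary education stratum before discretisation. Defaults
#'   emulate the study's information-quality deficits on items 7, 9, 11, 12.
#' @param baseline_means_sds named list `variable = c(mean, sd)` for
#'   baseline bmi, weight, sbp, dbp, hba1c.
#' @param change_means_sds named list `variable = c(mean, sd)` for the
#'   non-structural 90-day changes (bmi, weight, dbp, hba1c). The bmi and
#'   hba1c changes additionally receive their mediator effects; sbp change
#'   is fully structural and configured through the path coefficients.
#' @param married_prop,employed_prop marginal probabilities of being
#'   married / employed.
#' @param missing_item_rate probability that any CSUQ item is missing
#'   completely at random (default 0).
#'
#' @return A list of class `generator_config`.
#' @seealso [generate_trial()]
#' @export
generator_config <- function(n_participants = 22,
                             seed = 1L,
                             age_mean = 59,
                             age_sd = 8.1,
                             age_bounds = c(45, 74),
                             female_prop = 0.86,
                             education_probs = c(primary = 0.41,
                                                 secondary = 0.23,
                                                 technical_bachelor = 0.36),
                             path_a = 0.12,
                             path_b = -1.35,
                             path_c_prime = -0.28,
                             path_b_bmi = -0.15,
                             path_b_hba1c = -0.05,
                             covariate_effects = list(mediator = numeric(0),
                                                      outcome = numeric(0)),
                             person_sd = 0.75,
                             sigma_mediator = 0.7,
                             sigma_outcome = 9.5,
                             interface_mean = 5.65,
                             latent_means = c(system = 5.11,
                                              information = 5.30,
                                              satisfaction = 6.09),
                             latent_sds = c(system = 0.6,
                                            information = 0.5,
                                            satisfaction = 0.6),
                             item_noise_sd = 1.0,
                             item_education_deficits = c(`7` = -1.9,
                                                         `9` = -1.4,
                                                         `11` = -1.1,
                                                         `12` = -1.2),
                             baseline_means_sds = list(bmi = c(28.4, 3.2),
                                                       weight = c(71.2, 12.4),
                                                       sbp = c(128.5, 14.2),
                                                       dbp = c(78.3, 9.1),
                                                       hba1c = c(7.8, 0.9)),
                             change_means_sds = list(bmi = c(-0.47, 0.86),
                                                     weight = c(-1.53, 2.98),
                                                     dbp = c(-1.8, 7.9),
                                                     hba1c = c(-0.18, 0.64)),
                             married_prop = 0.59,
                             employed_prop = 0.59,
                             missing_item_rate = 0) {
  cfg <- list(n_participants = as.integer(n_participants), seed = as.integer(seed),
              age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
              female_prop = female_prop, education_probs = education_probs,
              path_a = path_a, path_b = path_b, path_c_prime = path_c_prime,
              path_b_bmi = path_b_bmi, path_b_hba1c = path_b_hba1c,
              covariate_effects = covariate_effects, person_sd = person_sd,
              sigma_mediator = sigma_mediator, sigma_outcome = sigma_outcome,
              interface_mean = interface_mean,
              latent_means = latent_means, latent_sds = latent_sds,
              item_noise_sd = item_noise_sd,
              item_education_deficits = item_education_deficits,
              baseline_means_sds = baseline_means_sds,
              change_means_sds = change_means_sds,
              married_prop = married_prop, employed_prop = employed_prop,
              missing_item_rate = missing_item_rate)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_participants < 1) stop("n_participants must be positive")
  if (abs(sum(cfg$education_probs) - 1) > 1e-9)
    stop("education_probs must sum to 1")
  probs <- c(cfg$female_prop, cfg$education_probs, cfg$missing_item_rate,
             cfg$married_prop, cfg$employed_prop)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$age_bounds[1] >= cfg$age_bounds[2])
    stop("age_bounds must be increasing")
  if (cfg$sigma_mediator <= 0 || cfg$sigma_outcome <= 0)
    stop("residual SDs must be positive")
  if (cfg$person_sd < 0) stop("person_sd must be non-negative")
  known <- c("female", "education")
  for (eq in c("mediator", "outcome")) {
    nm <- names(cfg$covariate_effects[[eq]])
    bad <- setdiff(nm, known)
    if (length(bad))
      stop("unknown covariate name(s) in covariate_effects$", eq, ": ",
           paste(bad, collapse = ", "))
  }
  dk <- names(cfg$item_education_deficits)
  if (length(dk) && any(!as.integer(dk) %in% 1:16))
    stop("item_education_deficits names must be item indices 1..16")
  invisible(cfg)
}

# Deterministic per-participant seed stream: a fixed affine map of the master
# seed and the participant counter, reduced mod a Mersenne prime so streams
# stay distinct and order-independent.
participant_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 99991) %% 2147483629)
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

# CSUQ dimension membership
csuq_dimension_items <- list(system = 1:6, information = 7:12,
                             interface = 13:15, satisfaction = 16L)

likert_discretize <- function(x) pmin(7L, pmax(1L, as.integer(round(x))))

#' Simulate a participant-level trial dataset
#'
#' Draws `n_participants` records under the structural model configured in
#' `config`. The latent interface-quality mediator is
#' `M = alpha_M + a * age + covariate terms + Normal(0, sigma_mediator)`;
#' the systolic change is
#' `dSBP = alpha_Y + b * M + c' * age + covariate terms +
#' Normal(0, sigma_outcome)`. CSUQ interface items (13--15) are `M` plus
#' item noise, rounded to the nearest integer and clamped to 1--7; the other
#' dimensions come from independent latents; information items receive the
#' configured education deficits for the at-most-primary stratum before
#' discretisation. Intercepts are fixed so that marginal means match the
#' configured targets at the mean age.
#'
#' The generator's internal latent trace (exact pre-noise mediator and
#' dimension latents per participant) is attached as attribute `"latents"`
#' so structural identities can be audited.
#'
#' @param config a [generator_config()] object.
#' @return A `data.frame` of class `trial_data`, one row per participant,
#'   with demographics, baseline and 90-day-change clinical values, 16 CSUQ
#'   item columns `csuq_01` ... `csuq_16`, and optional covariates
#'   (diabetes duration, comorbidity count, medication regimen).
#' @examples
#' trial <- generate_trial(generator_config(seed = 7))
#' dim(trial)
#' @export
generate_trial <- function(config) {
  validate_generator_config(config)
  n <- config$n_participants
  edu_levels <- c("primary", "secondary", "technical_bachelor")

  alpha_m <- config$interface_mean - config$path_a * config$age_mean
  # outcome intercept anchors the marginal dSBP mean at -4.6 mmHg (trial value)
  dsbp_mean <- -4.6
  alpha_y <- dsbp_mean - config$path_b * config$interface_mean -
    config$path_c_prime * config$age_mean

  cov_term <- function(eq, female, edu_ord) {
    ce <- config$covariate_effects[[eq]]
    out <- 0
    if ("female" %in% names(ce)) out <- out + ce[["female"]] * female
    if ("education" %in% names(ce)) out <- out + ce[["education"]] * edu_ord
    out
  }

  num_cols <- c("age", "female", "married", "employed",
                "bmi_baseline", "bmi_change", "weight_baseline", "weight_change",
                "sbp_baseline", "sbp_change", "dbp_baseline", "dbp_change",
                "hba1c_baseline", "hba1c_change", "diabetes_duration",
                "comorbidity_count")
  V <- matrix(NA_real_, n, length(num_cols), dimnames = list(NULL, num_cols))
  IT <- matrix(NA_integer_, n, 16)
  edu_vec <- character(n); reg_vec <- character(n)
  LAT <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("M", "S", "I", "O", "eps_m", "eps_y")))
  for (i in seq_len(n)) {
    set.seed(participant_seed(config$seed, i))
    age <- rtruncnorm1(config$age_mean, config$age_sd,
                       config$age_bounds[1], config$age_bounds[2])
    female <- as.integer(stats::runif(1) < config$female_prop)
    edu <- sample(edu_levels, 1, prob = config$education_probs)
    edu_ord <- match(edu, edu_levels)
    married <- as.integer(stats::runif(1) < config$married_prop)
    employed <- as.integer(stats::runif(1) < config$employed_prop)

    bl <- lapply(config$baseline_means_sds,
                 function(ms) stats::rnorm(1, ms[1], ms[2]))

    # shared person-level usability factor: part of the mediator-equation
    # residual, and common to every dimension latent
    u <- stats::rnorm(1, 0, config$person_sd)
    eps_m <- u + stats::rnorm(1, 0, config$sigma_mediator)
    M <- alpha_m + config$path_a * age + cov_term("mediator", female, edu_ord) +
      eps_m
    eps_y <- stats::rnorm(1, 0, config$sigma_outcome)
    dsbp <- alpha_y + config$path_b * M + config$path_c_prime * age +
      cov_term("outcome", female, edu_ord) + eps_y

    ch <- config$change_means_sds
    dbmi <- ch$bmi[1] + config$path_b_bmi * (M - config$interface_mean) +
      stats::rnorm(1, 0, ch$bmi[2])
    dhba1c <- ch$hba1c[1] + config$path_b_hba1c * (M - config$interface_mean) +
      stats::rnorm(1, 0, ch$hba1c[2])
    dweight <- stats::rnorm(1, ch$weight[1], ch$weight[2])
    ddbp <- stats::rnorm(1, ch$dbp[1], ch$dbp[2])

    S <- u + stats::rnorm(1, config$latent_means[["system"]],
                          config$latent_sds[["system"]])
    I <- u + stats::rnorm(1, config$latent_means[["information"]],
                          config$latent_sds[["information"]])
    O <- u + stats::rnorm(1, config$latent_means[["satisfaction"]],
                          config$latent_sds[["satisfaction"]])

    lat_by_item <- c(rep(S, 6), rep(I, 6), rep(M, 3), O)
    defs <- config$item_education_deficits
    if (edu == "primary" && length(defs)) {
      idx <- as.integer(names(defs))
      lat_by_item[idx] <- lat_by_item[idx] + as.numeric(defs)
    }
    items <- likert_discretize(lat_by_item +
                                 stats::rnorm(16, 0, config$item_noise_sd))
    if (config$missing_item_rate > 0) {
      gone <- stats::runif(16) < config$missing_item_rate
      items[gone] <- NA_integer_
    }

    dur <- max(1, round(stats::rnorm(1, 8, 4)))
    comorb <- stats::rpois(1, 1.2)
    regimen <- sample(c("oral_mono", "oral_dual", "oral_plus"), 1,
                      prob = c(0.5, 0.35, 0.15))

    V[i, ] <- c(age, female, married, employed,
                bl$bmi, dbmi, bl$weight, dweight, bl$sbp, dsbp,
                bl$dbp, ddbp, bl$hba1c, dhba1c, dur, comorb)
    IT[i, ] <- items
    edu_vec[i] <- edu
    reg_vec[i] <- regimen
    LAT[i, ] <- c(M, S, I, O, eps_m, eps_y)
  }
  ids <- sprintf("P%03d", seq_len(n))
  out <- data.frame(id = ids, V[, 1:4, drop = FALSE], education = edu_vec,
                    V[, 5:16, drop = FALSE], medication_regimen = reg_vec,
                    stringsAsFactors = FALSE)
  out$female <- as.integer(out$female)
  out$married <- as.integer(out$married)
  out$employed <- as.integer(out$employed)
  out$diabetes_duration <- as.integer(out$diabetes_duration)
  out$comorbidity_count <- as.integer(out$comorbidity_count)
  itdf <- as.data.frame(IT)
  names(itdf) <- sprintf("csuq_%02d", 1:16)
  out <- cbind(out, itdf)
  out <- out[, trial_columns()]
  attr(out, "latents") <- data.frame(id = ids, LAT)
  attr(out, "config") <- config
  class(out) <- c("trial_data", "data.frame")
  out
}

#' Structural intercepts implied by a generator configuration
#'
#' The generator anchors the mediator equation at the configured marginal
#' interface mean and the outcome equation at the trial's marginal systolic
#' change (-4.6 mmHg), both evaluated at the mean age. Returns the implied
#' intercepts so structural identities can be checked externally.
#'
#' @param config a [generator_config()] object.
#' @return Named numeric vector with `alpha_m` and `alpha_y`.
#' @export
structural_intercepts <- function(config) {
  alpha_m <- config$interface_mean - config$path_a * config$age_mean
  alpha_y <- -4.6 - config$path_b * config$interface_mean -
    config$path_c_prime * config$age_mean
  c(alpha_m = alpha_m, alpha_y = alpha_y)
}

trial_columns <- function() {
  c("id", "age", "female", "education", "married", "employed",
    "bmi_baseline", "bmi_change", "weight_baseline", "weight_change",
    "sbp_baseline", "sbp_change", "dbp_baseline", "dbp_change",
    "hba1c_baseline", "hba1c_change",
    "diabetes_duration", "comorbidity_count", "medication_regimen",
    sprintf("csuq_%02d", 1:16))
}

#' Write / read a trial dataset as CSV
#'
#' One row per participant, columns as documented in the package data
#' dictionary (`inst/extdata/data_dictionary.md`). Missing CSUQ items are
#' stored as empty cells. `read_trial()` validates the header and every
#' Likert cell, naming the offending row and column on failure.
#'
#' @param records a `trial_data` data.frame (or compatible data.frame).
#' @param path file path.
#' @return `write_trial()` returns `path` invisibly; `read_trial()` returns
#'   a `trial_data` data.frame.
#' @export
write_trial <- function(records, path) {
  missing_cols <- setdiff(trial_columns(), names(records))
  if (length(missing_cols))
    stop("records lack required columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(records[, trial_columns()], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", check.names = FALSE)
  missing_cols <- setdiff(trial_columns(), names(df))
  if (length(missing_cols))
    stop("malformed header; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (j in sprintf("csuq_%02d", 1:16)) {
    v <- df[[j]]
    bad <- which(!is.na(v) & (v %% 1 != 0 | v < 1 | v > 7))
    if (length(bad))
      stop(sprintf("Likert value out of range 1-7 at row %d, column %s (value %s)",
                   bad[1], j, v[bad[1]]))
    df[[j]] <- as.integer(v)
  }
  class(df) <- c("trial_data", "data.frame")
  df
}
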