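#' Cohen's d standardized mean difference
#'
#' Pooled variant: `(mean(x) - mean(y)) / s_pooled` with the
#' `(n - 1)`-weighted pooled SD; the Hedges variant multiplies by the
#' small-sample correction `J = 1 - 3 / (4 df - 1)`, `df = n1 + n2 - 2`.
#' A zero pooled SD is reported explicitly as `Inf`/`-Inf`/`NaN`, with a
#' warning, never silently.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param variant `"pooled"` or `"hedges"`.
#' @return Scalar effect size.
#' @export
cohens_d <- function(x, y, variant = c("pooled", "hedges")) {
  variant <- match.arg(variant)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  cohens_d_summary(mean(x), stats::sd(x), n1, mean(y), stats::sd(y), n2, variant)
}

#' @rdname cohens_d
#' @param m1,s1,n1,m2,s2,n2 group means, SDs and sizes (closed form from
#'   summary statistics, e.g. published tables).
#' @export
cohens_d_summary <- function(m1, s1, n1, m2, s2, n2,
                             variant = c("pooled", "hedges")) {
  variant <- match.arg(variant)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  if (sp == 0) {
    warning("zero pooled SD; effect size undefined/infinite")
    return((m1 - m2) / sp) # Inf, -Inf or NaN, stated explicitly
  }
  d <- (m1 - m2) / sp
  if (variant == "hedges") d <- d * (1 - 3 / (4 * df - 1))
  d
}

#' Bias-corrected and accelerated bootstrap confidence interval
#'
#' Nonparametric bootstrap of `statistic` over `n_boot` resamples (drawn
#' within `strata` when given), with the BCa adjustment: bias correction
#' `z0` from the proportion of replicates below the point estimate, and
#' acceleration from the jackknife skewness of the statistic. Forcing
#' `z0 = 0` and `accel = 0` reduces the interval exactly to the
#' percentile interval; `method = "bc"` applies bias correction only.
#' Degenerate data whose replicates all equal the point estimate collapse
#' to a zero-width interval at the statistic.
#'
#' @param data data frame or numeric vector to resample (rows).
#' @param statistic function of the resampled `data` returning a scalar.
#' @param n_boot number of bootstrap replicates (>= 1000).
#' @param seed integer seed; identical seeds give identical intervals.
#' @param level confidence level.
#' @param strata optional factor of length `nrow(data)`; resampling is
#'   done within strata.
#' @param z0,accel optional forced values for the bias correction and
#'   acceleration (testing/reduction modes).
#' @param method `"bca"`, `"bc"` (acceleration forced to 0) or
#'   `"percentile"` (both forced to 0).
#' @return List with `lower`, `upper`, `point`, `z0`, `accel`, `n_boot`.
#' @export
bca_bootstrap_ci <- function(data, statistic, n_boot = 10000L, seed = 1L,
                             level = 0.95, strata = NULL,
                             z0 = NULL, accel = NULL,
                             method = c("bca", "bc", "percentile")) {
  method <- match.arg(method)
  if (n_boot < 1000) stop("n_boot must be at least 1000")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  take <- function(d, idx) if (is.data.frame(d)) d[idx, , drop = FALSE] else d[idx]
  safe_stat <- function(d)
    tryCatch(as.numeric(statistic(d)), error = function(e) NA_real_)
  theta_hat <- statistic(data)
  if (!is.finite(theta_hat)) stop("statistic undefined on the original data")

  set.seed(seed)
  idx_pool <- if (is.null(strata)) NULL else split(seq_len(n), strata)
  reps <- vapply(seq_len(n_boot), function(i) {
    idx <- if (is.null(idx_pool)) sample.int(n, n, replace = TRUE)
      else unlist(lapply(idx_pool, function(s) sample(s, length(s), replace = TRUE)))
    safe_stat(take(data, idx))
  }, 1.0)
  bad <- sum(!is.finite(reps))
  if (bad > 0.01 * n_boot)
    stop("statistic undefined on ", bad, " of ", n_boot, " resamples")
  reps <- reps[is.finite(reps)]

  if (all(reps == theta_hat))
    return(list(lower = theta_hat, upper = theta_hat, point = theta_hat,
                z0 = 0, accel = 0, n_boot = n_boot))

  if (is.null(z0)) {
    if (method == "percentile") z0 <- 0
    else {
      prop <- mean(reps < theta_hat)
      if (prop == 0 || prop == 1)
        stop("bias correction undefined: all replicates on one side of the estimate")
      z0 <- stats::qnorm(prop)
    }
  }
  if (is.null(accel)) {
    if (method %in% c("percentile", "bc")) accel <- 0
    else {
      # acceleration from jackknife skewness; leave-one-out points where the
      # statistic is undefined (e.g. a group shrinking below its minimum n)
      # are dropped, falling back to accel = 0 if too few remain
      jack <- vapply(seq_len(n), function(i) safe_stat(take(data, -i)), 1.0)
      jack <- jack[is.finite(jack)]
      if (length(jack) < 2) {
        accel <- 0
      } else {
        jm <- mean(jack)
        num <- sum((jm - jack)^3)
        den <- 6 * (sum((jm - jack)^2))^1.5
        accel <- if (den == 0) 0 else num / den
      }
    }
  }
  alpha <- c((1 - level) / 2, 1 - (1 - level) / 2)
  zq <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - accel * (z0 + zq)))
  ci <- unname(stats::quantile(reps, adj, type = 6))
  list(lower = ci[1], upper = ci[2], point = theta_hat,
       z0 = z0, accel = accel, n_boot = n_boot)
}

#' Clinical outcomes stratified by usability level
#'
#' Splits participants into high / moderate / low usability strata from
#' their overall CSUQ scores and summarises each 90-day clinical change
#' per stratum (n, mean, SD), with a high-vs-low Cohen's d and BCa
#' bootstrap confidence interval per outcome. Strata with fewer than
#' `small_n` participants are flagged descriptive-only; an empty stratum
#' yields NA summaries with a warning.
#'
#' @param records trial data frame with the change columns.
#' @param scores data frame from [score_cohort()] (matched by `id`).
#' @param outcomes change columns to summarise.
#' @param n_boot,seed,level bootstrap settings (see [bca_bootstrap_ci()]).
#' @param variant Cohen's d variant.
#' @param small_n strata below this size are flagged.
#' @return List of class `stratum_outcome_table`: `summary` (stratum x
#'   outcome), `effects` (per outcome d and CI), `stratum_n`,
#'   `small_strata`.
#' @export
stratified_table <- function(records, scores,
                             outcomes = c("bmi_change", "weight_change",
                                          "sbp_change", "dbp_change",
                                          "hba1c_change"),
                             n_boot = 10000L, seed = 1L, level = 0.95,
                             variant = "pooled", small_n = 6L) {
  dat <- merge(records, scores[, c("id", "stratum")], by = "id")
  strata <- c("high", "moderate", "low")
  ns <- vapply(strata, function(s) sum(dat$stratum == s, na.rm = TRUE), 1L)
  if (any(ns == 0)) warning("empty usability stratum: ",
                            paste(strata[ns == 0], collapse = ", "))
  summ <- do.call(rbind, lapply(strata, function(s) {
    sub <- dat[dat$stratum == s & !is.na(dat$stratum), , drop = FALSE]
    do.call(rbind, lapply(outcomes, function(oc) {
      v <- sub[[oc]]
      data.frame(stratum = s, outcome = oc, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }))
  }))
  rownames(summ) <- NULL

  hi <- dat[dat$stratum == "high" & !is.na(dat$stratum), , drop = FALSE]
  lo <- dat[dat$stratum == "low" & !is.na(dat$stratum), , drop = FALSE]
  effects <- do.call(rbind, lapply(outcomes, function(oc) {
    if (nrow(hi) < 2 || nrow(lo) < 2)
      return(data.frame(outcome = oc, d = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, n_boot = n_boot))
    pool <- data.frame(value = c(hi[[oc]], lo[[oc]]),
                       grp = rep(c("high", "low"), c(nrow(hi), nrow(lo))))
    stat <- function(d) {
      g1 <- d$value[d$grp == "high"]; g2 <- d$value[d$grp == "low"]
      suppressWarnings(cohens_d(g1, g2, variant))
    }
    ci <- bca_bootstrap_ci(pool, stat, n_boot = n_boot, seed = seed,
                           level = level, strata = pool$grp)
    data.frame(outcome = oc, d = ci$point, ci_lower = ci$lower,
               ci_upper = ci$upper, n_boot = n_boot)
  }))
  rownames(effects) <- NULL
  out <- list(summary = summ, effects = effects,
              stratum_n = ns,
              small_strata = strata[ns < small_n & ns > 0])
  class(out) <- "stratum_outcome_table"
  out
}
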