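#' Independent two-sample t-test (closed form)
#'
#' Student variant pools the variances (`df = n1 + n2 - 2`); Welch uses
#' the Satterthwaite df. Computed by closed form so degenerate inputs are
#' handled per contract: zero variance in both groups with equal means
#' gives `t = 0, p = 1`; with unequal means the statistic is undefined and
#' an error is raised.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @param variant `"student"` or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
item_ttest <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) stop("each group needs at least 2 values")
  ttest_summary(mean(x), stats::sd(x), length(x),
                mean(y), stats::sd(y), length(y), variant)
}

#' @rdname item_ttest
#' @param m1,s1,n1,m2,s2,n2 group means, SDs and sizes (closed form from
#'   summary statistics, e.g. published tables).
#' @export
ttest_summary <- function(m1, s1, n1, m2, s2, n2,
                          variant = c("student", "welch")) {
  variant <- match.arg(variant)
  diff <- m1 - m2
  if (s1 == 0 && s2 == 0) {
    if (diff == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1, mean_diff = 0))
    stop("zero variance in both groups with unequal means: t undefined")
  }
  if (variant == "student") {
    df <- n1 + n2 - 2
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
    se <- sp * sqrt(1 / n1 + 1 / n2)
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tt <- diff / se
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), mean_diff = diff)
}

#' Holm step-down multiple-comparison adjustment
#'
#' Step-down familywise-error control: sort the p-values ascending,
#' multiply the i-th smallest by `(m - i + 1)`, enforce the running
#' maximum, cap at 1, and restore input order. Delegates to
#' `stats::p.adjust(method = "holm")` after validating the inputs.
#'
#' @param p numeric vector of raw p-values, each in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Item-level educational disparity table
#'
#' Compares each of the 16 CSUQ items between participants with at most
#' primary education and those with more than primary education
#' (secondary, technical or bachelor), using independent-samples t-tests
#' with Holm adjustment across the full 16-item family, plus Cohen's d per
#' item. A covariate-adjusted sensitivity analysis refits each item as an
#' ordinary least-squares model `item ~ education group + covariates`
#' (Holm re-applied) and is reported separately. Items where either
#' education stratum has fewer than 2 responses are flagged and excluded
#' from the Holm family with a warning.
#'
#' @param records trial data frame with `education` and `csuq_01..16`.
#' @param variant t-test variant (see [item_ttest()]).
#' @param adjust_covariates covariate columns for the sensitivity models
#'   (default age and baseline systolic BP).
#' @param d_variant Cohen's d variant.
#' @return List of class `item_disparity_table`: `items` (one row per
#'   testable item, sorted by absolute difference), `adjusted` (the
#'   covariate-adjusted sensitivity rows), `excluded_items`, `group_n`.
#' @export
disparity_table <- function(records, variant = "student",
                            adjust_covariates = c("age", "sbp_baseline"),
                            d_variant = "pooled") {
  g1_idx <- records$education == "primary"
  g2_idx <- !g1_idx
  if (!any(g1_idx) || !any(g2_idx))
    stop("both education strata must be non-empty")
  dims <- c(rep("system", 6), rep("information", 6), rep("interface", 3),
            "overall")
  rows <- list(); adj_rows <- list(); excluded <- integer(0)
  for (j in 1:16) {
    col <- sprintf("csuq_%02d", j)
    v1 <- records[[col]][g1_idx]; v1 <- v1[!is.na(v1)]
    v2 <- records[[col]][g2_idx]; v2 <- v2[!is.na(v2)]
    if (length(v1) < 2 || length(v2) < 2) {
      excluded <- c(excluded, j)
      next
    }
    tt <- item_ttest(v1, v2, variant)
    rows[[length(rows) + 1]] <- data.frame(
      item = j, dimension = dims[j],
      mean_leprimary = mean(v1), sd_leprimary = stats::sd(v1), n_leprimary = length(v1),
      mean_gtprimary = mean(v2), sd_gtprimary = stats::sd(v2), n_gtprimary = length(v2),
      difference = mean(v1) - mean(v2),
      t = tt$t, df = tt$df, p_raw = tt$p,
      d = suppressWarnings(cohens_d(v1, v2, d_variant)))
    # covariate-adjusted sensitivity (OLS per item)
    keep <- !is.na(records[[col]])
    dd <- data.frame(y = records[[col]][keep],
                     leprimary = as.integer(g1_idx[keep]))
    for (cv in adjust_covariates) dd[[cv]] <- records[[cv]][keep]
    fit <- stats::lm(y ~ ., data = dd)
    co <- summary(fit)$coefficients
    adj_rows[[length(adj_rows) + 1]] <- data.frame(
      item = j, estimate = co["leprimary", "Estimate"],
      se = co["leprimary", "Std. Error"],
      p_raw = co["leprimary", "Pr(>|t|)"])
  }
  if (length(excluded))
    warning("item(s) excluded from the Holm family (stratum n < 2): ",
            paste(excluded, collapse = ", "))
  items <- do.call(rbind, rows)
  items$p_holm <- holm_adjust(items$p_raw)
  items <- items[order(-abs(items$difference)), ]
  rownames(items) <- NULL
  adjusted <- do.call(rbind, adj_rows)
  adjusted$p_holm <- holm_adjust(adjusted$p_raw)
  rownames(adjusted) <- NULL
  out <- list(items = items, adjusted = adjusted,
              excluded_items = excluded,
              group_n = c(leprimary = sum(g1_idx), gtprimary = sum(g2_idx)))
  class(out) <- "item_disparity_table"
  out
}

#' Monte-Carlo power of a two-group item comparison
#'
#' Simulates `n_sim` pairs of Normal samples with unit SD and mean gap
#' `d`, applies the pooled two-sample t-test at level `alpha`, and
#' reports the rejection fraction with its Monte-Carlo standard error
#' `sqrt(p (1 - p) / n_sim)`.
#'
#' @param d true standardized mean difference.
#' @param n1,n2 group sizes.
#' @param alpha two-sided significance level in (0, 1).
#' @param n_sim number of simulated datasets (>= 1000).
#' @param seed integer seed.
#' @return List with `power`, `mc_se`, `n_sim`.
#' @export
power_simulation <- function(d, n1, n2, alpha = 0.05, n_sim = 10000L,
                             seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_sim < 1000) stop("n_sim must be at least 1000")
  set.seed(seed)
  x <- matrix(stats::rnorm(n1 * n_sim, mean = d), n1, n_sim)
  y <- matrix(stats::rnorm(n2 * n_sim, mean = 0), n2, n_sim)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- (colSums(x^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(y^2) - n2 * m2^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  crit <- stats::qt(1 - alpha / 2, df)
  p <- mean(abs(tt) > crit)
  list(power = p, mc_se = sqrt(p * (1 - p) / n_sim), n_sim = n_sim)
}
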