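#' Score one CSUQ questionnaire
#'
#' The 16-item Computer System Usability Questionnaire groups into system
#' quality (items 1--6), information quality (7--12), interface quality
#' (13--15) and overall satisfaction (item 16), each on a 1--7 Likert
#' scale. Dimension scores are means of constituent items; the overall
#' score is the mean of all 16 items. Missing items are handled by an
#' answered-item threshold: a dimension score is computed only when more
#' than half of its items are answered, the overall score only when at
#' least `min_overall_items` items are answered; otherwise the score is
#' `NA`.
#'
#' @param items numeric vector of length 16; each present value must be an
#'   integer in 1..7; `NA` marks a missing item.
#' @param min_dim_frac minimum answered fraction (exclusive) for a
#'   dimension score; default 0.5 means "more than half".
#' @param min_overall_items minimum answered items for the overall score.
#' @return A list of class `csuq_scores` with `system_quality`,
#'   `information_quality`, `interface_quality`, `overall_satisfaction`,
#'   `overall`, `n_answered`, and `stratum` (see [classify_stratum()]).
#' @examples
#' score_csuq(c(rep(5, 6), rep(4, 6), rep(6, 3), 7))
#' @export
score_csuq <- function(items, min_dim_frac = 0.5, min_overall_items = 12L) {
  if (length(items) != 16) stop("items must have length 16")
  present <- !is.na(items)
  if (!any(present)) stop("all 16 items missing; cannot score")
  vals <- items[present]
  if (any(vals %% 1 != 0 | vals < 1 | vals > 7))
    stop("CSUQ items must be integers in 1..7")

  dim_mean <- function(idx) {
    p <- present[idx]
    if (sum(p) <= min_dim_frac * length(idx)) return(NA_real_)
    mean(items[idx][p])
  }
  overall <- if (sum(present) >= min_overall_items) mean(items[present]) else NA_real_
  out <- list(system_quality = dim_mean(csuq_dimension_items$system),
              information_quality = dim_mean(csuq_dimension_items$information),
              interface_quality = dim_mean(csuq_dimension_items$interface),
              overall_satisfaction = dim_mean(csuq_dimension_items$satisfaction),
              overall = overall,
              n_answered = sum(present),
              stratum = if (is.na(overall)) NA_character_ else classify_stratum(overall))
  class(out) <- "csuq_scores"
  out
}

#' Classify an overall CSUQ score into a usability stratum
#'
#' High usability is an overall score of at least 6, low is below 5, and
#' moderate covers the half-open interval \[5, 6). The three predicates
#' partition \[1, 7\]; scores in (5.9, 6) — attainable as 16-item means —
#' are moderate.
#'
#' @param overall overall CSUQ score in \[1, 7\].
#' @return `"high"`, `"moderate"` or `"low"`.
#' @export
classify_stratum <- function(overall) {
  if (length(overall) != 1 || is.na(overall))
    stop("overall must be a single non-missing score")
  if (overall < 1 || overall > 7) stop("overall score outside [1, 7]")
  if (overall >= 6) "high" else if (overall < 5) "low" else "moderate"
}

#' Score every participant in a trial dataset
#'
#' @param records a `trial_data` data.frame with `csuq_01` ... `csuq_16`.
#' @inheritParams score_csuq
#' @return Data frame with one row per participant: `id`, the four
#'   dimension scores, `overall`, `n_answered`, `stratum`.
#' @export
score_cohort <- function(records, min_dim_frac = 0.5, min_overall_items = 12L) {
  it_cols <- sprintf("csuq_%02d", 1:16)
  if (!all(it_cols %in% names(records)))
    stop("records lack CSUQ item columns csuq_01..csuq_16")
  res <- lapply(seq_len(nrow(records)), function(i) {
    s <- score_csuq(as.numeric(records[i, it_cols]),
                    min_dim_frac = min_dim_frac,
                    min_overall_items = min_overall_items)
    data.frame(id = records$id[i],
               system_quality = s$system_quality,
               information_quality = s$information_quality,
               interface_quality = s$interface_quality,
               overall_satisfaction = s$overall_satisfaction,
               overall = s$overall, n_answered = s$n_answered,
               stratum = ifelse(is.null(s$stratum), NA_character_, s$stratum),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Paired comparison of two CSUQ dimension scores
#'
#' Paired t-test on per-participant differences `dim1 - dim2` computed by
#' closed form (`t = mean(d) / (sd(d) / sqrt(n))`, df = n - 1, two-sided p
#' from the Student t distribution). Participants missing either dimension
#' are dropped. When the differences have zero variance the statistic is
#' reported explicitly: `t = 0, p = 1` if the mean difference is zero,
#' infinite `t` with `p = 0` otherwise.
#'
#' @param scores data frame from [score_cohort()].
#' @param dim1,dim2 column names of the two dimensions to compare.
#' @return List with `mean_diff`, `sd_diff`, `t`, `df`, `p`, `n`.
#' @export
compare_dimensions <- function(scores, dim1 = "interface_quality",
                               dim2 = "information_quality") {
  if (!all(c(dim1, dim2) %in% names(scores)))
    stop("dimension columns not found in scores")
  d <- scores[[dim1]] - scores[[dim2]]
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2) stop("need at least 2 participants with both dimensions present")
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    tt <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    tt <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tt), df = n - 1)
  }
  list(mean_diff = m, sd_diff = s, t = tt, df = n - 1, p = p, n = n)
}
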