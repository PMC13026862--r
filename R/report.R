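fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
fmt_pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.0f%%", 100 * x))

#' Pipeline run configuration
#'
#' Exactly one input source: a [generator_config()] for a synthetic
#' cohort, or a participant CSV path readable by [read_trial()]. A seed
#' is mandatory because every stage past scoring is stochastic.
#'
#' @param synthetic optional [generator_config()].
#' @param csv optional path to a participant CSV.
#' @param analyses character subset of
#'   `c("mediation", "stratify", "equity", "sensitivity")`; scoring always
#'   runs.
#' @param priors `"default"`, `"weakened"`, `"skeptical"`, or a YAML path.
#' @param profile MCMC profile, `"test"` or `"paper"`.
#' @param n_boot bootstrap replicates for the stratified analysis.
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @return List of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, csv = NULL,
                       analyses = c("mediation", "stratify", "equity",
                                    "sensitivity"),
                       priors = "default", profile = "test",
                       n_boot = 2000L, seed = 1L, out_dir = tempfile("usabmed_")) {
  if (is.null(synthetic) == is.null(csv))
    stop("exactly one input source: synthetic config or csv path")
  if (is.null(seed)) stop("seed is mandatory")
  bad <- setdiff(analyses, c("mediation", "stratify", "equity", "sensitivity"))
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  structure(list(synthetic = synthetic, csv = csv, analyses = analyses,
                 priors = priors, profile = profile, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

resolve_prior_set <- function(priors) {
  if (inherits(priors, "prior_set")) return(priors)
  switch(priors,
         default = default_prior_set(),
         weakened = weakened_prior_set(),
         skeptical = skeptical_prior_set(),
         read_prior_set(priors))
}

#' Run the full analysis pipeline
#'
#' Generate or ingest the cohort, score the CSUQ, then (per the enabled
#' analyses) fit the Bayesian mediation model, stratify clinical outcomes
#' by usability, run the item-level educational-disparity analysis, and
#' the sensitivity suite. Writes, under `config$out_dir`: the cohort CSV
#' (synthetic input only), a scores CSV, paper-style text tables, a
#' machine-readable `estimates.json` with full-precision estimates, the
#' retained posterior draws as a plain-text table, and a run log with
#' stage seeds. Output is deterministic given the seed. Any stage failure
#' aborts with the stage name and removes partial outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, the list of in-memory results (`records`, `scores`,
#'   `mediation`, `stratified`, `equity`, `sensitivity`, `estimates`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- character(0)
  log_stage <- function(stage, what) {
    log_lines <<- c(log_lines, sprintf("%s %s (seed %d)", stage, what, config$seed))
    writeLines(log_lines, log_path)
  }
  written <- character(0)
  emit <- function(name) {
    written <<- c(written, file.path(config$out_dir, name))
    file.path(config$out_dir, name)
  }
  stage <- "input"
  res <- list()
  tryCatch({
    log_stage(stage, "start")
    if (!is.null(config$synthetic)) {
      cfg <- config$synthetic
      cfg$seed <- config$seed
      res$records <- generate_trial(cfg)
      write_trial(res$records, emit("trial.csv"))
    } else {
      res$records <- read_trial(config$csv)
    }
    log_stage(stage, "end")

    stage <- "score"
    log_stage(stage, "start")
    res$scores <- score_cohort(res$records)
    utils::write.csv(res$scores, emit("scores.csv"), row.names = FALSE)
    writeLines(render_table(res, "t1"), emit("table1.txt"))
    log_stage(stage, "end")

    prior_set <- resolve_prior_set(config$priors)
    prof <- mcmc_profile(config$profile)
    merged <- merge(res$records,
                    res$scores[, c("id", "system_quality", "information_quality",
                                   "interface_quality", "overall")],
                    by = "id")

    if ("mediation" %in% config$analyses) {
      stage <- "mediation"
      log_stage(stage, "start")
      spec <- mediation_spec(prior_set = prior_set, chains = prof$chains,
                             iterations = prof$iterations, warmup = prof$warmup,
                             seed = config$seed)
      draws <- sample_posterior(spec, merged)
      res$mediation <- summarize_mediation(draws)
      utils::write.table(draws, emit("draws.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      writeLines(render_table(res, "t2"), emit("table2.txt"))
      log_stage(stage, "end")
    }
    if ("stratify" %in% config$analyses) {
      stage <- "stratify"
      log_stage(stage, "start")
      res$stratified <- stratified_table(res$records, res$scores,
                                         n_boot = config$n_boot,
                                         seed = config$seed)
      writeLines(render_table(res, "t3"), emit("table3.txt"))
      log_stage(stage, "end")
    }
    if ("equity" %in% config$analyses) {
      stage <- "equity"
      log_stage(stage, "start")
      res$equity <- disparity_table(res$records)
      utils::write.csv(res$equity$items, emit("table4_full.csv"),
                       row.names = FALSE)
      writeLines(render_table(res, "t4"), emit("table4.txt"))
      log_stage(stage, "end")
    }
    if ("sensitivity" %in% config$analyses) {
      stage <- "sensitivity"
      log_stage(stage, "start")
      spec <- mediation_spec(prior_set = prior_set, chains = prof$chains,
                             iterations = prof$iterations, warmup = prof$warmup,
                             seed = config$seed)
      res$sensitivity <- list(priors = prior_sensitivity(merged, spec),
                              loo = loo_influence(merged, spec, method = "ml"))
      jsonlite::write_json(
        list(priors = res$sensitivity$priors$rows,
             width_ratio = res$sensitivity$priors$width_ratio_default_vs_ml,
             loo_max_abs_deviation = res$sensitivity$loo$max_abs_deviation),
        emit("sensitivity.json"), auto_unbox = TRUE, digits = NA, na = "null")
      log_stage(stage, "end")
    }

    stage <- "estimates"
    log_stage(stage, "start")
    res$estimates <- collect_estimates(res)
    jsonlite::write_json(res$estimates, emit("estimates.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    log_stage(stage, "end")
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

collect_estimates <- function(res) {
  out <- list(n = nrow(res$records),
              scores = list(
                overall = mean(res$scores$overall, na.rm = TRUE),
                system = mean(res$scores$system_quality, na.rm = TRUE),
                information = mean(res$scores$information_quality, na.rm = TRUE),
                interface = mean(res$scores$interface_quality, na.rm = TRUE),
                satisfaction = mean(res$scores$overall_satisfaction, na.rm = TRUE)))
  if (!is.null(res$mediation)) {
    eff <- res$mediation$effects
    out$mediation <- stats::setNames(
      lapply(seq_len(nrow(eff)), function(i)
        list(mean = eff$mean[i], cri_lower = eff$cri_lower[i],
             cri_upper = eff$cri_upper[i], p_negative = eff$p_negative[i])),
      eff$effect)
    out$mediation$proportion_mediated <- res$mediation$proportion_mediated
  }
  if (!is.null(res$stratified)) {
    out$stratified <- list(summary = res$stratified$summary,
                           effects = res$stratified$effects)
  }
  if (!is.null(res$equity)) {
    it <- res$equity$items
    out$equity <- it[, c("item", "difference", "p_raw", "p_holm", "d")]
  }
  out
}

#' Render a paper-style text table
#'
#' Templates `t1` (cohort characteristics), `t2` (mediation posterior
#' summaries; header `Effect, Posterior Mean (β), 95% CrI,
#' P(β < 0)`), `t3` (outcomes by usability stratum), `t4` (item-level
#' educational disparities). Scores and effects print with 2 decimals;
#' proportions as whole percents. Missing estimates render as `NA` with a
#' warning.
#'
#' @param estimates pipeline results list (as built by [run_pipeline()]),
#'   needing `scores`/`mediation`/`stratified`/`equity` depending on the
#'   template.
#' @param template one of `"t1"`, `"t2"`, `"t3"`, `"t4"`.
#' @return Character vector of text lines.
#' @export
render_table <- function(estimates, template = c("t1", "t2", "t3", "t4")) {
  template <- match.arg(template)
  switch(template,
         t1 = render_t1(estimates),
         t2 = render_t2(estimates$mediation),
         t3 = render_t3(estimates$stratified),
         t4 = render_t4(estimates$equity))
}

render_t1 <- function(res) {
  r <- res$records; s <- res$scores
  if (is.null(r) || is.null(s)) {
    warning("missing estimates for template t1")
    return("Characteristic, Value\nNA, NA")
  }
  msd <- function(v) sprintf("%s (%s)", fmt2(mean(v, na.rm = TRUE)),
                             fmt2(stats::sd(v, na.rm = TRUE)))
  c("Characteristic, n (%) or Mean (SD)",
    sprintf("Age (years), %s", msd(r$age)),
    sprintf("Female sex, %d (%s)", sum(r$female), fmt_pct(mean(r$female))),
    sprintf("Primary only, %d (%s)", sum(r$education == "primary"),
            fmt_pct(mean(r$education == "primary"))),
    sprintf("Secondary, %d (%s)", sum(r$education == "secondary"),
            fmt_pct(mean(r$education == "secondary"))),
    sprintf("Technical/Bachelor's, %d (%s)",
            sum(r$education == "technical_bachelor"),
            fmt_pct(mean(r$education == "technical_bachelor"))),
    sprintf("HbA1c (%%), %s", msd(r$hba1c_baseline)),
    sprintf("Body mass index (kg/m2), %s", msd(r$bmi_baseline)),
    sprintf("Systolic BP (mmHg), %s", msd(r$sbp_baseline)),
    sprintf("dBMI (kg/m2), %s", msd(r$bmi_change)),
    sprintf("dSystolic BP (mmHg), %s", msd(r$sbp_change)),
    sprintf("dHbA1c (%%), %s", msd(r$hba1c_change)),
    sprintf("Overall usability, %s", msd(s$overall)),
    sprintf("System quality, %s", msd(s$system_quality)),
    sprintf("Information quality, %s", msd(s$information_quality)),
    sprintf("Interface quality, %s", msd(s$interface_quality)),
    sprintf("Overall satisfaction (item 16), %s", msd(s$overall_satisfaction)))
}

render_t2 <- function(sm) {
  header <- "Effect, Posterior Mean (β), 95% CrI, P(β < 0)"
  if (is.null(sm)) {
    warning("missing estimates for template t2")
    return(c(header, "NA, NA, NA, NA"))
  }
  eff <- sm$effects
  row <- function(label, nm, dir = "neg") {
    e <- eff[eff$effect == nm, ]
    pv <- if (dir == "neg") fmt2(e$p_negative) else "-"
    sprintf("%s, %s, %s to %s, %s", label, fmt2(e$mean),
            fmt2(e$cri_lower), fmt2(e$cri_upper), pv)
  }
  pm <- sm$proportion_mediated
  c(header,
    row("Path a: Age -> Interface quality (points/year)", "a", dir = "pos"),
    row("Path b: Interface quality -> Systolic BP (mmHg/point)", "b"),
    row("Indirect effect (a x b) (mmHg/year)", "indirect"),
    row("Direct effect (mmHg/year)", "direct"),
    row("Total effect (mmHg/year)", "total"),
    sprintf("Proportion mediated (%%), %s, %s to %s, -",
            fmt_pct(pm$point), fmt_pct(pm$cri_lower), fmt_pct(pm$cri_upper)))
}

render_t3 <- function(st) {
  header <- "Outcome, High Usability (>=6), Moderate (5-5.9), Low Usability (<5), Effect Size (High vs. Low)"
  if (is.null(st)) {
    warning("missing estimates for template t3")
    return(c(header, "NA, NA, NA, NA, NA"))
  }
  sm <- st$summary; ef <- st$effects
  cell <- function(oc, s) {
    z <- sm[sm$outcome == oc & sm$stratum == s, ]
    sprintf("%s (%s)", fmt2(z$mean), fmt2(z$sd))
  }
  lines <- vapply(unique(sm$outcome), function(oc) {
    d <- ef$d[ef$outcome == oc]
    sprintf("%s, %s, %s, %s, d = %s", oc, cell(oc, "high"),
            cell(oc, "moderate"), cell(oc, "low"), fmt2(d))
  }, "")
  c(header, unname(lines))
}

render_t4 <- function(eq) {
  header <- "Item, Dimension, <=Primary M (SD), >Primary M (SD), Diff., p (Adj)"
  if (is.null(eq)) {
    warning("missing estimates for template t4")
    return(c(header, "NA, NA, NA, NA, NA, NA"))
  }
  it <- eq$items
  lines <- vapply(seq_len(nrow(it)), function(i)
    sprintf("%d, %s, %s (%s), %s (%s), %s, %s",
            it$item[i], it$dimension[i],
            fmt2(it$mean_leprimary[i]), fmt2(it$sd_leprimary[i]),
            fmt2(it$mean_gtprimary[i]), fmt2(it$sd_gtprimary[i]),
            fmt2(it$difference[i]), fmt2(it$p_holm[i])), "")
  c(header, lines)
}
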