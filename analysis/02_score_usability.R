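#!/usr/bin/env Rscript
# Score the CSUQ for every participant, summarise the cohort in a Table-1
# style block, and compare the interface- and information-quality dimensions
# with a paired t-test.

suppressPackageStartupMessages(library(usabmed))

cohort <- read_trial("results/trial.csv")
scores <- score_cohort(cohort)
write.csv(scores, "results/scores.csv", row.names = FALSE)

writeLines(render_table(list(records = cohort, scores = scores), "t1"),
           "results/table1.txt")
cat("Wrote results/scores.csv and results/table1.txt\n")
cat(sprintf("Overall usability %.2f (SD %.2f); strata: %s\n",
            mean(scores$overall), sd(scores$overall),
            paste(names(table(scores$stratum)), table(scores$stratum),
                  collapse = ", ", sep = "=")))

cmp <- compare_dimensions(scores, "interface_quality", "information_quality")
cat(sprintf("Interface - information gap: %.2f points (t = %.2f, df = %d, p = %.3f)\n",
            cmp$mean_diff, cmp$t, cmp$df, cmp$p))
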