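#!/usr/bin/env Rscript
# Stage 3: descriptive marriage-age summaries, overall and per covariate
# group (full-sample denominators, ages over observed marriages only).

library(frailtyLL)

schema <- default_marriage_schema()
data <- read_marriage_data("results/dataset.csv", schema = schema)

ov <- overall_summary(data)
cat(sprintf("%d of %d women married (%.2f%%)\n", ov$n_married, ov$n_total,
            ov$pct_married))
cat(sprintf("marriage age: mean %.1f, median %.1f, min %.1f, max %.1f years\n",
            ov$mean_age, ov$median_age, ov$min_age, ov$max_age))

desc <- rbind(
  describe_by_group(data, "cluster"),
  do.call(rbind, lapply(names(schema), function(nm)
    describe_by_group(data, nm))))
write.csv(desc, "results/descriptives.csv", row.names = FALSE)

res <- describe_by_group(data, "residence")
cat(sprintf("\nrural: %.2f%% of sample married; urban: %.2f%%\n",
            res$pct_married_of_total[res$group == "rural"],
            res$pct_married_of_total[res$group == "urban"]))
cat(sprintf("median marriage age: rural %.1f, urban %.1f years\n",
            res$median_age[res$group == "rural"],
            res$median_age[res$group == "urban"]))
cat("wrote results/descriptives.csv\n")
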