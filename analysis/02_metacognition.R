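#!/usr/bin/env Rscript
# Stage 2: behavioural metacognition metrics.
#
# For every included subject: response-conditional AUROC2 for the four
# responses and meta-d'/d' per task, followed by the group-level yes-vs-no
# comparison of metacognitive sensitivity. Reads stage-1 output; writes
# results/analysis/auroc2.csv and meta_d.csv.

suppressPackageStartupMessages(library(metadetect))

out_dir <- "results/analysis"
trials <- read_trials(file.path(out_dir, "trials.csv"))
excl <- read.csv(file.path(out_dir, "exclusions.csv"))
included <- excl$subject[excl$included]

rows_a <- rows_m <- list()
for (s in included) {
  st <- trials[trials$subject == s, ]
  a <- auroc2_from_trials(st)
  a$subject <- s
  rows_a[[s]] <- a
  for (task in c("detection", "discrimination")) {
    fit <- meta_dprime(response_confidence_counts(st[st$task == task, ], task))
    rows_m[[paste(s, task)]] <- data.frame(
      subject = s, task = task, dprime = fit$dprime, meta_d = fit$meta_d,
      m_ratio = fit$m_ratio)
  }
}
auroc <- do.call(rbind, rows_a)
metad <- do.call(rbind, rows_m)
write.csv(auroc, file.path(out_dir, "auroc2.csv"), row.names = FALSE)
write.csv(metad, file.path(out_dir, "meta_d.csv"), row.names = FALSE)

wide <- reshape(auroc, idvar = "subject", timevar = "response",
                direction = "wide")
dyn <- wide$auroc2.yes - wide$auroc2.no
tt <- t.test(dyn)
cat(sprintf("mean AUROC2 yes / no      : %.3f / %.3f\n",
            mean(wide$auroc2.yes), mean(wide$auroc2.no)))
cat(sprintf("yes - no t(%d) = %.2f, p = %.2g, BF01 = %.2f\n",
            tt$parameter, tt$statistic, tt$p.value,
            jzs_bayes_factor(unname(tt$statistic), nrow(wide))))
cat(sprintf("mean m-ratio detection    : %.3f\n",
            mean(metad$m_ratio[metad$task == "detection"])))
cat(sprintf("mean m-ratio discrimination: %.3f\n",
            mean(metad$m_ratio[metad$task == "discrimination"])))
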