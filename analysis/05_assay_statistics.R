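#!/usr/bin/env Rscript
# Assay statistics on the simulated plates plus the closed-form metrics:
# single-hit clonogenic frequencies with 95% CI, the likelihood-ratio
# comparison between the two populations, and worked examples of the
# tumor-volume, fold-change, viability, and 2^-ddCt copy-number formulas.

suppressMessages(library(cupsig))

sim <- "results/sim"
high <- read.csv(file.path(sim, "lda_high.csv"))
low <- read.csv(file.path(sim, "lda_low.csv"))

fh <- lda_frequency(high)
fl <- lda_frequency(low)
cat(sprintf("high population: %.2f%% clonogenic (95%% CI %.2f-%.2f%%), 1 in %.0f\n",
            fh$percent, 100 * fh$lower, 100 * fh$upper, fh$one_in))
cat(sprintf("low population:  %.2f%% clonogenic (95%% CI %.2f-%.2f%%), 1 in %.0f\n",
            fl$percent, 100 * fl$lower, 100 * fl$upper, fl$one_in))
cmp <- compare_frequencies(high, low)
cat(sprintf("frequency difference: chi-square(1) = %.2f, p = %.3g\n",
            cmp$statistic, cmp$p))

vol <- tumor_volume(10, 20)
fc <- fold_change_series(c(150, 300, 600))
viab <- viability_fold_change(rep(5, 6), rep(10, 6))
cnv <- cnv_call(26, 25, 25, 25)
cat(sprintf("tumor volume d=10, D=20: %.0f mm^3; growth fold changes: %s\n",
            vol, paste(fc, collapse = ", ")))
cat(sprintf("treated/control viability: %.2f\n", viab))
cat(sprintf("copy-number ratio 2^-ddCt (one extra target cycle): %.2f -> %s\n",
            cnv$ratio, cnv$call))

write.csv(data.frame(population = c("high", "low"),
                     frequency = c(fh$frequency, fl$frequency),
                     lower = c(fh$lower, fl$lower),
                     upper = c(fh$upper, fl$upper),
                     one_in = c(fh$one_in, fl$one_in)),
          "results/lda_frequencies.csv", row.names = FALSE)
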