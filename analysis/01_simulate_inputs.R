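#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a 300-line training panel and a
# 100-line held-out panel sharing the same 100 planted resistance markers
# (log2 effect 1.0 per unit latent score, noise sd 0.5, AUC slope 1.0),
# plus limiting-dilution plates for two cell populations. Everything
# downstream reads the files written here.

suppressMessages(library(cupsig))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 11

train <- simulate_ccl_panel(n_lines = 300, n_genes = 2000, n_markers = 100,
                            beta = 1.0, gamma = 1.0, noise_sd = 0.5,
                            seed = seed)
write_count_matrix(train$counts, file.path(out, "train_counts.tsv"))
write.csv(train$resp, file.path(out, "train_auc.csv"), row.names = FALSE)
writeLines(train$truth$markers, file.path(out, "true_markers.txt"))

held <- simulate_ccl_panel(n_lines = 100, n_genes = 2000,
                           markers = train$truth$markers,
                           beta = 1.0, gamma = 1.0, noise_sd = 0.5,
                           seed = seed + 1)
write_count_matrix(held$counts, file.path(out, "heldout_counts.tsv"))
# held-out truth labels use an IC50-style readout derived from the latent
# response: sensitive lines sit below 1 uM
ic50 <- data.frame(cell_line = held$resp$cell_line,
                   ic50_um = 2^(held$resp$auc - median(held$resp$auc)))
write.csv(ic50, file.path(out, "heldout_ic50.csv"), row.names = FALSE)
write.csv(held$resp, file.path(out, "heldout_auc.csv"), row.names = FALSE)

plates <- list(high = simulate_lda(0.10, doses = c(1, 10, 100),
                                   wells_per_dose = 24, seed = seed + 2),
               low = simulate_lda(0.01, doses = c(10, 100, 1000),
                                  wells_per_dose = 24, seed = seed + 3))
for (nm in names(plates))
  write.csv(plates[[nm]], file.path(out, sprintf("lda_%s.csv", nm)),
            row.names = FALSE)

cat(sprintf("wrote training panel (%d x %d), held-out panel (%d x %d), 2 LDA plates to %s\n",
            nrow(train$counts), ncol(train$counts),
            nrow(held$counts), ncol(held$counts), out))
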