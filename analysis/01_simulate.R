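#!/usr/bin/env Rscript

## Step 1 — simulate the synthetic national register.
##
## Generates the admissions extract (1998-2019, with a 1987-1997 lookback
## of earlier injury admissions), the population and projected-population
## tables, per-admission ground-truth labels, and the death register.
## Everything downstream reads the CSVs written here.

suppressMessages(library(fractrace))

cfg <- cohort_config(seed = 20240106, scale = 0.1)
pop <- generate_population(cfg)
reg <- generate_admissions(cfg, pop$observed)

dir.create("results/register", showWarnings = FALSE, recursive = TRUE)
write_register(reg, pop, "results/register")

cat(sprintf(
  "simulated %d study admissions for %d fracture patients (+%d lookback rows)\n",
  nrow(reg$admissions), nrow(reg$deaths), nrow(reg$lookback)
))
tab <- table(reg$truth$true_class)
cat(sprintf(
  "ground truth: %d incident, %d transfer, %d readmission admissions\n",
  tab[["incident"]], tab[["transfer"]], tab[["readmission"]]
))
cat("tables written under results/register/\n")
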