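#!/usr/bin/env Rscript

## Step 5 — project annual fracture counts 2020-2050 under the three
## scenarios: the observed average annual percent change continues; rates
## freeze at the 2019 level; or the decline continues through 2029 and
## then stops.

suppressMessages({
  library(fractrace)
  library(data.table)
})

counts <- fread("results/stratified_counts.csv",
  colClasses = list(character = c("sex", "age_band"))
)
proj_pop <- read_population("results/register/projected_population.csv")

aapc <- estimate_aapc(counts)
cat("estimated average annual percent change by stratum (in %):\n")
print(aapc[, .(sex, age_band, aapc_pct = round(100 * aapc, 2), pooled)])

projections <- rbindlist(lapply(
  c("continued_decline", "constant_rates", "decline_then_constant"),
  function(sc) {
    project_counts(counts, proj_pop, sc,
      horizon_year = 2050,
      aapc = aapc, base_year = 2019, breakpoint_year = 2029
    )
  }
))

for (y in c(2034, 2050)) {
  p <- projections[sex == "All" & year == y]
  cat(sprintf(
    "%d: %.0f fractures if the decline continues, %.0f with constant rates, %.0f in between\n",
    y,
    p[scenario == "continued_decline", projected_count],
    p[scenario == "constant_rates", projected_count],
    p[scenario == "decline_then_constant", projected_count]
  ))
}

fwrite(aapc, "results/aapc.csv")
fwrite(projections, "results/projections.csv")
cat("wrote results/aapc.csv, projections.csv\n")
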