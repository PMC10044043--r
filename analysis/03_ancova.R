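#!/usr/bin/env Rscript
# Fixed-effects ANCOVA layer per trait: Type III tables, goodness of fit
# and standardized-residual flagging, in the layouts of the published
# evaluation tables.
#
# Reads:  results/herd/
# Writes: results/ancova/{type_iii,model_table,goodness_of_fit,
#         residual_flags}.tsv

library(caprigen)

herd <- read_herd("results/herd")
traits <- c("stature", "chest_width", "rump_width", "mobility")

res <- run_ancova(herd$records, traits, spec_for = function(tr)
  model_spec(tr,
             factors = c("farm", "lactation_stage", "kidding_month"),
             interactions = list(c("farm", "kidding_year")),
             covariates = c(dim = 1, age = 2)))

emit_reports(res, NULL, NULL, "results/ancova")

cat("Whole-model F tests (per trait):\n")
print(res$model_table[, c("trait", "df", "statistic", "error_df", "rms")],
      row.names = FALSE)
cat("\nGoodness of fit:\n")
print(res$fit_table, row.names = FALSE)
cat("\nResidual rule (<= 5% outside +/-1.96):\n")
print(res$residual_table, row.names = FALSE)
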