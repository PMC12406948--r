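#!/usr/bin/env Rscript
# Synthetic organ-panel biodistribution study.
#
# Runs the full pipeline on the default design: PBS and tracer-injected
# groups across six organs (eight specimens per cell), dietary magnetic
# contamination in intestinal tissue, instrument noise at the documented
# background level. All outputs land under results/study/.

suppressPackageStartupMessages(library(mpsquant))

rc <- run_config(seed = 1)
res <- run_pipeline(rc, out_dir = "results/study", force = TRUE)

records <- res$records
message("\nlabel counts by treatment:")
print(table(records$label, records$treatment))

q <- records[records$label == "target_MNP" & records$truth_fe_kg > 0, ]
err <- abs(q$fe_mass_kg - q$truth_fe_kg) / q$truth_fe_kg
message(sprintf(paste0("\nquantified tracer records: n = %d, median |error| ",
                       "= %.1f%%, max = %.1f%%"),
                nrow(q), 100 * median(err), 100 * max(err)))
message("Contamination concentrates in intestinal organs; liver and spleen ",
        "carry the bulk of the injected dose and are never excluded.")
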