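#!/usr/bin/env Rscript
# Compute decadal growth rates for linked pairs and run the QC cascade:
# keep growth >= -5 in, keep 1 <= starting DBH <= 40 in, then trim 5% from
# each growth tail within every 1-inch starting-DBH bin.

library(streetgrowth)

pairs <- readr::read_csv("results/pairs.csv", show_col_types = FALSE)
qc <- apply_qc(pairs)
s <- summarize_growth(qc$records)

readr::write_csv(qc$records, "results/growth.csv", progress = FALSE)
readr::write_csv(s$by_species, "results/growth_by_species.csv", progress = FALSE)
jsonlite::write_json(s[setdiff(names(s), "by_species")],
                     "results/growth_summary.json",
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("QC kept %d of %d pairs; status counts:\n", s$n, nrow(qc$records)))
print(table(qc$records$qc_status))
cat(sprintf("mean rate %.3f +/- %.3f in/yr (min %.1f, max %.1f);\n",
            s$mean_rate, s$sd_rate, s$min_rate, s$max_rate),
    sprintf("%.1f%% negative, %.1f%% within [0, 1] in/yr.\n",
            100 * s$frac_negative, 100 * s$frac_0_to_1))
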