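#!/usr/bin/env Rscript
# Time-dependent predictive-value comparison on the PD-L1-available subset:
# PPV for mortality of iSEND Poor vs PD-L1 = 0%, and NPV of iSEND Good vs
# PD-L1 >= 50%, at 6/12/18/24 months, paired-bootstrap p-values.

library(isend)

sc <- read_cohort("results/data/pooled_scored.csv")$records
sc <- assign_groups(derive_haematology(sc))$records
avail <- sc[sc$pdl1 != "unknown", ]
cat(sprintf("PD-L1 available: n = %d of %d\n", nrow(avail), nrow(sc)))

ppv <- compare_markers_table(avail, marker_isend_poor(), marker_pdl1_0(),
                             horizons = c(6, 12, 18, 24), endpoint = "os",
                             kind = "ppv", B = 2000, seed = 20260104)
write.csv(ppv, "results/ppv_poor_vs_pdl1_0.csv", row.names = FALSE)
cat("PPV for mortality, iSEND Poor (a) vs PD-L1 0% (b):\n")
print(ppv, digits = 3)

npv <- compare_markers_table(avail, marker_isend_good(), marker_pdl1_high(),
                             horizons = c(6, 12, 18, 24), endpoint = "os",
                             kind = "npv", B = 2000, seed = 20260105)
write.csv(npv, "results/npv_good_vs_pdl1_50.csv", row.names = FALSE)
cat("NPV for mortality, iSEND Good (a) vs PD-L1 >= 50% (b):\n")
print(npv, digits = 3)

jsonlite::write_json(list(B = 2000, seeds = c(20260104, 20260105),
                          method = "paired bootstrap + Wald"),
                     "results/ppv_meta.json", auto_unbox = TRUE)
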