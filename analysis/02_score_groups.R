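#!/usr/bin/env Rscript
# Apply the exclusion cascade and the iSEND score to the simulated pooled
# cohort; write the scored cohort and the risk-group split.

library(isend)

res <- read_cohort("results/data/pooled_cohort.csv")
stopifnot(nrow(res$diagnostics) == 0)

excl <- apply_exclusions(res$records)
write_exclusion_tally(excl$tally, "results/exclusions.json")

scored <- assign_groups(derive_haematology(excl$records))
write_cohort(scored$records, "results/data/pooled_scored.csv")
write.csv(scored$summary, "results/group_sizes.csv", row.names = FALSE)

cat("exclusions:", paste(names(excl$tally), excl$tally, sep = "=",
                         collapse = ", "), "\n")
cat("risk-group split:\n")
print(scored$summary)
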