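#!/usr/bin/env Rscript
# Stage 2: per-cross lethality verdicts and dual-background concordance.
#
# A cross is lethal at the first stage transition whose pooled survival
# falls below 10%; a duplication counts as hybrid-lethal only when both
# attached-X backgrounds (C(1)RM and C(1)DX) agree on the stage.

suppressPackageStartupMessages(library(dmimap))

viab <- read_viability("results/viability.tsv")
calls <- screen_calls(viab, threshold = 0.10, min_replicates = 3)
concordant <- concordant_calls(calls)

write_table_tsv(calls, "results/calls.tsv")
write_table_tsv(concordant, "results/concordant_calls.tsv")

lethal <- concordant[concordant$concordant_stage != "none", ]
cat(sprintf("%d of %d crosses excluded; %d lethal verdicts concordant",
            sum(calls$verdict == "excluded"), nrow(calls), nrow(lethal)),
    sprintf("across both backgrounds; %d discordant\n",
            sum(concordant$discordant)))
print(table(lethal$paternal_species, lethal$concordant_stage))
cat("wrote results/calls.tsv and results/concordant_calls.tsv\n")
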