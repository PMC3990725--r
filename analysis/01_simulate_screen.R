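#!/usr/bin/env Rscript
# Stage 1: simulate the duplication screen.
#
# Builds the 40-stock tiling panel of Dp(1;Y) duplications, the five
# paternal lines (santomea, simulans, mauritiana and two intraspecific
# melanogaster controls), and the default planted lethal architecture
# (12 san-acting loci: 9 embryonic + 3 pupal; the 4C pupal locus shared
# with sim/mau; a sim/mau-only larval locus at 9D4), then simulates the
# per-replicate stage censuses for every duplication x background x line
# cross and writes the panel and viability tables.

suppressPackageStartupMessages(library(dmimap))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed")
  args[2] else "1")
dir.create("results", showWarnings = FALSE)

panel <- make_tiling_panel(20)
lines <- default_study_lines()
loci <- default_planted_loci(penetrance = 1)

viab <- simulate_panel(panel, lines, loci = loci, clutch_size = 300,
                       n_replicates = 3, seed = seed)

write_table_tsv(panel, "results/panel.tsv")
write_table_tsv(viab, "results/viability.tsv")

cat(sprintf("simulated %d crosses (%d stocks x 2 backgrounds x %d lines),",
            nrow(viab) / 3, nrow(panel), length(lines)),
    "3 replicates of 300 embryos each\n")
cat("wrote results/panel.tsv and results/viability.tsv\n")
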