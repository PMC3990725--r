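#!/usr/bin/env Rscript
# Stage 3: minimal lethal regions by minimum interval piercing.
#
# Within each (paternal line, lethal stage) class, overlapping lethal
# duplications are assumed to share their cause, so the minimal region
# count is the minimum number of bands piercing every lethal interval
# (right-endpoint greedy; exact).

suppressPackageStartupMessages(library(dmimap))

panel <- read_panel("results/panel.tsv")
concordant <- utils::read.delim("results/concordant_calls.tsv",
                                stringsAsFactors = FALSE)
regions <- infer_regions(concordant, panel)
write_table_tsv(regions, "results/regions.tsv")

# ordinal-coordinate track of the lethal region cores
if (nrow(regions)) {
  cyto_bed(regions$region_id, lapply(regions$core, parse_interval),
           file = "results/regions.bed")
}

for (nm in unique(paste(regions$paternal_species, regions$line))) {
  sub <- regions[paste(regions$paternal_species, regions$line) == nm, ]
  counts <- count_by_stage(sub)
  cat(sprintf("%-28s %2d regions (embryonic %d, larval %d, pupal %d)\n",
              nm, sum(counts), counts[["embryonic"]], counts[["larval"]],
              counts[["pupal"]]))
}
cat("wrote results/regions.tsv and results/regions.bed\n")
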