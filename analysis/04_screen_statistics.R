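#!/usr/bin/env Rscript
# Stage 4: statistical summary of the screen.
#
# Stage-uniformity chi-square for the most divergent cross, Sidak
# per-comparison thresholds at the study's comparison counts, and the
# linear-versus-quadratic snowball model comparison over all five
# (divergence, region count) points.

suppressPackageStartupMessages(library(dmimap))

regions <- utils::read.delim("results/regions.tsv",
                             stringsAsFactors = FALSE)
lines <- default_study_lines()

san <- regions[regions$paternal_species == "santomea", ]
counts <- count_by_stage(san)
uni <- stage_uniformity_test(counts)
cat(sprintf("santomea stage counts (%d, %d, %d):", counts[["embryonic"]],
            counts[["larval"]], counts[["pupal"]]),
    sprintf("chi-square = %.4g, df = %d, p = %.3g\n", uni$statistic,
            uni$df, uni$p))

for (m in c(6, 18))
  cat(sprintf("Sidak threshold, %2d comparisons at alpha 0.05: %.4g\n",
              m, sidak_threshold(0.05, m)))

snow_data <- snowball_dataset(regions, lines)
cmp <- snowball_compare(snow_data)
cat("snowball points (Ks, regions):",
    paste(sprintf("(%.2f, %d)", snow_data$Ks, snow_data$n_regions),
          collapse = " "), "\n")
cat(sprintf("linear AIC %.4g (rss %.4g); quadratic %s;", cmp$linear$aic,
            cmp$linear$rss,
            if (cmp$quadratic$degenerate)
              "degenerate exact fit (AIC -Inf)" else
                sprintf("AIC %.4g", cmp$quadratic$aic)),
    sprintf("preferred degree: %d\n", cmp$preferred_degree))

report <- list(
  stage_counts_santomea = as.list(counts),
  uniformity = unclass(uni),
  sidak_thresholds = list(m6 = sidak_threshold(0.05, 6),
                          m18 = sidak_threshold(0.05, 18)),
  snowball = list(data = snow_data,
                  linear_aic = cmp$linear$aic,
                  linear_rss = cmp$linear$rss,
                  quadratic_degenerate = cmp$quadratic$degenerate,
                  preferred_degree = cmp$preferred_degree))
write_report_json(report, "results/statistics.json")
cat("wrote results/statistics.json\n")
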