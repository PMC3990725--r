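# End-to-end orchestration: census table -> per-cross verdicts ->
# dual-background concordance -> minimal regions -> stage and snowball
# statistics.

#' Pipeline configuration
#'
#' @param threshold Lethality cut-off on stage survival (default 0.10).
#' @param alpha Family-wise significance level for Sidak thresholds.
#' @param denominator `"total"` or `"male_only"` embryonic denominator.
#' @param min_replicates Minimum replicates per cross.
#' @param rss_floor Degeneracy floor for polynomial fits.
#' @param seed Root seed for simulation mode.
#' @param clutch_size,n_replicates Simulation census parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold = 0.10, alpha = 0.05,
                            denominator = "total", min_replicates = 3,
                            rss_floor = 1e-12, seed = 1L,
                            clutch_size = 300, n_replicates = 3) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(threshold = threshold, alpha = alpha,
                 denominator = denominator,
                 min_replicates = min_replicates, rss_floor = rss_floor,
                 seed = seed, clutch_size = clutch_size,
                 n_replicates = n_replicates),
            class = "pipeline_config")
}

#' Run the full duplication-mapping pipeline
#'
#' Either consumes a real viability table or simulates one from the panel,
#' then: classifies every cross ([screen_calls()]), reduces to
#' dual-background concordant lethal calls ([concordant_calls()]), infers
#' minimal lethal regions per line and stage ([infer_regions()]),
#' tabulates region counts by stage, tests stage uniformity for lines with
#' enough regions, and runs the linear-versus-quadratic snowball
#' comparison over all lines. Exclusions and discordant calls are
#' collected into a structured log. Deterministic given the config seed.
#'
#' @param panel Panel data.frame (`stock_id`, `dp_name`, `interval`).
#' @param lines List of [paternal_line()] objects.
#' @param viability Optional real viability data.frame (as from
#'   [read_viability()]); when `NULL` the screen is simulated.
#' @param loci Planted loci for simulation mode.
#' @param survival Survival table for simulation mode.
#' @param config A [pipeline_config()].
#' @param uniformity_min_regions Minimum total regions a line needs for
#'   its stage-uniformity test (default 6; testing uniformity over three
#'   stages with fewer lethals than that is uninformative).
#' @return A list: `viability`, `calls`, `concordant`, `regions`,
#'   `stage_counts` (per line), `uniformity` (per eligible line),
#'   `snowball` (dataset + model comparison), `log` (exclusions and
#'   discordances with reason codes), `config`.
#' @export
run_pipeline <- function(panel, lines, viability = NULL, loci = list(),
                         survival = default_survival_table(),
                         config = pipeline_config(),
                         uniformity_min_regions = 6) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(viability)) {
    viability <- simulate_panel(
      panel, lines, loci = loci, survival = survival,
      clutch_size = config$clutch_size,
      n_replicates = config$n_replicates, seed = config$seed)
  }
  calls <- screen_calls(viability, threshold = config$threshold,
                        min_replicates = config$min_replicates,
                        denominator = config$denominator)
  concordant <- concordant_calls(calls)
  regions <- infer_regions(concordant, panel)

  line_key <- function(df) paste(df$paternal_species, df$line, sep = " / ")
  stage_counts <- lapply(split(regions, line_key(regions)), count_by_stage)

  uniformity <- list()
  for (nm in names(stage_counts)) {
    if (sum(stage_counts[[nm]]) >= uniformity_min_regions)
      uniformity[[nm]] <- stage_uniformity_test(stage_counts[[nm]])
  }

  snow_data <- snowball_dataset(regions, lines)
  snow <- tryCatch(snowball_compare(snow_data, config$rss_floor),
                   error = identity)
  if (inherits(snow, "error")) {
    warning("snowball comparison not computable: ",
            conditionMessage(snow), call. = FALSE)
    snow <- NULL
  }

  log <- rbind(
    if (any(calls$verdict == "excluded"))
      data.frame(event = "exclusion",
                 stock_id = calls$stock_id[calls$verdict == "excluded"],
                 background = calls$background[calls$verdict == "excluded"],
                 line = calls$line[calls$verdict == "excluded"],
                 reason = calls$reason[calls$verdict == "excluded"],
                 stringsAsFactors = FALSE),
    if (any(concordant$discordant))
      data.frame(event = "discordance",
                 stock_id = concordant$stock_id[concordant$discordant],
                 background = NA_character_,
                 line = concordant$line[concordant$discordant],
                 reason = "background_discordant",
                 stringsAsFactors = FALSE))

  list(viability = viability, calls = calls, concordant = concordant,
       regions = regions, stage_counts = stage_counts,
       uniformity = uniformity,
       snowball = list(data = snow_data, comparison = snow),
       log = log, config = config)
}

#' Summarise a pipeline result as a flat report
#'
#' Collects the headline numbers of a pipeline run (region counts per
#' line and stage, uniformity chi-square, Sidak thresholds at the
#' config's alpha, snowball AICs and preference) into a plain list
#' suitable for [write_report_json()].
#'
#' @param result Output of [run_pipeline()].
#' @param n_comparisons Comparison counts for which Sidak thresholds are
#'   reported.
#' @return A nested list.
#' @export
pipeline_report <- function(result, n_comparisons = c(6, 18)) {
  cfg <- result$config
  snow <- result$snowball$comparison
  list(
    config = unclass(cfg),
    n_crosses = nrow(result$calls),
    n_excluded = sum(result$calls$verdict == "excluded"),
    regions_per_line = lapply(result$stage_counts, function(x)
      c(as.list(x), total = sum(x))),
    uniformity = lapply(result$uniformity, unclass),
    sidak_thresholds = stats::setNames(
      lapply(n_comparisons, function(m) sidak_threshold(cfg$alpha, m)),
      paste0("m", n_comparisons)),
    snowball = if (!is.null(snow)) list(
      data = result$snowball$data,
      linear_aic = snow$linear$aic,
      quadratic_aic = snow$quadratic$aic,
      quadratic_degenerate = snow$quadratic$degenerate,
      preferred_degree = snow$preferred_degree),
    log = result$log)
}
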