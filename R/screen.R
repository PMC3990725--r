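# Lethality calling: the qualitative screen rule.
#
# A duplication is called lethal at the first stage transition whose pooled
# survival falls below the threshold (default 10%), and only counts as a
# hybrid lethal when both attached-X backgrounds agree on the stage.

#' Stage-transition survival proportions of a census
#'
#' Computes the three transition survivals of a pooled or single-replicate
#' census: hatched/fertilized, pupae/larvae-entering, adults/pupae. With the
#' default `"total"` denominator mode the embryonic proportion is over all
#' fertilized embryos (the screen's as-printed convention, even though only
#' ~1/4 of a clutch — the dp_male class — can hatch in the most divergent
#' cross); `"male_only"` rescales the embryonic denominator to the expected
#' male quarter of the clutch. A zero denominator yields `NA` for that
#' proportion — undefined, not zero.
#'
#' @param counts A one-row data.frame or list with `n_fertilized`,
#'   `n_hatched`, `n_pupae`, `n_adults`.
#' @param denominator `"total"` or `"male_only"` (embryonic stage only).
#' @return Named numeric `c(embryonic=, larval=, pupal=)`, entries in
#'   `[0, 1]` or `NA` where undefined.
#' @export
stage_survival <- function(counts, denominator = c("total", "male_only")) {
  denominator <- match.arg(denominator)
  nf <- counts$n_fertilized
  nh <- counts$n_hatched
  np <- counts$n_pupae
  na <- counts$n_adults
  if (any(c(nf, nh, np, na) < 0)) stop("negative counts", call. = FALSE)
  emb_den <- if (denominator == "male_only") nf / 4 else nf
  prop <- function(num, den) if (den > 0) min(num / den, 1) else NA_real_
  c(embryonic = prop(nh, emb_den),
    larval = prop(np, nh),
    pupal = prop(na, np))
}

pool_counts <- function(replicates) {
  list(n_fertilized = sum(replicates$n_fertilized),
       n_hatched = sum(replicates$n_hatched),
       n_pupae = sum(replicates$n_pupae),
       n_adults = sum(replicates$n_adults))
}

verdict_from_survival <- function(surv, threshold) {
  for (stage in STAGES) {
    s <- surv[[stage]]
    if (!is.na(s) && s < threshold) return(stage)
  }
  "none"
}

#' Classify one cross series as lethal at a stage, non-lethal, or excluded
#'
#' Pools the replicate censuses of a single (duplication, background,
#' paternal line) series and returns the first stage transition (embryonic,
#' then larval, then pupal) whose pooled survival falls below `threshold`;
#' `"none"` if no transition fails. Later stages are unobservable once an
#' earlier one fails, so the earliest failing transition labels the cross.
#' Crosses with no observed insemination or no embryonic progeny are
#' `"excluded"` (pre- and postmating-prezygotic isolation filters), as are
#' series with fewer than `min_replicates` replicates.
#'
#' @param replicates data.frame of per-replicate censuses for one cross
#'   (columns as in [simulate_cross()] output).
#' @param threshold Lethality cut-off on survival (default 0.10).
#' @param min_replicates Minimum replicates required (default 3).
#' @param denominator Passed to [stage_survival()].
#' @param mode `"pool"` (default: threshold the pooled counts) or
#'   `"majority"` (per-replicate verdicts, majority stage wins).
#' @return A list with `verdict` (stage, `"none"` or `"excluded"`),
#'   `reason` (exclusion reason or `NA`), `survival` (pooled proportions),
#'   `n_replicates`.
#' @export
classify_cross <- function(replicates, threshold = 0.10, min_replicates = 3,
                           denominator = c("total", "male_only"),
                           mode = c("pool", "majority")) {
  denominator <- match.arg(denominator)
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  empty <- c(embryonic = NA_real_, larval = NA_real_, pupal = NA_real_)
  excluded <- function(reason)
    list(verdict = "excluded", reason = reason, survival = empty,
         n_replicates = if (is.null(replicates)) 0L else nrow(replicates))
  if (is.null(replicates) || !nrow(replicates))
    return(excluded("no_data"))
  if (!any(replicates$inseminated))
    return(excluded("not_inseminated"))
  kept <- replicates[replicates$inseminated, , drop = FALSE]
  if (nrow(kept) < min_replicates)
    return(excluded("insufficient_replicates"))
  pooled <- pool_counts(kept)
  if (pooled$n_fertilized == 0)
    return(excluded("no_embryonic_progeny"))
  surv <- stage_survival(pooled, denominator)
  verdict <- if (mode == "pool") {
    verdict_from_survival(surv, threshold)
  } else {
    votes <- vapply(seq_len(nrow(kept)), function(i)
      verdict_from_survival(stage_survival(kept[i, ], denominator),
                            threshold), character(1))
    tab <- sort(table(votes), decreasing = TRUE)
    if (tab[1] > nrow(kept) / 2) names(tab)[1] else "none"
  }
  list(verdict = verdict, reason = NA_character_, survival = surv,
       n_replicates = nrow(kept))
}

#' Per-cross verdicts for a whole viability table
#'
#' Applies [classify_cross()] to every (stock, background, line) series of
#' a viability table.
#'
#' @param viability data.frame in the schema written by [simulate_panel()].
#' @param ... Passed to [classify_cross()].
#' @return data.frame with one row per cross: identifiers, `verdict`,
#'   `reason`, pooled stage survivals, `n_replicates`.
#' @export
screen_calls <- function(viability, ...) {
  key <- interaction(viability$stock_id, viability$background,
                     viability$paternal_species, viability$line,
                     drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(viability)), key)
  rows <- lapply(groups, function(idx) {
    sub <- viability[idx, , drop = FALSE]
    cl <- classify_cross(sub, ...)
    data.frame(stock_id = sub$stock_id[1], background = sub$background[1],
               paternal_species = sub$paternal_species[1],
               line = sub$line[1], verdict = cl$verdict,
               reason = cl$reason,
               surv_embryonic = cl$survival[["embryonic"]],
               surv_larval = cl$survival[["larval"]],
               surv_pupal = cl$survival[["pupal"]],
               n_replicates = cl$n_replicates,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$paternal_species, out$line, out$stock_id,
            out$background), ]
}

#' Dual-background concordant lethal calls
#'
#' Reduces per-background verdicts to one call per (stock, paternal line).
#' A duplication counts as hybrid-lethal only when both attached-X
#' backgrounds name the same lethal stage; verdict pairs that disagree
#' (lethal in one background only, or lethal at different stages) are kept
#' with `concordant_stage = "none"` and a discordance flag, and stocks seen
#' in a single background are reported but never called lethal.
#'
#' @param calls Per-cross verdict table from [screen_calls()].
#' @return data.frame with one row per (stock, line): per-background
#'   verdicts, `concordant_stage`, `discordant`, `single_background`.
#' @export
concordant_calls <- function(calls) {
  key <- interaction(calls$stock_id, calls$paternal_species, calls$line,
                     drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(calls)), key)
  rows <- lapply(groups, function(idx) {
    sub <- calls[idx, , drop = FALSE]
    v <- function(bg) {
      x <- sub$verdict[sub$background == bg]
      if (length(x)) x[1] else NA_character_
    }
    v1 <- v("C1RM"); v2 <- v("C1DX")
    single <- is.na(v1) || is.na(v2)
    lethal_stages <- STAGES
    concordant <- if (!single && v1 == v2 && v1 %in% lethal_stages)
      v1 else "none"
    discordant <- !single && v1 != v2 &&
      (v1 %in% lethal_stages || v2 %in% lethal_stages)
    data.frame(stock_id = sub$stock_id[1],
               paternal_species = sub$paternal_species[1],
               line = sub$line[1],
               verdict_C1RM = v1, verdict_C1DX = v2,
               concordant_stage = concordant,
               discordant = discordant,
               single_background = single,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$paternal_species, out$line, out$stock_id), ]
}
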