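# Minimal lethal-region inference.
#
# Overlapping lethal duplications are assumed to share their cause of
# lethality, so the minimal number of distinct lethal regions is the
# minimum number of points (bands) piercing every lethal interval —
# solved exactly by the classical right-endpoint greedy, and equal to the
# maximum number of pairwise disjoint intervals. Regions are inferred
# within each (paternal line, lethal stage) class separately, since two
# overlapping duplications lethal at different stages cannot share a cause.

#' Minimum piercing of a set of lethal intervals
#'
#' Computes a minimum-cardinality set of piercing bands such that every
#' interval contains at least one, by the right-endpoint greedy: sort by
#' right endpoint under the band order (ties broken by stock id), then
#' repeatedly pierce at the right endpoint of the leftmost-ending interval
#' not yet covered. Each region's members are all input intervals
#' containing its piercing band; its core is the intersection of the
#' members. The region count equals the maximum number of pairwise
#' disjoint input intervals.
#'
#' @param stock_ids Character vector of duplication stock ids.
#' @param intervals List of [cyto_interval()] objects (or strings), same
#'   length; all from one (paternal line, stage) class.
#' @return A list of regions, each a list with `piercing_band`
#'   ([cyto_band()]), `core` ([cyto_interval()]), `members` (stock ids).
#'   Empty input yields an empty list.
#' @export
minimal_regions <- function(stock_ids, intervals) {
  stopifnot(length(stock_ids) == length(intervals))
  if (!length(intervals)) return(list())
  intervals <- lapply(intervals, function(i)
    if (is.character(i)) parse_interval(i) else i)
  end_keys <- t(vapply(intervals, function(i) band_key(i$end), numeric(3)))
  ord <- order(end_keys[, 1], end_keys[, 2], end_keys[, 3], stock_ids)
  covered <- rep(FALSE, length(intervals))
  regions <- list()
  for (j in ord) {
    if (covered[j]) next
    pierce <- intervals[[j]]$end
    members <- which(vapply(intervals, band_in_interval,
                            logical(1), band = pierce))
    covered[members] <- TRUE
    core <- Reduce(interval_intersect, intervals[members])
    regions[[length(regions) + 1L]] <- list(
      piercing_band = pierce, core = core,
      members = stock_ids[members])
  }
  regions
}

#' Infer lethal regions from concordant calls
#'
#' Partitions the concordant lethal calls by (paternal species, line,
#' stage) and runs [minimal_regions()] within each class.
#'
#' @param concordant Output of [concordant_calls()].
#' @param panel Panel data.frame mapping `stock_id` to `interval`.
#' @return data.frame with one row per region: `paternal_species`, `line`,
#'   `stage`, `region_id`, `core` and `piercing_band` in band notation,
#'   `members` (comma-separated stock ids), `n_members`.
#' @export
infer_regions <- function(concordant, panel) {
  lethal <- concordant[concordant$concordant_stage %in% STAGES, ,
                       drop = FALSE]
  iv_of <- stats::setNames(panel$interval, panel$stock_id)
  out <- list()
  if (nrow(lethal)) {
    key <- interaction(lethal$paternal_species, lethal$line,
                       lethal$concordant_stage, drop = TRUE, sep = "\r")
    for (idx in split(seq_len(nrow(lethal)), key)) {
      sub <- lethal[idx, , drop = FALSE]
      missing <- setdiff(sub$stock_id, names(iv_of))
      if (length(missing))
        stop("lethal stocks absent from panel: ",
             paste(missing, collapse = ", "), call. = FALSE)
      regs <- minimal_regions(sub$stock_id,
                              as.list(iv_of[sub$stock_id]))
      for (k in seq_along(regs)) {
        r <- regs[[k]]
        out[[length(out) + 1L]] <- data.frame(
          paternal_species = sub$paternal_species[1],
          line = sub$line[1],
          stage = sub$concordant_stage[1],
          region_id = NA_character_,
          core = format(r$core),
          piercing_band = format_band(r$piercing_band),
          members = paste(sort(r$members), collapse = ","),
          n_members = length(r$members),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(paternal_species = character(), line = character(),
                      stage = character(), region_id = character(),
                      core = character(), piercing_band = character(),
                      members = character(), n_members = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$paternal_species, res$line,
                   match(res$stage, STAGES), res$piercing_band), ]
  res$region_id <- sprintf("R%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Region counts per developmental stage
#'
#' @param regions Region table from [infer_regions()], already restricted
#'   to one paternal line (or any subset of interest).
#' @return Named integer vector `c(embryonic=, larval=, pupal=)`.
#' @export
count_by_stage <- function(regions) {
  counts <- vapply(STAGES, function(s) sum(regions$stage == s), integer(1))
  stats::setNames(as.integer(counts), STAGES)
}

#' Assemble the snowball dataset
#'
#' One (Ks, region count) point per cross: the total number of distinct
#' lethal regions found against each paternal line, at that line's
#' synonymous divergence from the maternal stock. Intraspecific lines
#' enter at the within-species polymorphism proxy and contribute whatever
#' count the screen found there (zero, in the absence of dominant
#' intraspecific lethals).
#'
#' @param regions Region table from [infer_regions()].
#' @param lines List of [paternal_line()] objects covering every cross
#'   (lines with no regions contribute zero counts).
#' @return data.frame with columns `species`, `line`, `Ks`, `n_regions`.
#' @export
snowball_dataset <- function(regions, lines) {
  if (inherits(lines, "paternal_line")) lines <- list(lines)
  rows <- lapply(lines, function(pl) {
    if (is.null(pl$Ks) || is.na(pl$Ks))
      stop("missing Ks for line ", pl$line, call. = FALSE)
    n <- sum(regions$paternal_species == pl$species &
               regions$line == pl$line)
    data.frame(species = pl$species, line = pl$line, Ks = pl$Ks,
               n_regions = as.integer(n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
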