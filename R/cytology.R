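# Cytological band coordinates on the Drosophila X polytene map.
#
# The axis is ordinal, not physical: euchromatic divisions 1-20, each with
# subdivisions A-F and positive band numbers, followed by the centric
# heterochromatin blocks h25-h29. Duplication extents are closed intervals
# on this order ("2C1-3E4" carries both endpoint bands).

H_BLOCKS <- 25:29
SUBDIVISIONS <- LETTERS[1:6]

#' Construct a cytological band
#'
#' A band is a position on the ordered cytological map of the X chromosome:
#' either a euchromatic band (division 1-20, optional subdivision letter A-F,
#' optional band number) or a centric heterochromatin block (h25-h29).
#' The band number may be the sentinel `Inf`, meaning "last band of the
#' subdivision"; it is used to complete right interval endpoints written
#' without a band number (e.g. the right end of "9C-10B") and sorts after
#' every concrete band number.
#'
#' @param division Integer division 1-20, or h-block number 25-29 when
#'   `het = TRUE`.
#' @param subdivision Subdivision letter `"A"`-`"F"`, or `NA` if absent.
#'   Required when `band` is given; disallowed for h-blocks.
#' @param band Positive band number, `Inf` (last-band sentinel), or `NA`.
#' @param het Logical; `TRUE` for a heterochromatin block.
#' @return An object of class `cyto_band`.
#' @examples
#' cyto_band(2, "C", 1)
#' cyto_band(28, het = TRUE)
#' @export
cyto_band <- function(division, subdivision = NA_character_, band = NA_real_,
                      het = FALSE) {
  division <- as.integer(division)
  band <- as.numeric(band)
  if (isTRUE(het)) {
    if (!division %in% H_BLOCKS)
      stop("unknown heterochromatin block: h", division, call. = FALSE)
    if (!is.na(subdivision) || !is.na(band))
      stop("h-blocks carry no subdivision or band number", call. = FALSE)
  } else {
    if (is.na(division) || division < 1L || division > 20L)
      stop("euchromatic division must be in 1-20, got: ", division,
           call. = FALSE)
    if (!is.na(subdivision)) {
      subdivision <- toupper(subdivision)
      if (!subdivision %in% SUBDIVISIONS)
        stop("subdivision must be one of A-F, got: ", subdivision,
             call. = FALSE)
    }
    if (!is.na(band)) {
      if (is.na(subdivision))
        stop("a band number requires a subdivision letter", call. = FALSE)
      if (band < 1)
        stop("band number must be positive, got: ", band, call. = FALSE)
    }
  }
  structure(list(division = division, subdivision = subdivision,
                 band = band, het = isTRUE(het)),
            class = "cyto_band")
}

#' Parse a band-notation string
#'
#' Accepts euchromatic notation `<division><letter?><number?>` (e.g. `"2C1"`,
#' `"9C"`, `"12"`) and heterochromatin notation `h<number>` (e.g. `"h28"`).
#' Input is case-normalized to uppercase (`"2c1"` parses as `"2C1"`,
#' `"H28"` as `"h28"`). Parsing round-trips through [format_band()].
#'
#' @param text A single band string.
#' @return A [cyto_band()].
#' @examples
#' parse_band("2C1")
#' parse_band("20F3")
#' parse_band("h28")
#' @export
parse_band <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stop("band string must be a single non-empty string", call. = FALSE)
  token <- toupper(trimws(text))
  m <- regmatches(token, regexec("^H([0-9]+)$", token))[[1]]
  if (length(m)) {
    h <- as.integer(m[2])
    if (!h %in% H_BLOCKS)
      stop("unknown heterochromatin block in '", text, "'", call. = FALSE)
    return(cyto_band(h, het = TRUE))
  }
  m <- regmatches(token, regexec("^([0-9]+)([A-F]?)([0-9]*)$", token))[[1]]
  if (!length(m))
    stop("malformed band string: '", text, "'", call. = FALSE)
  division <- as.integer(m[2])
  if (division < 1L || division > 20L)
    stop("division out of euchromatic range 1-20 in '", text, "'",
         call. = FALSE)
  subdivision <- if (nzchar(m[3])) m[3] else NA_character_
  band <- if (nzchar(m[4])) as.numeric(m[4]) else NA_real_
  if (!is.na(band) && is.na(subdivision))
    stop("band number without subdivision letter in '", text, "'",
         call. = FALSE)
  cyto_band(division, subdivision, band)
}

#' Format a band back to its string notation
#'
#' Inverse of [parse_band()] on all valid band strings. The last-band
#' sentinel (`band = Inf`) is rendered without a band number.
#'
#' @param b A [cyto_band()].
#' @return A band string such as `"2C1"` or `"h28"`.
#' @export
format_band <- function(b) {
  stopifnot(inherits(b, "cyto_band"))
  if (b$het) return(paste0("h", b$division))
  out <- as.character(b$division)
  if (!is.na(b$subdivision)) out <- paste0(out, b$subdivision)
  if (!is.na(b$band) && is.finite(b$band)) out <- paste0(out, b$band)
  out
}

#' @export
print.cyto_band <- function(x, ...) {
  cat("<cyto_band> ", format_band(x), "\n", sep = "")
  invisible(x)
}

#' Sort key of a band on the cytological order
#'
#' Maps a band to a numeric triple (major, minor, micro) whose lexicographic
#' order is the total band order: euchromatic divisions 1-20 first, ordered
#' by (division, subdivision letter, band number), then h-blocks by h-number.
#' A missing subdivision or band sorts before any concrete value within its
#' level; the `Inf` sentinel sorts after every concrete band number.
#'
#' @param b A [cyto_band()].
#' @return Numeric vector of length 3.
#' @export
band_key <- function(b) {
  stopifnot(inherits(b, "cyto_band"))
  if (b$het) return(c(20L + b$division - 24L, 0, 0))
  minor <- if (is.na(b$subdivision)) 0 else match(b$subdivision, SUBDIVISIONS)
  micro <- if (is.na(b$band)) 0 else b$band
  c(b$division, minor, micro)
}

key_leq <- function(ka, kb) {
  for (i in seq_along(ka)) {
    if (ka[i] < kb[i]) return(TRUE)
    if (ka[i] > kb[i]) return(FALSE)
  }
  TRUE
}

#' Total order on cytological bands
#'
#' `band_leq(a, b)` is `TRUE` iff `a` precedes or equals `b` on the
#' chromosome-walking order (proximal tip of the X through 20F, then the
#' centric heterochromatin blocks). The relation is reflexive, antisymmetric
#' and transitive.
#'
#' @param a,b [cyto_band()] objects.
#' @return Logical.
#' @examples
#' band_leq(parse_band("11D1"), parse_band("11D5"))
#' @export
band_leq <- function(a, b) key_leq(band_key(a), band_key(b))

band_equal <- function(a, b) identical(band_key(a), band_key(b))

band_max <- function(a, b) if (band_leq(a, b)) b else a
band_min <- function(a, b) if (band_leq(a, b)) a else b

#' Construct a closed cytological interval
#'
#' @param start,end [cyto_band()] endpoints, both included in the interval;
#'   `start` must not follow `end` on the band order.
#' @return An object of class `cyto_interval`.
#' @export
cyto_interval <- function(start, end) {
  stopifnot(inherits(start, "cyto_band"), inherits(end, "cyto_band"))
  if (!band_leq(start, end))
    stop("reversed interval: ", format_band(start), "-", format_band(end),
         call. = FALSE)
  structure(list(start = start, end = end), class = "cyto_interval")
}

#' Parse a duplication extent string
#'
#' Parses `"A-B"` into a closed interval. Endpoints written without a
#' subdivision or band number are completed outward, so that the interval
#' covers everything the loose notation could denote: on the left, a missing
#' letter becomes `A` and a missing band number `1`; on the right, a missing
#' letter becomes `F` and a missing band number the last-band sentinel.
#' `"9C-10B"` therefore spans 9C1 through the last band of 10B.
#'
#' @param text An interval string such as `"2C1-3E4"`.
#' @return A [cyto_interval()].
#' @examples
#' parse_interval("2C1-3E4")
#' parse_interval("9C-10B")
#' @export
parse_interval <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stop("interval string must be a single non-empty string", call. = FALSE)
  parts <- strsplit(trimws(text), "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("interval must be written '<band>-<band>': '", text, "'",
         call. = FALSE)
  lo <- parse_band(parts[1])
  hi <- parse_band(parts[2])
  if (!lo$het) {
    if (is.na(lo$subdivision)) lo$subdivision <- "A"
    if (is.na(lo$band)) lo$band <- 1
  }
  if (!hi$het) {
    if (is.na(hi$subdivision)) hi$subdivision <- "F"
    if (is.na(hi$band)) hi$band <- Inf
  }
  if (!band_leq(lo, hi))
    stop("reversed interval: '", text, "'", call. = FALSE)
  cyto_interval(lo, hi)
}

#' @export
format.cyto_interval <- function(x, ...) {
  paste0(format_band(x$start), "-", format_band(x$end))
}

#' @export
print.cyto_interval <- function(x, ...) {
  cat("<cyto_interval> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Do two intervals share at least one band?
#'
#' Closed-interval overlap under the band order:
#' `max(starts) <= min(ends)`. Symmetric.
#'
#' @param i1,i2 [cyto_interval()] objects.
#' @return Logical.
#' @export
interval_overlaps <- function(i1, i2) {
  stopifnot(inherits(i1, "cyto_interval"), inherits(i2, "cyto_interval"))
  band_leq(band_max(i1$start, i2$start), band_min(i1$end, i2$end))
}

#' Intersection of two overlapping intervals
#'
#' @param i1,i2 Overlapping [cyto_interval()] objects.
#' @return The [cyto_interval()] `[max(starts), min(ends)]`, contained in
#'   both inputs.
#' @export
interval_intersect <- function(i1, i2) {
  if (!interval_overlaps(i1, i2))
    stop("intervals ", format(i1), " and ", format(i2),
         " share no region", call. = FALSE)
  cyto_interval(band_max(i1$start, i2$start), band_min(i1$end, i2$end))
}

#' Does an interval contain a band?
#'
#' @param band A [cyto_band()].
#' @param interval A [cyto_interval()].
#' @return Logical; `TRUE` iff `start <= band <= end`.
#' @export
band_in_interval <- function(band, interval) {
  stopifnot(inherits(band, "cyto_band"), inherits(interval, "cyto_interval"))
  band_leq(interval$start, band) && band_leq(band, interval$end)
}

#' BED-like export with ordinal coordinates
#'
#' Converts named intervals to a BED-like table whose coordinates are the
#' 0-based, half-open ranks of the endpoint bands on the band order across
#' the whole input set. Coordinates are ordinal (rank-indexed), not physical
#' base pairs; the written file says so in a header comment.
#'
#' @param names Character vector of feature names.
#' @param intervals List of [cyto_interval()] objects, same length.
#' @param file Optional path; when given the table is written as
#'   tab-separated text with a `#` header declaring the coordinate system.
#' @return Invisibly, a data.frame with columns `chrom`, `start`, `end`,
#'   `name` plus the band-notation `interval` column.
#' @export
cyto_bed <- function(names, intervals, file = NULL) {
  stopifnot(length(names) == length(intervals))
  keys <- unique(do.call(rbind, lapply(intervals, function(i)
    rbind(band_key(i$start), band_key(i$end)))))
  ord <- order(keys[, 1], keys[, 2], keys[, 3])
  keys <- keys[ord, , drop = FALSE]
  rank_of <- function(b) {
    k <- band_key(b)
    which(keys[, 1] == k[1] & keys[, 2] == k[2] & keys[, 3] == k[3]) - 1L
  }
  bed <- data.frame(
    chrom = "X_ordinal",
    start = vapply(intervals, function(i) rank_of(i$start), integer(1)),
    end = vapply(intervals, function(i) rank_of(i$end), integer(1)) + 1L,
    name = names,
    interval = vapply(intervals, format, character(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste(
      "# ordinal coordinates: 0-based half-open ranks of cytological bands",
      "on the X band order; not physical positions"), con)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(bed)
}
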