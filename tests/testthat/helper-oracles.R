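# Brute-force oracles and fixture builders, independent of the code paths
# they check.

# Full enumeration of a band universe in cytological order: euchromatic
# (division, letter, band) triples lexicographically, then h-blocks.
# Returns a list of cyto_band objects whose list order IS the band order.
enumerate_band_universe <- function(max_division = 20, max_band = 5) {
  out <- list()
  for (d in seq_len(max_division))
    for (l in LETTERS[1:6])
      for (b in seq_len(max_band))
        out[[length(out) + 1L]] <- cyto_band(d, l, b)
  for (h in 25:29)
    out[[length(out) + 1L]] <- cyto_band(h, het = TRUE)
  out
}

# A 50-band axis: divisions 1-10 x subdivisions A-E, band 1 each.
band_axis_50 <- function() {
  out <- list()
  for (d in 1:10)
    for (l in LETTERS[1:5])
      out[[length(out) + 1L]] <- cyto_band(d, l, 1)
  out
}

# Interval over an explicit axis, by index pair; also returns its index set
# so set operations can serve as the overlap/intersection oracle.
axis_interval <- function(axis, i, j) {
  list(interval = cyto_interval(axis[[i]], axis[[j]]), idx = i:j)
}

random_axis_intervals <- function(axis, n) {
  lapply(seq_len(n), function(k) {
    ij <- sort(sample(length(axis), 2, replace = TRUE))
    axis_interval(axis, ij[1], ij[2])
  })
}

# Exhaustive minimum piercing over candidate right-endpoint indices:
# smallest subset of endpoints such that every interval (as an index range)
# contains at least one.
brute_force_piercing <- function(idx_sets) {
  if (!length(idx_sets)) return(0L)
  candidates <- sort(unique(vapply(idx_sets, max, integer(1))))
  for (size in seq_along(candidates)) {
    combos <- utils::combn(candidates, size, simplify = FALSE)
    for (pts in combos) {
      if (all(vapply(idx_sets, function(s) any(pts %in% s), logical(1))))
        return(size)
    }
  }
  length(idx_sets)
}

# One-cross replicate table in the viability schema, from explicit counts.
make_counts <- function(n_fertilized, n_hatched, n_pupae, n_adults,
                        inseminated = TRUE, replicate = 1L) {
  data.frame(replicate = replicate, n_fertilized = n_fertilized,
             n_hatched = n_hatched, n_pupae = n_pupae,
             n_adults = n_adults,
             n_adults_female = 0L,
             inseminated = inseminated)
}

# Replicate table whose pooled survivals equal the given proportions
# (denominators chosen so the products are integers).
counts_with_survivals <- function(emb, larv, pup, n_fertilized = 400) {
  h <- round(n_fertilized * emb)
  p <- round(h * larv)
  a <- round(p * pup)
  make_counts(n_fertilized, h, p, a)
}
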