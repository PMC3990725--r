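# Stage-structured simulator for attached-X, Dp(1;Y) crosses.
#
# A C(1)RM (or C(1)DX), Dp(1;Y) female crossed to a paternal male yields four
# Mendelian genotype classes, each 1/4 of the clutch:
#   nullo_X          Y(pat)/Dp(1;Y): dies before cellularization
#   metafemale       C(1)/X(pat): three X doses
#   attachedX_female C(1)/Y(pat)
#   dp_male          X(pat)/Dp(1;Y): the assayed class; carries the X fragment
# Survival is genotype-, species- and stage-specific; planted dominant lethal
# loci additionally kill dp_male carriers at their lethal stage.

GENOTYPES <- c("nullo_X", "metafemale", "attachedX_female", "dp_male")
STAGES <- c("embryonic", "larval", "pupal")
SPECIES <- c("santomea", "simulans", "mauritiana", "melanogaster")
BACKGROUNDS <- c("C1RM", "C1DX")

#' Describe a paternal line
#'
#' @param species One of `"santomea"`, `"simulans"`, `"mauritiana"`,
#'   `"melanogaster"` (the last for intraspecific control crosses).
#' @param line Free-text line label (e.g. `"SYN2005"`, `"Malawi-6-3"`).
#' @param Ks Nonnegative synonymous divergence from the maternal
#'   D. melanogaster stock (substitutions per site); intraspecific lines
#'   carry the within-species polymorphism proxy instead.
#' @return A `paternal_line` object.
#' @export
paternal_line <- function(species, line, Ks) {
  species <- match.arg(species, SPECIES)
  if (!is.numeric(Ks) || length(Ks) != 1L || is.na(Ks) || Ks < 0)
    stop("Ks must be a single nonnegative number", call. = FALSE)
  structure(list(species = species, line = line, Ks = Ks),
            class = "paternal_line")
}

#' Define a planted dominant lethal locus
#'
#' A point locus (single band) that kills dp_male carriers at one
#' developmental stage with the given penetrance, but only in crosses to
#' the listed paternal species — emulating a dominant partner of a
#' lineage-specific Dobzhansky-Muller incompatibility.
#'
#' @param position A [cyto_band()] or band string.
#' @param lethal_stage `"embryonic"`, `"larval"` or `"pupal"`.
#' @param penetrance Death probability in carriers, in `[0, 1]`.
#' @param species Nonempty character vector of paternal species in which
#'   the locus acts.
#' @return A `planted_locus` object.
#' @export
planted_locus <- function(position, lethal_stage, penetrance = 1,
                          species = "santomea") {
  if (is.character(position)) position <- parse_band(position)
  stopifnot(inherits(position, "cyto_band"))
  lethal_stage <- match.arg(lethal_stage, STAGES)
  if (!is.numeric(penetrance) || penetrance < 0 || penetrance > 1)
    stop("penetrance must be in [0, 1]", call. = FALSE)
  species <- match.arg(species, SPECIES, several.ok = TRUE)
  if (!length(species)) stop("species set must be nonempty", call. = FALSE)
  structure(list(position = position, lethal_stage = lethal_stage,
                 penetrance = penetrance, species = species),
            class = "planted_locus")
}

#' Default stage-survival table
#'
#' Per (species, genotype, stage-transition) survival probabilities encoding
#' the qualitative biology of the crosses: nullo-X embryos never hatch; in
#' crosses to D. santomea both female classes predominantly die as embryos
#' (escaper rate 0.05); in crosses to D. simulans or D. mauritiana the female
#' classes survive embryonic and larval stages but never pupate; dp_male
#' baseline survival is 0.9 per stage in every cross; intraspecific
#' D. melanogaster attached-X females survive like males while metafemales
#' are lost almost entirely as larvae (survival to eclosion well under 0.2%
#' of females).
#'
#' @return A data.frame with columns `species`, `genotype`, `transition`,
#'   `p`.
#' @export
default_survival_table <- function() {
  tab <- expand.grid(species = SPECIES, genotype = GENOTYPES,
                     transition = STAGES, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  tab$p <- 0.9
  set_p <- function(tab, species, genotype, transition, p) {
    sel <- tab$species %in% species & tab$genotype %in% genotype &
      tab$transition %in% transition
    tab$p[sel] <- p
    tab
  }
  tab <- set_p(tab, SPECIES, "nullo_X", STAGES, 0)
  tab <- set_p(tab, "santomea", c("metafemale", "attachedX_female"),
               "embryonic", 0.05)
  tab <- set_p(tab, "santomea", c("metafemale", "attachedX_female"),
               c("larval", "pupal"), 0)
  tab <- set_p(tab, c("simulans", "mauritiana"),
               c("metafemale", "attachedX_female"), "pupal", 0)
  tab <- set_p(tab, "melanogaster", "metafemale", "larval", 0.002)
  tab
}

validate_survival <- function(survival) {
  need <- c("species", "genotype", "transition", "p")
  if (!all(need %in% names(survival)))
    stop("survival table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(survival$p)) || any(survival$p < 0 | survival$p > 1))
    stop("survival probabilities must all lie in [0, 1]", call. = FALSE)
  invisible(survival)
}

survival_lookup <- function(survival, species) {
  sub <- survival[survival$species == species, ]
  get <- function(genotype, transition) {
    p <- sub$p[sub$genotype == genotype & sub$transition == transition]
    if (length(p) != 1L)
      stop("survival table has no unique entry for (", species, ", ",
           genotype, ", ", transition, ")", call. = FALSE)
    p
  }
  get
}

# Death multipliers on dp_male survival from planted loci carried by the
# duplication, one per stage transition.
locus_factors <- function(duplication, loci, species) {
  fac <- c(embryonic = 1, larval = 1, pupal = 1)
  if (is.null(duplication) || !length(loci)) return(fac)
  for (locus in loci) {
    if (species %in% locus$species &&
        band_in_interval(locus$position, duplication)) {
      fac[locus$lethal_stage] <- fac[locus$lethal_stage] *
        (1 - locus$penetrance)
    }
  }
  fac
}

#' Simulate one cross series
#'
#' Draws `n_replicates` clutches for a single (duplication, background,
#' paternal line) cross. Each clutch is a symmetric four-way multinomial
#' over the Mendelian genotype classes; survival through each stage
#' transition is binomial thinning at the table's probabilities, with
#' dp_male carriers of planted loci additionally killed at the locus's
#' lethal stage with probability equal to its penetrance. Post-embryonic
#' tallies (`n_pupae`, `n_adults`) are male-only, emulating the sex-sorting
#' of the protocol; adult females are carried in an extra column so sex
#' ratios remain computable. Deterministic given `seed` and parameters.
#'
#' @param background `"C1RM"` or `"C1DX"`.
#' @param paternal A [paternal_line()].
#' @param duplication A [cyto_interval()], interval string, or `NULL` for a
#'   cross without a Dp(1;Y) fragment.
#' @param loci List of [planted_locus()] objects.
#' @param survival Survival table as from [default_survival_table()].
#' @param clutch_size Fertilized embryos per replicate (>= 1).
#' @param n_replicates Number of replicate clutches.
#' @param seed Integer seed for this cross.
#' @param inseminated Logical; `FALSE` marks a failed mating (no progeny).
#' @param count_nullo Count nullo-X embryos inside `n_fertilized` (default
#'   `TRUE`: the census counts all fertilized embryos, dead and hatched;
#'   `FALSE` excludes them as grossly indistinguishable from unfertilized
#'   eggs, for sensitivity analysis).
#' @return A data.frame with one row per replicate: `replicate`,
#'   `n_fertilized`, `n_hatched`, `n_pupae`, `n_adults`, `n_adults_female`,
#'   `inseminated`.
#' @export
simulate_cross <- function(background, paternal, duplication = NULL,
                           loci = list(),
                           survival = default_survival_table(),
                           clutch_size = 300, n_replicates = 3, seed = 1L,
                           inseminated = TRUE, count_nullo = TRUE) {
  background <- match.arg(background, BACKGROUNDS)
  stopifnot(inherits(paternal, "paternal_line"))
  if (is.character(duplication)) duplication <- parse_interval(duplication)
  if (!is.null(duplication)) stopifnot(inherits(duplication, "cyto_interval"))
  if (!is.numeric(clutch_size) || clutch_size < 1)
    stop("clutch_size must be at least 1", call. = FALSE)
  validate_survival(survival)
  if (inherits(loci, "planted_locus")) loci <- list(loci)

  sv <- survival_lookup(survival, paternal$species)
  fac <- locus_factors(duplication, loci, paternal$species)

  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- n_replicates
  if (!inseminated || n == 0L) {
    return(data.frame(replicate = seq_len(n), n_fertilized = integer(n),
                      n_hatched = integer(n), n_pupae = integer(n),
                      n_adults = integer(n), n_adults_female = integer(n),
                      inseminated = rep(FALSE, n)))
  }
  g <- stats::rmultinom(n, clutch_size, rep(0.25, 4))
  rownames(g) <- GENOTYPES

  hatch <- matrix(0L, 4, n, dimnames = list(GENOTYPES, NULL))
  for (gt in GENOTYPES) {
    p <- sv(gt, "embryonic")
    if (gt == "dp_male") p <- p * fac["embryonic"]
    hatch[gt, ] <- stats::rbinom(n, g[gt, ], p)
  }
  pupae_m <- stats::rbinom(n, hatch["dp_male", ],
                           sv("dp_male", "larval") * fac["larval"])
  adults_m <- stats::rbinom(n, pupae_m,
                            sv("dp_male", "pupal") * fac["pupal"])
  # female classes thinned sequentially (class-specific larval/pupal rates)
  pup_f_att <- stats::rbinom(n, hatch["attachedX_female", ],
                             sv("attachedX_female", "larval"))
  pup_f_meta <- stats::rbinom(n, hatch["metafemale", ],
                              sv("metafemale", "larval"))
  adults_f <- stats::rbinom(n, pup_f_att, sv("attachedX_female", "pupal")) +
    stats::rbinom(n, pup_f_meta, sv("metafemale", "pupal"))

  n_fert <- colSums(g)
  if (!count_nullo) n_fert <- n_fert - g["nullo_X", ]
  data.frame(replicate = seq_len(n),
             n_fertilized = as.integer(n_fert),
             n_hatched = as.integer(colSums(hatch)),
             n_pupae = as.integer(pupae_m),
             n_adults = as.integer(adults_m),
             n_adults_female = as.integer(adults_f),
             inseminated = rep(TRUE, n))
}

# Stable 32-bit FNV-1a string hash, folded with the root seed so every
# cross gets its own reproducible stream.
string_hash <- function(text) {
  h <- 2166136261
  for (code in utf8ToInt(text)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h)
}

cross_seed <- function(root_seed, stock_id, background, species, line) {
  key <- paste(stock_id, background, species, line, sep = "|")
  as.integer((as.numeric(root_seed) + string_hash(key)) %% (2^31 - 1))
}

#' Simulate a whole duplication screen
#'
#' Runs [simulate_cross()] for every duplication x background x paternal
#' line combination of a panel, with per-cross seeds derived by stable
#' hashing so any single cross is independently reproducible from the root
#' seed. A configurable fraction of crosses can be marked failed (not
#' inseminated, no progeny) to exercise the downstream exclusion filters.
#'
#' @param panel data.frame with columns `stock_id`, `dp_name`, `interval`
#'   (band-notation extent), as from [make_tiling_panel()] or
#'   [read_panel()].
#' @param lines List of [paternal_line()] objects.
#' @param loci List of [planted_locus()] objects.
#' @param survival Survival table.
#' @param clutch_size,n_replicates Per-cross census parameters.
#' @param seed Root integer seed.
#' @param backgrounds Attached-X backgrounds to cross (default both).
#' @param fail_fraction Fraction of crosses marked as failed matings.
#' @return A data.frame in the viability-table schema: `stock_id`,
#'   `background`, `paternal_species`, `line`, `replicate`, `n_fertilized`,
#'   `n_hatched`, `n_pupae`, `n_adults`, `n_adults_female`, `inseminated`.
#' @export
simulate_panel <- function(panel, lines, loci = list(),
                           survival = default_survival_table(),
                           clutch_size = 300, n_replicates = 3, seed = 1L,
                           backgrounds = BACKGROUNDS, fail_fraction = 0) {
  if (!nrow(panel)) stop("panel must be nonempty", call. = FALSE)
  if (anyDuplicated(panel$stock_id))
    stop("duplicate stock ids in panel: ",
         paste(unique(panel$stock_id[duplicated(panel$stock_id)]),
               collapse = ", "), call. = FALSE)
  if (inherits(lines, "paternal_line")) lines <- list(lines)
  intervals <- lapply(panel$interval, parse_interval)

  combos <- expand.grid(stock = seq_len(nrow(panel)),
                        background = backgrounds,
                        line = seq_along(lines),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # failed matings chosen reproducibly from the root seed
  fail <- rep(FALSE, nrow(combos))
  if (fail_fraction > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    fail <- stats::runif(nrow(combos)) < fail_fraction
  }
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    si <- combos$stock[i]
    li <- combos$line[i]
    pat <- lines[[li]]
    counts <- simulate_cross(
      background = combos$background[i], paternal = pat,
      duplication = intervals[[si]], loci = loci, survival = survival,
      clutch_size = clutch_size, n_replicates = n_replicates,
      seed = cross_seed(seed, panel$stock_id[si], combos$background[i],
                        pat$species, pat$line),
      inseminated = !fail[i])
    out[[i]] <- cbind(
      data.frame(stock_id = panel$stock_id[si],
                 background = combos$background[i],
                 paternal_species = pat$species, line = pat$line,
                 stringsAsFactors = FALSE),
      counts)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("stock_id", "background", "paternal_species", "line", "replicate",
          "n_fertilized", "n_hatched", "n_pupae", "n_adults",
          "n_adults_female", "inseminated")]
}

#' Build a non-overlapping tiling panel of X duplications
#'
#' Produces `2 * n_divisions` Dp(1;Y) stocks tiling euchromatic divisions
#' `1..n_divisions`, two half-division tiles per division (`dA-dC` and
#' `dD-dF`, completed outward), mimicking the structure of a Y-linked
#' X-duplication panel.
#'
#' @param n_divisions Number of divisions to tile (default 20, i.e. a
#'   40-stock panel over the whole euchromatic X).
#' @return A panel data.frame (`stock_id`, `dp_name`, `interval`).
#' @export
make_tiling_panel <- function(n_divisions = 20) {
  stopifnot(n_divisions >= 1, n_divisions <= 20)
  rows <- list()
  k <- 0L
  for (d in seq_len(n_divisions)) {
    for (half in c("A-%dC", "D-%dF")) {
      k <- k + 1L
      iv <- paste0(d, sprintf(half, d))
      rows[[k]] <- data.frame(
        stock_id = sprintf("DPX%03d", k),
        dp_name = sprintf("Dp(1;Y)SYN%03d", k),
        interval = iv, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default planted lethal architecture of the simulated study
#'
#' Twelve loci acting in crosses to D. santomea (nine embryonic, three
#' pupal), of which the pupal locus at 4C3 also acts in D. simulans and
#' D. mauritiana; one additional larval locus at 9D4 (the Hmr/CG11160
#' neighbourhood) acting in D. simulans and D. mauritiana only. No locus
#' acts intraspecifically. Each locus falls in a distinct tile of the
#' default 40-stock panel, so full recovery yields region counts
#' (9, 0, 3) for santomea, 2 each for simulans and mauritiana, and 0 for
#' the intraspecific controls.
#'
#' @param penetrance Penetrance applied to every locus (default 1).
#' @return A list of [planted_locus()] objects.
#' @export
default_planted_loci <- function(penetrance = 1) {
  sidekick <- c("simulans", "mauritiana")
  emb <- c("2B2", "3E1", "5B1", "6E2", "7B3", "11C3", "12D1", "13B2", "17A2")
  loci <- lapply(emb, planted_locus, lethal_stage = "embryonic",
                 penetrance = penetrance, species = "santomea")
  loci <- c(loci, list(
    planted_locus("4C3", "pupal", penetrance,
                  species = c("santomea", sidekick)),
    planted_locus("17E3", "pupal", penetrance, species = "santomea"),
    planted_locus("19B1", "pupal", penetrance, species = "santomea"),
    planted_locus("9D4", "larval", penetrance, species = sidekick)))
  loci
}

#' Default paternal lines of the simulated study
#'
#' One line per interspecific cross with genome-wide synonymous divergence
#' from D. melanogaster (Ks 0.24 to D. santomea; 0.11 to D. simulans and,
#' assuming equidistance, to D. mauritiana) and two intraspecific
#' D. melanogaster lines at the maximal within-species polymorphism proxy
#' (pi = 0.03).
#'
#' @return A list of [paternal_line()] objects.
#' @export
default_study_lines <- function() {
  list(paternal_line("santomea", "SYN2005", 0.24),
       paternal_line("simulans", "FloridaCity", 0.11),
       paternal_line("mauritiana", "SYN", 0.11),
       paternal_line("melanogaster", "Malawi-6-3", 0.03),
       paternal_line("melanogaster", "Malawi-9-2", 0.03))
}
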