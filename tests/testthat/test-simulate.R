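san_line <- function() paternal_line("santomea", "SYN2005", 0.24)
mel_line <- function() paternal_line("melanogaster", "Malawi-6-3", 0.03)

test_that("constructors validate their domains", {
  expect_error(paternal_line("santomea", "x", -0.1), "nonnegative")
  expect_error(paternal_line("bogus", "x", 0.1))
  expect_error(planted_locus("2C1", "embryonic", penetrance = 1.2),
               "penetrance")
  expect_error(planted_locus("2C1", "embryonic", species = character(0)))
  expect_error(simulate_cross("C1RM", san_line(), clutch_size = 0),
               "clutch_size")
  bad <- default_survival_table()
  bad$p[5] <- 1.4
  expect_error(simulate_cross("C1RM", san_line(), survival = bad),
               "\\[0, 1\\]")
})

test_that("censuses are deterministic given the seed and monotone in stage", {
  a <- simulate_cross("C1RM", san_line(), duplication = "4A-4F",
                      clutch_size = 250, n_replicates = 5, seed = 99)
  b <- simulate_cross("C1RM", san_line(), duplication = "4A-4F",
                      clutch_size = 250, n_replicates = 5, seed = 99)
  expect_identical(a, b)
  for (seed in 1:25) {
    x <- simulate_cross("C1RM", san_line(), clutch_size = 120,
                        n_replicates = 3, seed = seed)
    expect_true(all(x$n_fertilized >= x$n_hatched))
    expect_true(all(x$n_hatched >= x$n_pupae))
    expect_true(all(x$n_pupae >= x$n_adults))
    expect_true(all(x$n_adults >= 0))
  }
})

test_that("with unit survival and no loci every individual reaches adulthood", {
  all_live <- default_survival_table()
  all_live$p <- 1
  x <- simulate_cross("C1RM", san_line(), survival = all_live,
                      clutch_size = 200, n_replicates = 20, seed = 5)
  expect_true(all(x$n_hatched == x$n_fertilized))
  # no attrition within the male cohort
  expect_true(all(x$n_adults == x$n_pupae))
  # male and female adults together account for the three non-nullo
  # genotype quarters of the clutch (nullo-X never enter the sexed tallies)
  frac <- sum(x$n_adults + x$n_adults_female) / sum(x$n_fertilized)
  se <- sqrt(0.75 * 0.25 / sum(x$n_fertilized))
  expect_lt(abs(frac - 0.75), 4 * se)
})

test_that("genotype fractions converge to 1/4 and hatch rate matches theory", {
  # locus-free santomea cross: only dp_male hatch (0.25 * 0.9), female
  # escapers at 0.05 add 2 * 0.25 * 0.05
  x <- simulate_cross("C1RM", san_line(), duplication = "5A-5F",
                      clutch_size = 400, n_replicates = 30, seed = 21)
  hatch_frac <- sum(x$n_hatched) / sum(x$n_fertilized)
  expected <- 0.25 * 0.9 + 2 * 0.25 * 0.05
  se <- sqrt(expected * (1 - expected) / sum(x$n_fertilized))
  expect_lt(abs(hatch_frac - expected), 4 * se)
})

test_that("planted loci kill carriers at their stage with given penetrance", {
  dup <- "5A-5F"
  lethal <- planted_locus("5C2", "embryonic", 1, "santomea")
  x <- simulate_cross("C1RM", san_line(), duplication = dup,
                      loci = list(lethal), clutch_size = 400,
                      n_replicates = 10, seed = 31)
  # only female escapers hatch: ~2.5% of the clutch, far below 10%
  expect_lt(sum(x$n_hatched) / sum(x$n_fertilized), 0.10)

  # penetrance 0 is byte-identical to the no-locus draw at the same seed
  null_locus <- planted_locus("5C2", "embryonic", 0, "santomea")
  x0 <- simulate_cross("C1RM", san_line(), duplication = dup,
                       loci = list(null_locus), clutch_size = 400,
                       n_replicates = 10, seed = 31)
  x1 <- simulate_cross("C1RM", san_line(), duplication = dup,
                       clutch_size = 400, n_replicates = 10, seed = 31)
  expect_identical(x0, x1)

  # a locus outside the duplication, or scoped to another species, is inert
  x2 <- simulate_cross("C1RM", san_line(), duplication = dup,
                       loci = list(planted_locus("6A1", "embryonic", 1,
                                                 "santomea")),
                       clutch_size = 400, n_replicates = 10, seed = 31)
  expect_identical(x2, x1)
  x3 <- simulate_cross("C1RM", san_line(), duplication = dup,
                       loci = list(planted_locus("5C2", "embryonic", 1,
                                                 "simulans")),
                       clutch_size = 400, n_replicates = 10, seed = 31)
  expect_identical(x3, x1)

  # pupal-stage locus empties eclosion but not earlier transitions
  xp <- simulate_cross("C1RM", san_line(), duplication = dup,
                       loci = list(planted_locus("5C2", "pupal", 1,
                                                 "santomea")),
                       clutch_size = 400, n_replicates = 10, seed = 31)
  expect_gt(sum(xp$n_pupae), 0)
  expect_equal(sum(xp$n_adults), 0)
})

test_that("simulate_panel covers every cross combination reproducibly", {
  panel <- make_tiling_panel(2)[1:3, ]
  lines <- list(san_line())
  a <- simulate_panel(panel, lines, seed = 77)
  b <- simulate_panel(panel, lines, seed = 77)
  expect_identical(a, b)
  # 3 duplications x 2 backgrounds x 1 species, 3 replicates each
  expect_equal(nrow(a), 3 * 2 * 1 * 3)
  combos <- unique(a[, c("stock_id", "background")])
  expect_equal(nrow(combos), 6)

  dup_panel <- rbind(panel, panel[1, ])
  expect_error(simulate_panel(dup_panel, lines, seed = 1), "duplicate")

  # failed matings are flagged not inseminated with zero counts
  f <- simulate_panel(panel, lines, seed = 77, fail_fraction = 1)
  expect_true(all(!f$inseminated))
  expect_true(all(f$n_fertilized == 0))
})

test_that("a cross is reproducible independently of the rest of the panel", {
  panel <- make_tiling_panel(3)
  full <- simulate_panel(panel, list(san_line()), seed = 13)
  solo <- simulate_panel(panel[4, , drop = FALSE], list(san_line()),
                         seed = 13)
  got <- full[full$stock_id == panel$stock_id[4], ]
  rownames(got) <- NULL
  expect_identical(got, solo)
})

test_that("intraspecific crosses eclose adults at a 1:1 sex ratio", {
  panel <- make_tiling_panel(5)
  x <- simulate_panel(panel, list(mel_line()), clutch_size = 400,
                      seed = 8)
  males <- sum(x$n_adults)
  females <- sum(x$n_adults_female)
  res <- chisq_homogeneity(rbind(c(males, females),
                                 c((males + females) / 2,
                                   (males + females) / 2)))
  expect_gt(res$p, 0.01)
  expect_lt(abs(males / females - 1), 0.1)
})
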