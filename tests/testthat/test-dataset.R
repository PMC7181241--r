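test_that("mole fractions follow the mass/molar-mass definition", {
  ect <- substance("emtricitabine", 247.24)
  peg <- substance("PEG-400", 400)
  h2o <- substance("water", 18.07)

  # one mole of each component -> 0.5 by symmetry
  expect_equal(mole_fraction(247.24, 400, 0, ect, peg), 0.5)
  # hand-computed: 2.4724/247.24 = 0.01 mol, 4.0/400 = 0.01 mol
  expect_equal(mole_fraction(2.4724, 4.0, 0, ect, peg), 0.5)
  # hand-computed ternary: moles 0.02, 0.03, 0.05 -> 0.2
  expect_equal(mole_fraction(0.02 * 247.24, 0.03 * 400, 0.05 * 18.07,
                             ect, peg, h2o), 0.2)
  # equal mole counts of all three -> 1/3
  expect_equal(mole_fraction(247.24, 400, 18.07, ect, peg, h2o), 1 / 3)
  # vanishing solute mass drives the fraction to zero
  expect_lt(mole_fraction(1e-12, 4, 0, ect, peg), 1e-9)
  # ternary with m3 = 0 reduces exactly to the binary form
  expect_identical(mole_fraction(1.3, 2.7, 0, ect, peg, h2o),
                   mole_fraction(1.3, 2.7, 0, ect, peg))

  expect_error(mole_fraction(0, 1, 0, ect, peg), "positive")
  expect_error(mole_fraction(1, 0, 0, ect, peg), "solvent")
  expect_error(substance("x", -1), "positive")
})

test_that("mole fractions are invariant under common rescaling of masses", {
  ect <- substance("s", 247.24); peg <- substance("c", 400)
  h2o <- substance("w", 18.07)
  set.seed(11)
  for (k in 1:25) {
    masses <- runif(3, 0.01, 10)
    scale <- runif(1, 0.1, 100)
    expect_equal(
      mole_fraction(masses[1], masses[2], masses[3], ect, peg, h2o),
      mole_fraction(scale * masses[1], scale * masses[2], scale * masses[3],
                    ect, peg, h2o),
      tolerance = 1e-12)
  }
})

test_that("solubility_table validates and canonicalises its grid", {
  x <- matrix(c(0.01, 0.02, 0.03, 0.06), nrow = 2, byrow = TRUE)
  tab <- solubility_table(c(0, 1), c(300, 310), x)
  expect_s3_class(tab, "solubility_table")

  # shuffled input is sorted with the matrix permuted consistently
  shuf <- solubility_table(c(1, 0), c(310, 300), x[2:1, 2:1])
  expect_equal(shuf$m, tab$m)
  expect_equal(shuf$temperature, tab$temperature)
  expect_equal(unname(shuf$x), unname(tab$x))

  expect_error(solubility_table(c(0, 1), 300, x), "matrix must be")
  expect_error(solubility_table(c(0, 1.2), c(300, 310), x), "\\[0, 1\\]")
  expect_error(solubility_table(c(0, 0), c(300, 310), x), "duplicate")
  expect_error(solubility_table(c(0, 1), c(-5, 310), x), "positive")
  expect_error(solubility_table(c(0, 1), c(300, 310),
                                matrix(c(0.1, NA, 0.2, 0.3), 2)),
               "missing solubility at")
  expect_error(solubility_table(c(0, 1), c(300, 310),
                                matrix(c(0.1, 1.2, 0.2, 0.3), 2)),
               "out of \\(0, 1\\)")
})

test_that("the packaged emtricitabine fixture matches the published grid", {
  ect <- ect_solubility()
  expect_equal(ect$m, ect_m)
  expect_equal(ect$temperature, ect_temps)
  # published spot values
  expect_identical(unname(ect$x["0.0", "298.2"]), 7.95e-3)
  expect_identical(unname(ect$x["1.0", "318.2"]), 1.45e-1)
  expect_identical(unname(ect$x["0.5", "308.2"]), 3.47e-2)
  expect_identical(unname(ect$x["0.9", "313.2"]), 1.03e-1)
  # substance metadata
  expect_equal(ect$solute$molar_mass, 247.24)
  expect_equal(ect$cosolvent$molar_mass, 400)
  expect_equal(ect$antisolvent$molar_mass, 18.07)
})

test_that("fixture transcription is exact at string level", {
  path <- system.file("extdata", "ect_peg400_water.csv",
                      package = "cosolvency", mustWork = TRUE)
  body <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  expect_identical(body[body != ""][1:3], c(
    "m,298.2,303.2,308.2,313.2,318.2",
    "0.0,7.95e-3,8.74e-3,9.53e-3,1.05e-2,1.15e-2",
    "0.1,1.01e-2,1.11e-2,1.19e-2,1.30e-2,1.44e-2"))
  expect_identical(body[body != ""][12],
                   "1.0,1.06e-1,1.16e-1,1.25e-1,1.33e-1,1.45e-1")
})

test_that("fixture solubility is strictly increasing in T and in m", {
  ect <- ect_solubility()
  expect_true(all(apply(ect$x, 1, diff) > 0))  # along temperature
  expect_true(all(apply(ect$x, 2, diff) > 0))  # along composition
})

test_that("tables round-trip through delimited text and JSON", {
  ect <- ect_solubility()
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_solubility_table(ect, path)
    back <- read_solubility_table(path)
    expect_equal(unname(back$x), unname(ect$x), tolerance = 0)
    expect_equal(back$m, ect$m)
    expect_equal(back$temperature, ect$temperature)
    expect_equal(back$solute$name, ect$solute$name)
  }
  # tab-separated with sniffed separator
  path <- withr::local_tempfile(fileext = ".tsv")
  write_solubility_table(ect, path, sep = "\t")
  expect_equal(unname(read_solubility_table(path)$x), unname(ect$x))
})

test_that("malformed tables raise parse errors naming the offending cell", {
  good <- c("m,300,310", "0.0,0.01,0.02", "1.0,0.05,0.06")
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c(good[1:2], "1.0,0.05"), path)
  expect_error(read_solubility_table(path), "row 2 is ragged")

  writeLines(c(good[1:2], "1.0,abc,0.06"), path)
  expect_error(read_solubility_table(path), "row 2.*'abc'")

  writeLines(c(good, "1.0,0.05,0.06"), path)
  expect_error(read_solubility_table(path), "duplicate composition")

  writeLines(c("q,300,310", good[2:3]), path)
  expect_error(read_solubility_table(path), "header")

  # header out of order: temperatures re-sorted, matrix permuted
  writeLines(c("m,310,300", "0.0,0.02,0.01", "1.0,0.06,0.05"), path)
  tab <- read_solubility_table(path)
  expect_equal(tab$temperature, c(300, 310))
  expect_equal(unname(tab$x[1, ]), c(0.01, 0.02))
})
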