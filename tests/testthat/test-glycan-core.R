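# Mass engine: residue masses, sodiated m/z, ppm arithmetic, enumeration,
# neutral-loss interpretation.

test_that("residue masses match the published derivatization deltas", {
  expect_equal(round(residue_mass("Fuc"), 2), 146.06)
  expect_equal(round(residue_mass("ENeuAc"), 2), 319.13)
  expect_equal(round(residue_mass("LNeuAc"), 2), 273.08)
  # Hex from IUPAC atomic masses of C6H10O5 (independent sum)
  hex_oracle <- 6 * 12 + 10 * 1.0078250319 + 5 * 15.9949146221
  expect_equal(residue_mass("Hex"), hex_oracle, tolerance = 1e-10)
  expect_error(residue_mass("Xyl"), "unknown residue class.*Xyl")
})

test_that("residue mass table is consistent with residue_mass()", {
  tab <- residue_mass_table()
  expect_setequal(tab$residue, c("Hex", "HexNAc", "Fuc", "ENeuAc", "LNeuAc"))
  expect_equal(tab$mass, residue_mass(tab$residue), tolerance = 1e-12)
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  residue_mass_table(f)
  reread <- read.delim(f)
  expect_equal(reread$mass, tab$mass, tolerance = 1e-9)
})

printed_pairs <- c(
  H3N4 = 1339.476, H4N4 = 1501.529, H5N4 = 1663.581, H4N5 = 1704.608,
  H5N5 = 1866.661, H6N5 = 2028.714,
  H3N4F1 = 1485.533, H4N4F1 = 1647.586, H5N4F1 = 1809.639,
  H4N5F1 = 1850.666, H5N5F1 = 2012.719, H6N5F1 = 2174.771
)

test_that("sodiated theoretical m/z reproduces all printed reference values", {
  computed <- theoretical_mz(names(printed_pairs))
  # to the printed precision (one unit in the third decimal)
  expect_true(all(abs(computed - printed_pairs) <= 0.0011))
})

test_that("theoretical m/z is additive in residues", {
  expect_equal(theoretical_mz("H5N4F1") - theoretical_mz("H5N4"),
               residue_mass("Fuc"), tolerance = 1e-9)
  expect_equal(theoretical_mz("H5N4E2L1") - theoretical_mz("H5N4"),
               2 * residue_mass("ENeuAc") + residue_mass("LNeuAc"),
               tolerance = 1e-9)
  expect_error(theoretical_mz(data.frame(hex = 0, hexnac = 0, fuc = 0,
                                         eneuac = 0, lneuac = 0)),
               "empty composition")
})

test_that("composition text form round-trips and omits zero counts", {
  expect_equal(format(parse_composition("H3N4F1E1L0")), "H3N4F1E1")
  expect_equal(format(parse_composition("H5N2")), "H5N2")
  expect_equal(format(glycan_composition(5, 4, fuc = 2, lneuac = 1)), "H5N4F2L1")
  expect_error(parse_composition("5H4N"), "cannot parse")
  expect_error(glycan_composition(-1, 2), "non-negative")
  expect_error(glycan_composition(0, 0), "empty composition")
})

test_that("ppm_error does signed ppm arithmetic and rejects bad input", {
  expect_equal(ppm_error(1000, 1000), 0)
  expect_equal(ppm_error(1339.503, 1339.476), 20.2, tolerance = 0.01)
  expect_lt(abs(ppm_error(1485.533, theoretical_mz("H3N4F1"))), 2)
  expect_error(ppm_error(-1, 1000), "positive")
})

test_that("enumeration finds printed assignments and respects bounds", {
  hits <- enumerate_compositions(1339.476, 20)
  expect_true("H3N4" %in% hits$composition)
  expect_equal(hits$composition[1], "H3N4")  # most probable candidate first
  expect_equal(nrow(enumerate_compositions(100, 20)), 0)
})

test_that("enumeration equals the brute-force oracle on random probes", {
  set.seed(71)
  bounds <- enum_bounds()
  probes <- c(runif(80, 1000, 3500),
              theoretical_mz(c("H3N4", "H5N4F1", "H6N5F2", "H5N4E1L1",
                               "H9N2")) * (1 + runif(5, -15, 15) * 1e-6),
              2174.771, runif(20, 900, 5100))
  for (mz in probes) {
    got <- sort(enumerate_compositions(mz, 20, bounds)$composition)
    want <- brute_force_enumeration(mz, 20, bounds)
    expect_identical(got, want)
  }
})

test_that("enumeration without the biosynthetic filter is a superset", {
  mz <- theoretical_mz("H5N4E1")
  with_filter <- enumerate_compositions(mz, 200)
  without <- enumerate_compositions(mz, 200, biosynthetic_filter = FALSE)
  expect_true(all(with_filter$composition %in% without$composition))
  expect_gt(nrow(without), nrow(with_filter))
})

test_that("neutral-loss interpretation flags residue losses", {
  hits <- interpret_losses(1809.504, 1663.420, tol_da = 0.1)
  expect_true("Fuc" %in% hits$residue)
  expect_equal(nrow(interpret_losses(1809.504, numeric(0), 0.1)), 0)
  m <- 2301.805
  hits_e <- interpret_losses(m, m - 319.127, tol_da = 0.05)
  expect_true("ENeuAc" %in% hits_e$residue)
})
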