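test_that("energy conversions use the pinned factors and compose as a group action", {
  expect_equal(convert_energy(1, "hartree", "kcal/mol"), 627.5095)
  expect_identical(convert_energy(72.9, "kcal/mol", "kcal/mol"), 72.9)
  expect_equal(convert_energy(72.9, "kcal/mol", "kJ/mol"), 72.9 * 4.184)

  units <- c("hartree", "kcal/mol", "kJ/mol", "cm-1")
  for (a in units) for (b in units) {
    x <- 72.9
    expect_equal(convert_energy(convert_energy(x, a, b), b, a), x,
                 tolerance = 1e-12)
    # A -> B -> C equals A -> C
    for (cc in units) {
      expect_equal(convert_energy(convert_energy(x, a, b), b, cc),
                   convert_energy(x, a, cc), tolerance = 1e-12)
    }
  }
  expect_error(convert_energy(1, "eV", "kcal/mol"), "unknown energy unit 'eV'")
})

test_that("thermal RT is linear in temperature and rejects non-physical input", {
  expect_equal(thermal_rt(298.15), 1.98720425e-3 * 298.15)
  expect_equal(thermal_rt(298.15), 0.59248, tolerance = 1e-4)
  expect_equal(thermal_rt(596.30), 2 * thermal_rt(298.15))
  expect_error(thermal_rt(0), "positive")
  expect_error(thermal_rt(-5), "positive")
})

test_that("species records enforce the saddle-point/minimum frequency invariants", {
  ts <- species_thermo("TS", "transition_state", 8.6, imag_frequency = -306)
  expect_equal(ts$imag_frequency, 306)  # sign convention: magnitude stored
  expect_error(species_thermo("TS", "transition_state", 8.6),
               "must carry an imaginary frequency")
  expect_error(species_thermo("M", "mecp", 8.6), "imaginary frequency")
  expect_error(species_thermo("RC", "reactant_complex", -2, imag_frequency = 100),
               "must not carry")
  expect_error(species_thermo("X", "intermediate", 0), "'arg' should be one of")
  expect_error(species_thermo("X", "reactant", 0, multiplicity = 0),
               "positive integer")
})

test_that("species table reader normalizes units, validates rows, and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment line",
    "name\trole\tG\tG_unit\tnu_imag_cm1\tmultiplicity",
    "RC\treactant_complex\t-2.5\tkcal/mol\t\t1",
    "TS\ttransition_state\t0.01\thartree\t-1551\t1",
    "PC\tproduct_complex\t-30\tkcal/mol\t\t1"), path)
  sp <- read_species_table(path)
  expect_length(sp, 3)
  expect_equal(sp[[2]]$gibbs_energy, 0.01 * 627.5095)  # hartree input
  expect_equal(sp[[2]]$imag_frequency, 1551)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_species_table(sp, out)
  sp2 <- read_species_table(out)
  expect_equal(sp2, sp)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\trole\tG\tG_unit\tnu_imag_cm1\tmultiplicity",
               "TS\ttransition_state\t10\tkcal/mol\t\t1"), bad)
  expect_error(read_species_table(bad), "row 1")

  shortcols <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\trole\tG", "A\treactant\t0"), shortcols)
  expect_error(read_species_table(shortcols), "missing column")

  badrole <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\trole\tG\tG_unit\tnu_imag_cm1\tmultiplicity",
               "A\tweird_role\t0\tkcal/mol\t\t1"), badrole)
  expect_error(read_species_table(badrole), "row 1")
})
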