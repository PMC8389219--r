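test_that("Eyring rates reproduce reference barrier kinetics and the exponential law", {
  # reference rows: 3-sig-fig barrier inputs, so 5-10% agreement expected
  expect_equal(eyring_rate(72.9), 2.3e-41, tolerance = 0.05)
  expect_equal(eyring_rate(23.9), 1.9e-5, tolerance = 0.05)
  expect_equal(eyring_rate(0), 6.212e12, tolerance = 1e-3)

  # halves for every +RT*ln(2) added to the barrier, exactly
  rt <- thermal_rt(298.15)
  for (dg in seq(2, 40, by = 7)) {
    expect_equal(eyring_rate(dg + rt * log(2)), eyring_rate(dg) / 2,
                 tolerance = 1e-12)
  }
  expect_true(all(diff(eyring_rate(c(5, 10, 20, 40))) < 0))  # monotone
  expect_error(eyring_rate(Inf), "finite")
  expect_error(eyring_rate(10, sigma = 0), "sigma")
})

test_that("Wigner coefficient matches hand-evaluated values and its limit", {
  expect_equal(wigner_kappa(1384, 298.15), 2.86, tolerance = 2e-3)
  expect_equal(wigner_kappa(838, 298.15), 1.68, tolerance = 3e-3)
  expect_equal(wigner_kappa(1e-6, 298.15), 1, tolerance = 1e-9)
  expect_error(wigner_kappa(-5), "imag_frequency")
})

test_that("Eckart thermal average has the right limits and magnitudes", {
  # no-tunneling limit
  expect_equal(eckart_kappa(eckart_barrier(10, 12, 1e-2)), 1, tolerance = 1e-3)
  # high-temperature symmetric regime agrees with the independent Wigner form
  ksym <- eckart_kappa(eckart_barrier(10, 10, 500, 298.15))
  expect_equal(ksym, wigner_kappa(500, 298.15), tolerance = 0.1)
  # strongly asymmetric proton-transfer barrier: same order as ~10
  kasym <- eckart_kappa(eckart_barrier(23.9, 48.2, 1384))
  expect_gt(kasym, 3); expect_lt(kasym, 40)
  # kappa approaches 1 from above as T grows, for fixed finite barriers
  kT <- vapply(c(298.15, 600, 1200, 2400), function(T)
    eckart_kappa(eckart_barrier(12, 20, 900, T)), numeric(1))
  expect_true(all(diff(kT) < 0))
  expect_equal(kT[4], 1, tolerance = 0.05)
  # thermal average exceeds the classical-threshold transmission
  expect_gte(eckart_kappa(eckart_barrier(12, 20, 900)),
             eckart_transmission(12, 12, 20, 900))
  expect_error(eckart_barrier(-1, 10, 500), "positive")
})

test_that("adaptive Eckart quadrature matches a dense-grid trapezoid oracle", {
  set.seed(42)
  for (i in 1:20) {
    V1 <- runif(1, 4, 35); V2 <- runif(1, 4, 60); nu <- runif(1, 200, 1700)
    ka <- eckart_kappa(eckart_barrier(V1, V2, nu))
    kb <- eckart_kappa_bruteforce(V1, V2, nu)
    expect_equal(ka, kb, tolerance = 1e-5)
  }
})

test_that("pathway assembly reproduces a forced-kappa spin-forbidden rate and the hand formula", {
  # MECP-over-barrier path at dG_act = 8.6 kcal/mol with reported kappa 0.9
  sp <- list(
    species_thermo("A", "reactant", 0, multiplicity = 2),
    species_thermo("B", "reactant", 0, multiplicity = 2),
    species_thermo("X", "mecp", 8.6, imag_frequency = 306),
    species_thermo("P", "product", -50.4)
  )
  pr <- pathway_rate(sp, molecularity = "bimolecular", kappa = 0.9)
  expect_equal(pr$k_tst_eck, 2.8e6, tolerance = 0.1)
  expect_equal(pr$k_tst_eck, pr$kappa_eckart * pr$k_tst, tolerance = 1e-12)
  expect_equal(pr$delta_rG, -50.4)

  # barrierless: k equals the universal prefactor
  sp0 <- list(species_thermo("A", "reactant", 5),
              species_thermo("TS", "transition_state", 5, imag_frequency = 100),
              species_thermo("P", "product", -10))
  expect_equal(pathway_rate(sp0, kappa = "none")$k_tst, eyring_rate(0),
               tolerance = 1e-12)

  # randomized triples: direct re-evaluation of the closed form
  set.seed(7)
  cst <- physical_constants()
  for (i in 1:10) {
    dg <- runif(1, 3, 30); drg <- runif(1, -60, -5); nu <- runif(1, 200, 1500)
    sp <- list(species_thermo("A", "reactant", 0),
               species_thermo("RC", "reactant_complex", -runif(1, 0.5, 3)),
               species_thermo("TS", "transition_state", dg, imag_frequency = nu),
               species_thermo("PC", "product_complex", drg - runif(1, 0.5, 3)),
               species_thermo("P", "product", drg))
    pr <- pathway_rate(sp)
    k_hand <- cst$kB_J_per_K * 298.15 / cst$h_J_s *
      exp(-dg / (cst$R_kcal * 298.15))
    expect_equal(pr$k_tst, k_hand, tolerance = 1e-12)
    expect_equal(pr$k_tst_eck, pr$kappa_eckart * k_hand, tolerance = 1e-12)
  }

  # structural validation
  expect_error(pathway_rate(sp[-3]), "exactly one")
  bad <- list(species_thermo("A", "reactant", 0),
              species_thermo("TS", "transition_state", 5, imag_frequency = 100),
              species_thermo("PC", "product_complex", 9))
  expect_error(pathway_rate(bad, kappa = "none"), "above the saddle point")
})

test_that("overall rate sums corrected constants and branches to unity", {
  mk <- function(label, k_eck) {
    structure(list(path_label = label, delta_rG = NA_real_, delta_G_act = 10,
                   imag_frequency = 300, sigma = 1L, temperature = 298.15,
                   k_tst = k_eck, kappa_eckart = 1, k_tst_eck = k_eck,
                   molecularity = "bimolecular", kappa_method = "fixed"),
              class = "pathway_rate")
  }
  paths <- Map(mk, rrc_reference$path, rrc_reference$k_tst_eck)
  ov <- overall_rate(paths)
  expect_equal(signif(ov$k_overall, 3), 3.03e6)
  expect_equal(sum(ov$branching), 1, tolerance = 1e-12)
  expect_equal(unname(ov$branching["C8"]), 0.983, tolerance = 1e-3)
  expect_gte(ov$k_overall, max(rrc_reference$k_tst_eck))

  expect_equal(unname(overall_rate(paths[1])$branching), 1)
  uni <- mk("u", 1); uni$molecularity <- "unimolecular"
  expect_error(overall_rate(c(paths[1], list(uni))), "mixed molecularity")
})

test_that("water-series report sorts by water count and flags barrier catalysis", {
  mk <- function(dg) {
    sp <- list(species_thermo("keto", "reactant", 0),
               species_thermo("TS", "transition_state", dg, imag_frequency = 1000),
               species_thermo("enol", "product", -25))
    pathway_rate(sp, kappa = "none")
  }
  paths <- lapply(taut_reference$delta_G_act, mk)
  rep <- water_series_report(taut_reference$n, paths)
  expect_equal(rep$n_waters, 0:3)
  expect_true(attr(rep, "monotone_decreasing_barrier"))

  shuffled <- water_series_report(taut_reference$n[c(3, 1, 4, 2)],
                                  paths[c(3, 1, 4, 2)])
  expect_equal(shuffled, rep)
  expect_true(attr(water_series_report(2L, paths[3]),
                   "monotone_decreasing_barrier"))
  expect_error(water_series_report(c(1, 1), paths[1:2]), "duplicate")
})

test_that("diffusion-limit classification uses the inclusive 1e7-1e10 window", {
  expect_equal(classify_diffusion_limited(2.29e9), "in_range")
  expect_equal(classify_diffusion_limited(3.03e6), "below")
  expect_equal(classify_diffusion_limited(1e10), "in_range")
  expect_equal(classify_diffusion_limited(1e7), "in_range")
  expect_equal(classify_diffusion_limited(2e10), "above")
  expect_error(classify_diffusion_limited(1e8, "unimolecular"), "bimolecular")
})
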