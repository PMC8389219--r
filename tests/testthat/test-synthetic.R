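test_that("generators are pure functions of their seed", {
  a <- gen_two_state_profile(42, "before_ts")
  b <- gen_two_state_profile(42, "before_ts")
  expect_identical(a, b)

  g1 <- gen_polyprotic(7, 3); g2 <- gen_polyprotic(7, 3)
  expect_identical(g1, g2)

  q1 <- gen_quadratic_surface_pair(5); q2 <- gen_quadratic_surface_pair(5)
  expect_identical(q1$params_A, q2$params_A)
  expect_identical(q1$truth, q2$truth)

  p1 <- gen_pathway_thermo(3, 10, -20, 900)
  p2 <- gen_pathway_thermo(3, 10, -20, 900)
  expect_identical(p1, p2)
})

test_that("planted profile crossings are recovered and classified by construction", {
  for (s in 1:20) {
    pos <- if (s %% 2 == 0) "before_ts" else "after_ts"
    g <- gen_two_state_profile(s, pos, barrier_height = 12, n_grid = 101)
    cr <- find_profile_crossings(g$profile)
    expect_gte(length(cr), 1)
    spacing <- diff(g$profile$coordinate[1:2])
    best <- cr[[which.min(abs(vapply(cr, `[[`, numeric(1), "coordinate") -
                                g$truth$crossing_coordinate))]]
    expect_lt(abs(best$coordinate - g$truth$crossing_coordinate), spacing)
    cls <- classify_crossing(best, g$profile)$relevance
    expect_equal(cls, if (pos == "before_ts") "rate_determining" else "post_barrier")
  }
})

test_that("noise widens but does not break crossing recovery", {
  g <- gen_two_state_profile(99, "before_ts", barrier_height = 15,
                             n_grid = 201, noise_sd = 0.05)
  cr <- find_profile_crossings(g$profile)
  coords <- vapply(cr, `[[`, numeric(1), "coordinate")
  expect_lt(min(abs(coords - g$truth$crossing_coordinate)), 0.1)
})

test_that("quadratic surface pairs embed an exact seam minimum the optimizer finds", {
  for (s in 1:20) {
    g <- gen_quadratic_surface_pair(s)
    # truth lies on the seam
    expect_lt(abs(g$energy_fn_A(g$truth$geometry) -
                    g$energy_fn_B(g$truth$geometry)), 1e-6)
    m <- mecp_optimize(g$energy_fn_A, g$energy_fn_B,
                       start = g$truth$geometry + 0.5)
    expect_lt(sqrt(sum((m$geometry - g$truth$geometry)^2)), 1e-4)
  }
  # generalizes beyond 2-D
  g5 <- gen_quadratic_surface_pair(7, dim = 5)
  m5 <- mecp_optimize(g5$energy_fn_A, g5$energy_fn_B,
                      start = g5$truth$geometry + 0.3)
  expect_lt(sqrt(sum((m5$geometry - g5$truth$geometry)^2)), 1e-3)
})

test_that("pathway thermochemistry generators carry their own rate constant", {
  for (s in 1:20) {
    set.seed(s + 2000)
    dg <- runif(1, 4, 30); drg <- runif(1, -60, -5); nu <- runif(1, 300, 1500)
    g <- gen_pathway_thermo(s, dg, drg, nu)
    pr <- pathway_rate(g$species)
    expect_equal(pr$k_tst, g$truth$k_tst, tolerance = 1e-10)
    expect_equal(pr$k_tst_eck, g$truth$k_tst_eck, tolerance = 1e-10)
    expect_equal(pr$kappa_eckart, g$truth$kappa, tolerance = 1e-10)
  }
  # the shape mirrors a spin-forbidden coupling row
  g <- gen_pathway_thermo(1, 8.6, -50.4, 306)
  roles <- vapply(g$species, `[[`, character(1), "role")
  expect_setequal(roles, c("reactant", "reactant_complex", "transition_state",
                           "product_complex", "product"))
  # zero barrier is rejected, prefactor path checked via the direct API
  expect_error(gen_pathway_thermo(1, 0, -10, 300), "delta_G_act > 0")
  expect_error(gen_pathway_thermo(1, 5, 10, 300), "inconsistent targets")
})

test_that("random polyprotic acids match the package fractions to machine precision", {
  for (s in 1:20) {
    g <- gen_polyprotic(seed = s, n_sites = (s %% 4) + 1L)
    f <- species_fractions(g$acid, g$ph)$fractions
    expect_equal(f, g$truth_fractions, tolerance = 1e-12)
  }
  # pKa spread > 20: no overflow
  wide <- polyprotic_acid(c(1, 25))
  expect_true(all(is.finite(species_fractions(wide, 12)$fractions)))
})
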