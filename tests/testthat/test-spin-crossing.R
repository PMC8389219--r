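test_that("profile crossings are found at nodes and by interpolation", {
  r <- 0:4
  # gap zero exactly at a node
  p1 <- state_profile(r, r - 2, rep(0, 5))
  cr1 <- find_profile_crossings(p1)
  expect_length(cr1, 1)
  expect_equal(cr1[[1]]$coordinate, 2)
  # interpolated crossing: 2r - 5 meets 1 at r = 3
  p2 <- state_profile(r, 2 * r - 5, rep(1, 5))
  cr2 <- find_profile_crossings(p2)
  expect_length(cr2, 1)
  expect_equal(cr2[[1]]$coordinate, 3)
  expect_equal(cr2[[1]]$energy, 1)
  # no crossing is an empty list, not an error
  expect_length(find_profile_crossings(state_profile(r, r + 10, rep(0, 5))), 0)
})

test_that("crossing count equals the sign-change count of the sampled gap", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    r <- sort(runif(n, 0, 10))
    lo <- rnorm(n); hi <- rnorm(n)
    gap <- lo - hi
    while (any(gap == 0)) { lo <- rnorm(n); gap <- lo - hi }
    p <- state_profile(r, lo, hi)
    expect_length(find_profile_crossings(p),
                  sum(gap[-1] * gap[-n] < 0))
  }
})

test_that("crossing classification follows the pre/post-barrier topology", {
  r <- seq(0, 4, by = 0.1)
  hi <- 10 * exp(-(r - 2)^2)          # high-spin barrier at r = 2
  lo_pre <- 12 - 8 * r                # crosses well before the TS, below it
  p <- state_profile(r, lo_pre, hi, ts_coordinate = 2)
  cr <- find_profile_crossings(p)[[1]]
  expect_equal(classify_crossing(cr, p)$relevance, "rate_determining")

  lo_post <- rep(4, length(r))        # cuts the barrier flank on both sides
  p2 <- state_profile(r, lo_post, hi, ts_coordinate = 2)
  cr2 <- find_profile_crossings(p2)
  cr2 <- cr2[[length(cr2)]]
  expect_gt(cr2$coordinate, 2)
  expect_equal(classify_crossing(cr2, p2)$relevance, "post_barrier")

  # without a TS coordinate the call is honest about not knowing
  p3 <- state_profile(r, lo_pre, hi)
  expect_equal(classify_crossing(find_profile_crossings(p3)[[1]], p3)$relevance,
               "indeterminate")

  # reversing the coordinate direction together with the TS (same traversal
  # order, mirrored axis) gives the same answer
  prev <- state_profile(-r, lo_pre, hi, ts_coordinate = -2)
  crr <- find_profile_crossings(prev)[[1]]
  expect_equal(classify_crossing(crr, prev)$relevance, "rate_determining")

  out <- cr; out$coordinate <- 99
  expect_error(classify_crossing(out, p), "outside")
})

test_that("profile TSV round trip preserves the scan and the TS annotation", {
  p <- state_profile(seq(1, 3, by = 0.5), c(5, 3, 1, -1, -3),
                     c(0, 2, 4, 2, 0), ts_coordinate = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, f)
  expect_equal(read_profile_tsv(f), p)
})

test_that("MECP optimizer solves closed-form paraboloid seams", {
  fA <- function(p) p[1]^2 + p[2]^2
  fB <- function(p) (p[1] - 2)^2 + p[2]^2
  m <- mecp_optimize(fA, fB, c(0.3, 0.7))
  expect_true(m$converged)
  expect_equal(m$geometry, c(1, 0), tolerance = 1e-4)
  expect_equal(m$energy, 1, tolerance = 1e-4)
  # converged result invariants hold under re-evaluation
  expect_lt(abs(fA(m$geometry) - fB(m$geometry)), 1e-5)

  fB2 <- function(p) (p[1] - 2)^2 + p[2]^2 + 1
  m2 <- mecp_optimize(fA, fB2, c(0.3, 0.7))
  expect_equal(m2$geometry, c(1.25, 0), tolerance = 1e-4)
  # brute-force grid seam search agrees
  bf <- grid_seam_minimum(fA, fB2, center = c(1.25, 0), half_width = 2,
                          n = 801, band = 0.02)
  expect_equal(m2$geometry, bf$geometry, tolerance = 2e-2)

  expect_error(mecp_optimize(fA, fA, c(1, 1)), "degenerate seam")
  # iteration cap returns an honest unconverged result, not an error
  m3 <- mecp_optimize(fA, fB, c(50, 90), max_iter = 1L)
  expect_false(m3$converged)
})

test_that("scan prediction then surface refinement recovers analytic crossings", {
  # 2-D paraboloids cut along y = 0
  fA <- function(p) p[1]^2 + p[2]^2
  fB <- function(p) (p[1] - 2)^2 + p[2]^2
  r <- seq(-1, 3, by = 0.25)
  prof <- state_profile(r, vapply(r, function(x) fA(c(x, 0)), numeric(1)),
                        vapply(r, function(x) fB(c(x, 0)), numeric(1)))
  res <- predict_then_refine(prof, fA, fB, embed = function(r) c(r, 0))
  expect_equal(res$predicted$coordinate, 1, tolerance = 0.25)
  expect_equal(res$refined$geometry, c(1, 0), tolerance = 1e-4)

  # 1-D parabola pairs with closed-form crossings, 20 random seeds
  set.seed(23)
  for (i in 1:20) {
    a1 <- runif(1, 0.5, 3); c1 <- runif(1, -1, 1)
    a2 <- runif(1, 0.5, 3); c2 <- c1 + runif(1, 1, 3); d <- runif(1, -2, 2)
    f1 <- function(x) a1 * (x - c1)^2
    f2 <- function(x) a2 * (x - c2)^2 + d
    disc <- function(x) f1(x) - f2(x)
    # closed-form roots of the quadratic gap
    A <- a1 - a2; B <- -2 * (a1 * c1 - a2 * c2)
    C <- a1 * c1^2 - a2 * c2^2 - d
    roots <- if (abs(A) > 1e-12) {
      D <- B^2 - 4 * A * C
      if (D < 0) next
      (-B + c(-1, 1) * sqrt(D)) / (2 * A)
    } else -C / B
    r <- seq(min(c1, c2) - 2, max(c1, c2) + 2, length.out = 81)
    roots <- roots[roots >= min(r) & roots <= max(r)]
    if (length(roots) == 0) next
    truth <- roots[which.min(vapply(roots, f1, numeric(1)))]
    prof <- state_profile(r, vapply(r, f1, numeric(1)),
                          vapply(r, f2, numeric(1)))
    if (length(find_profile_crossings(prof)) == 0) next
    res <- predict_then_refine(prof, f1, f2)
    expect_equal(res$refined$geometry, truth, tolerance = 1e-3)
  }

  flat <- state_profile(0:4, (0:4) + 5, rep(0, 5))
  expect_error(predict_then_refine(flat, fA, fB), "no crossing to refine")
})
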