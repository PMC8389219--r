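# Synthetic inputs with embedded ground truth, one generator per pipeline
# stage: two-state scans with a planted crossing, quadratic surface pairs
# with an exactly solvable crossing-seam minimum, pathway thermochemistry
# with a closed-form rate constant, and random polyprotic acids. Every
# generator is a pure function of its seed and arguments, and the truth it
# stores always refers to the noiseless construction.

#' Generate a two-state profile with a planted crossing
#'
#' Builds a high-spin curve with a Gaussian barrier (height `barrier_height`
#' at a random TS position) and a steep logistic low-spin curve pinned to
#' cross it exactly once, at a controlled position before or after the TS.
#' This mirrors the two scan topologies of spin-forbidden radical-coupling
#' steps: a pre-barrier crossing that takes over as the bottleneck, and a
#' post-barrier crossing with no kinetic consequence. The exact crossing
#' coordinate (of the noiseless construction) and the TS coordinate are
#' stored in `truth`.
#'
#' @param seed Integer seed.
#' @param crossing_position `"before_ts"` or `"after_ts"`.
#' @param barrier_height High-spin barrier height in kcal/mol (> 0).
#' @param n_grid Number of scan points (>= 3), default 101.
#' @param range Coordinate range (angstrom-like), default `c(0.5, 4)`.
#' @param noise_sd Optional Gaussian noise (kcal/mol) added to both sampled
#'   curves; 0 (off) by default.
#' @return List with `profile` (a [state_profile()]) and `truth`
#'   (`crossing_coordinate`, `crossing_energy`, `ts_coordinate`,
#'   `ts_energy`).
#' @export
gen_two_state_profile <- function(seed, crossing_position = c("before_ts", "after_ts"),
                                  barrier_height = 15, n_grid = 101L,
                                  range = c(0.5, 4), noise_sd = 0) {
  crossing_position <- match.arg(crossing_position)
  stopifnot(barrier_height > 0, n_grid >= 3L, range[2] > range[1],
            noise_sd >= 0)
  span <- range[2] - range[1]
  set.seed(as.integer(seed))
  r_ts <- range[1] + span * stats::runif(1, 0.40, 0.60)
  width <- span * stats::runif(1, 0.06, 0.10)
  # crossing offset >= width*sqrt(2 log 2) keeps the crossing energy at or
  # below half the barrier, which guarantees a single sign change
  delta <- width * stats::runif(1, sqrt(2 * log(2)), 2.5)
  r_star <- if (crossing_position == "before_ts") r_ts - delta else r_ts + delta
  if (r_star <= range[1] + 0.05 * span || r_star >= range[2] - 0.05 * span) {
    stop("infeasible geometry: requested crossing falls outside the scan window",
         call. = FALSE)
  }
  steep <- span * stats::runif(1, 0.015, 0.03)
  e_hi <- function(r) barrier_height * exp(-(r - r_ts)^2 / (2 * width^2))
  y_star <- e_hi(r_star)
  amp <- 2 * (barrier_height - y_star) + 2   # logistic swing: above B left, below 0 right
  e_lo <- function(r) y_star + amp * (1 / (1 + exp((r - r_star) / steep)) - 0.5)

  r <- seq(range[1], range[2], length.out = n_grid)
  lo <- e_lo(r)
  hi <- e_hi(r)
  if (noise_sd > 0) {
    lo <- lo + stats::rnorm(n_grid, sd = noise_sd)
    hi <- hi + stats::rnorm(n_grid, sd = noise_sd)
  }
  list(
    profile = state_profile(r, lo, hi, ts_coordinate = r_ts),
    truth = list(crossing_coordinate = r_star, crossing_energy = y_star,
                 ts_coordinate = r_ts, ts_energy = barrier_height)
  )
}

#' Generate a pair of quadratic surfaces with an exact seam minimum
#'
#' Draws two axis-aligned positive-definite quadratics
#' `E_i(x) = sum_j a_ij (x_j - c_ij)^2 + d_i` with coefficients in
#' `[0.5, 3]` and centres in `[-3, 3]`, offsets adjusted so the seam
#' `E_A = E_B` is non-empty, and solves the crossing-seam minimum of the mean
#' energy exactly via the stationarity (Lagrange) condition -- a per-
#' coordinate linear solve in the multiplier plus a guarded 1-D root search,
#' entirely independent of the iterative optimizer it serves as oracle for.
#'
#' @param seed Integer seed.
#' @param dim Dimension of the surfaces (default 2).
#' @return List with functions `energy_fn_A`, `energy_fn_B`, the parameter
#'   sets `params_A`, `params_B` (`a`, `c`, `d`), and `truth`
#'   (`geometry`, `energy` of the seam minimum).
#' @export
gen_quadratic_surface_pair <- function(seed, dim = 2L) {
  set.seed(as.integer(seed))
  dim <- as.integer(dim)
  stopifnot(dim >= 1L)
  aA <- stats::runif(dim, 0.5, 3); cA <- stats::runif(dim, -3, 3)
  aB <- stats::runif(dim, 0.5, 3); cB <- stats::runif(dim, -3, 3)
  if (any(aA <= 0) || any(aB <= 0)) {
    stop("quadratic coefficients must be positive definite", call. = FALSE)
  }
  dA <- stats::runif(1, -2, 2)
  # choose dB so that min_x (E_A - E_B) < 0 < max over some region: shift the
  # gap so the seam exists and is compact when the gap is convex
  gap_no_offset <- function(x) sum(aA * (x - cA)^2) - sum(aB * (x - cB)^2) + dA
  # minimize the gap (it may be unbounded below; then any offset works)
  alpha <- aA - aB
  bounded_below <- all(alpha > 0)
  if (bounded_below) {
    xmin <- (aA * cA - aB * cB) / alpha
    m <- gap_no_offset(xmin)
    dB <- m + stats::runif(1, 0.5, 3)     # gap minimum becomes strictly negative
  } else {
    dB <- dA + stats::runif(1, -1, 1)
  }
  fA <- function(x) sum(aA * (x - cA)^2) + dA
  fB <- function(x) sum(aB * (x - cB)^2) + dB
  truth <- .quadratic_seam_minimum(aA, cA, dA, aB, cB, dB)
  list(energy_fn_A = fA, energy_fn_B = fB,
       params_A = list(a = aA, c = cA, d = dA),
       params_B = list(a = aB, c = cB, d = dB),
       truth = truth)
}

# Exact seam minimum of the mean energy of two axis-aligned quadratics,
# via the Lagrange stationarity condition grad(mean) = lambda * grad(gap):
# per coordinate x_j(lambda) is a ratio of linear terms; the multiplier is
# located by a dense sign-change scan (poles excluded) + uniroot, and the
# feasible root with the lowest mean energy is returned.
.quadratic_seam_minimum <- function(aA, cA, dA, aB, cB, dB) {
  p <- (aA + aB) / 2                 # mean-energy curvature
  alpha <- aA - aB                   # gap curvature
  mean_e <- function(x) (sum(aA * (x - cA)^2) + dA + sum(aB * (x - cB)^2) + dB) / 2
  gap <- function(x) sum(aA * (x - cA)^2) + dA - sum(aB * (x - cB)^2) - dB
  x_of_lambda <- function(l) {
    # d/dx_j [mean - l*gap] = 0: (p_j - l*alpha_j) x_j = p_j centers...
    num <- (aA * cA + aB * cB) / 2 - l * (aA * cA - aB * cB)
    den <- p - l * alpha
    num / den
  }
  g <- function(l) gap(x_of_lambda(l))
  poles <- p / alpha
  poles <- poles[is.finite(poles)]
  # the multiplier can be arbitrarily large: scan lambda = tan(t) over a
  # dense t-grid so the whole real line is covered
  grid <- tan(seq(-pi / 2 + 1e-4, pi / 2 - 1e-4, length.out = 8001))
  grid <- sort(unique(c(grid, poles + 1e-6, poles - 1e-6)))
  vals <- vapply(grid, function(l) tryCatch(g(l), error = function(e) NA_real_),
                 numeric(1))
  candidates <- list()
  for (i in seq_len(length(grid) - 1L)) {
    v1 <- vals[i]; v2 <- vals[i + 1L]
    if (!is.finite(v1) || !is.finite(v2)) next
    if (any(poles > grid[i] & poles < grid[i + 1L])) next
    if (v1 == 0) candidates[[length(candidates) + 1L]] <- grid[i]
    if (v1 * v2 < 0) {
      root <- stats::uniroot(g, c(grid[i], grid[i + 1L]), tol = 1e-14)$root
      candidates[[length(candidates) + 1L]] <- root
    }
  }
  if (length(candidates) == 0L) {
    stop("no seam found for the generated quadratic pair", call. = FALSE)
  }
  xs <- lapply(candidates, x_of_lambda)
  feasible <- vapply(xs, function(x) abs(gap(x)) < 1e-6, logical(1))
  xs <- xs[feasible]
  if (length(xs) == 0L) stop("seam root refinement failed", call. = FALSE)
  energies <- vapply(xs, mean_e, numeric(1))
  best <- xs[[which.min(energies)]]
  list(geometry = best, energy = mean_e(best))
}

#' Generate pathway thermochemistry with a known rate constant
#'
#' Emits a consistent set of stationary-point records (separated reactant,
#' reactant complex, transition state, product complex, separated product)
#' realizing the requested activation and reaction free energies and
#' imaginary frequency, plus the analytically evaluated TST and TST/Eckart
#' rate constants as ground truth.
#'
#' @param seed Integer seed (randomizes the complex well depths).
#' @param delta_G_act Activation free energy, TS relative to the separated
#'   reactant (kcal/mol, > 0).
#' @param delta_rG Reaction free energy (kcal/mol); must not place the
#'   product complex above the TS.
#' @param nu Imaginary-frequency magnitude (cm^-1).
#' @param sigma Reaction-path degeneracy.
#' @param temperature Temperature in kelvin.
#' @return List with `species` (list of [species_thermo()]), and `truth`
#'   (`k_tst`, `kappa`, `k_tst_eck`, `V1`, `V2`).
#' @export
gen_pathway_thermo <- function(seed, delta_G_act, delta_rG, nu, sigma = 1L,
                               temperature = 298.15) {
  set.seed(as.integer(seed))
  stopifnot(delta_G_act > 0, nu > 0)
  if (delta_rG >= delta_G_act) {
    stop("inconsistent targets: delta_rG at or above the barrier leaves no product complex below the transition state",
         call. = FALSE)
  }
  rc_depth <- stats::runif(1, 1, 4)       # RC below separated reactants
  # PC sits below the separated products but, for an endergonic reaction,
  # must stay at or above the reactants (an uphill profile with a PC below
  # the reactants is rejected as inconsistent)
  pc_depth <- if (delta_rG > 0) {
    stats::runif(1, 0.1, 0.9) * delta_rG
  } else {
    stats::runif(1, 1, 4)
  }
  g_rc <- -rc_depth
  g_pc <- delta_rG - pc_depth
  if (g_pc >= delta_G_act) {
    stop("inconsistent targets: product complex would sit above the transition state",
         call. = FALSE)
  }
  species <- list(
    species_thermo("reactant", "reactant", 0),
    species_thermo("RC", "reactant_complex", g_rc),
    species_thermo("TS", "transition_state", delta_G_act, imag_frequency = nu),
    species_thermo("PC", "product_complex", g_pc),
    species_thermo("product", "product", delta_rG)
  )
  V1 <- delta_G_act - g_rc
  V2 <- delta_G_act - g_pc
  cst <- physical_constants()
  k_tst <- sigma * cst$kB_J_per_K * temperature / cst$h_J_s *
    exp(-delta_G_act / (cst$R_kcal * temperature))
  kappa <- eckart_kappa(eckart_barrier(V1, V2, nu, temperature))
  list(species = species,
       truth = list(k_tst = k_tst, kappa = kappa, k_tst_eck = kappa * k_tst,
                    V1 = V1, V2 = V2))
}

#' Generate a random polyprotic acid with known fractions
#'
#' Draws `n_sites` ascending pKa values (uniform in `[1, 14]` with a minimum
#' separation of 0.5) and evaluates the ground-truth fractions at a sampled
#' pH by the direct (non-log-normalized) closed form -- an independent
#' evaluation path from [species_fractions()].
#'
#' @param seed Integer seed.
#' @param n_sites Number of acidic sites (1 to 6).
#' @return List with `acid` (a [polyprotic_acid()]), `ph` (the sampled pH),
#'   and `truth_fractions`.
#' @export
gen_polyprotic <- function(seed, n_sites = 2L) {
  set.seed(as.integer(seed))
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites >= 1L, n_sites <= 6L)
  raw <- sort(stats::runif(n_sites, 1, 14))
  pka <- raw + 0.5 * (seq_len(n_sites) - 1L)   # enforce separation
  ph <- stats::runif(1, 0, 14)
  acid <- polyprotic_acid(pka, name = sprintf("synthetic-%d-protic", n_sites))
  # direct evaluation: term_j = prod_{i<=j} 10^(ph - pKa_i)
  terms <- c(1, cumprod(10^(ph - pka)))
  truth <- terms / sum(terms)
  names(truth) <- acid$state_labels
  list(acid = acid, ph = ph, truth_fractions = truth)
}
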