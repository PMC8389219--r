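# Conventional transition-state-theory kinetics from Gibbs free energies:
#   k = sigma * kappa * (kB T / h) * exp(-dG_act / RT)
# with the tunneling coefficient kappa taken from a thermally averaged
# transmission through an asymmetric Eckart barrier (forward/reverse heights
# V1, V2 and the saddle-point imaginary frequency nu), or from the Wigner
# expansion as an independent cross-check.

#' Eyring transition-state-theory rate constant
#'
#' Evaluates `k = sigma * kappa * (kB*T/h) * exp(-delta_G_act / RT)`. The
#' activation free energy is interpreted at whatever standard state it was
#' computed at; for bimolecular reactions on the 1 M standard state the result
#' carries units of 1/(M s), otherwise 1/s.
#'
#' @param delta_G_act Activation Gibbs free energy in kcal/mol.
#' @param temperature Temperature in kelvin.
#' @param sigma Reaction-path degeneracy (integer >= 1).
#' @param kappa Transmission (tunneling) coefficient; 1 for classical TST.
#' @return Rate constant (s^-1 for unimolecular, M^-1 s^-1 for bimolecular
#'   barriers expressed at 1 M).
#' @examples
#' eyring_rate(23.9, 298.15)          # ~1.9e-5 s^-1
#' eyring_rate(0, 298.15)             # kB*T/h prefactor, ~6.21e12 s^-1
#' @export
eyring_rate <- function(delta_G_act, temperature = 298.15, sigma = 1L,
                        kappa = 1) {
  if (!is.numeric(delta_G_act) || any(!is.finite(delta_G_act))) {
    stop("delta_G_act must be finite (kcal/mol)", call. = FALSE)
  }
  if (any(sigma < 1)) stop("sigma must be >= 1", call. = FALSE)
  if (any(kappa <= 0)) stop("kappa must be positive", call. = FALSE)
  rt <- thermal_rt(temperature)
  cst <- physical_constants()
  prefactor <- cst$kB_J_per_K * temperature / cst$h_J_s
  sigma * kappa * prefactor * exp(-delta_G_act / rt)
}

#' Wigner tunneling coefficient
#'
#' Leading-order correction `1 + u^2/24` with `u = h*c*nu/(kB*T)`. Used as an
#' independent high-temperature cross-check of the Eckart thermal average.
#'
#' @param imag_frequency Imaginary-frequency magnitude in cm^-1 (> 0).
#' @param temperature Temperature in kelvin.
#' @return Dimensionless transmission coefficient (>= 1).
#' @examples
#' wigner_kappa(1384, 298.15) # ~2.86
#' @export
wigner_kappa <- function(imag_frequency, temperature = 298.15) {
  if (any(imag_frequency <= 0)) stop("imag_frequency must be > 0", call. = FALSE)
  if (any(temperature <= 0)) stop("temperature must be > 0", call. = FALSE)
  u <- physical_constants()$c2_cm_K * imag_frequency / temperature
  1 + u^2 / 24
}

#' Asymmetric Eckart barrier description
#'
#' Forward and reverse barrier heights are measured from the reactant complex
#' and the product complex up to the saddle point, together with the magnitude
#' of the saddle-point imaginary frequency.
#'
#' @param forward_barrier Forward height V1 (kcal/mol, > 0).
#' @param reverse_barrier Reverse height V2 (kcal/mol, > 0).
#' @param imag_frequency Imaginary-frequency magnitude (cm^-1, > 0).
#' @param temperature Temperature in kelvin.
#' @return An object of class `eckart_barrier`.
#' @export
eckart_barrier <- function(forward_barrier, reverse_barrier, imag_frequency,
                           temperature = 298.15) {
  if (!is.finite(forward_barrier) || forward_barrier <= 0 ||
      !is.finite(reverse_barrier) || reverse_barrier <= 0) {
    stop("Eckart barrier heights must be positive and finite", call. = FALSE)
  }
  if (!is.finite(imag_frequency) || imag_frequency <= 0) {
    stop("imag_frequency must be a positive wavenumber", call. = FALSE)
  }
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  structure(list(forward_barrier = forward_barrier,
                 reverse_barrier = reverse_barrier,
                 imag_frequency = imag_frequency,
                 temperature = temperature),
            class = "eckart_barrier")
}

# log(cosh(x)) and log(sinh(x)) without overflow
.logcosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)
.logsinh <- function(x) ifelse(x <= 0, -Inf, x + log1p(-exp(-2 * x)) - log(2))

#' Transmission probability through an asymmetric Eckart barrier
#'
#' The standard closed-form transmission probability `p(E)` for a particle of
#' energy `E` (measured from the reactant-side well) crossing an asymmetric
#' Eckart potential parameterized by barrier heights `V1`, `V2` and the
#' barrier (imaginary) frequency. Evaluated in log space so it is stable for
#' arbitrarily thick/high barriers; vectorized over `E`.
#'
#' @param E Energies in kcal/mol (vector allowed), relative to the
#'   reactant-side minimum.
#' @param forward_barrier,reverse_barrier Barrier heights V1, V2 (kcal/mol).
#' @param imag_frequency Barrier frequency magnitude (cm^-1).
#' @return Transmission probabilities in `[0, 1]`; 0 below the product-side
#'   asymptote `max(0, V1 - V2)`.
#' @export
eckart_transmission <- function(E, forward_barrier, reverse_barrier,
                                imag_frequency) {
  V1 <- forward_barrier
  V2 <- reverse_barrier
  Fq <- imag_frequency * physical_constants()$cm1_kcal  # h*c*nu, kcal/mol
  alpha1 <- 2 * pi * V1 / Fq
  alpha2 <- 2 * pi * V2 / Fq
  inv <- 1 / sqrt(alpha1) + 1 / sqrt(alpha2)
  xi <- E / V1
  open <- E > max(0, V1 - V2) & E > 0
  xa <- ifelse(open, 2 * sqrt(pmax(alpha1 * xi, 0)) / inv, 0)
  xb <- ifelse(open, 2 * sqrt(pmax((xi - 1) * alpha1 + alpha2, 0)) / inv, 0)
  dd <- alpha1 * alpha2 - pi^2 / 4
  s <- xa + xb
  m <- abs(xa - xb)
  # cosh(s) - cosh(m) = 2 sinh((s+m)/2) sinh((s-m)/2)
  log_num <- log(2) + .logsinh((s + m) / 2) + .logsinh((s - m) / 2)
  if (dd >= 0) {
    xd <- 2 * sqrt(dd)
    # cosh(s) + cosh(xd) = 2 cosh((s+xd)/2) cosh((s-xd)/2)
    log_den <- log(2) + .logcosh((s + xd) / 2) + .logcosh((s - xd) / 2)
  } else {
    cosv <- cos(2 * sqrt(-dd))
    log_den <- .logcosh(s) + log1p(cosv * exp(-.logcosh(s)))
  }
  p <- exp(log_num - log_den)
  p[!open] <- 0
  p
}

#' Thermally averaged Eckart tunneling coefficient
#'
#' Computes the thermal transmission average
#' `kappa = exp(V1/RT)/RT * integral p(E) exp(-E/RT) dE` over
#' `E in [max(0, V1-V2), max(V1, V2) + 40 RT]`, with `p(E)` the asymmetric
#' Eckart transmission probability ([eckart_transmission()]). The integral is
#' evaluated adaptively on the shifted variable `(E - V1)/RT` to avoid
#' overflow, with relative tolerance 1e-8. `kappa` may fall below 1 when
#' above-barrier reflection dominates (low, thin barriers).
#'
#' @param barrier An [eckart_barrier()].
#' @param rel_tol Relative tolerance of the adaptive quadrature.
#' @return Dimensionless tunneling coefficient.
#' @examples
#' eckart_kappa(eckart_barrier(10, 10, 500))
#' @export
eckart_kappa <- function(barrier, rel_tol = 1e-8) {
  stopifnot(inherits(barrier, "eckart_barrier"))
  V1 <- barrier$forward_barrier
  V2 <- barrier$reverse_barrier
  nu <- barrier$imag_frequency
  rt <- thermal_rt(barrier$temperature)
  # integrand in u = (E - V1)/RT; kappa = int p(E) exp(-u) du
  g <- function(u) {
    E <- V1 + u * rt
    p <- eckart_transmission(E, V1, V2, nu)
    out <- ifelse(p > 0, exp(log(p) - u), 0)
    out[!is.finite(out)] <- 0
    out
  }
  u0 <- (max(0, V1 - V2) - V1) / rt
  u1 <- (max(V1, V2) + 40 * rt - V1) / rt
  # split at the barrier top: below-threshold tunneling and above-barrier
  # reflection have very different scales
  i1 <- stats::integrate(g, u0, 0, rel.tol = rel_tol, abs.tol = 0,
                         subdivisions = 2000L, stop.on.error = FALSE)
  i2 <- stats::integrate(g, 0, u1, rel.tol = rel_tol, abs.tol = 0,
                         subdivisions = 2000L, stop.on.error = FALSE)
  i1$value + i2$value
}

#' Assemble a pathway rate record from stationary-point thermochemistry
#'
#' Builds the full TST/Eckart bookkeeping for one reaction path from its
#' stationary points: activation free energy (referenced to the separated
#' reactants by default, or to the reactant complex), reaction free energy,
#' Eckart forward/reverse heights `V1 = G(TS) - G(RC)`,
#' `V2 = G(TS) - G(PC)`, the tunneling coefficient, and the corrected rate
#' constant `k_tst_eck = kappa * k_tst`. An MECP record may stand in for the
#' transition state on spin-forbidden paths. Gibbs barrier heights are used as
#' proxies for the Eckart inputs, so the coefficient is labelled approximate.
#'
#' @param species List of [species_thermo()] records covering at minimum one
#'   saddle point (`transition_state` or `mecp`) and the `reactant` record(s);
#'   `reactant_complex`, `product_complex` and `product` records are used when
#'   present.
#' @param sigma Reaction-path degeneracy (default 1; the analysis tables this
#'   mirrors never state sigma).
#' @param temperature Temperature in kelvin.
#' @param molecularity `"unimolecular"` or `"bimolecular"` (sets the unit
#'   label of the rate constant; barriers are assumed already expressed at the
#'   1 M standard state for bimolecular paths).
#' @param reference Barrier reference: `"reactants"` (separated reactants,
#'   default) or `"reactant_complex"`.
#' @param kappa `"eckart"` (default), `"wigner"`, `"none"`, or a fixed numeric
#'   transmission coefficient.
#' @param path_label Label carried into reports.
#' @return An object of class `pathway_rate` with fields `path_label`,
#'   `delta_rG`, `delta_G_act`, `imag_frequency`, `sigma`, `temperature`,
#'   `k_tst`, `kappa_eckart`, `k_tst_eck`, `molecularity`, `kappa_method`.
#' @export
pathway_rate <- function(species, sigma = 1L, temperature = 298.15,
                         molecularity = c("unimolecular", "bimolecular"),
                         reference = c("reactants", "reactant_complex"),
                         kappa = "eckart", path_label = NULL) {
  molecularity <- match.arg(molecularity)
  reference <- match.arg(reference)
  stopifnot(is.list(species),
            all(vapply(species, inherits, logical(1), "species_thermo")))
  roles <- vapply(species, `[[`, character(1), "role")
  gof <- function(r) vapply(species[roles == r], `[[`, numeric(1), "gibbs_energy")

  ts_idx <- which(roles %in% c("transition_state", "mecp"))
  if (length(ts_idx) != 1L) {
    stop("exactly one transition_state or mecp record is required", call. = FALSE)
  }
  ts <- species[[ts_idx]]
  g_react <- gof("reactant")
  if (length(g_react) == 0L) stop("at least one reactant record is required",
                                  call. = FALSE)
  g_prod <- gof("product")
  g_rc <- gof("reactant_complex")
  g_pc <- gof("product_complex")
  if (length(g_rc) > 1L || length(g_pc) > 1L) {
    stop("at most one reactant_complex and one product_complex allowed",
         call. = FALSE)
  }
  if (reference == "reactant_complex" && length(g_rc) == 0L) {
    stop("reference = 'reactant_complex' but no reactant_complex record given",
         call. = FALSE)
  }
  g_ref <- if (reference == "reactants") sum(g_react) else g_rc
  delta_G_act <- ts$gibbs_energy - g_ref
  delta_rG <- if (length(g_prod) > 0) sum(g_prod) - sum(g_react) else NA_real_

  # Eckart heights from the flanking complexes; fall back to the separated
  # species when a complex record is absent
  v1_ref <- if (length(g_rc) == 1L) g_rc else sum(g_react)
  v2_ref <- if (length(g_pc) == 1L) g_pc else if (length(g_prod) > 0) sum(g_prod) else NA_real_
  V1 <- ts$gibbs_energy - v1_ref
  V2 <- if (is.na(v2_ref)) NA_real_ else ts$gibbs_energy - v2_ref
  if (!is.na(V2) && V2 <= 0) {
    stop(sprintf("product side (G = %.4f) lies above the saddle point (G = %.4f); not a valid barrier",
                 v2_ref, ts$gibbs_energy), call. = FALSE)
  }

  kappa_method <- if (is.numeric(kappa)) "fixed" else match.arg(kappa, c("eckart", "wigner", "none"))
  kap <- switch(kappa_method,
    fixed  = as.numeric(kappa),
    none   = 1,
    wigner = wigner_kappa(ts$imag_frequency, temperature),
    eckart = {
      if (is.na(V2)) {
        stop("Eckart correction needs a product_complex (or product) record for the reverse height",
             call. = FALSE)
      }
      if (V1 <= 0) {
        stop("Eckart correction needs a positive forward height G(TS) - G(RC)",
             call. = FALSE)
      }
      eckart_kappa(eckart_barrier(V1, V2, ts$imag_frequency, temperature))
    })
  k_tst <- eyring_rate(delta_G_act, temperature, sigma, kappa = 1)
  structure(list(
    path_label = if (is.null(path_label)) ts$name else path_label,
    delta_rG = delta_rG, delta_G_act = delta_G_act,
    imag_frequency = ts$imag_frequency, sigma = as.integer(sigma),
    temperature = temperature, k_tst = k_tst, kappa_eckart = kap,
    k_tst_eck = kap * k_tst, molecularity = molecularity,
    kappa_method = kappa_method,
    eckart_forward = V1, eckart_reverse = V2
  ), class = "pathway_rate")
}

#' @export
print.pathway_rate <- function(x, ...) {
  unit <- if (x$molecularity == "bimolecular") "M^-1 s^-1" else "s^-1"
  cat(sprintf("<pathway_rate> %s: dG_act = %.2f kcal/mol, k_tst = %.3g %s, kappa = %.3g (%s), k_tst_eck = %.3g %s\n",
              x$path_label, x$delta_G_act, x$k_tst, unit, x$kappa_eckart,
              x$kappa_method, x$k_tst_eck, unit))
  invisible(x)
}

#' Overall rate constant and branching fractions of competing paths
#'
#' Sums the tunneling-corrected rate constants of parallel pathways and
#' reports each path's branching fraction. All paths must share the same
#' temperature and molecularity.
#'
#' @param paths List of [pathway_rate()] objects.
#' @return List with `k_overall` and a named numeric vector `branching`
#'   summing to 1.
#' @export
overall_rate <- function(paths) {
  stopifnot(is.list(paths), length(paths) >= 1L,
            all(vapply(paths, inherits, logical(1), "pathway_rate")))
  temps <- vapply(paths, `[[`, numeric(1), "temperature")
  mols <- vapply(paths, `[[`, character(1), "molecularity")
  if (length(unique(mols)) > 1L) {
    stop("cannot sum rate constants of mixed molecularity", call. = FALSE)
  }
  if (length(unique(temps)) > 1L) {
    stop("cannot sum rate constants at different temperatures", call. = FALSE)
  }
  k <- vapply(paths, `[[`, numeric(1), "k_tst_eck")
  names(k) <- vapply(paths, `[[`, character(1), "path_label")
  k_overall <- sum(k)
  list(k_overall = k_overall, branching = k / k_overall)
}

#' Water-assisted tautomerization series report
#'
#' Orders the per-pathway kinetics of a proton-relay series by the number of
#' bridging water molecules and flags whether the activation free energy
#' decreases strictly as waters are added (the hydrogen-bond-lattice
#' catalysis signature).
#'
#' @param n_waters Integer vector (>= 0, unique) of catalytic water counts.
#' @param paths List of [pathway_rate()] objects, parallel to `n_waters`.
#' @return A data.frame sorted by `n_waters` with columns `n_waters`,
#'   `delta_rG`, `delta_G_act`, `nu`, `k_tst`, `kappa_eck`, `k_tst_eck`, plus
#'   attribute `monotone_decreasing_barrier` (logical).
#' @export
water_series_report <- function(n_waters, paths) {
  stopifnot(length(n_waters) == length(paths), length(paths) >= 1L,
            all(vapply(paths, inherits, logical(1), "pathway_rate")))
  n_waters <- as.integer(n_waters)
  if (any(n_waters < 0)) stop("n_waters must be >= 0", call. = FALSE)
  if (anyDuplicated(n_waters)) {
    stop("duplicate n_waters entries in tautomerization series", call. = FALSE)
  }
  ord <- order(n_waters)
  df <- data.frame(
    n_waters = n_waters[ord],
    delta_rG = vapply(paths[ord], `[[`, numeric(1), "delta_rG"),
    delta_G_act = vapply(paths[ord], `[[`, numeric(1), "delta_G_act"),
    nu = vapply(paths[ord], `[[`, numeric(1), "imag_frequency"),
    k_tst = vapply(paths[ord], `[[`, numeric(1), "k_tst"),
    kappa_eck = vapply(paths[ord], `[[`, numeric(1), "kappa_eckart"),
    k_tst_eck = vapply(paths[ord], `[[`, numeric(1), "k_tst_eck")
  )
  attr(df, "monotone_decreasing_barrier") <-
    all(diff(df$delta_G_act) < 0) || nrow(df) == 1L
  df
}

#' Classify a bimolecular rate constant against the diffusion limit
#'
#' Aqueous diffusion-limited bimolecular rate constants fall in the range
#' 1e7 to 1e10 1/(M s) (inclusive bounds); a computed rate at or above this
#' window means the reaction is effectively encounter-controlled.
#'
#' @param k Rate constant in 1/(M s).
#' @param molecularity Must be `"bimolecular"`.
#' @return `"below"`, `"in_range"`, or `"above"`.
#' @examples
#' classify_diffusion_limited(2.29e9, "bimolecular") # "in_range"
#' @export
classify_diffusion_limited <- function(k, molecularity = "bimolecular") {
  if (!identical(molecularity, "bimolecular")) {
    stop("diffusion-limit classification applies to bimolecular rate constants only",
         call. = FALSE)
  }
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("k must be a positive finite rate constant", call. = FALSE)
  }
  ifelse(k < 1e7, "below", ifelse(k <= 1e10, "in_range", "above"))
}
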