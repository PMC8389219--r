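# Two-state (spin-forbidden) reactivity tools: locate low-spin/high-spin
# crossings along a 1-D reaction-coordinate scan, refine a minimum-energy
# crossing point (MECP) on model surfaces with Harvey's effective-gradient
# construction, and classify whether a crossing can be rate-determining
# (before the adiabatic barrier) or is kinetically irrelevant (after it).

#' Two-state energy profile along a reaction coordinate
#'
#' Holds pointwise singlet/triplet (low-spin/high-spin) energies sampled on a
#' strictly monotone 1-D reaction coordinate, optionally with the coordinate
#' of the adiabatic (high-spin) transition state.
#'
#' @param coordinate Strictly monotone numeric vector (e.g. an interatomic
#'   distance in angstrom), length >= 3.
#' @param energy_low_spin,energy_high_spin Energies in kcal/mol, same length
#'   as `coordinate`.
#' @param ts_coordinate Optional coordinate of the high-spin TS.
#' @return An object of class `state_profile`.
#' @export
state_profile <- function(coordinate, energy_low_spin, energy_high_spin,
                          ts_coordinate = NULL) {
  if (length(coordinate) < 3L) stop("profile needs at least 3 points", call. = FALSE)
  d <- diff(coordinate)
  if (!(all(d > 0) || all(d < 0))) {
    stop("coordinate must be strictly monotone", call. = FALSE)
  }
  if (length(energy_low_spin) != length(coordinate) ||
      length(energy_high_spin) != length(coordinate)) {
    stop("energy vectors must match the coordinate length", call. = FALSE)
  }
  if (!is.null(ts_coordinate)) {
    stopifnot(is.numeric(ts_coordinate), length(ts_coordinate) == 1L)
  }
  structure(list(coordinate = as.numeric(coordinate),
                 energy_low_spin = as.numeric(energy_low_spin),
                 energy_high_spin = as.numeric(energy_high_spin),
                 ts_coordinate = ts_coordinate),
            class = "state_profile")
}

#' Read a two-state profile scan from TSV
#'
#' Expects tab-separated columns `r_angstrom`, `E_singlet_kcal`,
#' `E_triplet_kcal`. An optional comment line `# ts_coordinate: <value>`
#' records the adiabatic TS position.
#'
#' @param path Path to the TSV file.
#' @return A [state_profile()].
#' @export
read_profile_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  ts <- NULL
  key <- grep("^#\\s*ts_coordinate\\s*:", lines, value = TRUE)
  if (length(key) > 0) {
    ts <- as.numeric(sub("^#\\s*ts_coordinate\\s*:\\s*", "", key[1]))
  }
  df <- utils::read.delim(text = lines, comment.char = "#")
  required <- c("r_angstrom", "E_singlet_kcal", "E_triplet_kcal")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("profile '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  state_profile(df$r_angstrom, df$E_singlet_kcal, df$E_triplet_kcal,
                ts_coordinate = ts)
}

#' Write a two-state profile scan to TSV
#'
#' @param profile A [state_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "state_profile"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(profile$ts_coordinate)) {
    writeLines(sprintf("# ts_coordinate: %.10g", profile$ts_coordinate), con)
  }
  utils::write.table(
    data.frame(r_angstrom = profile$coordinate,
               E_singlet_kcal = profile$energy_low_spin,
               E_triplet_kcal = profile$energy_high_spin),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Locate state crossings along a scanned profile
#'
#' Scans the pointwise gap `dE(r) = E_low(r) - E_high(r)` for sign changes.
#' Each sign change yields one crossing, with the coordinate placed by linear
#' interpolation between the bracketing scan points (matching the pointwise
#' single-point-energy scan procedure; no spline smoothing). A gap that is
#' exactly zero at a scan node returns that node.
#'
#' @param profile A [state_profile()].
#' @return A list of `crossing_point` objects (possibly empty), ordered along
#'   the coordinate, each with fields `coordinate`, `energy`, `bracket`
#'   (index pair), and `relevance` (`"indeterminate"` until classified).
#' @export
find_profile_crossings <- function(profile) {
  stopifnot(inherits(profile, "state_profile"))
  r <- profile$coordinate
  gap <- profile$energy_low_spin - profile$energy_high_spin
  out <- list()
  n <- length(r)
  for (i in seq_len(n)) {
    if (gap[i] == 0) {
      out[[length(out) + 1L]] <- structure(
        list(coordinate = r[i], energy = profile$energy_high_spin[i],
             bracket = c(i, i), relevance = "indeterminate"),
        class = "crossing_point")
    }
  }
  for (i in seq_len(n - 1L)) {
    if (gap[i] * gap[i + 1L] < 0) {
      w <- gap[i] / (gap[i] - gap[i + 1L])   # fraction toward node i+1
      rc <- r[i] + w * (r[i + 1L] - r[i])
      ec <- profile$energy_high_spin[i] +
        w * (profile$energy_high_spin[i + 1L] - profile$energy_high_spin[i])
      out[[length(out) + 1L]] <- structure(
        list(coordinate = rc, energy = ec, bracket = c(i, i + 1L),
             relevance = "indeterminate"),
        class = "crossing_point")
    }
  }
  if (length(out) > 1L) {
    ord <- order(vapply(out, `[[`, numeric(1), "coordinate"))
    out <- out[ord]
  }
  out
}

#' Classify the kinetic relevance of a crossing point
#'
#' A spin crossing can replace the adiabatic transition state as the
#' rate-determining bottleneck only if it is met *before* the high-spin TS
#' along the reaction direction and lies below the TS energy; a crossing
#' passed after the TS leaves the rate constant untouched. Reaction direction
#' is taken as the direction of increasing index of the scan (so reversing
#' the scan together with `ts_coordinate` gives the same answer).
#'
#' @param crossing A `crossing_point` from [find_profile_crossings()].
#' @param profile The [state_profile()] it came from; if `ts_coordinate` is
#'   absent the classification is `"indeterminate"`.
#' @return The crossing with `relevance` set to `"rate_determining"`,
#'   `"post_barrier"`, or `"indeterminate"`.
#' @export
classify_crossing <- function(crossing, profile) {
  stopifnot(inherits(crossing, "crossing_point"),
            inherits(profile, "state_profile"))
  r <- profile$coordinate
  lo <- min(r); hi <- max(r)
  if (crossing$coordinate < lo || crossing$coordinate > hi) {
    stop("crossing lies outside the profile coordinate range", call. = FALSE)
  }
  if (is.null(profile$ts_coordinate)) {
    crossing$relevance <- "indeterminate"
    return(crossing)
  }
  # orient along the scan direction: "before" means encountered earlier
  direction <- sign(r[length(r)] - r[1])
  before_ts <- direction * (crossing$coordinate - profile$ts_coordinate) < 0
  e_ts <- stats::approx(r, profile$energy_high_spin,
                        xout = profile$ts_coordinate, rule = 2)$y
  crossing$relevance <- if (before_ts && crossing$energy < e_ts) {
    "rate_determining"
  } else if (!before_ts) {
    "post_barrier"
  } else {
    "indeterminate"
  }
  crossing
}

# central-difference gradient, step scaled per coordinate
.num_grad <- function(f, x, h_rel = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- h_rel * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

#' Optimize a minimum-energy crossing point between two surfaces
#'
#' Minimizes the mean energy on the seam `E_A = E_B` using the
#' effective-gradient construction: with the difference-gradient direction
#' `x = (gA - gB)/|gA - gB|`, the working gradient combines the
#' seam-restoring force `(E_A - E_B) x` with the mean gradient projected
#' orthogonal to `x`. Gradients are numerical central differences; descent is
#' steepest-descent with an adaptive backtracking step. Convergence requires
#' both `|E_A - E_B| < gap_tol` and the projected mean-gradient norm below
#' `grad_tol`; hitting the iteration cap returns the best iterate flagged
#' unconverged (not an error).
#'
#' @param energy_fn_A,energy_fn_B Functions mapping a coordinate vector to an
#'   energy (kcal/mol).
#' @param start Numeric starting coordinate vector.
#' @param gap_tol Seam-degeneracy tolerance (kcal/mol), default 1e-6.
#' @param grad_tol Projected-gradient tolerance, default 1e-5.
#' @param max_iter Iteration cap, default 500.
#' @param step0 Initial step length.
#' @return An object of class `mecp_result`: `geometry`, `energy`,
#'   `energy_gap`, `grad_norm_projected`, `iterations`, `converged`.
#' @examples
#' fA <- function(p) p[1]^2 + p[2]^2
#' fB <- function(p) (p[1] - 2)^2 + p[2]^2
#' mecp_optimize(fA, fB, c(0.3, 0.7))$geometry  # ~ (1, 0)
#' @export
mecp_optimize <- function(energy_fn_A, energy_fn_B, start, gap_tol = 1e-6,
                          grad_tol = 1e-5, max_iter = 500L, step0 = 0.1) {
  x <- as.numeric(start)
  if (any(!is.finite(c(energy_fn_A(x), energy_fn_B(x))))) {
    stop("surfaces must be finite at the starting point", call. = FALSE)
  }
  eff <- function(x) {
    eA <- energy_fn_A(x); eB <- energy_fn_B(x)
    gA <- .num_grad(energy_fn_A, x)
    gB <- .num_grad(energy_fn_B, x)
    dg <- gA - gB
    ndg <- sqrt(sum(dg^2))
    if (ndg < 1e-9 * max(1, sqrt(sum(gA^2)))) {
      stop("degenerate seam: the two surfaces have (numerically) identical gradients",
           call. = FALSE)
    }
    xhat <- dg / ndg
    gm <- (gA + gB) / 2
    f_perp <- gm - sum(gm * xhat) * xhat       # move along the seam
    f_gap <- (eA - eB) * xhat                  # restore degeneracy
    list(eA = eA, eB = eB, gap = eA - eB, G = f_gap + f_perp,
         perp_norm = sqrt(sum(f_perp^2)))
  }
  st <- eff(x)
  merit <- function(s) s$gap^2 + s$perp_norm^2
  gnorm <- function(s) sqrt(sum(s$G^2))
  # steepest descent on the effective gradient with a safeguarded
  # Barzilai-Borwein step (scale-free on quadratics) and backtracking
  alpha <- step0 / max(1, gnorm(st))
  iter <- 0L
  sd_cap <- ceiling(0.8 * max_iter)   # reserve the tail for the polish phase
  best <- list(x = x, st = st, m = merit(st))
  x_prev <- NULL; G_prev <- NULL
  while (iter < sd_cap) {
    iter <- iter + 1L
    if (abs(st$gap) < gap_tol && st$perp_norm < grad_tol) break
    if (!is.null(x_prev)) {
      s_vec <- x - x_prev
      y_vec <- st$G - G_prev
      sy <- sum(s_vec * y_vec)
      if (sy > 0) alpha <- min(max(sum(s_vec^2) / sy, 1e-10), 1e4)
    }
    accepted <- FALSE
    a_try <- alpha
    for (bt in 1:50) {
      xt <- x - a_try * st$G
      stt <- tryCatch(eff(xt), error = function(e) NULL)
      if (!is.null(stt) && merit(stt) < merit(st)) {
        x_prev <- x; G_prev <- st$G
        x <- xt; st <- stt
        accepted <- TRUE
        break
      }
      a_try <- a_try / 2
    }
    if (!accepted) break   # step collapsed; polish below
    if (merit(st) < best$m) best <- list(x = x, st = st, m = merit(st))
  }
  st <- best$st; x <- best$x
  converged <- abs(st$gap) < gap_tol && st$perp_norm < grad_tol
  if (!converged && iter < max_iter) {
    # quasi-Newton polish: Levenberg-Marquardt on the residual
    # [E_A - E_B; projected mean gradient], which vanishes exactly at the MECP
    resid <- function(x) {
      s <- eff(x)
      c(s$gap, s$G)   # G = gap-restoring + projected component; zero iff both zero
    }
    n <- length(x)
    lambda <- 1e-3
    r <- resid(x)
    for (it in seq_len(max_iter - iter)) {
      J <- matrix(0, length(r), n)
      for (j in seq_len(n)) {
        h <- 1e-6 * max(1, abs(x[j]))
        xp <- x; xp[j] <- x[j] + h
        xm <- x; xm[j] <- x[j] - h
        J[, j] <- (resid(xp) - resid(xm)) / (2 * h)
      }
      A <- crossprod(J) + lambda * diag(n)
      delta <- tryCatch(solve(A, -crossprod(J, r)), error = function(e) NULL)
      if (is.null(delta)) break
      xt <- x + as.numeric(delta)
      rt <- tryCatch(resid(xt), error = function(e) NULL)
      if (!is.null(rt) && sum(rt^2) < sum(r^2)) {
        x <- xt; r <- rt; lambda <- max(lambda / 3, 1e-12)
        iter <- iter + 1L
        stt <- eff(x)
        if (abs(stt$gap) < gap_tol && stt$perp_norm < grad_tol) break
      } else {
        lambda <- lambda * 10
        if (lambda > 1e10) break
      }
    }
    st <- eff(x)
    converged <- abs(st$gap) < gap_tol && st$perp_norm < grad_tol
  }
  structure(list(
    geometry = x, energy = (st$eA + st$eB) / 2, energy_gap = st$gap,
    grad_norm_projected = st$perp_norm, iterations = iter,
    converged = converged
  ), class = "mecp_result")
}

#' @export
print.mecp_result <- function(x, ...) {
  cat(sprintf("<mecp_result> E = %.6f kcal/mol at (%s); gap = %.2e, |g_perp| = %.2e, %s in %d iterations\n",
              x$energy, paste(signif(x$geometry, 6), collapse = ", "),
              x$energy_gap, x$grad_norm_projected,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Predict a crossing from a scan, then refine the MECP on the surfaces
#'
#' Two-stage procedure: the scan-based prediction takes the lowest-energy
#' crossing of the 1-D profile (a cheap estimate, accurate to the scan
#' spacing), then the effective-gradient optimizer refines the crossing-seam
#' minimum on the full surfaces starting from that point. The 1-D scan
#' coordinate is lifted into surface space by `embed`.
#'
#' @param profile A [state_profile()] with at least one crossing.
#' @param energy_fn_A,energy_fn_B Surface functions as in [mecp_optimize()].
#' @param embed Function mapping a scan coordinate to a surface coordinate
#'   vector (default: identity, for 1-D surfaces).
#' @param ... Passed to [mecp_optimize()].
#' @return A list with `predicted` (the seeding `crossing_point`) and
#'   `refined` (the `mecp_result`).
#' @export
predict_then_refine <- function(profile, energy_fn_A, energy_fn_B,
                                embed = function(r) r, ...) {
  crossings <- find_profile_crossings(profile)
  if (length(crossings) == 0L) {
    stop("no crossing to refine: the scanned states do not intersect",
         call. = FALSE)
  }
  energies <- vapply(crossings, `[[`, numeric(1), "energy")
  seed <- crossings[[which.min(energies)]]
  refined <- mecp_optimize(energy_fn_A, energy_fn_B,
                           start = embed(seed$coordinate), ...)
  list(predicted = seed, refined = refined)
}
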