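# Acid-base speciation of a polyprotic acid at fixed pH, from its stepwise
# pKa values. Fractions follow the ideal (activity-free) Henderson-Hasselbalch
# arithmetic; all accumulation is done in log10 space with a max-shift so that
# extreme pH or widely split pKa values cannot overflow.

#' Define a polyprotic acid by its stepwise pKa values
#'
#' @param pka_values Numeric vector of stepwise pKa values, strictly
#'   ascending (pKa1 < pKa2 < ...), length >= 1.
#' @param state_labels Optional labels for the `n + 1` protonation states,
#'   most protonated first (default `AH`, `A-`, `A2-`, ...).
#' @param name Acid label.
#' @return An object of class `polyprotic_acid`.
#' @examples
#' polyprotic_acid(c(4.56, 8.65), name = "ferulic acid")
#' @export
polyprotic_acid <- function(pka_values, state_labels = NULL, name = "acid") {
  if (!is.numeric(pka_values) || length(pka_values) < 1L ||
      any(!is.finite(pka_values))) {
    stop("pka_values must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (any(diff(pka_values) <= 0)) {
    stop("pKa values must be strictly ascending", call. = FALSE)
  }
  n <- length(pka_values)
  if (is.null(state_labels)) {
    state_labels <- c("AH", "A-", if (n >= 2) paste0("A", 2:n, "-"))
  }
  if (length(state_labels) != n + 1L || anyDuplicated(state_labels)) {
    stop(sprintf("state_labels must be %d unique labels (one per protonation state)",
                 n + 1L), call. = FALSE)
  }
  structure(list(name = name, pka_values = as.numeric(pka_values),
                 state_labels = as.character(state_labels)),
            class = "polyprotic_acid")
}

#' Molar fractions of protonation states at a given pH
#'
#' The fraction of the `j`-times-deprotonated state is
#' `10^(j*pH - sum(pKa[1:j])) / sum_k 10^(k*pH - sum(pKa[1:k]))` (the `j = 0`
#' term being 1). Evaluated in log10 space with max-shift normalization, so
#' fractions stay finite and sum to 1 to machine precision for any finite pH.
#'
#' @param acid A [polyprotic_acid()].
#' @param ph pH value (dimensionless).
#' @return An object of class `speciation_result`: `ph`, named `fractions`
#'   aligned with `acid$state_labels`, and the acid name.
#' @examples
#' fa <- polyprotic_acid(c(4.56, 8.65))
#' species_fractions(fa, 7.4)$fractions # ~ (0.0014, 0.9454, 0.0532)
#' @export
species_fractions <- function(acid, ph) {
  stopifnot(inherits(acid, "polyprotic_acid"), is.numeric(ph),
            length(ph) == 1L, is.finite(ph))
  j <- seq_along(acid$pka_values)
  log_terms <- c(0, j * ph - cumsum(acid$pka_values))   # log10 of each term
  shifted <- log_terms - max(log_terms)
  w <- 10^shifted
  fractions <- w / sum(w)
  names(fractions) <- acid$state_labels
  structure(list(ph = ph, fractions = fractions, acid = acid$name),
            class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf("<speciation_result> %s at pH %.2f\n", x$acid, x$ph))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Dominant protonation state at a given pH
#'
#' Returns the state with the largest molar fraction; exact ties resolve to
#' the less-deprotonated state (the earlier label).
#'
#' @inheritParams species_fractions
#' @return List with `label` and `fraction`.
#' @examples
#' dominant_species(polyprotic_acid(c(4.56, 8.65)), 7.4)$label # "A-"
#' @export
dominant_species <- function(acid, ph) {
  f <- species_fractions(acid, ph)$fractions
  i <- which.max(f)   # which.max takes the first maximum: the tie-break rule
  list(label = names(f)[i], fraction = unname(f[i]))
}
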