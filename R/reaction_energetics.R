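# Reaction Gibbs-free-energy bookkeeping: compose Delta_r G from component
# free energies on a shared standard state, classify exergonicity, and rank
# metal-chelation reactions by exergonicity grouped by metal:ligand ratio.

#' Specify a reaction and the free energies of its components
#'
#' Reactants and products are named species with positive integer
#' stoichiometric coefficients. Component free energies (kcal/mol) must all
#' refer to one declared standard state; mixing tags is an error because the
#' composition subtracts absolute free energies. When component values are
#' unavailable (as is common for published complexation tables that print
#' only the reaction values), `delta_g_override` supplies the reaction free
#' energy directly.
#'
#' @param label Reaction label.
#' @param reactants,products Named numeric vectors of stoichiometric
#'   coefficients, e.g. `c("FA-" = 1, "[Fe(H2O)6]2+" = 1)`.
#' @param component_G Named numeric vector mapping species to Gibbs free
#'   energies (kcal/mol); may be `NULL` if `delta_g_override` is given.
#' @param delta_g_override Optional reaction free energy (kcal/mol) used
#'   instead of composing from components.
#' @param standard_state Tag describing the shared standard state of all
#'   component energies (e.g. `"aqueous-298.15K-1M"`).
#' @param metadata Free-form list (metal:ligand ratio, ligand protonation
#'   state, coordination site, ...).
#' @return An object of class `reaction_spec`.
#' @export
reaction_spec <- function(label, reactants, products, component_G = NULL,
                          delta_g_override = NULL,
                          standard_state = "aqueous-298.15K-1M",
                          metadata = list()) {
  check_side <- function(side, what) {
    if (length(side) == 0L || is.null(names(side)) || any(names(side) == "")) {
      stop(sprintf("%s must be a named coefficient vector", what), call. = FALSE)
    }
    if (any(side <= 0) || any(side != round(side))) {
      stop(sprintf("%s coefficients must be positive integers", what),
           call. = FALSE)
    }
  }
  check_side(reactants, "reactants")
  check_side(products, "products")
  if (!is.null(delta_g_override)) {
    stopifnot(is.numeric(delta_g_override), length(delta_g_override) == 1L,
              is.finite(delta_g_override))
  }
  structure(list(label = label, reactants = reactants, products = products,
                 component_G = component_G,
                 delta_g_override = delta_g_override,
                 standard_state = standard_state, metadata = metadata),
            class = "reaction_spec")
}

#' Reaction Gibbs free energy from component free energies
#'
#' `Delta_r G = sum(coeff * G(products)) - sum(coeff * G(reactants))`, or the
#' spec's `delta_g_override` when present. A species without a free-energy
#' entry is rejected by name.
#'
#' @param spec A [reaction_spec()].
#' @return Reaction Gibbs free energy in kcal/mol.
#' @export
reaction_delta_g <- function(spec) {
  stopifnot(inherits(spec, "reaction_spec"))
  if (!is.null(spec$delta_g_override)) return(spec$delta_g_override)
  lookup <- function(side) {
    missing <- setdiff(names(side), names(spec$component_G))
    if (length(missing) > 0) {
      stop(sprintf("reaction '%s': no Gibbs free energy supplied for species: %s",
                   spec$label, paste(missing, collapse = ", ")), call. = FALSE)
    }
    sum(side * spec$component_G[names(side)])
  }
  lookup(spec$products) - lookup(spec$reactants)
}

#' Classify a reaction free energy by sign
#'
#' @param delta_g Reaction Gibbs free energy (kcal/mol).
#' @param tol Magnitudes below `tol` are called isoergonic (default 0.1).
#' @return `"exergonic"`, `"endergonic"`, or `"isoergonic"`.
#' @examples
#' classify_exergonic(-20.9369) # "exergonic"
#' @export
classify_exergonic <- function(delta_g, tol = 0.1) {
  if (!is.numeric(delta_g) || any(!is.finite(delta_g))) {
    stop("delta_g must be finite", call. = FALSE)
  }
  ifelse(abs(delta_g) < tol, "isoergonic",
         ifelse(delta_g < 0, "exergonic", "endergonic"))
}

#' Rank chelation reactions by exergonicity
#'
#' Evaluates every reaction's free energy, sorts ascending (most exergonic
#' first) with ties broken by label, groups by the `ratio` metadata entry
#' (metal:ligand stoichiometry), and emits comparative flags: the most
#' exergonic reaction overall, the best ratio group (by its most exergonic
#' member), and whether one ratio group uniformly beats another.
#'
#' @param specs List of >= 2 [reaction_spec()] objects.
#' @return List with `table` (data.frame: `label`, `ratio`, `ligand_state`,
#'   `delta_rG`, `classification`, sorted by `delta_rG`) and `flags`
#'   (`best_label`, `best_ratio`, and for each ratio pair whether the finer
#'   group is uniformly more exergonic).
#' @export
chelation_ranking <- function(specs) {
  stopifnot(is.list(specs), length(specs) >= 2L,
            all(vapply(specs, inherits, logical(1), "reaction_spec")))
  dg <- vapply(specs, reaction_delta_g, numeric(1))
  meta_chr <- function(key) vapply(specs, function(s) {
    v <- s$metadata[[key]]
    if (is.null(v)) NA_character_ else as.character(v)
  }, character(1))
  df <- data.frame(
    label = vapply(specs, `[[`, character(1), "label"),
    ratio = meta_chr("ratio"),
    ligand_state = meta_chr("ligand_state"),
    delta_rG = dg,
    classification = classify_exergonic(dg),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$delta_rG, df$label), , drop = FALSE]
  rownames(df) <- NULL
  flags <- list(best_label = df$label[1], best_ratio = df$ratio[1])
  ratios <- unique(stats::na.omit(df$ratio))
  if (length(ratios) >= 2L) {
    cmp <- list()
    for (a in ratios) for (b in ratios) {
      if (a == b) next
      ga <- df$delta_rG[df$ratio %in% a]
      gb <- df$delta_rG[df$ratio %in% b]
      cmp[[sprintf("%s_uniformly_more_exergonic_than_%s", a, b)]] <-
        max(ga) < min(gb)
    }
    flags$ratio_comparisons <- cmp
  }
  list(table = df, flags = flags)
}

#' Read a chelation reaction set from YAML
#'
#' The YAML document holds a list `reactions`, each with `label`, `reactants`
#' and `products` (species-to-coefficient maps), optional `delta_g_override`
#' (kcal/mol), optional `metadata` (e.g. `ratio`, `ligand_state`, `site`),
#' and an optional top-level `component_G` map and `standard_state` shared by
#' all reactions.
#'
#' @param path Path to the YAML file.
#' @return List of [reaction_spec()] objects.
#' @export
read_chelation_yaml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$reactions)) {
    stop(sprintf("chelation file '%s' has no 'reactions' list", path),
         call. = FALSE)
  }
  shared_G <- if (!is.null(doc$component_G)) unlist(doc$component_G) else NULL
  ss <- if (!is.null(doc$standard_state)) doc$standard_state else "aqueous-298.15K-1M"
  lapply(doc$reactions, function(r) {
    reaction_spec(
      label = r$label,
      reactants = unlist(r$reactants),
      products = unlist(r$products),
      component_G = shared_G,
      delta_g_override = r$delta_g_override,
      standard_state = ss,
      metadata = if (is.null(r$metadata)) list() else r$metadata
    )
  })
}
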