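# Post-processing of docking energy decompositions: recompose the binding
# free energy from its reported components, derive inhibition constants on
# the 1 M reference state, and compare ligand affinities. No docking is
# performed here -- the inputs are the scoring function's printed terms.

#' Recompose a binding free energy from its docking decomposition
#'
#' `dG_bind = dG_inter + dG_total + dG_tor - dG_unb`, where `dG_inter` is the
#' intermolecular energy (itself the sum of the van der Waals + hydrogen-bond
#' + desolvation term and the electrostatic term), `dG_total` the final total
#' internal energy, `dG_tor` the torsional free energy, and `dG_unb` the
#' unbound system's energy. All terms in kcal/mol.
#'
#' @param dG_inter,dG_total,dG_tor,dG_unb Decomposition terms (kcal/mol).
#' @return Binding free energy `dG_bind` in kcal/mol.
#' @examples
#' compose_binding(-9.78, -0.25, 1.49, -0.25) # -8.29
#' @export
compose_binding <- function(dG_inter, dG_total, dG_tor, dG_unb) {
  if (missing(dG_inter)) stop("missing binding component: dG_inter", call. = FALSE)
  if (missing(dG_total)) stop("missing binding component: dG_total", call. = FALSE)
  if (missing(dG_tor)) stop("missing binding component: dG_tor", call. = FALSE)
  if (missing(dG_unb)) stop("missing binding component: dG_unb", call. = FALSE)
  args <- list(dG_inter = dG_inter, dG_total = dG_total, dG_tor = dG_tor,
               dG_unb = dG_unb)
  for (nm in names(args)) {
    if (is.null(args[[nm]]) || !is.numeric(args[[nm]]) ||
        any(!is.finite(args[[nm]]))) {
      stop(sprintf("missing or non-finite binding component: %s", nm),
           call. = FALSE)
    }
  }
  dG_inter + dG_total + dG_tor - dG_unb
}

#' Inhibition constant from a binding free energy
#'
#' `Ki = exp(dG_bind / RT)` interpreted on the 1 M reference state and
#' reported in micromolar. The docking convention of evaluating at 298.15 K
#' is the default.
#'
#' @param dG_bind Binding free energy in kcal/mol (negative for favourable
#'   binding).
#' @param temperature Temperature in kelvin.
#' @return Inhibition constant in uM.
#' @examples
#' ki_from_binding(-8.29) # ~0.84 uM
#' ki_from_binding(0)     # 1e6 uM = 1 M reference
#' @export
ki_from_binding <- function(dG_bind, temperature = 298.15) {
  if (!is.numeric(dG_bind) || any(!is.finite(dG_bind))) {
    stop("dG_bind must be finite (kcal/mol)", call. = FALSE)
  }
  exp(dG_bind / thermal_rt(temperature)) * 1e6
}

#' Fold difference in affinity between two binding free energies
#'
#' `exp((dG_b - dG_a)/RT)`: the factor by which the inhibition constant of
#' ligand B exceeds that of ligand A when A binds more tightly. Swapping the
#' arguments gives the reciprocal.
#'
#' @param dG_a,dG_b Binding free energies (kcal/mol).
#' @param temperature Temperature in kelvin.
#' @return Fold ratio `Ki_b / Ki_a` (dimensionless).
#' @examples
#' affinity_ratio(-8.29, -7.25) # ~5.8, i.e. ~6-fold
#' @export
affinity_ratio <- function(dG_a, dG_b, temperature = 298.15) {
  exp((dG_b - dG_a) / thermal_rt(temperature))
}

#' Read a docking binding-decomposition table (TSV)
#'
#' Expects tab-separated columns `complex_label`, `dG_bind`, `Ki_uM`,
#' `dG_inter`, `dG_vdw_hbond_desolv`, `dG_elec`, `dG_total`, `dG_tor`,
#' `dG_unb` (the full seven-term decomposition plus the reported binding
#' energy and inhibition constant).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the columns above.
#' @export
read_binding_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#")
  required <- c("complex_label", "dG_bind", "Ki_uM", "dG_inter",
                "dG_vdw_hbond_desolv", "dG_elec", "dG_total", "dG_tor",
                "dG_unb")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("binding table '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Consistency report for a binding-decomposition table
#'
#' For each complex: recomposes `dG_bind` from the components, derives the
#' inhibition constant from the reported `dG_bind`, and flags whether the
#' printed values are internally consistent -- `dG_inter` against
#' `dG_vdw_hbond_desolv + dG_elec` and `dG_bind` against the recomposition
#' (both within `energy_tol`, reflecting printed rounding), and the derived
#' Ki against the printed one (within `ki_rel_tol` relative).
#'
#' @param decomp A data.frame as returned by [read_binding_table()].
#' @param temperature Temperature in kelvin for the Ki derivation.
#' @param energy_tol Energy consistency tolerance (kcal/mol), default 0.02.
#' @param ki_rel_tol Relative Ki tolerance, default 0.01.
#' @return The input with added columns `dG_bind_recomposed`, `Ki_uM_derived`,
#'   `inter_consistent`, `bind_consistent`, `ki_consistent`.
#' @export
binding_report <- function(decomp, temperature = 298.15, energy_tol = 0.02,
                           ki_rel_tol = 0.01) {
  stopifnot(is.data.frame(decomp))
  decomp$dG_bind_recomposed <- compose_binding(decomp$dG_inter,
                                               decomp$dG_total,
                                               decomp$dG_tor, decomp$dG_unb)
  decomp$Ki_uM_derived <- ki_from_binding(decomp$dG_bind, temperature)
  decomp$inter_consistent <-
    abs(decomp$dG_inter - (decomp$dG_vdw_hbond_desolv + decomp$dG_elec)) <= energy_tol
  decomp$bind_consistent <-
    abs(decomp$dG_bind - decomp$dG_bind_recomposed) <= energy_tol
  decomp$ki_consistent <-
    abs(decomp$Ki_uM_derived - decomp$Ki_uM) / decomp$Ki_uM <= ki_rel_tol
  attr(decomp, "temperature") <- temperature
  attr(decomp, "ki_model") <- "Ki = exp(dG_bind/RT), 1 M reference state"
  decomp
}
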