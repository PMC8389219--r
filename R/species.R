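# Stationary-point records: one row per optimized species (or separated
# reactant/product) with its Gibbs free energy, mechanistic role, spin
# multiplicity and -- for saddle points -- the magnitude of the imaginary
# frequency. These records are the common currency of the kinetics modules.

.species_roles <- c("reactant", "reactant_complex", "transition_state",
                    "mecp", "product_complex", "product")

#' Create a stationary-point thermochemistry record
#'
#' A `species_thermo` holds the Gibbs free energy of one species together with
#' its role along a reaction path. Transition states and MECPs must carry a
#' positive imaginary-frequency magnitude; minima must not carry one. Energies
#' are stored in kcal/mol (convert on input with [convert_energy()]).
#'
#' @param name Species label.
#' @param role One of `"reactant"`, `"reactant_complex"`, `"transition_state"`,
#'   `"mecp"`, `"product_complex"`, `"product"`.
#' @param gibbs_energy Gibbs free energy in kcal/mol.
#' @param imag_frequency Imaginary-frequency magnitude in cm^-1 (positive);
#'   `NA` for minima. A negative value (the common sign convention for saddle
#'   points in program output) is accepted and stored as its magnitude.
#' @param multiplicity Spin multiplicity (integer >= 1; singlet = 1,
#'   triplet = 3).
#' @return An object of class `species_thermo`.
#' @examples
#' species_thermo("TS-C8", "transition_state", 8.6, imag_frequency = 306,
#'                multiplicity = 1)
#' @export
species_thermo <- function(name, role, gibbs_energy, imag_frequency = NA_real_,
                           multiplicity = 1L) {
  role <- match.arg(role, .species_roles)
  if (!is.numeric(gibbs_energy) || length(gibbs_energy) != 1L ||
      !is.finite(gibbs_energy)) {
    stop("gibbs_energy must be a single finite number (kcal/mol)",
         call. = FALSE)
  }
  if (length(imag_frequency) != 1L) {
    stop("imag_frequency must be a single value or NA", call. = FALSE)
  }
  if (!is.na(imag_frequency)) {
    imag_frequency <- abs(as.numeric(imag_frequency))
    if (!is.finite(imag_frequency) || imag_frequency <= 0) {
      stop("imag_frequency must be a positive wavenumber (cm^-1)",
           call. = FALSE)
    }
  } else {
    imag_frequency <- NA_real_
  }
  multiplicity <- as.integer(multiplicity)
  if (is.na(multiplicity) || multiplicity < 1L) {
    stop("multiplicity must be a positive integer", call. = FALSE)
  }
  saddle <- role %in% c("transition_state", "mecp")
  if (saddle && is.na(imag_frequency)) {
    stop(sprintf("species '%s' with role '%s' must carry an imaginary frequency",
                 name, role), call. = FALSE)
  }
  if (!saddle && !is.na(imag_frequency)) {
    stop(sprintf("species '%s' is a minimum (role '%s') and must not carry an imaginary frequency",
                 name, role), call. = FALSE)
  }
  structure(
    list(name = as.character(name), role = role,
         gibbs_energy = as.numeric(gibbs_energy),
         imag_frequency = imag_frequency, multiplicity = multiplicity),
    class = "species_thermo"
  )
}

#' @export
print.species_thermo <- function(x, ...) {
  nu <- if (is.na(x$imag_frequency)) "-" else sprintf("%.1fi cm^-1", x$imag_frequency)
  cat(sprintf("<species_thermo> %s [%s] G = %.4f kcal/mol, nu = %s, 2S+1 = %d\n",
              x$name, x$role, x$gibbs_energy, nu, x$multiplicity))
  invisible(x)
}

#' Read a species thermochemistry table (TSV)
#'
#' The dialect is a UTF-8 tab-separated table with header columns
#' `name`, `role`, `G`, `G_unit`, `nu_imag_cm1`, `multiplicity`; lines starting
#' with `#` are comments. Energies are normalized to kcal/mol on read using
#' the `G_unit` column (`hartree`, `kcal/mol`, `kJ/mol`, `cm-1`). Imaginary
#' frequencies may be written with a leading minus sign (program-output
#' convention); the magnitude is stored. All `species_thermo` invariants are
#' enforced, with row numbers reported on failure.
#'
#' @param path Path to the TSV file.
#' @return A list of [species_thermo()] records.
#' @seealso [write_species_table()]
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  required <- c("name", "role", "G", "G_unit", "nu_imag_cm1", "multiplicity")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("species table '%s' is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    nu <- trimws(row$nu_imag_cm1)
    nu <- if (identical(nu, "") || is.na(nu)) NA_real_ else as.numeric(nu)
    rec <- tryCatch(
      species_thermo(
        name = row$name, role = trimws(row$role),
        gibbs_energy = convert_energy(as.numeric(row$G), row$G_unit, "kcal/mol"),
        imag_frequency = nu,
        multiplicity = as.integer(row$multiplicity)
      ),
      error = function(e) {
        stop(sprintf("species table '%s', row %d: %s", path, i,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    out[[i]] <- rec
  }
  out
}

#' Write a species thermochemistry table (TSV)
#'
#' Serializes records in the dialect read by [read_species_table()]; energies
#' are written in kcal/mol so a read/write round trip preserves every field.
#'
#' @param species A list of [species_thermo()] records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(species, path) {
  stopifnot(is.list(species),
            all(vapply(species, inherits, logical(1), "species_thermo")))
  df <- data.frame(
    name = vapply(species, `[[`, character(1), "name"),
    role = vapply(species, `[[`, character(1), "role"),
    G = vapply(species, `[[`, numeric(1), "gibbs_energy"),
    G_unit = "kcal/mol",
    nu_imag_cm1 = vapply(species, `[[`, numeric(1), "imag_frequency"),
    multiplicity = vapply(species, `[[`, integer(1), "multiplicity"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
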