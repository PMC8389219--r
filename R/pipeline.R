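# Config-driven pipeline runs: each stage reads its declared input files,
# executes the corresponding module, and emits a TSV report (numbers at
# report precision) together with a full-precision JSON twin. Reports carry
# no timestamps, so identical inputs give byte-identical outputs.

#' Read a pathway definition file (YAML)
#'
#' The document holds a list `pathways`, each with `id`, optional `mechanism`
#' (`PCET`, `HAT`, `RRC`, `RAF`, `tautomerization`), `sigma` (default 1),
#' `molecularity`, optional `temperature`, optional `kappa` (`eckart`,
#' `wigner`, `none`, or a number), optional `n_waters`, and a `species` map
#' from role to species name(s) resolved against a species table.
#'
#' @param path Path to the YAML file.
#' @return List of pathway definition lists.
#' @export
read_pathway_yaml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$pathways) || length(doc$pathways) == 0L) {
    stop(sprintf("pathway file '%s' defines no pathways", path), call. = FALSE)
  }
  doc$pathways
}

# resolve one pathway definition against a species list and build its rate
.build_pathway <- function(def, species, default_temperature = 298.15) {
  names_all <- vapply(species, `[[`, character(1), "name")
  wanted <- unlist(def$species, use.names = FALSE)
  missing <- setdiff(wanted, names_all)
  if (length(missing) > 0) {
    stop(sprintf("pathway '%s': species not found in table: %s", def$id,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  subset <- species[match(wanted, names_all)]
  kappa <- if (is.null(def$kappa)) "eckart" else def$kappa
  pathway_rate(
    subset,
    sigma = if (is.null(def$sigma)) 1L else as.integer(def$sigma),
    temperature = if (is.null(def$temperature)) default_temperature else def$temperature,
    molecularity = if (is.null(def$molecularity)) "unimolecular" else def$molecularity,
    kappa = kappa,
    path_label = def$id
  )
}

#' Run the rate-constant stage
#'
#' Reads a species table and a pathway file, computes every pathway's
#' TST/Eckart rate, and appends the overall (summed) rate with branching
#' fractions. Bimolecular path sets additionally get a diffusion-limit
#' classification.
#'
#' @param config List with `species` (species TSV path), `pathways` (pathway
#'   YAML path), optional `temperature` (default 298.15), optional `out_dir`
#'   and `formats` (subset of `"tsv"`, `"json"`).
#' @return List with `table` (per-path rows), `overall` (`k_overall`,
#'   `branching`), `paths` (the `pathway_rate` objects), and `files` written.
#' @export
run_rates <- function(config) {
  stopifnot(is.list(config), !is.null(config$species), !is.null(config$pathways))
  temperature <- if (is.null(config$temperature)) 298.15 else config$temperature
  species <- read_species_table(config$species)
  defs <- read_pathway_yaml(config$pathways)
  paths <- lapply(defs, .build_pathway, species = species,
                  default_temperature = temperature)
  ov <- overall_rate(paths)
  tab <- data.frame(
    path = vapply(paths, `[[`, character(1), "path_label"),
    delta_rG = vapply(paths, `[[`, numeric(1), "delta_rG"),
    delta_G_act = vapply(paths, `[[`, numeric(1), "delta_G_act"),
    nu = vapply(paths, `[[`, numeric(1), "imag_frequency"),
    k_tst = vapply(paths, `[[`, numeric(1), "k_tst"),
    kappa_eck = vapply(paths, `[[`, numeric(1), "kappa_eckart"),
    k_tst_eck = vapply(paths, `[[`, numeric(1), "k_tst_eck"),
    stringsAsFactors = FALSE
  )
  molec <- paths[[1]]$molecularity
  if (molec == "bimolecular") {
    tab$diffusion_class <- classify_diffusion_limited(tab$k_tst_eck, molec)
  }
  result <- list(table = tab, overall = ov, paths = paths)
  result$files <- .write_stage_reports(
    config, "rates",
    tsv = .format_rates_tsv(tab, ov),
    json = list(table = tab, k_overall = ov$k_overall,
                branching = as.list(ov$branching), temperature = temperature,
                molecularity = molec))
  result
}

.format_rates_tsv <- function(tab, ov) {
  ftab <- tab
  for (col in c("delta_rG", "delta_G_act")) ftab[[col]] <- sprintf("%.2f", ftab[[col]])
  ftab$nu <- sprintf("%.0f", ftab$nu)
  for (col in c("k_tst", "kappa_eck", "k_tst_eck")) {
    ftab[[col]] <- sprintf("%.1e", signif(tab[[col]], 2))
  }
  c(paste(names(ftab), collapse = "\t"),
    apply(ftab, 1, paste, collapse = "\t"),
    sprintf("k_overall\t\t\t\t\t\t%.1e", signif(ov$k_overall, 2)))
}

# shared writer: returns the file paths written (possibly none)
.write_stage_reports <- function(config, stage, tsv, json) {
  files <- character(0)
  if (is.null(config$out_dir)) return(files)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  formats <- if (is.null(config$formats)) c("tsv", "json") else config$formats
  if ("tsv" %in% formats) {
    f <- file.path(config$out_dir, paste0(stage, ".tsv"))
    writeLines(tsv, f)
    files <- c(files, f)
  }
  if ("json" %in% formats) {
    f <- file.path(config$out_dir, paste0(stage, ".json"))
    jsonlite::write_json(json, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f)
  }
  files
}

#' Run the spin-crossing stage
#'
#' Reads a two-state profile scan, locates and classifies every crossing,
#' and reports the lowest-energy crossing as the predicted MECP.
#'
#' @param config List with `profile` (profile TSV path), optional `out_dir`,
#'   `formats`.
#' @return List with `crossings` (classified `crossing_point`s), `predicted`
#'   (lowest-energy crossing or `NULL`), and `files`.
#' @export
run_mecp <- function(config) {
  stopifnot(is.list(config), !is.null(config$profile))
  profile <- read_profile_tsv(config$profile)
  crossings <- lapply(find_profile_crossings(profile), classify_crossing,
                      profile = profile)
  predicted <- if (length(crossings) > 0) {
    crossings[[which.min(vapply(crossings, `[[`, numeric(1), "energy"))]]
  }
  rows <- if (length(crossings) > 0) {
    data.frame(
      coordinate = vapply(crossings, `[[`, numeric(1), "coordinate"),
      energy = vapply(crossings, `[[`, numeric(1), "energy"),
      relevance = vapply(crossings, `[[`, character(1), "relevance"))
  } else {
    data.frame(coordinate = numeric(0), energy = numeric(0),
               relevance = character(0))
  }
  files <- .write_stage_reports(
    config, "mecp",
    tsv = c("coordinate\tenergy\trelevance",
            if (nrow(rows)) sprintf("%.5f\t%.4f\t%s", rows$coordinate,
                                    rows$energy, rows$relevance)),
    json = list(crossings = rows,
                ts_coordinate = profile$ts_coordinate))
  list(crossings = crossings, predicted = predicted, files = files)
}

#' Run the speciation stage
#'
#' @param config List with `pka` (numeric vector), `ph` (number), optional
#'   `labels`, `name`, `out_dir`, `formats`.
#' @return List with `result` (a `speciation_result`), `dominant`, `files`.
#' @export
run_speciation <- function(config) {
  stopifnot(is.list(config), !is.null(config$pka), !is.null(config$ph))
  acid <- polyprotic_acid(as.numeric(config$pka),
                          state_labels = config$labels,
                          name = if (is.null(config$name)) "acid" else config$name)
  res <- species_fractions(acid, as.numeric(config$ph))
  dom <- dominant_species(acid, as.numeric(config$ph))
  files <- .write_stage_reports(
    config, "speciation",
    tsv = c("species\tfraction",
            sprintf("%s\t%.4f", names(res$fractions), res$fractions)),
    json = list(ph = res$ph, fractions = as.list(res$fractions),
                dominant = dom))
  list(result = res, dominant = dom, files = files)
}

#' Run the chelation-energetics stage
#'
#' @param config List with `reactions` (chelation YAML path), optional
#'   `out_dir`, `formats`.
#' @return List with `ranking` (see [chelation_ranking()]) and `files`.
#' @export
run_chelation <- function(config) {
  stopifnot(is.list(config), !is.null(config$reactions))
  specs <- read_chelation_yaml(config$reactions)
  ranking <- chelation_ranking(specs)
  tab <- ranking$table
  files <- .write_stage_reports(
    config, "chelation",
    tsv = c("label\tratio\tligand_state\tdelta_rG\tclassification",
            sprintf("%s\t%s\t%s\t%.4f\t%s", tab$label, tab$ratio,
                    tab$ligand_state, tab$delta_rG, tab$classification)),
    json = list(table = tab, flags = ranking$flags))
  list(ranking = ranking, files = files)
}

#' Run the binding-energetics stage
#'
#' @param config List with `table` (binding TSV path), optional
#'   `temperature`, `out_dir`, `formats`.
#' @return List with `report` (see [binding_report()]) and `files`.
#' @export
run_binding <- function(config) {
  stopifnot(is.list(config), !is.null(config$table))
  temperature <- if (is.null(config$temperature)) 298.15 else config$temperature
  rep <- binding_report(read_binding_table(config$table),
                        temperature = temperature)
  header <- paste(names(rep), collapse = "\t")
  body <- apply(rep, 1, function(r) paste(trimws(as.character(r)), collapse = "\t"))
  files <- .write_stage_reports(
    config, "binding", tsv = c(header, body),
    json = list(table = rep, temperature = temperature,
                ki_model = attr(rep, "ki_model")))
  list(report = rep, files = files)
}

#' Run every stage whose inputs are configured
#'
#' Executes the rates, MECP, speciation, chelation and binding stages for
#' whichever sections are present in the configuration; a failing stage is
#' recorded as failed without aborting the others. A summary JSON enumerating
#' stage statuses is written when `out_dir` is set.
#'
#' @param config Either a path to a YAML run configuration or an equivalent
#'   list, with optional top-level `temperature`, `out_dir`, `formats`, and
#'   per-stage sections `rates`, `mecp`, `speciation`, `chelation`,
#'   `binding` (arguments as in the individual `run_*` functions).
#' @return List with per-stage `results`, a `status` character vector
#'   (`"ok"`, `"skipped"`, `"failed"`), and `summary_file` (or `NULL`).
#' @export
run_full <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  stages <- c("rates", "mecp", "speciation", "chelation", "binding")
  runners <- list(rates = run_rates, mecp = run_mecp,
                  speciation = run_speciation, chelation = run_chelation,
                  binding = run_binding)
  status <- stats::setNames(rep("skipped", length(stages)), stages)
  results <- stats::setNames(vector("list", length(stages)), stages)
  errors <- stats::setNames(rep(NA_character_, length(stages)), stages)
  for (stage in stages) {
    sub <- config[[stage]]
    if (is.null(sub)) next
    for (key in c("temperature", "out_dir", "formats")) {
      if (is.null(sub[[key]]) && !is.null(config[[key]])) sub[[key]] <- config[[key]]
    }
    out <- tryCatch(list(ok = TRUE, value = runners[[stage]](sub)),
                    error = function(e) list(ok = FALSE,
                                             msg = conditionMessage(e)))
    if (out$ok) {
      status[stage] <- "ok"
      results[[stage]] <- out$value
    } else {
      status[stage] <- "failed"
      errors[stage] <- out$msg
    }
  }
  summary_file <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    summary_file <- file.path(config$out_dir, "summary.json")
    jsonlite::write_json(
      list(stages = lapply(stages, function(s) list(
        stage = s, status = unname(status[s]),
        error = if (is.na(errors[s])) NULL else unname(errors[s])))),
      summary_file, auto_unbox = TRUE, pretty = TRUE)
  }
  list(results = results, status = status, errors = errors,
       summary_file = summary_file)
}
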