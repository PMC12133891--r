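#' Read a whole-body model from disk
#'
#' Supported formats:
#' * the package's JSON dialect (`*.json`): metadata plus reaction records
#'   and stoichiometric triplets, as written by [write_wbm()];
#' * the triplet TSV dialect: a directory containing `reactions.tsv`,
#'   `stoich.tsv` and optionally `metadata.json`;
#' * SBML Level 3 with the `fbc` flux-bounds package (`*.xml`/`*.sbml`),
#'   read with a minimal reader built on xml2.
#'
#' Reaction kinds are classified from identifiers under `convention` unless
#' the file carries an explicit `kind` column; organ-blood exchanges written
#' blood-negative are re-oriented to the secretion-positive convention and
#' the flips recorded in the returned model.
#'
#' @param path File or directory path.
#' @param convention A [naming_convention()].
#' @return A validated [wbm()] model.
#' @export
read_wbm <- function(path, convention = naming_convention()) {
  if (!file.exists(path)) {
    abort(paste0("Model path does not exist: ", path),
          class = "dietwbm_format_error")
  }
  if (dir.exists(path)) {
    return(read_wbm_tsv(path, convention))
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = read_wbm_json(path, convention),
    xml = ,
    sbml = read_wbm_sbml(path, convention),
    abort(paste0("Unrecognized model format: .", ext),
          class = "dietwbm_format_error")
  )
}

read_wbm_json <- function(path, convention) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(paste0("Failed to parse model JSON: ", conditionMessage(e)),
                          class = "dietwbm_format_error")
                  })
  need <- c("model_id", "sex", "organs", "reactions", "stoich")
  if (!all(need %in% names(obj))) {
    abort("Model JSON is missing required fields.", class = "dietwbm_format_error")
  }
  wbm(
    reactions = as_tibble(obj$reactions),
    stoich = as_tibble(obj$stoich),
    sex = obj$sex,
    organs = as.character(unlist(obj$organs)),
    physiology = unlist(obj$physiology),
    convention = convention,
    model_id = obj$model_id
  )
}

read_wbm_tsv <- function(dir, convention) {
  rx_path <- file.path(dir, "reactions.tsv")
  st_path <- file.path(dir, "stoich.tsv")
  if (!file.exists(rx_path) || !file.exists(st_path)) {
    abort("Triplet model directory must contain reactions.tsv and stoich.tsv.",
          class = "dietwbm_format_error")
  }
  rx <- readr::read_tsv(rx_path, show_col_types = FALSE, progress = FALSE)
  st <- readr::read_tsv(st_path, show_col_types = FALSE, progress = FALSE)
  meta_path <- file.path(dir, "metadata.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
          else list(model_id = basename(dir), sex = "male", organs = character())
  wbm(rx, st, sex = meta$sex, organs = as.character(unlist(meta$organs)),
      physiology = unlist(meta$physiology), convention = convention,
      model_id = meta$model_id %||% basename(dir))
}

#' Write a whole-body model to disk
#'
#' Writes either the JSON dialect (single file, `format = "json"`) or the
#' triplet TSV dialect (directory with `reactions.tsv`, `stoich.tsv`,
#' `metadata.json`). Either round-trips exactly through [read_wbm()]:
#' identical reaction ids, bounds and stoichiometric coefficients.
#'
#' @param model A [wbm()] model.
#' @param path Target file (json) or directory (tsv).
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_wbm <- function(model, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      model_id = model$model_id,
      sex = model$sex,
      organs = model$organs,
      physiology = model$physiology,
      reactions = model$reactions,
      stoich = model$stoich
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(model$reactions, file.path(path, "reactions.tsv"), progress = FALSE)
    readr::write_tsv(model$stoich, file.path(path, "stoich.tsv"), progress = FALSE)
    jsonlite::write_json(
      list(model_id = model$model_id, sex = model$sex, organs = model$organs,
           physiology = model$physiology),
      file.path(path, "metadata.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# Minimal SBML L3 (+fbc v2) reader: species, reactions with
# reactant/product stoichiometries, and flux bounds resolved through fbc
# lowerFluxBound/upperFluxBound parameter references. Organs must be given
# by the caller or are inferred from metabolite prefixes.
read_wbm_sbml <- function(path, convention, organs = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("Failed to parse SBML: ", conditionMessage(e)),
          class = "dietwbm_format_error")
  })
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (is.na(xml2::xml_name(model_node))) {
    abort("SBML file contains no <model> element.", class = "dietwbm_format_error")
  }

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  get_bound <- function(node, which, default) {
    ref <- xml2::xml_attr(node, which)
    if (!is.na(ref) && ref %in% names(pvals)) pvals[[ref]] else default
  }
  rows <- list(); trip <- list()
  for (node in rx_nodes) {
    rid <- xml2::xml_attr(node, "id")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- get_bound(node, "lowerFluxBound", if (rev) -BIG_M else 0)
    ub <- get_bound(node, "upperFluxBound", BIG_M)
    rows[[length(rows) + 1]] <- tibble(id = rid, lb = lb, ub = ub)
    for (sp in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      s <- xml2::xml_attr(sp, "stoichiometry"); s <- if (is.na(s)) 1 else as.numeric(s)
      trip[[length(trip) + 1]] <- tibble(
        reaction_id = rid, metabolite_id = xml2::xml_attr(sp, "species"), coef = -s)
    }
    for (sp in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      s <- xml2::xml_attr(sp, "stoichiometry"); s <- if (is.na(s)) 1 else as.numeric(s)
      trip[[length(trip) + 1]] <- tibble(
        reaction_id = rid, metabolite_id = xml2::xml_attr(sp, "species"), coef = s)
    }
  }
  if (!length(rows)) {
    abort("SBML model has no reactions.", class = "dietwbm_format_error")
  }
  reactions <- bind_rows(rows)
  stoich <- bind_rows(trip)

  if (is.null(organs)) {
    # infer organ vocabulary from metabolite prefixes of organ compartments
    mets <- unique(stoich$metabolite_id)
    comp <- compartment_of(mets)
    candidates <- mets[!is.na(comp) & !comp %in% c(convention$blood_tag, convention$lumen_tag)]
    organs <- sort(unique(vapply(
      strsplit(candidates, convention$organ_separator, fixed = TRUE),
      `[[`, character(1), 1)))
  }
  sex <- xml2::xml_attr(model_node, "name")
  sex <- if (!is.na(sex) && grepl("female", sex, ignore.case = TRUE)) "female" else "male"
  wbm(reactions, stoich, sex = sex, organs = organs, convention = convention,
      model_id = xml2::xml_attr(model_node, "id") %||% "sbml_model")
}

#' Write a flux solution to disk
#'
#' @param solution A [pfba()]/[fba()] `flux_solution`.
#' @param path Target path; `.tsv` writes the `reaction_id`/`flux` table,
#'   `.json` additionally stores status, objective and residual diagnostics.
#' @return `path`, invisibly.
#' @export
write_flux_solution <- function(solution, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") {
    readr::write_tsv(solution$fluxes, path, progress = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(
      list(status = solution$status, objective = solution$objective,
           max_mass_balance_residual = solution$max_mass_balance_residual,
           max_bound_violation = solution$max_bound_violation,
           fluxes = solution$fluxes),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    abort("Flux solutions are written as .tsv or .json.",
          class = "dietwbm_format_error")
  }
  invisible(path)
}
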