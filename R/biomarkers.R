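panel_metrics <- c("glucose_exchange", "tag_synthesis", "ldl_exchange",
                   "hdl_exchange", "fao")

#' Resolve the metabolic-syndrome biomarker reaction panel
#'
#' Maps each biomarker to concrete reaction identifiers in a model. Each
#' metric is configured either with an explicit `ids` vector (the route
#' used for real whole-body models, whose reaction lists come from
#' supplementary material) or with a structural `pattern` rule resolved
#' against the model:
#'
#' * `glucose_exchange`, `ldl_exchange`, `hdl_exchange`: pattern
#'   `list(base_id = ...)` collects every organ-blood exchange of that
#'   metabolite (via [find_organ_exchanges()]).
#' * `tag_synthesis`: pattern `list(organ = ..., regex = ...)` collects
#'   matching reactions of that organ (default: adipocyte esterification).
#' * `fao`: pattern `list(organs = ..., consumes = ..., produces = ...)`
#'   collects reactions in those organs whose stoichiometry consumes the
#'   one metabolite base and produces the other (default: the thiolase
#'   step, butyryl-CoA to acetyl-CoA, in muscle and heart).
#'
#' @param model A [wbm()] model.
#' @param config Named list of per-metric configurations; defaults resolve
#'   the synthetic models structurally.
#' @return A `biomarker_panel`: list of reaction-id vectors per metric plus
#'   `sex`, with a resolution manifest attribute.
#' @export
resolve_panel <- function(model, config = default_panel_config()) {
  out <- list()
  for (metric in panel_metrics) {
    cfg <- config[[metric]]
    if (is.null(cfg)) {
      abort(paste0("Panel config missing metric: ", metric),
            class = "dietwbm_resolution_error")
    }
    if (!is.null(cfg$ids)) {
      missing <- setdiff(cfg$ids, model$reactions$id)
      if (length(missing)) {
        abort(sprintf("Panel metric %s lists %d id(s) absent from the model: %s",
                      metric, length(missing), paste(head(missing, 5), collapse = ", ")),
              class = "dietwbm_resolution_error")
      }
      ids <- cfg$ids
    } else if (!is.null(cfg$pattern)) {
      ids <- resolve_pattern(model, cfg$pattern)
      if (!length(ids)) {
        abort(sprintf("Panel pattern for %s resolved to zero reactions (%s).",
                      metric, paste(names(cfg$pattern), unlist(cfg$pattern),
                                    sep = "=", collapse = ", ")),
              class = "dietwbm_resolution_error")
      }
    } else {
      abort(paste0("Metric ", metric, " must provide ids or a pattern."),
            class = "dietwbm_resolution_error")
    }
    out[[metric]] <- sort(ids)
  }
  out$sex <- model$sex
  manifest <- tibble(metric = panel_metrics,
                     n_reactions = map_dbl(panel_metrics, ~ length(out[[.x]])))
  structure(out, manifest = manifest, class = "biomarker_panel")
}

resolve_pattern <- function(model, pattern) {
  if (!is.null(pattern$base_id)) {
    return(find_organ_exchanges(model, pattern$base_id)$reaction_id)
  }
  rx <- model$reactions
  keep <- rep(TRUE, nrow(rx))
  orgs <- pattern$organ %||% pattern$organs
  if (!is.null(orgs)) keep <- keep & !is.na(rx$organ) & rx$organ %in% orgs
  if (!is.null(pattern$regex)) keep <- keep & grepl(pattern$regex, rx$id)
  ids <- rx$id[keep]
  if (!is.null(pattern$consumes) || !is.null(pattern$produces)) {
    met_base <- setNames(model$metabolites$base_id, model$metabolites$id)
    keep <- map_lgl(ids, function(rid) {
      s <- model$stoich[model$stoich$reaction_id == rid, ]
      bases_in <- met_base[s$metabolite_id[s$coef < 0]]
      bases_out <- met_base[s$metabolite_id[s$coef > 0]]
      ok <- TRUE
      if (!is.null(pattern$consumes)) ok <- ok && pattern$consumes %in% bases_in
      if (!is.null(pattern$produces)) ok <- ok && pattern$produces %in% bases_out
      ok
    })
    ids <- ids[keep]
  }
  ids
}

#' Default biomarker panel configuration
#'
#' Structural pattern rules matching the synthetic whole-body models:
#' glucose/LDL-C/HDL-C organ-blood exchanges by metabolite base id,
#' adipocyte esterification reactions for TAG synthesis, and the
#' butyryl-CoA to acetyl-CoA (thiolase) step in muscle and heart for fatty
#' acid oxidation.
#'
#' @param glucose_base,ldl_base,hdl_base Metabolite base ids.
#' @return A named list usable as `config` in [resolve_panel()].
#' @export
default_panel_config <- function(glucose_base = "glc_D", ldl_base = "ldlc",
                                 hdl_base = "hdlc") {
  list(
    glucose_exchange = list(pattern = list(base_id = glucose_base)),
    tag_synthesis = list(pattern = list(organ = "Adipocyte", regex = "TAGSYN")),
    ldl_exchange = list(pattern = list(base_id = ldl_base)),
    hdl_exchange = list(pattern = list(base_id = hdl_base)),
    fao = list(pattern = list(organs = c("Muscle", "Heart"),
                              consumes = "butcoa", produces = "accoa"))
  )
}

#' Read a biomarker panel configuration from YAML or JSON
#'
#' Each metric entry provides either an `ids` list or a `pattern` mapping,
#' mirroring [default_panel_config()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A config list for [resolve_panel()].
#' @export
read_panel_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("Panel config must be YAML or JSON.", class = "dietwbm_format_error")
  }
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("<biomarker_panel> (%s)\n", x$sex))
  for (m in panel_metrics) {
    cat(sprintf("  %-17s %d reactions\n", m, length(x[[m]])))
  }
  invisible(x)
}

get_fluxes <- function(solution, reactions) {
  i <- match(reactions, solution$fluxes$reaction_id)
  if (anyNA(i)) {
    abort(paste0("Reactions absent from solution: ",
                 paste(reactions[is.na(i)], collapse = ", ")),
          class = "dietwbm_integrity_error")
  }
  setNames(solution$fluxes$flux[i], reactions)
}

#' Secretion and uptake totals over exchange reactions
#'
#' Under the secretion-positive sign convention, total secretion is the
#' sum of positive parts and total uptake the sum of negative parts
#' (positive-part sums, not the net, because organs secreting and organs
#' taking up are tallied separately; the net is reported alongside).
#'
#' @param solution A `flux_solution`.
#' @param reactions Character vector of exchange reaction ids.
#' @return One-row tibble: `total_secretion`, `total_uptake`, `net`.
#' @export
secretion_uptake_totals <- function(solution, reactions) {
  v <- get_fluxes(solution, reactions)
  tibble(total_secretion = sum(pmax(v, 0)),
         total_uptake = sum(pmax(-v, 0)),
         net = sum(v))
}

#' Signed sum of fluxes over a reaction set
#'
#' Plain signed aggregate flux, used e.g. for total adipocyte TAG
#' esterification and for total butyryl-CoA breakdown in muscle and heart.
#'
#' @inheritParams secretion_uptake_totals
#' @return A single numeric value; an empty reaction list returns 0 with a
#'   warning.
#' @export
sum_flux <- function(solution, reactions) {
  if (!length(reactions)) {
    warn("Empty reaction list; sum_flux returns 0.",
         class = "dietwbm_empty_reactions")
    return(0)
  }
  sum(get_fluxes(solution, reactions))
}

#' LDL-C to HDL-C secretion flux ratio
#'
#' Ratio of total LDL-C secretion to total HDL-C secretion into blood
#' (positive parts only). A vanishing HDL-C total raises a division-guard
#' error rather than returning infinity.
#'
#' @param solution A `flux_solution`.
#' @param ldl,hdl Reaction id vectors for the LDL-C and HDL-C organ-blood
#'   exchanges.
#' @param guard Smallest admissible HDL-C secretion total.
#' @return A single numeric ratio.
#' @export
ldl_hdl_ratio <- function(solution, ldl, hdl, guard = 1e-9) {
  ldl_tot <- secretion_uptake_totals(solution, ldl)$total_secretion
  hdl_tot <- secretion_uptake_totals(solution, hdl)$total_secretion
  if (hdl_tot <= guard) {
    abort(sprintf("HDL-C secretion total %.3g below guard %.3g; ratio undefined.",
                  hdl_tot, guard),
          class = "dietwbm_undefined_ratio")
  }
  ldl_tot / hdl_tot
}

#' Organ-by-diet exchange flux table
#'
#' Per-organ exchange flux of one metabolite for every solved diet
#' (secretion > 0); organs with several exchange reactions for the
#' metabolite are summed within organ.
#'
#' @param solutions Named list (diet -> `flux_solution`), all with status
#'   `optimal`.
#' @param exchanges Tibble with columns `organ`, `reaction_id` (e.g. from
#'   [find_organ_exchanges()]).
#' @return An `organ_flux_table`: tibble with `organ` and one numeric
#'   column per diet.
#' @export
organ_contribution_table <- function(solutions, exchanges) {
  bad <- names(solutions)[map_chr(solutions, "status") != "optimal"]
  if (length(bad)) {
    abort(paste0("Unsolved diets: ", paste(bad, collapse = ", ")),
          class = "dietwbm_partial_table_error")
  }
  organs <- sort(unique(exchanges$organ))
  cols <- map(solutions, function(s) {
    v <- get_fluxes(s, exchanges$reaction_id)
    unname(vapply(organs, function(o) {
      sum(v[exchanges$reaction_id[exchanges$organ == o]])
    }, numeric(1)))
  })
  out <- bind_cols(tibble(organ = organs), as_tibble(cols))
  structure(out, class = c("organ_flux_table", class(out)))
}

#' Classify organ roles from an organ-by-diet flux table
#'
#' An organ is a `secretor` when its exchange flux exceeds `tau` under
#' every diet, an `uptaker` when below `-tau` under every diet, `inactive`
#' when within `[-tau, tau]` under every diet, and `mixed` otherwise.
#' `tau` (mmol/day/person) operationalizes "consistent" engagement.
#'
#' @param table An [organ_contribution_table()].
#' @param tau Activity threshold in mmol/day/person.
#' @return Tibble with columns `organ`, `role`.
#' @export
classify_organ_roles <- function(table, tau = 1e-6) {
  vals <- as.matrix(table[, setdiff(names(table), "organ"), drop = FALSE])
  role <- apply(vals, 1, function(v) {
    if (all(v > tau)) "secretor"
    else if (all(v < -tau)) "uptaker"
    else if (all(abs(v) <= tau)) "inactive"
    else "mixed"
  })
  tibble(organ = table$organ, role = role)
}
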