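#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flux solution into its reaction-flux table
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return Tibble with columns `reaction_id`, `flux` (mmol/day/person).
#' @method tidy flux_solution
#' @export
tidy.flux_solution <- function(x, ...) x$fluxes

#' One-row summary of a flux solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return One-row tibble with status, objective and residual diagnostics.
#' @method glance flux_solution
#' @export
glance.flux_solution <- function(x, ...) {
  tibble(model_id = x$model_id, sex = x$sex, status = x$status,
         norm = x$norm, backend = x$backend, objective = x$objective,
         max_mass_balance_residual = x$max_mass_balance_residual,
         max_bound_violation = x$max_bound_violation)
}

#' Tidy a model into its reaction table
#'
#' @param x A [wbm()].
#' @param ... Unused.
#' @return The reaction tibble (`id`, `organ`, `lb`, `ub`, `kind`).
#' @method tidy wbm
#' @export
tidy.wbm <- function(x, ...) x$reactions

#' One-row structural summary of a model
#'
#' @param x A [wbm()].
#' @param ... Unused.
#' @return One-row tibble of counts and metadata.
#' @method glance wbm
#' @export
glance.wbm <- function(x, ...) {
  tibble(model_id = x$model_id, sex = x$sex,
         n_reactions = nrow(x$reactions), n_metabolites = nrow(x$metabolites),
         n_organs = length(x$organs),
         n_diet_exchanges = sum(x$reactions$kind == "diet_exchange"),
         n_organ_blood_exchanges = sum(x$reactions$kind == "organ_blood_exchange"),
         maintenance_id = x$maintenance_id)
}

#' Tidy an embedding into its coordinate table
#'
#' @param x A `wbm_embedding`.
#' @param ... Unused.
#' @return The coordinates tibble (`sample`, dims).
#' @method tidy wbm_embedding
#' @export
tidy.wbm_embedding <- function(x, ...) x$coordinates

#' One-row summary of an embedding
#'
#' @param x A `wbm_embedding`.
#' @param ... Unused.
#' @return One-row tibble with method, dimensions and (for PCA) the
#'   variance explained by the leading components.
#' @method glance wbm_embedding
#' @export
glance.wbm_embedding <- function(x, ...) {
  tibble(method = x$method, n_samples = nrow(x$coordinates),
         n_features = length(x$feature_names),
         var_pc1 = x$variance_explained[1] %||% NA_real_,
         var_pc2 = if (length(x$variance_explained) >= 2)
           x$variance_explained[2] else NA_real_,
         seed = x$seed)
}

#' Tidy an organ-by-diet flux table into long form
#'
#' @param x An [organ_contribution_table()].
#' @param ... Unused.
#' @return Long tibble with columns `organ`, `diet`, `flux`.
#' @method tidy organ_flux_table
#' @export
tidy.organ_flux_table <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"organ",
                      names_to = "diet", values_to = "flux")
}

#' Tidy a biomarker panel into a metric-reaction table
#'
#' @param x A [resolve_panel()] result.
#' @param ... Unused.
#' @return Tibble with columns `metric`, `reaction_id`.
#' @method tidy biomarker_panel
#' @export
tidy.biomarker_panel <- function(x, ...) {
  bind_rows(lapply(panel_metrics, function(m) {
    tibble(metric = m, reaction_id = x[[m]])
  }))
}

#' Tidy an intervention result into the long biomarker table
#'
#' @param x An [run_intervention()] result.
#' @param ... Unused.
#' @return Long tibble with columns `diet`, `sex`, `metric`, `value`.
#' @method tidy intervention_result
#' @export
tidy.intervention_result <- function(x, ...) x$biomarkers

#' One-row summary of an intervention run
#'
#' @param x An [run_intervention()] result.
#' @param ... Unused.
#' @return One-row tibble with cell counts and solver diagnostics.
#' @method glance intervention_result
#' @export
glance.intervention_result <- function(x, ...) {
  tibble(n_cells = nrow(x$summary),
         n_optimal = sum(x$summary$status == "optimal"),
         n_failed = nrow(x$failures),
         max_mass_balance_residual =
           max(x$summary$mass_balance_residual, na.rm = TRUE),
         max_maintenance_deviation =
           max(abs(x$summary$maintenance_flux - 1), na.rm = TRUE))
}
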