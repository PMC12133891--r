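#' Construct an organ-resolved whole-body stoichiometric model
#'
#' A `wbm` bundles the stoichiometry of a multi-organ metabolic network in
#' tidy form: one tibble of reactions (with flux bounds in mmol/day/person
#' and a structural `kind`), one triplet tibble of stoichiometric
#' coefficients, and one tibble of metabolites derived from the coefficient
#' table. Reaction kinds are classified from identifiers under the active
#' [naming_convention()] unless supplied explicitly.
#'
#' The package-wide sign convention for organ-blood exchange reactions is
#' *positive flux = secretion into blood*. Constructors and readers re-orient
#' reactions written the other way round (blood coefficient negative) and
#' record the flip.
#'
#' @param reactions Tibble with columns `id`, `lb`, `ub` and optionally
#'   `kind`; unknown bounds may be `Inf`/`-Inf` and are clamped to the
#'   finite big-M used internally (1e6).
#' @param stoich Triplet tibble with columns `reaction_id`, `metabolite_id`,
#'   `coef` (negative = consumed).
#' @param sex `"male"` or `"female"`.
#' @param organs Character vector of organ names used as identifier prefixes.
#' @param physiology Named numeric vector/list of physiological metadata
#'   (e.g. `body_weight_kg`); values must be strictly positive.
#' @param convention A [naming_convention()].
#' @param model_id Free-text identifier stored with the model.
#'
#' @return An object of class `wbm`.
#' @seealso [validate_wbm()], [read_wbm()], [make_toy_wbm()]
#' @export
wbm <- function(reactions, stoich, sex = c("male", "female"),
                organs = character(), physiology = numeric(),
                convention = naming_convention(), model_id = "wbm") {
  sex <- match.arg(sex)
  reactions <- as_tibble(reactions)
  stoich <- as_tibble(stoich)
  stopifnot(all(c("id", "lb", "ub") %in% names(reactions)),
            all(c("reaction_id", "metabolite_id", "coef") %in% names(stoich)))

  if (anyDuplicated(reactions$id)) {
    abort(paste0("Duplicate reaction ids: ",
                 paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", ")),
          class = "dietwbm_integrity_error")
  }
  bad <- setdiff(stoich$reaction_id, reactions$id)
  if (length(bad)) {
    abort(paste0("Stoichiometry references unknown reactions: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "dietwbm_integrity_error")
  }

  # clamp unbounded to finite big-M
  reactions$lb <- pmax(reactions$lb, -BIG_M)
  reactions$ub <- pmin(reactions$ub, BIG_M)

  if (!"kind" %in% names(reactions)) {
    reactions$kind <- classify_reactions(reactions$id, organs, convention)
  }
  n_maint <- sum(reactions$kind == "maintenance")
  if (n_maint != 1L) {
    abort(sprintf("Model must contain exactly one maintenance reaction, found %d.", n_maint),
          class = "dietwbm_model_error")
  }

  metabolites <- tibble(id = sort(unique(stoich$metabolite_id)))
  metabolites$compartment <- compartment_of(metabolites$id)
  metabolites$organ <- organ_of(metabolites$id, organs, convention$organ_separator)
  base <- strip_compartment(metabolites$id)
  prefix_len <- ifelse(is.na(metabolites$organ), 0L,
                       nchar(metabolites$organ) + nchar(convention$organ_separator))
  metabolites$base_id <- substring(base, prefix_len + 1L)

  reactions$organ <- organ_of(reactions$id, organs, convention$organ_separator)

  model <- structure(
    list(
      model_id = model_id,
      sex = sex,
      organs = organs,
      physiology = as.list(physiology),
      convention = convention,
      reactions = reactions[, c("id", "organ", "lb", "ub", "kind")],
      stoich = stoich[, c("reaction_id", "metabolite_id", "coef")],
      metabolites = metabolites[, c("id", "base_id", "organ", "compartment")],
      maintenance_id = reactions$id[reactions$kind == "maintenance"],
      flips = character()
    ),
    class = "wbm"
  )
  model <- orient_exchanges(model)

  phys <- unlist(model$physiology)
  if (length(phys) && any(!is.finite(phys) | phys <= 0)) {
    abort("Physiology values must be strictly positive finite numbers.",
          class = "dietwbm_model_error")
  }
  model
}

# Enforce secretion-positive orientation on organ-blood exchanges: the blood
# metabolite must carry a positive coefficient. Flipped reactions get negated
# stoichiometry and swapped bounds; ids of flipped reactions are recorded.
orient_exchanges <- function(model) {
  conv <- model$convention
  ex_ids <- model$reactions$id[model$reactions$kind == "organ_blood_exchange"]
  if (!length(ex_ids)) return(model)
  blood_met <- endsWith(model$stoich$metabolite_id, conv$blood_tag)
  flips <- character()
  for (rid in ex_ids) {
    rows <- model$stoich$reaction_id == rid
    bc <- rows & blood_met
    if (sum(bc) != 1L) next  # reported by validate_wbm()
    if (model$stoich$coef[bc] < 0) {
      model$stoich$coef[rows] <- -model$stoich$coef[rows]
      i <- match(rid, model$reactions$id)
      old <- c(model$reactions$lb[i], model$reactions$ub[i])
      model$reactions$lb[i] <- -old[2]
      model$reactions$ub[i] <- -old[1]
      flips <- c(flips, rid)
    }
  }
  model$flips <- flips
  model
}

#' @export
print.wbm <- function(x, ...) {
  cat(sprintf("<wbm> %s (%s)\n", x$model_id, x$sex))
  cat(sprintf("  %d reactions, %d metabolites, %d organs\n",
              nrow(x$reactions), nrow(x$metabolites), length(x$organs)))
  kinds <- table(x$reactions$kind)
  cat("  kinds: ", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  maintenance: ", x$maintenance_id, "\n", sep = "")
  invisible(x)
}

#' Sparse stoichiometric matrix of a model
#'
#' @param model A [wbm()] model.
#' @return A `dgCMatrix` with metabolites as rows and reactions as columns,
#'   dimnames set to the respective identifiers.
#' @export
stoich_matrix <- function(model) {
  Matrix::sparseMatrix(
    i = match(model$stoich$metabolite_id, model$metabolites$id),
    j = match(model$stoich$reaction_id, model$reactions$id),
    x = model$stoich$coef,
    dims = c(nrow(model$metabolites), nrow(model$reactions)),
    dimnames = list(model$metabolites$id, model$reactions$id)
  )
}

#' Validate a whole-body model
#'
#' Structural checks on an assembled model. The function reports and never
#' raises: an empty report means the model passes.
#'
#' Checks: a maintenance reaction with finite bounds; at least one diet
#' exchange; every organ-blood exchange touches exactly one blood-tagged
#' metabolite; bound order `lb <= ub`; no non-finite bounds or coefficients.
#'
#' @param model A [wbm()] model.
#' @return A tibble with columns `severity`, `code`, `message` (zero rows if
#'   the model passes).
#' @export
validate_wbm <- function(model) {
  rep_rows <- list()
  add <- function(severity, code, message) {
    rep_rows[[length(rep_rows) + 1]] <<- tibble(
      severity = severity, code = code, message = message)
  }
  rx <- model$reactions

  maint <- rx[rx$kind == "maintenance", ]
  if (nrow(maint) == 0) {
    add("error", "NO_MAINTENANCE", "No maintenance reaction in model.")
  } else if (any(!is.finite(maint$lb) | !is.finite(maint$ub))) {
    add("error", "NONFINITE_MAINTENANCE_BOUNDS",
        "Maintenance reaction has non-finite bounds.")
  }
  if (!any(rx$kind == "diet_exchange")) {
    add("error", "NO_DIET_EXCHANGE", "Model has no diet exchange reactions.")
  }
  bad_bounds <- rx$id[!is.na(rx$lb) & !is.na(rx$ub) & rx$lb > rx$ub]
  for (id in bad_bounds) {
    add("error", "BOUND_ORDER", sprintf("Reaction %s has lb > ub.", id))
  }
  nan_bounds <- rx$id[is.na(rx$lb) | is.na(rx$ub)]
  for (id in nan_bounds) {
    add("error", "NAN_BOUND", sprintf("Reaction %s has NaN/NA bounds.", id))
  }
  if (any(!is.finite(model$stoich$coef))) {
    add("error", "NONFINITE_COEF", "Stoichiometric coefficients must be finite.")
  }

  blood <- endsWith(model$stoich$metabolite_id, model$convention$blood_tag)
  for (rid in rx$id[rx$kind == "organ_blood_exchange"]) {
    n_blood <- sum(model$stoich$reaction_id == rid & blood)
    if (n_blood != 1L) {
      add("error", "BAD_EXCHANGE_BLOOD",
          sprintf("Organ-blood exchange %s touches %d blood metabolites (expected 1).",
                  rid, n_blood))
    }
  }

  orphan_organs <- setdiff(stats::na.omit(rx$organ), model$organs)
  for (o in orphan_organs) {
    add("error", "UNKNOWN_ORGAN", sprintf("Organ %s not declared in organs list.", o))
  }

  if (length(rep_rows)) bind_rows(rep_rows) else
    tibble(severity = character(), code = character(), message = character())
}

#' Find organ-blood exchange reactions for a nutrient
#'
#' Returns every organ-blood exchange reaction that moves the given
#' metabolite base id between an organ compartment and blood, in
#' deterministic lexicographic order.
#'
#' @param model A [wbm()] model.
#' @param base_id Metabolite base identifier (e.g. `"glc_D"`).
#' @return Tibble with columns `organ`, `reaction_id`. An unknown `base_id`
#'   yields zero rows (not an error).
#' @export
find_organ_exchanges <- function(model, base_id) {
  stopifnot(is.character(base_id), nzchar(base_id))
  ex <- model$reactions[model$reactions$kind == "organ_blood_exchange", ]
  if (!nrow(ex)) return(tibble(organ = character(), reaction_id = character()))
  met <- model$metabolites
  blood_ids <- met$id[met$base_id == base_id & met$compartment == model$convention$blood_tag]
  hit <- model$stoich$reaction_id[model$stoich$metabolite_id %in% blood_ids]
  out <- ex[ex$id %in% hit, c("organ", "id")]
  names(out) <- c("organ", "reaction_id")
  arrange(out, .data$reaction_id)
}

# Internal: replace bounds of one reaction, returning the model.
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  i <- match(reaction_id, model$reactions$id)
  if (any(is.na(i))) {
    abort(paste0("Unknown reaction id(s): ",
                 paste(reaction_id[is.na(i)], collapse = ", ")),
          class = "dietwbm_integrity_error")
  }
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  model
}
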