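#' Parse a diet file
#'
#' Reads the two-column diet dialect used by the Virtual Metabolic Human's
#' pre-defined diets: one row per nutrient, first column the diet exchange
#' reaction identifier (or bare nutrient id), second column the average
#' daily uptake in mmol/day. A header row is optional; TSV and CSV are both
#' accepted. Identifiers are normalized to nutrient base ids (diet prefix
#' and lumen tag stripped) and duplicate rows for the same nutrient are
#' summed.
#'
#' @param path Path to the diet file.
#' @param name Diet name; defaults to the file name without extension.
#' @param convention A [naming_convention()] for identifier normalization.
#' @return A `diet_spec`: tibble with columns `nutrient`, `amount`
#'   (mmol/day) and a `name` attribute.
#' @export
read_diet <- function(path, name = NULL, convention = naming_convention()) {
  if (!file.exists(path)) {
    abort(paste0("Diet file does not exist: ", path),
          class = "dietwbm_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (any(grepl("\t", lines))) "\t" else ","
  rows <- strsplit(lines, sep, fixed = TRUE)
  start <- 1L
  if (length(rows) && suppressWarnings(is.na(as.numeric(trimws(rows[[1]][2]))))) {
    start <- 2L  # header
  }
  nutrient <- character(); amount <- numeric()
  for (i in seq_along(rows)[seq_along(rows) >= start]) {
    parts <- trimws(rows[[i]])
    if (length(parts) < 2) {
      abort(sprintf("Unparseable diet row at line %d: %s", i, lines[i]),
            class = "dietwbm_parse_error")
    }
    a <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(a)) {
      abort(sprintf("Unparseable amount at line %d: %s", i, parts[2]),
            class = "dietwbm_parse_error")
    }
    if (a < 0) {
      abort(sprintf("Negative diet amount at line %d: %s", i, parts[2]),
            class = "dietwbm_value_error")
    }
    nutrient <- c(nutrient, diet_base_id(parts[1], convention))
    amount <- c(amount, a)
  }
  spec <- tibble(nutrient = nutrient, amount = amount)
  spec <- summarise(group_by(spec, .data$nutrient), amount = sum(.data$amount),
                    .groups = "drop")
  diet_spec(spec, name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' Construct a diet specification
#'
#' @param entries Tibble (or named numeric vector) mapping nutrient base id
#'   to daily uptake in mmol/day.
#' @param name Diet name.
#' @return A `diet_spec` tibble.
#' @export
diet_spec <- function(entries, name = "diet") {
  if (is.numeric(entries) && !is.null(names(entries))) {
    entries <- tibble(nutrient = names(entries), amount = as.numeric(entries))
  }
  entries <- as_tibble(entries)[, c("nutrient", "amount")]
  if (any(!is.finite(entries$amount)) || any(entries$amount < 0)) {
    abort("Diet amounts must be finite and non-negative.",
          class = "dietwbm_value_error")
  }
  structure(arrange(entries, .data$nutrient),
            name = name, class = c("diet_spec", class(entries)))
}

#' @export
print.diet_spec <- function(x, ...) {
  cat(sprintf("<diet_spec> %s: %d nutrients, %.1f mmol/day total\n",
              attr(x, "name"), nrow(x), sum(x$amount)))
  NextMethod()
}

diet_name <- function(diet) attr(diet, "name") %||% "diet"

#' Write a diet specification in the two-column dialect
#'
#' @param diet A [diet_spec()].
#' @param path Target TSV path.
#' @param convention A [naming_convention()]; nutrient ids are written as
#'   fully qualified diet exchange identifiers.
#' @return `path`, invisibly.
#' @export
write_diet <- function(diet, path, convention = naming_convention()) {
  out <- tibble(
    rxn_or_nutrient_id = paste0(convention$diet_prefix, diet$nutrient,
                                convention$lumen_tag),
    amount_mmol_per_day = diet$amount
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Diet application policy
#'
#' How diet amounts translate into bounds on diet exchange reactions
#' (uptake flux is negative). With `optional_uptake`, a daily amount `a`
#' becomes bounds `[-a, 0]`: the model may consume up to the dietary supply.
#' With `forced_uptake` the bounds are `[-a, -force_fraction * a]`: at least
#' that fraction of the stated intake must be consumed (the convention used
#' with VMH whole-body models, fraction 0.8).
#'
#' @param mode `"optional_uptake"` or `"forced_uptake"`.
#' @param force_fraction Fraction of the intake forced under
#'   `forced_uptake`; in `[0, 1]`.
#' @param close_unlisted If `TRUE`, diet exchanges absent from the diet get
#'   lower bound 0 (no uptake).
#' @return An object of class `diet_policy`.
#' @export
diet_policy <- function(mode = c("optional_uptake", "forced_uptake"),
                        force_fraction = 0.8, close_unlisted = TRUE) {
  mode <- match.arg(mode)
  stopifnot(force_fraction >= 0, force_fraction <= 1)
  structure(list(mode = mode, force_fraction = force_fraction,
                 close_unlisted = close_unlisted),
            class = "diet_policy")
}

#' Apply a diet to a model
#'
#' Sets the bounds of diet exchange reactions from the diet's daily
#' amounts under the given [diet_policy()]. All other flux bounds are left
#' untouched. Diet entries without a matching diet exchange reaction
#' produce a warning (with a count), not an error: real diet formulations
#' routinely contain compounds absent from a given model version.
#'
#' @param model A [wbm()] model.
#' @param diet A [diet_spec()].
#' @param policy A [diet_policy()].
#' @return A new `wbm` with updated diet-exchange bounds; the applied diet
#'   name is recorded in `model$applied_diet`.
#' @examples
#' toy <- make_toy_wbm(organs = "Liver", options = list(chain_only = TRUE))
#' fed <- apply_diet(toy$model, diet_spec(c(glc_D = 100)))
#' @export
apply_diet <- function(model, diet, policy = diet_policy()) {
  rx <- model$reactions
  is_dex <- rx$kind == "diet_exchange"
  dex_base <- diet_base_id(rx$id, model$convention)
  dex_base[!is_dex] <- NA_character_

  matched <- diet$nutrient %in% dex_base
  if (any(!matched)) {
    warn(sprintf("%d diet nutrient(s) have no diet exchange reaction in the model: %s",
                 sum(!matched),
                 paste(head(diet$nutrient[!matched], 5), collapse = ", ")),
         class = "dietwbm_unmatched_nutrient")
  }
  if (policy$close_unlisted) {
    rx$lb[is_dex] <- pmax(rx$lb[is_dex], 0)
  }
  for (k in which(matched)) {
    i <- which(dex_base == diet$nutrient[k])
    a <- diet$amount[k]
    if (policy$mode == "optional_uptake") {
      rx$lb[i] <- -a; rx$ub[i] <- 0
    } else {
      rx$lb[i] <- -a; rx$ub[i] <- -policy$force_fraction * a
    }
  }
  model$reactions <- rx
  model$applied_diet <- diet_name(diet)
  model
}

#' Read a nutrient classification table
#'
#' TSV with columns `base_id`, `class` (one of carbohydrate, fat, protein,
#' alcohol, fiber, micronutrient, other), `g_per_mmol` (> 0) and
#' `kcal_per_g` (>= 0; 0 only for micronutrient/fiber/other).
#'
#' @param path TSV path.
#' @return A validated `nutrient_table` tibble.
#' @export
read_nutrient_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nutrient_table(tab)
}

#' @rdname read_nutrient_table
#' @param tab Data frame with the columns described above.
#' @export
nutrient_table <- function(tab) {
  tab <- as_tibble(tab)
  need <- c("base_id", "class", "g_per_mmol", "kcal_per_g")
  stopifnot(all(need %in% names(tab)))
  classes <- c("carbohydrate", "fat", "protein", "alcohol", "fiber",
               "micronutrient", "other")
  if (any(!tab$class %in% classes)) {
    abort(paste0("Unknown nutrient class: ",
                 paste(setdiff(tab$class, classes), collapse = ", ")),
          class = "dietwbm_value_error")
  }
  if (any(tab$g_per_mmol <= 0)) {
    abort("g_per_mmol must be strictly positive.", class = "dietwbm_value_error")
  }
  zero_ok <- tab$class %in% c("micronutrient", "fiber", "other")
  if (any(tab$kcal_per_g < 0) || any(tab$kcal_per_g == 0 & !zero_ok)) {
    abort("kcal_per_g must be positive for energy-bearing classes.",
          class = "dietwbm_value_error")
  }
  structure(tab[, need], class = c("nutrient_table", class(tab)))
}

energy_classes <- c("carbohydrate", "fat", "protein", "alcohol", "fiber")

#' Macronutrient energy breakdown of a diet
#'
#' Converts mmol/day amounts to kilocalories using the table's grams per
#' mmol and kcal per gram (Atwater-style factors) and returns the fraction
#' of total energy contributed by each energy-bearing class. Diet nutrients
#' missing from the table are counted under `other` with a warning.
#'
#' @param diet A [diet_spec()].
#' @param table A [nutrient_table()].
#' @return Tibble with columns `class`, `kcal`, `fraction`; fractions sum
#'   to 1 over energy-bearing classes.
#' @export
macronutrient_breakdown <- function(diet, table) {
  joined <- left_join(diet, table, by = c(nutrient = "base_id"))
  missing <- is.na(joined$class)
  if (any(missing)) {
    warn(sprintf("%d nutrient(s) missing from the nutrient table counted as 'other': %s",
                 sum(missing), paste(head(joined$nutrient[missing], 5), collapse = ", ")),
         class = "dietwbm_missing_nutrient")
    joined$class[missing] <- "other"
    joined$g_per_mmol[missing] <- 0
    joined$kcal_per_g[missing] <- 0
  }
  joined$kcal <- joined$amount * joined$g_per_mmol * joined$kcal_per_g
  out <- summarise(group_by(joined, class = .data$class),
                   kcal = sum(.data$kcal), .groups = "drop")
  out <- out[out$class %in% energy_classes, , drop = FALSE]
  total <- sum(out$kcal)
  if (total <= 0) {
    abort(sprintf("Diet '%s' carries no energy; composition undefined.",
                  diet_name(diet)),
          class = "dietwbm_undefined_composition")
  }
  out$fraction <- out$kcal / total
  # fixed, complete class set in deterministic order
  full <- tibble(class = energy_classes)
  out <- left_join(full, out, by = "class")
  out$kcal[is.na(out$kcal)] <- 0
  out$fraction[is.na(out$fraction)] <- 0
  out
}

#' Nutrient feature matrix over a diet collection
#'
#' Builds the diets-by-features matrix used for composition embeddings.
#' Macro scope: energy fractions of the five energy-bearing classes.
#' Micro scope: mmol/day amounts of micronutrient-class entries
#' (micronutrients are largely non-caloric, so amounts are not converted
#' to energy).
#'
#' @param diets A list of [diet_spec()] objects (at least two).
#' @param table A [nutrient_table()].
#' @param scope `"macro"` or `"micro"`.
#' @return A tibble with a `diet` column followed by feature columns, rows
#'   in input order, columns deterministic.
#' @export
nutrient_matrix <- function(diets, table, scope = c("macro", "micro")) {
  scope <- match.arg(scope)
  if (length(diets) < 2) {
    abort("At least two diets are required.", class = "dietwbm_value_error")
  }
  names <- unname(map_chr(diets, diet_name))
  if (scope == "macro") {
    rows <- map(diets, function(d) {
      br <- macronutrient_breakdown(d, table)
      setNames(br$fraction, br$class)
    })
    out <- bind_rows(rows)
  } else {
    micro_ids <- sort(table$base_id[table$class == "micronutrient"])
    if (!length(micro_ids)) {
      abort("Nutrient table contains no micronutrient-class entries.",
            class = "dietwbm_empty_feature_error")
    }
    rows <- map(diets, function(d) {
      amt <- setNames(rep(0, length(micro_ids)), micro_ids)
      hit <- d$nutrient %in% micro_ids
      amt[d$nutrient[hit]] <- d$amount[hit]
      amt
    })
    out <- bind_rows(rows)
  }
  bind_cols(tibble(diet = names), out)
}
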