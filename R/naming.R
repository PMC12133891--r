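#' Identifier conventions for whole-body models
#'
#' Whole-body models use organ-prefixed reaction and metabolite namespaces in
#' the style of the Virtual Metabolic Human (VMH): reactions belonging to an
#' organ are prefixed `"<Organ>_"`, the systemic blood compartment is tagged
#' `"[bc]"`, the diet/lumen compartment `"[d]"`, and diet exchange reactions
#' start with `"Diet_EX_"`. All tags are overridable so the same machinery
#' runs on real models and on the synthetic toys.
#'
#' @param organ_separator Separator between the organ prefix and the rest of
#'   an identifier.
#' @param blood_tag Compartment tag of the shared systemic blood compartment.
#' @param diet_prefix Prefix of diet exchange reaction identifiers.
#' @param lumen_tag Compartment tag of the diet/gastrointestinal lumen.
#' @param maintenance_pattern Regular expression identifying the whole-body
#'   maintenance reaction.
#' @param sink_patterns Character vector of regular expressions identifying
#'   sink/demand boundary reactions.
#'
#' @return An object of class `naming_convention`.
#' @examples
#' naming_convention()
#' @export
naming_convention <- function(organ_separator = "_",
                              blood_tag = "[bc]",
                              diet_prefix = "Diet_EX_",
                              lumen_tag = "[d]",
                              maintenance_pattern = "^Whole_body_objective_rxn$",
                              sink_patterns = c("^Sink_", "_DM_", "^Excretion_EX_")) {
  tags <- c(organ_separator, blood_tag, diet_prefix, lumen_tag)
  if (any(!nzchar(tags))) {
    abort("All naming convention tags must be non-empty strings.",
          class = "dietwbm_convention_error")
  }
  if (anyDuplicated(c(blood_tag, diet_prefix, lumen_tag))) {
    abort("Naming convention tags must be mutually distinct.",
          class = "dietwbm_convention_error")
  }
  structure(
    list(
      organ_separator = organ_separator,
      blood_tag = blood_tag,
      diet_prefix = diet_prefix,
      lumen_tag = lumen_tag,
      maintenance_pattern = maintenance_pattern,
      sink_patterns = sink_patterns
    ),
    class = "naming_convention"
  )
}

#' @export
print.naming_convention <- function(x, ...) {
  cat("<naming_convention>\n")
  cat("  organ prefix sep : ", x$organ_separator, "\n", sep = "")
  cat("  blood tag        : ", x$blood_tag, "\n", sep = "")
  cat("  lumen tag        : ", x$lumen_tag, "\n", sep = "")
  cat("  diet prefix      : ", x$diet_prefix, "\n", sep = "")
  invisible(x)
}

# Extract the trailing "[...]" compartment tag from an identifier (or NA).
compartment_of <- function(id) {
  m <- regexpr("\\[[^]\\[]+\\]$", id)
  out <- rep(NA_character_, length(id))
  out[m > 0] <- regmatches(id, m)
  out
}

# Strip a trailing compartment tag.
strip_compartment <- function(id) sub("\\[[^]\\[]+\\]$", "", id)

# Organ prefix of an identifier, restricted to a known organ vocabulary.
organ_of <- function(id, organs, sep = "_") {
  if (length(organs) == 0) return(rep(NA_character_, length(id)))
  prefix <- vapply(strsplit(id, sep, fixed = TRUE), `[[`, character(1), 1)
  ifelse(prefix %in% organs, prefix, NA_character_)
}

# Nutrient base id of a diet exchange reaction id: strip prefix + lumen tag.
diet_base_id <- function(id, convention) {
  out <- sub(paste0("^", escape_regex(convention$diet_prefix)), "", id)
  strip_compartment(out)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Classify every reaction into exactly one kind from its identifier and the
# organ vocabulary. Precedence: maintenance > diet_exchange > sink_demand >
# organ_blood_exchange > internal.
classify_reactions <- function(ids, organs, convention) {
  kind <- rep("internal", length(ids))
  sink <- Reduce(`|`, lapply(convention$sink_patterns, grepl, x = ids))
  organ <- organ_of(ids, organs, convention$organ_separator)
  blood <- endsWith(ids, convention$blood_tag)
  kind[!is.na(organ) & blood & grepl("_EX_", ids)] <- "organ_blood_exchange"
  kind[sink] <- "sink_demand"
  kind[startsWith(ids, convention$diet_prefix)] <- "diet_exchange"
  kind[grepl(convention$maintenance_pattern, ids)] <- "maintenance"
  kind
}
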