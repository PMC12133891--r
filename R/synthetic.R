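#' Generate a toy whole-body metabolic model
#'
#' Builds a small organ-resolved stoichiometric model that is structurally
#' faithful to whole-body model conventions — organ-prefixed namespaces, a
#' shared blood compartment, diet exchange reactions on a lumen
#' compartment, a single whole-body maintenance reaction with organ-weight
#' coefficients — while keeping the biochemistry deliberately lumped (one
#' reaction per pathway stage). Every structural fact needed by downstream
#' analyses is planted by construction and stamped into the returned
#' manifest, so the full pipeline is testable without any downloads.
#'
#' The default model contains, per organ, a glucose-blood exchange and a
#' lumped ATP-from-glucose reaction; liver gluconeogenesis from amino
#' acids (and a small fatty-acid-derived contribution) as the sole net
#' glucose source; three adipocyte triacylglycerol esterification
#' reactions (one per fatty-acid species, the essential species having no
#' other fate); butyryl-CoA to acetyl-CoA (thiolase) reactions in muscle
#' and heart fed both by fatty-acid beta-oxidation and by fiber-derived
#' butyrate; LDL-C/HDL-C synthesis and secretion in liver, muscle and
#' adipocytes with capacity-capped HDL synthesis so that cholesterol
#' overflow routes to LDL; and one maintenance reaction consuming each
#' organ's ATP with equal organ-weight coefficients. The female variant
#' adds breast and uterus as additional glucose secretors and
#' kidney/renal-blood LDL-C exchanges (five LDL-C exchanges in total).
#'
#' Options:
#' * `chain_only = TRUE` (single organ): the minimal 5-reaction linear
#'   chain whose steady state forces unit flux through every step.
#' * `parallel_pair = TRUE`: two identical blood-to-ATP organ paths with a
#'   unit demand; the L2 optimum splits 0.5/0.5.
#' * `asym_pair = TRUE`: a 1-reaction path against a 2-reaction path with
#'   unit demand; the L2 optimum is (2/3, 1/3).
#' * `infeasible = TRUE` (with `chain_only`): all diet exchanges closed, so
#'   the pinned maintenance flux is unsatisfiable and the planted deficit
#'   equals the maintenance demand.
#'
#' Generation is a pure function of `(sex, organs, seed, options)`;
#' identical inputs give byte-identical serialized models. The seed is
#' recorded in the manifest (the default construction is deterministic).
#'
#' @param sex `"male"` or `"female"`.
#' @param organs Organ names; the default is the 8-organ male panel, with
#'   breast/uterus/renal blood added automatically for the female variant.
#' @param seed Integer recorded in the manifest.
#' @param options List of generator options (see above).
#' @return A list with elements `model` (a [wbm()]) and `manifest` (model
#'   id, seed, organs, and a named list of machine-checkable planted
#'   facts).
#' @examples
#' toy <- make_toy_wbm()
#' toy$model
#' @export
make_toy_wbm <- function(sex = c("male", "female"),
                         organs = c("Liver", "Adipocyte", "Muscle", "Heart",
                                    "Lung", "Kidney", "Pancreas", "Brain"),
                         seed = 42L, options = list()) {
  sex <- match.arg(sex)
  opt <- function(x, default = FALSE) options[[x]] %||% default
  if (opt("chain_only")) {
    if (length(organs) != 1) {
      abort("chain_only requires exactly one organ.",
            class = "dietwbm_config_error")
    }
    return(toy_chain(organs, seed, infeasible = opt("infeasible")))
  }
  if (opt("infeasible")) {
    abort("The infeasible variant is built on the chain model; set chain_only = TRUE.",
          class = "dietwbm_config_error")
  }
  if (opt("parallel_pair")) return(toy_split(seed, asym = FALSE))
  if (opt("asym_pair")) return(toy_split(seed, asym = TRUE))

  female <- sex == "female"
  if (female) {
    organs <- union(organs, c("Breast", "Uterus", "RenalBlood"))
  }
  atp_organs <- setdiff(organs, "RenalBlood")
  gng_organs <- intersect(c("Breast", "Uterus"), organs)  # extra glucose secretors

  rx <- list(); st <- list()
  add <- function(id, stoich, lb, ub) {
    rx[[length(rx) + 1]] <<- tibble(id = id, lb = lb, ub = ub)
    st[[length(st) + 1]] <<- tibble(reaction_id = id,
                                    metabolite_id = names(stoich),
                                    coef = as.numeric(stoich))
  }

  nutrients <- c("glc_D", "aa_L", "fa_sat", "fa_uns", "fa_ess", "fib", "chol",
                 paste0("vit", LETTERS[1:6]))
  vits <- paste0("vit", LETTERS[1:6])

  # diet exchanges and gastrointestinal absorption (lumen -> blood)
  for (n in nutrients) {
    add(paste0("Diet_EX_", n, "[d]"), setNames(-1, paste0(n, "[d]")), -BIG_M, 0)
  }
  for (n in setdiff(nutrients, "fib")) {
    add(paste0("GI_A_", n), setNames(c(-1, 1), paste0(n, c("[d]", "[bc]"))),
        0, BIG_M)
  }
  add("GI_FERM_fib", c("fib[d]" = -1, "but[bc]" = 2), 0, BIG_M)
  add("Excretion_EX_fib[d]", c("fib[d]" = -1), 0, BIG_M)

  # blood sinks: urinary glucose spill, lipoprotein turnover, micronutrients
  for (n in c("glc_D", "hdlc", "ldlc", vits)) {
    add(paste0("Sink_", n, "[bc]"), setNames(-1, paste0(n, "[bc]")), 0, BIG_M)
  }

  # per-organ glucose handling and ATP production (yield 1, lumped)
  for (o in atp_organs) {
    secretor <- o %in% c("Liver", gng_organs)
    add(paste0(o, "_EX_glc_D[bc]"),
        setNames(c(1, -1), c("glc_D[bc]", paste0(o, "_glc_D[c]"))),
        if (secretor) 0 else -BIG_M, BIG_M)
    add(paste0(o, "_ATP_glc"),
        setNames(c(-1, 1), paste0(o, c("_glc_D[c]", "_atp[c]"))), 0, BIG_M)
  }

  # liver gluconeogenesis: amino acids (plus a small fatty-acid-derived
  # glycerol contribution) are the sole net glucose source
  add("Liver_EX_aa_L[bc]", c("aa_L[bc]" = 1, "Liver_aa_L[c]" = -1), -BIG_M, 0)
  add("Liver_GNG_aa", c("Liver_aa_L[c]" = -1, "Liver_glc_D[c]" = 0.5), 0, BIG_M)
  add("Liver_EX_fa_uns[bc]", c("fa_uns[bc]" = 1, "Liver_fa_uns[c]" = -1), -BIG_M, 0)
  add("Liver_GNG_fa", c("Liver_fa_uns[c]" = -1, "Liver_glc_D[c]" = 0.15), 0, BIG_M)

  for (o in gng_organs) {
    add(paste0(o, "_EX_aa_L[bc]"),
        setNames(c(1, -1), c("aa_L[bc]", paste0(o, "_aa_L[c]"))), -BIG_M, 0)
    add(paste0(o, "_GNG_aa"),
        setNames(c(-1, 0.5), paste0(o, c("_aa_L[c]", "_glc_D[c]"))), 0, BIG_M)
  }

  # muscle and heart: beta-oxidation to butyryl-CoA, the thiolase step
  # (butyryl-CoA -> acetyl-CoA), citric-acid-cycle ATP, butyrate salvage,
  # and a demand sink for non-maintenance energy expenditure
  fao_organs <- intersect(c("Muscle", "Heart"), organs)
  for (o in fao_organs) {
    for (f in c("fa_sat", "fa_uns")) {
      add(paste0(o, "_EX_", f, "[bc]"),
          setNames(c(1, -1), c(paste0(f, "[bc]"), paste0(o, "_", f, "[c]"))),
          -BIG_M, 0)
      add(paste0(o, "_BOX_", f),
          setNames(c(-1, 1), paste0(o, c(paste0("_", f, "[c]"), "_butcoa[m]"))),
          0, BIG_M)
    }
    add(paste0(o, "_EX_but[bc]"),
        setNames(c(1, -1), c("but[bc]", paste0(o, "_but[c]"))), -BIG_M, 0)
    add(paste0(o, "_BUTCOA"),
        setNames(c(-1, 1), paste0(o, c("_but[c]", "_butcoa[m]"))), 0, BIG_M)
    add(paste0(o, "_FAOXC4"),
        setNames(c(-1, 1), paste0(o, c("_butcoa[m]", "_accoa[m]"))), 0, BIG_M)
    add(paste0(o, "_TCA"),
        setNames(c(-1, 1), paste0(o, c("_accoa[m]", "_atp[c]"))), 0, BIG_M)
    add(paste0(o, "_DM_atp"), setNames(-1, paste0(o, "_atp[c]")), 0, BIG_M)
  }

  # adipocyte triacylglycerol esterification (three fatty-acid species; the
  # essential species has no oxidative fate) and a storage demand
  if ("Adipocyte" %in% organs) {
    for (f in c("fa_sat", "fa_uns", "fa_ess")) {
      add(paste0("Adipocyte_EX_", f, "[bc]"),
          setNames(c(1, -1), c(paste0(f, "[bc]"), paste0("Adipocyte_", f, "[c]"))),
          -BIG_M, 0)
      add(paste0("Adipocyte_TAGSYN_", f),
          setNames(c(-1, 1), paste0("Adipocyte_", c(paste0("fa_", sub("fa_", "", f), "[c]"), "tag[c]"))),
          0, BIG_M)
    }
    add("Adipocyte_DM_tag", c("Adipocyte_tag[c]" = -1), 0, BIG_M)
  }

  # cholesterol packaging: capacity-capped HDL synthesis, uncapped hepatic
  # LDL route (via VLDL), small capped direct LDL routes elsewhere
  hdl_caps <- c(Liver = 0.4, Muscle = 0.05, Adipocyte = 0.05)
  ldl_caps <- c(Muscle = 0.05, Adipocyte = 0.05, Kidney = 0.03, RenalBlood = 0.03)
  chol_organs <- intersect(c("Liver", "Muscle", "Adipocyte"), organs)
  ldl_extra <- if (female) intersect(c("Kidney", "RenalBlood"), organs) else character()
  for (o in union(chol_organs, ldl_extra)) {
    add(paste0(o, "_EX_chol[bc]"),
        setNames(c(1, -1), c("chol[bc]", paste0(o, "_chol[c]"))), -BIG_M, 0)
    if (o %in% chol_organs) {
      add(paste0(o, "_HDLSYN"),
          setNames(c(-1, 1), paste0(o, c("_chol[c]", "_hdlc[c]"))),
          0, hdl_caps[[o]])
      add(paste0(o, "_EX_hdlc[bc]"),
          setNames(c(1, -1), c("hdlc[bc]", paste0(o, "_hdlc[c]"))), 0, BIG_M)
    }
    if (o == "Liver") {
      add("Liver_VLDLSYN", c("Liver_chol[c]" = -1, "Liver_vldl[c]" = 1), 0, BIG_M)
      add("Liver_LDLFORM", c("Liver_vldl[c]" = -1, "Liver_ldlc[c]" = 1), 0, BIG_M)
    } else {
      add(paste0(o, "_LDLSYN"),
          setNames(c(-1, 1), paste0(o, c("_chol[c]", "_ldlc[c]"))),
          0, ldl_caps[[o]])
    }
    add(paste0(o, "_EX_ldlc[bc]"),
        setNames(c(1, -1), c("ldlc[bc]", paste0(o, "_ldlc[c]"))), 0, BIG_M)
  }

  # whole-body maintenance: equal organ-weight coefficients on organ ATP
  atp_demand_total <- 100
  w <- rep(1 / length(atp_organs), length(atp_organs))
  add("Whole_body_objective_rxn",
      setNames(-w * atp_demand_total, paste0(atp_organs, "_atp[c]")),
      0, BIG_M)

  model <- wbm(bind_rows(rx), bind_rows(st), sex = sex, organs = organs,
               physiology = default_physiology(sex),
               model_id = paste0("toy_wbm_", sex))

  manifest <- list(
    model_id = model$model_id,
    seed = as.integer(seed),
    organs = organs,
    planted_facts = list(
      glucose_exchanges_per_organ = 1,
      n_glucose_exchanges = length(atp_organs),
      glucose_secretors = c("Liver", gng_organs),
      sole_net_glucose_sources = c("Liver", gng_organs),
      atp_demand_per_organ = setNames(w * atp_demand_total, atp_organs),
      fao_reactions = paste0(fao_organs, "_FAOXC4"),
      tag_reactions = paste0("Adipocyte_TAGSYN_", c("fa_sat", "fa_uns", "fa_ess")),
      hdl_exchanges = paste0(chol_organs, "_EX_hdlc[bc]"),
      ldl_exchanges = paste0(union(chol_organs, ldl_extra), "_EX_ldlc[bc]"),
      hdl_capacity_total = sum(hdl_caps[chol_organs]),
      essential_fat_sole_fate = "Adipocyte_TAGSYN_fa_ess"
    )
  )
  list(model = model, manifest = manifest)
}

default_physiology <- function(sex) {
  if (sex == "male") {
    c(body_weight_kg = 70, height_cm = 170, heart_rate_bpm = 67,
      stroke_volume_ml = 80, cardiac_output = 5360, hematocrit = 0.4)
  } else {
    c(body_weight_kg = 58, height_cm = 160, heart_rate_bpm = 67,
      stroke_volume_ml = 80, cardiac_output = 5360, hematocrit = 0.4)
  }
}

# 5-reaction single-organ chain: diet -> absorption -> organ uptake ->
# ATP -> maintenance. Steady state with the maintenance flux pinned to 1
# forces unit flux magnitude through every step.
toy_chain <- function(organ, seed, infeasible = FALSE) {
  o <- organ[1]
  dex_ub <- 0
  dex_lb <- if (infeasible) 0 else -BIG_M
  rx <- tibble(
    id = c("Diet_EX_glc_D[d]", "GI_A_glc_D",
           paste0(o, "_EX_glc_D[bc]"), paste0(o, "_ATP_glc"),
           "Whole_body_objective_rxn"),
    lb = c(dex_lb, 0, -BIG_M, 0, 0),
    ub = c(dex_ub, BIG_M, 0, BIG_M, BIG_M)
  )
  st <- bind_rows(
    tibble(reaction_id = "Diet_EX_glc_D[d]", metabolite_id = "glc_D[d]", coef = -1),
    tibble(reaction_id = "GI_A_glc_D",
           metabolite_id = c("glc_D[d]", "glc_D[bc]"), coef = c(-1, 1)),
    tibble(reaction_id = paste0(o, "_EX_glc_D[bc]"),
           metabolite_id = c("glc_D[bc]", paste0(o, "_glc_D[c]")), coef = c(1, -1)),
    tibble(reaction_id = paste0(o, "_ATP_glc"),
           metabolite_id = c(paste0(o, "_glc_D[c]"), paste0(o, "_atp[c]")),
           coef = c(-1, 1)),
    tibble(reaction_id = "Whole_body_objective_rxn",
           metabolite_id = paste0(o, "_atp[c]"), coef = -1)
  )
  model <- wbm(rx, st, sex = "male", organs = o,
               model_id = if (infeasible) "toy_chain_infeasible" else "toy3")
  manifest <- list(
    model_id = model$model_id, seed = as.integer(seed), organs = o,
    planted_facts = list(
      chain_fluxes = setNames(c(-1, 1, -1, 1, 1), rx$id),
      infeasible = infeasible,
      # minimum dietary uptake restoring feasibility when closed
      min_feasible_uptake = 1
    )
  )
  list(model = model, manifest = manifest)
}

# Two organ paths from blood to ATP under a unit maintenance demand.
# Symmetric variant: identical 1-step paths, optimum splits 0.5/0.5.
# Asymmetric variant: 1-step vs 2-step path; minimizing a^2 + 2 b^2 under
# a + b = 1 gives a = 2/3, b = 1/3.
toy_split <- function(seed, asym = FALSE) {
  rx <- list(); st <- list()
  add <- function(id, stoich, lb, ub) {
    rx[[length(rx) + 1]] <<- tibble(id = id, lb = lb, ub = ub)
    st[[length(st) + 1]] <<- tibble(reaction_id = id,
                                    metabolite_id = names(stoich),
                                    coef = as.numeric(stoich))
  }
  add("Diet_EX_glc_D[d]", c("glc_D[d]" = -1), -BIG_M, 0)
  add("GI_A_glc_D", c("glc_D[d]" = -1, "glc_D[bc]" = 1), 0, BIG_M)
  add("OrganA_PATH", c("glc_D[bc]" = -1, "atp[bc]" = 1), 0, BIG_M)
  if (asym) {
    add("OrganB_STEP1", c("glc_D[bc]" = -1, "OrganB_mid[c]" = 1), 0, BIG_M)
    add("OrganB_STEP2", c("OrganB_mid[c]" = -1, "atp[bc]" = 1), 0, BIG_M)
  } else {
    add("OrganB_PATH", c("glc_D[bc]" = -1, "atp[bc]" = 1), 0, BIG_M)
  }
  add("Whole_body_objective_rxn", c("atp[bc]" = -1), 0, BIG_M)
  model <- wbm(bind_rows(rx), bind_rows(st), sex = "male",
               organs = c("OrganA", "OrganB"),
               model_id = if (asym) "toy_asym" else "toy_parallel")
  expected <- if (asym) {
    c(OrganA_PATH = 2 / 3, OrganB_STEP1 = 1 / 3, OrganB_STEP2 = 1 / 3)
  } else {
    c(OrganA_PATH = 0.5, OrganB_PATH = 0.5)
  }
  manifest <- list(
    model_id = model$model_id, seed = as.integer(seed),
    organs = c("OrganA", "OrganB"),
    planted_facts = list(path_fluxes = expected)
  )
  list(model = model, manifest = manifest)
}

#' Nutrient classification table for the toy namespace
#'
#' Covers every nutrient emitted by [make_toy_diets()] with
#' physically-reasonable molar masses and Atwater-style energy factors
#' (4/9/4 kcal per gram for carbohydrate/fat/protein, 7 for alcohol, 2 for
#' fermentable fiber, 0 for micronutrients).
#'
#' @return A [nutrient_table()].
#' @export
toy_nutrient_table <- function() {
  nutrient_table(tibble(
    base_id = c("glc_D", "aa_L", "fa_sat", "fa_uns", "fa_ess", "chol",
                "fib", "etoh", paste0("vit", LETTERS[1:6])),
    class = c("carbohydrate", "protein", "fat", "fat", "fat", "fat",
              "fiber", "alcohol", rep("micronutrient", 6)),
    g_per_mmol = c(0.180, 0.131, 0.256, 0.282, 0.280, 0.387,
                   0.162, 0.046, rep(0.3, 6)),
    kcal_per_g = c(4, 4, 9, 9, 9, 9, 2, 7, rep(0, 6))
  ))
}

# kcal; energy fractions (of non-fiber kcal) carb/fat/protein; fat split
# sat/uns/ess; fiber g/day; cholesterol mmol/day; micronutrient profile
# scale. Profiles emulate the descriptive spectrum of common diet
# formulations: the unhealthy pattern has ~1.5x the energy of the balanced
# one with high saturated fat and cholesterol and low fiber; keto replaces
# carbohydrate with fat; plant-based patterns carry high fiber and near-zero
# cholesterol.
toy_diet_params <- function() {
  tibble::tribble(
    ~name,              ~kcal, ~carb, ~fat, ~prot, ~sat, ~uns, ~ess, ~fiber_g, ~chol_mmol, ~vit_scale,
    "toy-Balanced",      2000,  0.50, 0.30,  0.20, 0.35, 0.45, 0.20,       30,       0.52,       1.00,
    "toy-Unhealthy",     3000,  0.42, 0.43,  0.15, 0.65, 0.30, 0.05,        8,       1.55,       0.40,
    "toy-Keto",          2000,  0.05, 0.75,  0.20, 0.50, 0.40, 0.10,       15,       1.30,       0.70,
    "toy-Vegan",         2000,  0.55, 0.25,  0.20, 0.15, 0.55, 0.30,       45,       0.03,       1.30,
    "toy-Vegetarian",    2000,  0.52, 0.28,  0.20, 0.25, 0.50, 0.25,       38,       0.21,       1.20,
    "toy-Mediterranean", 2100,  0.45, 0.35,  0.20, 0.20, 0.65, 0.15,       35,       0.39,       1.25,
    "toy-DACH",          2000,  0.52, 0.30,  0.18, 0.35, 0.45, 0.20,       30,       0.57,       1.10,
    "toy-HighFiber",     2100,  0.50, 0.28,  0.22, 0.30, 0.50, 0.20,       55,       0.47,       1.15,
    "toy-HighProtein",   2200,  0.25, 0.30,  0.45, 0.40, 0.45, 0.15,       20,       1.03,       0.90,
    "toy-GlutenFree",    2200,  0.46, 0.36,  0.18, 0.40, 0.45, 0.15,       18,       0.78,       0.80,
    "toy-AvgAmerican",   2700,  0.48, 0.37,  0.15, 0.55, 0.35, 0.10,       15,       1.16,       0.60,
    "toy-AvgEuropean",   2300,  0.44, 0.38,  0.18, 0.45, 0.40, 0.15,       22,       0.90,       0.75
  )
}

# per-(diet, vitamin) multipliers: plant-based patterns enriched in the
# water-soluble proxies, low-quality patterns depleted across the board
toy_vit_profile <- function() {
  base <- c(vitA = 0.005, vitB = 0.02, vitC = 0.5,
            vitD = 0.0005, vitE = 0.05, vitF = 0.1)
  shape <- rbind(
    "toy-Balanced"      = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0),
    "toy-Unhealthy"     = c(0.7, 0.8, 0.5, 0.9, 0.6, 0.5),
    "toy-Keto"          = c(1.2, 0.9, 0.4, 1.3, 1.2, 0.5),
    "toy-Vegan"         = c(0.6, 0.7, 1.6, 0.3, 1.3, 1.5),
    "toy-Vegetarian"    = c(0.8, 0.9, 1.4, 0.6, 1.2, 1.3),
    "toy-Mediterranean" = c(1.0, 1.0, 1.3, 0.8, 1.4, 1.1),
    "toy-DACH"          = c(1.0, 1.1, 1.1, 0.9, 1.0, 1.1),
    "toy-HighFiber"     = c(0.9, 1.0, 1.2, 0.7, 1.1, 1.4),
    "toy-HighProtein"   = c(1.1, 1.3, 0.8, 1.2, 0.9, 0.8),
    "toy-GlutenFree"    = c(0.9, 0.8, 0.9, 0.9, 0.9, 0.9),
    "toy-AvgAmerican"   = c(0.8, 0.9, 0.6, 1.0, 0.7, 0.6),
    "toy-AvgEuropean"   = c(0.9, 0.9, 0.8, 0.9, 0.8, 0.8)
  )
  colnames(shape) <- names(base)
  sweep(shape, 2, base, `*`)
}

#' Generate the 12 toy diets
#'
#' Twelve named diets over the toy nutrient namespace spanning
#' unhealthy/balanced/keto/plant-based macronutrient mixes. Amounts are in
#' mmol/day and derive deterministically from per-diet energy targets via
#' the molar masses and energy factors of [toy_nutrient_table()].
#'
#' @return A named list of [diet_spec()] objects with a `manifest`
#'   attribute stamping each diet's energy and macronutrient targets.
#' @export
make_toy_diets <- function() {
  pars <- toy_diet_params()
  tab <- toy_nutrient_table()
  gp <- setNames(tab$g_per_mmol, tab$base_id)
  kc <- setNames(tab$kcal_per_g, tab$base_id)
  vits <- toy_vit_profile()
  to_mmol <- function(kcal, id) kcal / (kc[[id]] * gp[[id]])
  diets <- vector("list", nrow(pars))
  names(diets) <- pars$name
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    fat_kcal <- p$kcal * p$fat
    amounts <- c(
      glc_D = to_mmol(p$kcal * p$carb, "glc_D"),
      aa_L = to_mmol(p$kcal * p$prot, "aa_L"),
      fa_sat = to_mmol(fat_kcal * p$sat, "fa_sat"),
      fa_uns = to_mmol(fat_kcal * p$uns, "fa_uns"),
      fa_ess = to_mmol(fat_kcal * p$ess, "fa_ess"),
      fib = p$fiber_g / gp[["fib"]],
      chol = p$chol_mmol,
      vits[p$name, ] * p$vit_scale
    )
    diets[[i]] <- diet_spec(amounts, name = p$name)
  }
  attr(diets, "manifest") <- list(
    targets = pars,
    keto_fat_fraction_min = 0.53,
    unhealthy_to_balanced_kcal = pars$kcal[pars$name == "toy-Unhealthy"] /
      pars$kcal[pars$name == "toy-Balanced"]
  )
  diets
}

#' Glucose-secretion fixture: fat intake displaces hepatic glucose output
#'
#' A 12-reaction model isolating the mechanism by which energy-dense,
#' fat-forced diets depress total glucose secretion into blood: muscle
#' meets a fixed ATP demand from blood glucose and fatty acids; forced
#' fatty-acid uptake covers part of the demand, so the liver (the sole
#' glucose source, fed by optional amino-acid uptake) secretes the
#' remainder. Under the balanced diet (low forced fat) glucose secretion
#' therefore exceeds that under the unhealthy diet (high forced fat).
#' Small enough for [qp_oracle()] verification.
#'
#' @return A list with `model`, `diets` (list of two [diet_spec()]s,
#'   `balanced` and `unhealthy`), `policy` (forced uptake) and `manifest`
#'   with the closed-form expected secretions.
#' @export
toy_secretion_fixture <- function() {
  demand <- 10; fa_balanced <- 2; fa_unhealthy <- 8; f <- 0.8
  rx <- list(); st <- list()
  add <- function(id, stoich, lb, ub) {
    rx[[length(rx) + 1]] <<- tibble(id = id, lb = lb, ub = ub)
    st[[length(st) + 1]] <<- tibble(reaction_id = id,
                                    metabolite_id = names(stoich),
                                    coef = as.numeric(stoich))
  }
  add("Diet_EX_aa_L[d]", c("aa_L[d]" = -1), -BIG_M, 0)
  add("Diet_EX_fa_sat[d]", c("fa_sat[d]" = -1), -BIG_M, 0)
  add("GI_A_aa_L", c("aa_L[d]" = -1, "aa_L[bc]" = 1), 0, BIG_M)
  add("GI_A_fa_sat", c("fa_sat[d]" = -1, "fa_sat[bc]" = 1), 0, BIG_M)
  add("Liver_EX_aa_L[bc]", c("aa_L[bc]" = 1, "Liver_aa_L[c]" = -1), -BIG_M, 0)
  add("Liver_GNG", c("Liver_aa_L[c]" = -1, "Liver_glc_D[c]" = 1), 0, BIG_M)
  add("Liver_EX_glc_D[bc]", c("glc_D[bc]" = 1, "Liver_glc_D[c]" = -1), 0, BIG_M)
  add("Muscle_EX_glc_D[bc]", c("glc_D[bc]" = 1, "Muscle_glc_D[c]" = -1), -BIG_M, 0)
  add("Muscle_EX_fa_sat[bc]", c("fa_sat[bc]" = 1, "Muscle_fa_sat[c]" = -1), -BIG_M, 0)
  add("Muscle_ATP_glc", c("Muscle_glc_D[c]" = -1, "Muscle_atp[c]" = 1), 0, BIG_M)
  add("Muscle_ATP_fa", c("Muscle_fa_sat[c]" = -1, "Muscle_atp[c]" = 1), 0, BIG_M)
  add("Whole_body_objective_rxn", setNames(-demand, "Muscle_atp[c]"), 0, BIG_M)
  model <- wbm(bind_rows(rx), bind_rows(st), sex = "male",
               organs = c("Liver", "Muscle"), model_id = "toy_secretion")
  # only the fatty acid is forced; amino-acid uptake stays demand-driven
  # (close_unlisted = FALSE), which is the displacement mechanism itself
  diets <- list(
    balanced = diet_spec(c(fa_sat = fa_balanced), name = "balanced"),
    unhealthy = diet_spec(c(fa_sat = fa_unhealthy), name = "unhealthy")
  )
  # closed form: the fat path crosses 4 reactions and the hepatic glucose
  # path 7, so the unconstrained L2 split satisfies 4*fa = 7*glc with
  # fa + glc = demand, i.e. fa* = 7*demand/11 ~ 6.36. The balanced supply
  # (fa <= 2) binds below fa*, so all of it is taken; the unhealthy forced
  # minimum (0.8*8 = 6.4) binds above fa*. Glucose secretion = demand - fa.
  manifest <- list(
    model_id = "toy_secretion",
    planted_facts = list(
      expected_secretion = c(balanced = demand - fa_balanced,
                             unhealthy = demand - f * fa_unhealthy),
      demand = demand, force_fraction = f
    )
  )
  list(model = model, diets = diets,
       policy = diet_policy("forced_uptake", f, close_unlisted = FALSE),
       manifest = manifest)
}

#' Random small flux model for solver oracle testing
#'
#' Generates a feasible single-nutrient model with one to three organ
#' paths of random depth and random finite capacities, at most 12
#' reactions, suitable for exhaustive [qp_oracle()] enumeration. The pinned
#' maintenance demand is drawn randomly, and total path capacity always
#' exceeds it, so the model is feasible by construction.
#'
#' @param seed Integer seed; generation is a pure function of the seed.
#' @return A list with `model` and `manifest` (the drawn structure).
#' @export
random_toy_model <- function(seed) {
  set.seed(as.integer(seed))
  n_paths <- sample(1:3, 1)
  depths <- sample(1:3, n_paths, replace = TRUE)
  # keep within the oracle's 12-reaction cap: diet + absorb + maint = 3
  while (sum(depths) > 9) depths[which.max(depths)] <- depths[which.max(depths)] - 1L
  demand <- round(runif(1, 0.5, 2.5), 2)
  caps <- round(runif(n_paths, 0.4, 1.4) * demand, 2)
  caps[n_paths] <- BIG_M  # one uncapped path guarantees feasibility
  supply <- round(demand * runif(1, 1.3, 2.5), 2)

  rx <- list(); st <- list()
  add <- function(id, stoich, lb, ub) {
    rx[[length(rx) + 1]] <<- tibble(id = id, lb = lb, ub = ub)
    st[[length(st) + 1]] <<- tibble(reaction_id = id,
                                    metabolite_id = names(stoich),
                                    coef = as.numeric(stoich))
  }
  add("Diet_EX_glc_D[d]", c("glc_D[d]" = -1), -supply, 0)
  add("GI_A_glc_D", c("glc_D[d]" = -1, "glc_D[bc]" = 1), 0, BIG_M)
  organs <- paste0("Organ", LETTERS[seq_len(n_paths)])
  for (p in seq_len(n_paths)) {
    o <- organs[p]
    prev <- "glc_D[bc]"
    for (d in seq_len(depths[p])) {
      nxt <- if (d == depths[p]) "atp[bc]" else paste0(o, "_mid", d, "[c]")
      cap <- if (d == 1) caps[p] else BIG_M
      add(paste0(o, "_STEP", d), setNames(c(-1, 1), c(prev, nxt)), 0, cap)
      prev <- nxt
    }
  }
  add("Whole_body_objective_rxn", c("atp[bc]" = -demand), 0, BIG_M)
  model <- wbm(bind_rows(rx), bind_rows(st), sex = "male", organs = organs,
               model_id = paste0("random_toy_", seed))
  list(model = model,
       manifest = list(model_id = model$model_id, seed = as.integer(seed),
                       organs = organs,
                       planted_facts = list(n_paths = n_paths, depths = depths,
                                            demand = demand, caps = caps,
                                            supply = supply)))
}

#' Write the full synthetic study bundle to a directory
#'
#' Writes the toy model dialect files for one sex, the 12 toy diet TSVs,
#' the nutrient table and a `manifest.json` of planted facts.
#'
#' @param dir Output directory (created if needed).
#' @param sex `"male"` or `"female"`.
#' @param seed Integer seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_toy_bundle <- function(dir, sex = c("male", "female"), seed = 42L) {
  sex <- match.arg(sex)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_wbm(sex = sex, seed = seed)
  write_wbm(toy$model, file.path(dir, paste0("model_", sex, ".json")))
  diets <- make_toy_diets()
  diet_dir <- file.path(dir, "diets")
  dir.create(diet_dir, showWarnings = FALSE)
  for (d in diets) {
    write_diet(d, file.path(diet_dir, paste0(diet_name(d), ".tsv")))
  }
  tab <- toy_nutrient_table()
  readr::write_tsv(as_tibble(tab), file.path(dir, "nutrient_table.tsv"),
                   progress = FALSE)
  jsonlite::write_json(toy$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
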