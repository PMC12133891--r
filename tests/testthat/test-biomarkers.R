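fake_solution <- function(fluxes) {
  structure(list(
    fluxes = tibble::tibble(reaction_id = names(fluxes),
                            flux = as.numeric(fluxes)),
    objective = sum(fluxes^2), status = "optimal",
    max_mass_balance_residual = 0, max_bound_violation = 0,
    backend = "test", norm = "L2", model_id = "fake", sex = "male"),
    class = "flux_solution")
}

test_that("secretion/uptake totals use positive-part sums with net alongside", {
  s <- fake_solution(c(a = 2, b = -1, c = 0.5))
  tot <- secretion_uptake_totals(s, c("a", "b", "c"))
  expect_equal(tot$total_secretion, 2.5)
  expect_equal(tot$total_uptake, 1)
  expect_equal(tot$net, 1.5)

  z <- fake_solution(c(a = 0, b = 0))
  expect_equal(unlist(secretion_uptake_totals(z, c("a", "b"))),
               c(total_secretion = 0, total_uptake = 0, net = 0))
  # inequality |net| <= secretion + uptake holds for arbitrary vectors
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(5)
    s2 <- fake_solution(setNames(v, letters[1:5]))
    t2 <- secretion_uptake_totals(s2, letters[1:5])
    expect_gte(t2$total_secretion + t2$total_uptake, abs(t2$net) - 1e-12)
  }
})

test_that("sum_flux is a plain signed sum with an empty-list warning", {
  s <- fake_solution(c(a = 1, b = 0.5, c = 0.25))
  expect_equal(sum_flux(s, c("a", "b", "c")), 1.75)
  expect_warning(out <- sum_flux(s, character()),
                 class = "dietwbm_empty_reactions")
  expect_equal(out, 0)
  expect_error(sum_flux(s, "missing"), class = "dietwbm_integrity_error")
})

test_that("the LDL/HDL ratio divides secretion totals and guards zero HDL", {
  s <- fake_solution(c(l1 = 2, h1 = 4))
  expect_equal(ldl_hdl_ratio(s, "l1", "h1"), 0.5)
  s0 <- fake_solution(c(l1 = 2, h1 = 0))
  expect_error(ldl_hdl_ratio(s0, "l1", "h1"),
               class = "dietwbm_undefined_ratio")
  # uptake (negative) does not count towards secretion totals
  sm <- fake_solution(c(l1 = 1, l2 = -5, h1 = 2))
  expect_equal(ldl_hdl_ratio(sm, c("l1", "l2"), "h1"), 0.5)
})

test_that("the default panel resolves structurally on synthetic models", {
  suite <- study_suite()
  for (sx in c("male", "female")) {
    panel <- suite[[sx]]$panel
    facts <- suite[[sx]]$manifest$planted_facts
    expect_setequal(panel$fao, facts$fao_reactions)
    expect_setequal(panel$tag_synthesis, facts$tag_reactions)
    expect_setequal(panel$ldl_exchange, facts$ldl_exchanges)
    expect_setequal(panel$hdl_exchange, facts$hdl_exchanges)
    expect_equal(length(panel$glucose_exchange), facts$n_glucose_exchanges)
  }
  # female panel mirrors the wider LDL-C coverage
  expect_equal(length(suite$female$panel$ldl_exchange), 5)
  expect_equal(length(suite$male$panel$ldl_exchange), 3)
  expect_equal(length(suite$male$panel$hdl_exchange), 3)
})

test_that("panel configurations load from YAML and JSON files", {
  dir <- withr::local_tempdir()
  ypath <- file.path(dir, "panel.yaml")
  writeLines(c(
    "glucose_exchange:",
    "  pattern:",
    "    base_id: glc_D",
    "tag_synthesis:",
    "  pattern:",
    "    organ: Adipocyte",
    "    regex: TAGSYN",
    "ldl_exchange:",
    "  pattern:",
    "    base_id: ldlc",
    "hdl_exchange:",
    "  pattern:",
    "    base_id: hdlc",
    "fao:",
    "  ids:",
    "    - Muscle_FAOXC4",
    "    - Heart_FAOXC4"), ypath)
  m <- make_toy_wbm()$model
  panel <- resolve_panel(m, read_panel_config(ypath))
  expect_setequal(panel$fao, c("Muscle_FAOXC4", "Heart_FAOXC4"))
  expect_equal(length(panel$glucose_exchange), 8)

  jpath <- file.path(dir, "panel.json")
  jsonlite::write_json(default_panel_config(), jpath, auto_unbox = TRUE)
  panel2 <- resolve_panel(m, read_panel_config(jpath))
  expect_equal(panel2$tag_synthesis, panel$tag_synthesis)
})

test_that("flux solutions serialize to TSV and JSON with diagnostics", {
  sol <- pfba(chain_fed(10)$model)
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "sol.tsv")
  write_flux_solution(sol, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$reaction_id, sol$fluxes$reaction_id)
  expect_equal(back$flux, sol$fluxes$flux)

  js <- file.path(dir, "sol.json")
  write_flux_solution(sol, js)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(obj$status, "optimal")
  expect_equal(obj$objective, sol$objective)
  expect_lte(obj$max_mass_balance_residual, 1e-6)
})

test_that("panel resolution errors name missing ids and empty patterns", {
  m <- make_toy_wbm()$model
  cfg <- default_panel_config()
  cfg$fao <- list(ids = c("Muscle_FAOXC4", "Not_A_Reaction"))
  expect_error(resolve_panel(m, cfg), class = "dietwbm_resolution_error")
  cfg2 <- default_panel_config()
  cfg2$tag_synthesis <- list(pattern = list(organ = "Brain", regex = "TAGSYN"))
  expect_error(resolve_panel(m, cfg2), class = "dietwbm_resolution_error")
})

test_that("organ tables match individual lookups and are permutation-invariant", {
  suite <- study_suite()
  sols <- suite$male$solutions[c("toy-Balanced", "toy-Keto")]
  ex <- find_organ_exchanges(suite$male$model, "glc_D")
  tab <- organ_contribution_table(sols, ex)
  expect_equal(dim(tab), c(8, 3))
  for (dn in names(sols)) {
    v <- tidy(sols[[dn]])
    for (o in tab$organ) {
      rid <- ex$reaction_id[ex$organ == o]
      expect_equal(tab[[dn]][tab$organ == o],
                   sum(v$flux[v$reaction_id %in% rid]))
    }
  }
  shuffled <- ex[rev(seq_len(nrow(ex))), ]
  expect_equal(organ_contribution_table(sols, shuffled), tab)

  single <- organ_contribution_table(sols["toy-Keto"], ex)
  expect_equal(ncol(single), 2)

  broken <- sols
  broken[["toy-Keto"]]$status <- "infeasible"
  expect_error(organ_contribution_table(broken, ex),
               class = "dietwbm_partial_table_error")
})

test_that("organ role classification partitions and matches definitions", {
  tab <- structure(tibble::tibble(
    organ = c("A", "B", "C", "D"),
    d1 = c(1, -1, 0, 1), d2 = c(1, -1, 0, -1)),
    class = c("organ_flux_table", "tbl_df", "tbl", "data.frame"))
  roles <- classify_organ_roles(tab)
  expect_equal(roles$role, c("secretor", "uptaker", "inactive", "mixed"))
  # invariant to diet column order
  tab2 <- tab[, c("organ", "d2", "d1")]
  class(tab2) <- class(tab)
  expect_equal(classify_organ_roles(tab2)$role, roles$role)
  # every organ receives exactly one label
  expect_equal(nrow(roles), 4)
})

test_that("fat-forced diets depress hepatic glucose secretion (oracle-verified)", {
  fx <- toy_secretion_fixture()
  secretion <- sapply(names(fx$diets), function(dn) {
    fed <- apply_diet(fx$model, fx$diets[[dn]], fx$policy)
    sol <- pfba(fed)
    orc <- qp_oracle(fed)
    expect_lt(max(abs(tidy(sol)$flux - tidy(orc)$flux)), 1e-6)
    secretion_uptake_totals(sol, "Liver_EX_glc_D[bc]")$total_secretion
  })
  expect_gt(secretion[["balanced"]], secretion[["unhealthy"]])
  expect_equal(secretion, fx$manifest$planted_facts$expected_secretion,
               tolerance = 1e-6)
})
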