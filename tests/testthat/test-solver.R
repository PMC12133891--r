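test_that("the forced chain carries unit flux under every backend", {
  fx <- chain_fed(100)
  expected <- fx$manifest$planted_facts$chain_fluxes
  for (be in c("quadprog", "dual")) {
    sol <- pfba(fx$model, backend = be)
    expect_equal(sol$status, "optimal")
    v <- tidy(sol)
    expect_equal(setNames(v$flux, v$reaction_id), expected, tolerance = 1e-7)
  }
  orc <- qp_oracle(fx$model)
  expect_equal(setNames(tidy(orc)$flux, tidy(orc)$reaction_id), expected,
               tolerance = 1e-9)
})

test_that("symmetric parallel paths split evenly and the asymmetric pair is (2/3, 1/3)", {
  par <- make_toy_wbm(options = list(parallel_pair = TRUE))
  fed <- apply_diet(par$model, diet_spec(c(glc_D = 10)))
  v <- tidy(pfba(fed))
  expect_equal(v$flux[v$reaction_id == "OrganA_PATH"], 0.5, tolerance = 1e-8)
  expect_equal(v$flux[v$reaction_id == "OrganB_PATH"], 0.5, tolerance = 1e-8)

  asy <- make_toy_wbm(options = list(asym_pair = TRUE))
  fed2 <- apply_diet(asy$model, diet_spec(c(glc_D = 10)))
  for (solver in list(pfba(fed2), pfba(fed2, backend = "dual"), qp_oracle(fed2))) {
    v2 <- tidy(solver)
    expect_equal(v2$flux[v2$reaction_id == "OrganA_PATH"], 2 / 3, tolerance = 1e-7)
    expect_equal(v2$flux[v2$reaction_id == "OrganB_STEP1"], 1 / 3, tolerance = 1e-7)
  }
})

test_that("both backends match the exhaustive KKT oracle on random models", {
  for (s in 1:25) {
    rt <- random_toy_model(s)
    orc <- qp_oracle(rt$model)
    expect_equal(orc$status, "optimal")
    for (be in c("quadprog", "dual")) {
      sol <- pfba(rt$model, backend = be)
      expect_equal(sol$status, "optimal")
      expect_lt(max(abs(tidy(sol)$flux - tidy(orc)$flux)), 1e-6)
    }
  }
})

test_that("every optimal solution satisfies the protocol invariants", {
  sols <- c(
    list(pfba(chain_fed()$model)),
    lapply(1:10, function(s) pfba(random_toy_model(s)$model))
  )
  for (sol in sols) {
    expect_equal(sol$status, "optimal")
    v <- tidy(sol)$flux
    maint <- tidy(sol)$flux[tidy(sol)$reaction_id == "Whole_body_objective_rxn"]
    expect_lt(abs(maint - 1), 1e-9)
    expect_lte(sol$max_mass_balance_residual, 1e-6 * max(1, max(abs(v))))
    expect_lte(sol$max_bound_violation, 1e-8)
    expect_equal(sol$objective, sum(v^2), tolerance = 1e-10)
  }
})

test_that("the maintenance pin honors non-default maintenance values", {
  fx <- chain_fed(100)
  sol <- pfba(fx$model, solver_settings(maintenance_value = 2.5))
  v <- tidy(sol)
  expect_equal(v$flux[v$reaction_id == "Whole_body_objective_rxn"], 2.5,
               tolerance = 1e-9)
  expect_equal(abs(v$flux), rep(2.5, 5), tolerance = 1e-9)
})

test_that("infeasible models are detected and diagnosed with the planted deficit", {
  inf <- make_toy_wbm(organs = "Liver",
                      options = list(chain_only = TRUE, infeasible = TRUE))
  sol <- pfba(inf$model)
  expect_equal(sol$status, "infeasible")
  expect_equal(nrow(sol$fluxes), 0)

  diag <- diagnose_infeasibility(inf$model)
  expect_equal(diag$reaction_id, "Diet_EX_glc_D[d]")
  expect_equal(diag$bound, "lb")
  expect_equal(diag$relaxation,
               inf$manifest$planted_facts$min_feasible_uptake, tolerance = 1e-6)

  # doubling maintenance demand doubles the localized deficit
  inf2 <- inf$model
  sol2 <- pfba(inf2, solver_settings(maintenance_value = 2))
  expect_equal(sol2$status, "infeasible")
  diag2 <- diagnose_infeasibility(inf2, solver_settings(maintenance_value = 2))
  expect_equal(diag2$relaxation[diag2$reaction_id == "Diet_EX_glc_D[d]"], 2,
               tolerance = 1e-6)

  # feasible models yield an empty diagnosis
  expect_equal(nrow(diagnose_infeasibility(chain_fed()$model)), 0)
})

test_that("fba optimizes single fluxes against the diet-limited envelope", {
  fx <- chain_fed(1)   # diet supplies at most 1 mmol/day
  relaxed <- set_bounds_for_test(fx$model, "Whole_body_objective_rxn", 0, 10)
  top <- fba(relaxed, "Whole_body_objective_rxn", "max")
  expect_equal(top$status, "optimal")
  expect_equal(top$objective, 1, tolerance = 1e-8)

  shut <- set_bounds_for_test(relaxed, "Liver_ATP_glc", 0, 0)
  expect_equal(fba(shut, "Whole_body_objective_rxn", "max")$objective, 0,
               tolerance = 1e-9)

  starved <- apply_diet(fx$model, diet_spec(tibble::tibble(
    nutrient = character(), amount = numeric())))
  expect_equal(fba(starved, "GI_A_glc_D", "max")$status, "optimal")
  expect_error(fba(fx$model, "no_such_reaction"),
               class = "dietwbm_integrity_error")
})

test_that("tightening bounds weakly increases the optimal squared-flux total", {
  asy <- make_toy_wbm(options = list(asym_pair = TRUE))
  fed <- apply_diet(asy$model, diet_spec(c(glc_D = 10)))
  base <- pfba(fed)
  # cap the short path below its unconstrained optimum of 2/3
  tight <- set_bounds_for_test(fed, "OrganA_PATH", 0, 0.5)
  tight_sol <- pfba(tight)
  expect_equal(tight_sol$status, "optimal")
  expect_gt(tight_sol$objective, base$objective)
  # closed form: a = b = 1/2 once the cap binds, plus three unit-flux steps
  expect_equal(tight_sol$objective, 3 + 0.25 + 2 * 0.25, tolerance = 1e-8)

  # random models: forcing a minimum diet uptake (which the current optimum
  # already satisfies) can only raise the optimal total
  for (s in c(2, 4)) {
    rt <- random_toy_model(s)
    base_s <- pfba(rt$model)
    j <- match("Diet_EX_glc_D[d]", rt$model$reactions$id)
    flux_j <- tidy(base_s)$flux[j]   # negative uptake at the optimum
    forced <- set_bounds_for_test(rt$model, "Diet_EX_glc_D[d]",
                                  rt$model$reactions$lb[j], 0.5 * flux_j)
    sq <- pfba(forced)
    expect_equal(sq$status, "optimal")
    expect_gte(sq$objective, base_s$objective - 1e-9)
  }
})

test_that("L1 parsimonious mode solves and is flagged as non-protocol norm", {
  fx <- chain_fed(10)
  sol <- pfba(fx$model, solver_settings(norm = "L1"))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$norm, "L1")
  expect_equal(sol$objective, 5, tolerance = 1e-6)  # five unit-flux reactions
  expect_equal(abs(tidy(sol)$flux), rep(1, 5), tolerance = 1e-7)
})

test_that("qp_oracle refuses oversized models", {
  big <- make_toy_wbm()$model
  expect_error(qp_oracle(big), class = "dietwbm_oracle_error")
})
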