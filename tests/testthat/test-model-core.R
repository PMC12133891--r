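test_that("chain toy has the documented structure and classification partitions", {
  toy <- make_toy_wbm(organs = "Liver", options = list(chain_only = TRUE))
  m <- toy$model
  expect_equal(nrow(m$reactions), 5)
  expect_equal(m$organs, "Liver")
  expect_setequal(unique(m$reactions$kind),
                  c("diet_exchange", "internal", "organ_blood_exchange",
                    "maintenance"))
  # every reaction receives exactly one kind
  expect_true(all(m$reactions$kind %in%
    c("internal", "organ_blood_exchange", "diet_exchange", "maintenance",
      "sink_demand")))
  expect_equal(sum(m$reactions$kind == "maintenance"), 1)
})

test_that("constructor rejects duplicate ids and wrong maintenance counts", {
  rx <- tibble::tibble(id = c("A", "A"), lb = 0, ub = 1)
  st <- tibble::tibble(reaction_id = "A", metabolite_id = "x[c]", coef = 1)
  expect_error(wbm(rx, st), class = "dietwbm_integrity_error")

  rx2 <- tibble::tibble(
    id = c("Whole_body_objective_rxn", "Whole_body_objective_rxn2"),
    lb = 0, ub = 1,
    kind = c("maintenance", "maintenance"))
  st2 <- tibble::tibble(reaction_id = rx2$id, metabolite_id = "x[c]",
                        coef = c(-1, -1))
  expect_error(wbm(rx2, st2), class = "dietwbm_model_error")

  rx3 <- tibble::tibble(id = "A", lb = 0, ub = 1)
  st3 <- tibble::tibble(reaction_id = "A", metabolite_id = "x[c]", coef = 1)
  expect_error(wbm(rx3, st3), class = "dietwbm_model_error")  # no maintenance
})

test_that("validate_wbm reports structural defects and passes clean models", {
  toy <- make_toy_wbm()
  expect_equal(nrow(validate_wbm(toy$model)), 0)

  m <- toy$model
  m$reactions$kind[m$reactions$kind == "diet_exchange"] <- "internal"
  rep <- validate_wbm(m)
  expect_true("NO_DIET_EXCHANGE" %in% rep$code)

  m2 <- toy$model
  m2$reactions$lb[2] <- m2$reactions$ub[2] + 5
  rep2 <- validate_wbm(m2)
  expect_equal(sum(rep2$code == "BOUND_ORDER"), 1)
})

test_that("find_organ_exchanges resolves by nutrient and stays well-formed", {
  chain <- make_toy_wbm(organs = "Liver", options = list(chain_only = TRUE))$model
  hit <- find_organ_exchanges(chain, "glc_D")
  expect_equal(hit$reaction_id, "Liver_EX_glc_D[bc]")

  m <- make_toy_wbm()$model
  glc <- find_organ_exchanges(m, "glc_D")
  expect_equal(nrow(glc), 8)       # one per organ in the default panel
  expect_setequal(glc$organ, m$organs)
  # each hit is classified organ_blood_exchange with exactly one blood met
  kinds <- m$reactions$kind[match(glc$reaction_id, m$reactions$id)]
  expect_true(all(kinds == "organ_blood_exchange"))
  blood_counts <- vapply(glc$reaction_id, function(rid) {
    s <- m$stoich[m$stoich$reaction_id == rid, ]
    sum(endsWith(s$metabolite_id, "[bc]"))
  }, numeric(1))
  expect_true(all(blood_counts == 1))
  expect_true(!is.unsorted(glc$reaction_id))

  expect_equal(nrow(find_organ_exchanges(m, "nonexistent")), 0)
})

test_that("models round-trip exactly through the JSON and TSV dialects", {
  m <- make_toy_wbm()$model
  for (fmt in c("json", "tsv")) {
    path <- file.path(withr::local_tempdir(),
                      if (fmt == "json") "m.json" else "mdir")
    write_wbm(m, path, format = fmt)
    m2 <- read_wbm(path)
    expect_equal(m2$reactions$id, m$reactions$id)
    expect_identical(m2$reactions$lb, m$reactions$lb)
    expect_identical(m2$reactions$ub, m$reactions$ub)
    expect_identical(m2$stoich$coef, m$stoich$coef)
    expect_equal(m2$organs, m$organs)
    expect_equal(m2$sex, m$sex)
  }
})

test_that("blood-negative exchanges are re-oriented to secretion-positive", {
  rx <- tibble::tibble(
    id = c("Diet_EX_glc_D[d]", "GI_A_glc_D", "Liver_EX_glc_D[bc]",
           "Liver_ATP_glc", "Whole_body_objective_rxn"),
    lb = c(-10, 0, 0, 0, 0),
    ub = c(0, 10, 7, 10, 10))
  st <- tibble::tibble(
    reaction_id = c("Diet_EX_glc_D[d]", rep("GI_A_glc_D", 2),
                    rep("Liver_EX_glc_D[bc]", 2), rep("Liver_ATP_glc", 2),
                    "Whole_body_objective_rxn"),
    metabolite_id = c("glc_D[d]", "glc_D[d]", "glc_D[bc]",
                      "glc_D[bc]", "Liver_glc_D[c]",   # blood NEGATIVE here
                      "Liver_glc_D[c]", "Liver_atp[c]", "Liver_atp[c]"),
    coef = c(-1, -1, 1, -1, 1, -1, 1, -1))
  m <- wbm(rx, st, organs = "Liver")
  expect_equal(m$flips, "Liver_EX_glc_D[bc]")
  i <- match("Liver_EX_glc_D[bc]", m$reactions$id)
  expect_equal(m$reactions$lb[i], -7)   # bounds swapped and negated
  expect_equal(m$reactions$ub[i], 0)
  bc <- m$stoich$reaction_id == "Liver_EX_glc_D[bc]" &
    m$stoich$metabolite_id == "glc_D[bc]"
  expect_equal(m$stoich$coef[bc], 1)
  # the re-oriented model still carries unit chain flux
  sol <- pfba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(unname(abs(tidy(sol)$flux)), rep(1, 5), tolerance = 1e-9)
})

test_that("the SBML reader recovers species, stoichiometry and fbc bounds", {
  path <- file.path(withr::local_tempdir(), "toy.xml")
  writeLines(sbml_fixture_text(), path)
  m <- read_wbm(path)
  expect_s3_class(m, "wbm")
  expect_equal(nrow(m$reactions), 5)
  expect_equal(m$organs, "Liver")
  i <- match("Diet_EX_glc_D[d]", m$reactions$id)
  expect_equal(m$reactions$lb[i], -50)
  expect_equal(m$reactions$ub[i], 0)
  # defaults: irreversible reactions get [0, big-M]
  j <- match("GI_A_glc_D", m$reactions$id)
  expect_equal(m$reactions$lb[j], 0)
  sol <- pfba(apply_diet(m, diet_spec(c(glc_D = 5))))
  expect_equal(sol$status, "optimal")
  expect_equal(abs(tidy(sol)$flux), rep(1, 5), tolerance = 1e-9)
})

test_that("unreadable files and unknown formats raise format errors", {
  expect_error(read_wbm(file.path(tempdir(), "nope.json")),
               class = "dietwbm_format_error")
  bad <- file.path(withr::local_tempdir(), "bad.txt")
  writeLines("x", bad)
  expect_error(read_wbm(bad), class = "dietwbm_format_error")
})
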