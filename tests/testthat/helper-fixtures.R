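# Shared fixtures, all generated in code.

chain_fed <- function(amount = 100) {
  toy <- make_toy_wbm(organs = "Liver", options = list(chain_only = TRUE))
  list(model = apply_diet(toy$model, diet_spec(c(glc_D = amount))),
       manifest = toy$manifest)
}

# Solve the full two-sex x 12-diet synthetic study once per test run.
study_suite <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    diets <- make_toy_diets()
    out <- list()
    for (sx in c("male", "female")) {
      toy <- make_toy_wbm(sex = sx)
      panel <- resolve_panel(toy$model)
      sols <- list()
      for (dn in names(diets)) {
        fed <- apply_diet(toy$model, diets[[dn]], diet_policy("forced_uptake"))
        sols[[dn]] <- pfba(fed)
      }
      out[[sx]] <- list(model = toy$model, manifest = toy$manifest,
                        panel = panel, solutions = sols)
    }
    out$diets <- diets
    cache <<- out
    cache
  }
})

set_bounds_for_test <- function(model, id, lb, ub) {
  i <- match(id, model$reactions$id)
  model$reactions$lb[i] <- lb
  model$reactions$ub[i] <- ub
  model
}

# Minimal SBML L3 + fbc document over the package's identifier style.
sbml_fixture_text <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="sbml_toy" name="male toy">
    <listOfParameters>
      <parameter id="lb_open" value="-50" constant="true"/>
      <parameter id="ub_open" value="50" constant="true"/>
      <parameter id="zero" value="0" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="glc_D[d]"/><species id="glc_D[bc]"/>
      <species id="Liver_glc_D[c]"/><species id="Liver_atp[c]"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="Diet_EX_glc_D[d]" reversible="true"
                fbc:lowerFluxBound="lb_open" fbc:upperFluxBound="zero">
        <listOfReactants>
          <speciesReference species="glc_D[d]" stoichiometry="1"/>
        </listOfReactants>
      </reaction>
      <reaction id="GI_A_glc_D" reversible="false">
        <listOfReactants>
          <speciesReference species="glc_D[d]"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="glc_D[bc]"/>
        </listOfProducts>
      </reaction>
      <reaction id="Liver_EX_glc_D[bc]" reversible="true"
                fbc:lowerFluxBound="lb_open" fbc:upperFluxBound="zero">
        <listOfReactants>
          <speciesReference species="Liver_glc_D[c]"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="glc_D[bc]"/>
        </listOfProducts>
      </reaction>
      <reaction id="Liver_ATP_glc" reversible="false">
        <listOfReactants>
          <speciesReference species="Liver_glc_D[c]"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="Liver_atp[c]"/>
        </listOfProducts>
      </reaction>
      <reaction id="Whole_body_objective_rxn" reversible="false">
        <listOfReactants>
          <speciesReference species="Liver_atp[c]"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
}
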