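test_that("model validation reports all offenses at once", {
  mets <- data.frame(id = c("a_c", "b_c"), name = c("a", "b"),
                     formula = NA_character_, charge = NA_integer_,
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "R1", stoichiometry = c(a_c = -1, ghost_c = 1),
         lower_bound = 5, upper_bound = 0))
  err <- tryCatch(new_model("bad", mets, rxns), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "undeclared metabolites: ghost_c")
  expect_match(conditionMessage(err), "lower_bound > upper_bound")
})

test_that("GPR genes missing from the gene list load with a warning", {
  mets <- data.frame(id = "a_c", name = "a", formula = NA_character_,
                     charge = NA_integer_, compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- list(list(id = "R1", stoichiometry = c(a_c = 1),
                    lower_bound = 0, upper_bound = 1, gpr = "gX"))
  expect_warning(m <- new_model("partial", mets, rxns, genes = character()),
                 "gX")
  # the orphan gene leaf is treated as present
  expect_equal(apply_gene_knockout(m, character())$disabled, character())
})

test_that("model_stats reproduces the ORF coverage arithmetic", {
  m <- chain_model()
  st <- model_stats(m, total_orfs = 5488, assigned_genes = 1074)
  expect_identical(st$orf_coverage_percent, 19.57)
  expect_equal(st$n_reactions, st$n_biochemical + st$n_transport)
  # chain: EX_A, At, Bt, EX_B span compartments / are exchanges
  expect_equal(st$n_transport, 4)
  expect_equal(st$n_biochemical, 1)
  expect_error(model_stats(m, total_orfs = 0), "total_orfs")

  empty <- new_model("empty",
                     data.frame(id = character(), name = character(),
                                formula = character(), charge = integer(),
                                compartment = character()),
                     list(), genes = character())
  expect_identical(model_stats(empty, 100)$orf_coverage_percent, 0)
})

test_that("exchange bounds follow the uptake sign convention", {
  m <- chain_model()
  m2 <- set_exchange_bounds(m, "A_e", -5, 0)
  expect_equal(m2$reactions$EX_A$lower_bound, -5)
  expect_equal(optimize_fluxes(m2, "EX_B")$objective_value, 5)
  # zero-secretion constraint
  m3 <- set_exchange_bounds(m, "B_e", 0, 0)
  expect_equal(optimize_fluxes(m3, "EX_B")$objective_value, 0)
  expect_error(set_exchange_bounds(m, "A_e", 1, 0), "lb > ub")
  expect_error(set_exchange_bounds(m, "A_c", -1, 0), "no exchange")
})

test_that("mass balance checking flags constructed defects and skips exchanges", {
  m <- fixture_model()
  ok <- check_mass_balance(m, "BTDD_RR")
  expect_equal(ok$status, "balanced")

  # deliberately remove the CO2 product of acetolactate synthase
  broken <- m
  st <- broken$reactions$ACLS$stoichiometry
  st <- st[names(st) != "co2_c"]
  broken$reactions$ACLS$stoichiometry <- st
  imb <- check_mass_balance(broken, "ACLS")
  expect_equal(imb$status, "imbalanced")
  expect_equal(unname(imb$imbalance[["C"]]), -1)
  expect_equal(unname(imb$imbalance[["O"]]), -2)

  expect_equal(check_mass_balance(m, "EX_glc__D_e")$status, "skipped")
  expect_equal(check_mass_balance(m, "BIOMASS")$status, "unverifiable")
})

test_that("JSON and TSV round trips preserve the model", {
  m <- fixture_model()
  td <- withr::local_tempdir()
  jp <- file.path(td, "model.json")
  write_model(m, jp, "json")
  m2 <- read_model(jp)
  expect_equal(names(m2$reactions), names(m$reactions))
  for (rid in names(m$reactions)) {
    a <- m$reactions[[rid]]; b <- m2$reactions[[rid]]
    expect_equal(sort(names(a$stoichiometry)), sort(names(b$stoichiometry)))
    expect_equal(a$stoichiometry[sort(names(a$stoichiometry))],
                 b$stoichiometry[sort(names(b$stoichiometry))])
    expect_equal(a$lower_bound, b$lower_bound)
    expect_equal(a$upper_bound, b$upper_bound)
    expect_equal(parse_gpr(a$gpr), parse_gpr(b$gpr))
  }
  expect_equal(m2$metabolites, m$metabolites)
  expect_equal(m2$genes, m$genes)
  expect_equal(m2$objective, m$objective)

  tp <- file.path(td, "tsvmodel")
  write_model(m, tp, "tsv")
  m3 <- read_model(tp)
  expect_equal(names(m3$reactions), names(m$reactions))
  S_a <- stoichiometric_matrix(m)
  S_b <- stoichiometric_matrix(m3)[rownames(S_a), colnames(S_a)]
  expect_equal(S_b, S_a)
  bb_a <- reaction_bounds(m); bb_b <- reaction_bounds(m3)
  expect_equal(bb_b$lb, bb_a$lb)
  expect_equal(bb_b$ub, bb_a$ub)

  # a model with empty GPRs serializes them as ""
  rtab <- utils::read.delim(file.path(tp, "reactions.tsv"))
  expect_true(any(!nzchar(trimws(rtab$gpr)) | is.na(rtab$gpr)))
})

test_that("reading a reaction with an undeclared metabolite fails", {
  td <- withr::local_tempdir()
  jp <- file.path(td, "bad.json")
  jsonlite::write_json(list(
    id = "bad",
    metabolites = list(list(id = "a_c", name = "a", compartment = "c")),
    reactions = list(list(id = "R1", name = "R1",
                          stoichiometry = list(ghost_c = 1),
                          lower_bound = 0, upper_bound = 1, gpr = "",
                          subsystem = "", ec_numbers = list())),
    genes = list(), objective = NULL), jp, auto_unbox = TRUE, null = "null")
  expect_error(read_model(jp), "undeclared")
})

test_that("the SBML L3/fbc import subset maps species, bounds, GPRs and objective", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_e" name="A ext" compartment="e" fbc:charge="0"
               fbc:chemicalFormula="C1" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
      <species id="A_c" name="A" compartment="c" fbc:charge="0"
               fbc:chemicalFormula="C1" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_m10" value="-10" constant="true"/>
      <parameter id="ub_1000" value="1000" constant="true"/>
      <parameter id="lb_0" value="0" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_A" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="UPT" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_g1"/>
            <fbc:geneProductRef fbc:geneProduct="G_g2"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="SINK" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_1000">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="SINK" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>'
  td <- withr::local_tempdir()
  sp <- file.path(td, "toy.xml")
  writeLines(sbml, sp)
  m <- read_model(sp)
  expect_equal(m$id, "toy")
  expect_equal(nrow(m$metabolites), 2)
  expect_equal(m$reactions$EX_A$lower_bound, -10)
  expect_true(m$reactions$EX_A$is_exchange)
  expect_equal(sort(m$genes), c("g1", "g2"))
  expect_equal(parse_gpr(m$reactions$UPT$gpr), parse_gpr("g1 or g2"))
  expect_equal(m$objective, "SINK")
  expect_equal(optimize_fluxes(m, "SINK")$objective_value, 10)
})
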