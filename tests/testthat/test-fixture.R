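test_that("the core model builds to size, validates and grows", {
  m <- fixture_model()
  expect_s3_class(m, "cb_model")
  expect_true(validate_model(m))
  expect_equal(m$objective, "BIOMASS")
  # desk-scale reconstruction: ~85 reactions, ~75 metabolites, ~75 genes
  expect_gt(length(m$reactions), 70)
  expect_lt(length(m$reactions), 100)
  expect_gt(nrow(m$metabolites), 60)
  expect_true(all(c("ldhA", "budB", "budA", "budC") %in% m$genes))
  r <- optimize_fluxes(m)
  expect_equal(r$status, "optimal")
  expect_gt(r$objective_value, 0)
})

test_that("the named pathway reactions carry their EC numbers", {
  m <- fixture_model()
  ecs <- function(rid) m$reactions[[rid]]$ec_numbers
  expect_equal(ecs("ACLS"), "2.2.1.6")
  expect_equal(ecs("ACLDC"), "4.1.1.5")
  expect_equal(ecs("BTDD_RR"), "1.1.1.4")
  expect_equal(ecs("DAR"), "1.1.1.303")
  expect_equal(ecs("GLYK"), "2.7.1.30")
  expect_equal(ecs("G3PD_OPM"), "1.1.5.3")
  expect_equal(ecs("GLYCDH"), "1.1.1.6")
  expect_equal(ecs("DHAK"), "2.7.1.29")
  # spontaneous diacetyl branch is gene-free and oxygen-dependent
  sp <- m$reactions$ACLS_SPONT
  expect_equal(sp$gpr_tree$kind, "ALWAYS_ACTIVE")
  expect_lt(sp$stoichiometry[["o2_c"]], 0)
})

test_that("every non-exchange reaction with formulas is elementally balanced", {
  m <- fixture_model()
  for (rid in names(m$reactions)) {
    res <- check_mass_balance(m, rid)
    expect_false(identical(res$status, "imbalanced"),
                 info = paste(rid, paste(names(res$imbalance),
                                         round(res$imbalance, 6),
                                         collapse = " ")))
  }
  # the only unverifiable reactions involve the formula-less biomass
  unver <- names(m$reactions)[vapply(names(m$reactions), function(r) {
    check_mass_balance(m, r)$status == "unverifiable"
  }, logical(1))]
  expect_setequal(unver, c("BIOMASS", "DM_biomass"))
})

test_that("manifest covers every reaction and the fixture genes", {
  m <- fixture_model()
  man <- fixture_manifest(m)
  expect_setequal(man$id, names(m$reactions))
  expect_true(all(c("EX_glc__D_e", "EX_glyc_e", "EX_o2_e", "EX_co2_e",
                    "EX_btd_e", "EX_actn__R_e", "EX_lac__D_e", "EX_ac_e",
                    "EX_etoh_e", "EX_for_e", "EX_succ_e", "EX_nh4_e",
                    "EX_pi_e", "EX_h2o_e", "EX_h_e") %in% man$id))
})

test_that("the bud pathway net stoichiometry releases 2 CO2 and oxidizes 1 NADH", {
  m <- fixture_model()
  net <- net_stoichiometry(m, c("ACLS", "ACLDC", "BTDD_RR"), "btd_RR_c")
  expect_equal(net[["btd_RR_c"]], 1)
  expect_equal(net[["pyr_c"]], -2)
  expect_equal(net[["co2_c"]], 2)
  expect_equal(net[["nadh_c"]], -1)
  expect_equal(net[["nad_c"]], 1)
  # intermediates cancel
  expect_false(any(c("alac__S_c", "actn__R_c") %in% names(net)))

  expect_error(net_stoichiometry(m, character(), "btd_RR_c"), "empty")
  expect_error(net_stoichiometry(m, c("ACLS", "ACLDC"), "pep_c"),
               "cancels out")
})

test_that("a glycolysis lump nets 2 pyruvate, 2 ATP, 2 NADH per glucose", {
  m <- fixture_model()
  ids <- c("GLCpts", "PGI", "PFK", "FBA", "TPI", "GAPD_PGK", "ENO_PGM",
           "PYK")
  w <- c(1, 1, 1, 1, 1, 2, 2, 1)
  net <- net_stoichiometry(m, ids, "glc__D_e", weights = w)
  expect_equal(net[["glc__D_e"]], -1)
  expect_equal(net[["pyr_c"]], 2)
  expect_equal(net[["atp_c"]], 2)
  expect_equal(net[["nadh_c"]], 2)
})

test_that("anaerobic and glycerol media both support fermentative growth", {
  ma <- build_core_model(aerobic = FALSE)
  ra <- optimize_fluxes(ma)
  expect_gt(ra$objective_value, 0)
  # fermentation products are secreted anaerobically
  secr <- ra$fluxes[kox_byproduct_exchanges()]
  expect_gt(sum(secr) + ra$fluxes[["EX_btd_e"]], 1)

  mg <- build_core_model(glycerol = TRUE)
  rg <- optimize_fluxes(mg)
  expect_gt(rg$objective_value, 0)
  expect_lt(rg$fluxes[["EX_glyc_e"]], 0)
  expect_equal(rg$fluxes[["EX_glc__D_e"]], 0)
  # both glycerol routes can carry the substrate on their own
  m_ox <- apply_gene_knockout(mg, "gldA")$model
  expect_gt(optimize_fluxes(m_ox)$objective_value, 0)
  m_red <- apply_gene_knockout(mg, "glpK")$model
  expect_gt(optimize_fluxes(m_red)$objective_value, 0)
})

test_that("anaerobic maximum 2,3-BD yield is below the aerobic maximum", {
  m <- build_core_model(o2_uptake = 1000)
  ya <- theoretical_yield_fraction(0.478, m, "EX_btd_e", "EX_glc__D_e")
  man <- set_exchange_bounds(m, "o2_e", 0, 0)
  yn <- theoretical_yield_fraction(0.478, man, "EX_btd_e", "EX_glc__D_e")
  expect_lt(yn$molar_yield, ya$molar_yield - 0.05)
})

test_that("bound perturbation is deterministic, sign-preserving and balance-invariant", {
  m <- fixture_model()
  p1 <- perturb_bounds(m, seed = 7, magnitude = 0.2)
  p2 <- perturb_bounds(m, seed = 7, magnitude = 0.2)
  expect_equal(p1, p2)
  p3 <- perturb_bounds(m, seed = 8, magnitude = 0.2)
  expect_false(identical(p1$reactions, p3$reactions))

  bb <- reaction_bounds(m)
  for (seed in 1:10) {
    p <- perturb_bounds(m, seed, magnitude = 0.3)
    pb <- reaction_bounds(p)
    # no reversibility flips, exchanges untouched
    expect_true(all(sign(pb$lb) == sign(bb$lb)))
    expect_true(all(sign(pb$ub) == sign(bb$ub)))
    ex <- vapply(m$reactions, `[[`, logical(1), "is_exchange")
    expect_equal(pb$lb[ex], bb$lb[ex])
    expect_equal(pb$ub[ex], bb$ub[ex])
    # stoichiometry untouched: still mass balanced
    expect_equal(stoichiometric_matrix(p), stoichiometric_matrix(m))
  }
  # vanishing magnitude approaches the identity
  p0 <- perturb_bounds(m, seed = 3, magnitude = 1e-9)
  pb0 <- reaction_bounds(p0)
  expect_equal(pb0$lb, bb$lb, tolerance = 1e-6)
  expect_equal(pb0$ub, bb$ub, tolerance = 1e-6)
  expect_error(perturb_bounds(m, 1, magnitude = 1.5), "magnitude")
})
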