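test_that("every optimal solve satisfies steady state and bounds", {
  models <- list(chain_model(), parallel_model(), fixture_model())
  for (m in models) {
    r <- optimize_fluxes(m)
    expect_equal(r$status, "optimal")
    expect_silent(check_flux_result(m, r))
  }
})

test_that("closing all uptakes gives zero growth, not a solver error", {
  m <- fixture_model()
  m <- set_exchange_bounds(m, "glc__D_e", 0, 0)
  m <- set_exchange_bounds(m, "o2_e", 0, 0)
  # with the forced maintenance flux the starved model is truly infeasible,
  # and that is reported as such, never as a silent zero
  r_maint <- optimize_fluxes(m)
  expect_equal(r_maint$status, "infeasible")
  expect_true(is.na(r_maint$objective_value))
  # without forced maintenance the LP is feasible with zero growth
  m0 <- set_reaction_bounds(m, "ATPM", lb = 0)
  r <- optimize_fluxes(m0)
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_value, 0, tolerance = 1e-9)
})

test_that("an invalid objective id is an error", {
  expect_error(optimize_fluxes(chain_model(), "NOPE"), "objective")
})

test_that("lexicographic optimization fixes stages and is deterministic", {
  m <- fixture_model()
  single <- optimize_fluxes(m)
  lex1 <- lexicographic_optimize(m, list(list(id = "BIOMASS", sense = "max")))
  expect_equal(lex1$objective_value, single$objective_value, tolerance = 1e-9)

  byp <- kox_byproduct_exchanges()
  agg <- byproduct_aggregate(byp)
  lex3 <- lexicographic_optimize(m, list(
    list(id = "BIOMASS", sense = "max"),
    list(id = "EX_btd_e", sense = "max"),
    list(id = "byproducts", sense = "min")),
    aggregates = list(byproducts = agg))
  # growth preserved within the stage tolerance
  expect_equal(lex3$stage_values[["BIOMASS"]], single$objective_value,
               tolerance = 1e-5)
  # product stage dominates any single arbitrary vertex
  expect_gte(lex3$stage_values[["EX_btd_e"]],
             single$fluxes[["EX_btd_e"]] - 1e-6)
  # deterministic across repeated runs
  lex3b <- lexicographic_optimize(m, list(
    list(id = "BIOMASS", sense = "max"),
    list(id = "EX_btd_e", sense = "max"),
    list(id = "byproducts", sense = "min")),
    aggregates = list(byproducts = agg))
  expect_equal(lex3b$stage_values, lex3$stage_values, tolerance = 1e-9)
})

test_that("flux variability brackets the optimum and shrinks with the growth floor", {
  p <- parallel_model()
  fva1 <- flux_variability(p, c("P1", "P2"), fraction_of_optimum = 1)
  # two equivalent parallel paths carrying total 10: each ranges (0, 10)
  expect_equal(fva1$min, c(0, 0), tolerance = 1e-6)
  expect_equal(fva1$max, c(10, 10), tolerance = 1e-6)

  # blocked reaction has a degenerate (0, 0) range
  pb <- set_reaction_bounds(p, "P2", 0, 0)
  fvab <- flux_variability(pb, "P2")
  expect_equal(c(fvab$min, fvab$max), c(0, 0))

  m <- fixture_model()
  ids <- c("LDH_D", "PDH", "ACLS", "EX_btd_e", "NADH_OPM")
  lo <- flux_variability(m, ids, fraction_of_optimum = 0.5)
  hi <- flux_variability(m, ids, fraction_of_optimum = 1)
  # monotonicity: ranges shrink (or stay equal) as the floor rises
  expect_true(all(hi$min >= lo$min - 1e-6))
  expect_true(all(hi$max <= lo$max + 1e-6))
  # the optimum flux lies inside its own range at fraction 1
  wt <- optimize_fluxes(m)
  expect_true(all(wt$fluxes[ids] >= hi$min - 1e-5))
  expect_true(all(wt$fluxes[ids] <= hi$max + 1e-5))
})

test_that("essentiality matches an exhaustive deletion sweep", {
  p <- parallel_model()
  # sole uptake essential, either parallel path dispensable
  er <- essential_reactions(p)
  expect_true(all(c("EX_A", "At", "Bt", "EX_B") %in% er))
  expect_false(any(c("P1", "P2") %in% er))
  eg <- essential_genes(p)
  expect_equal(eg, character())

  m <- fixture_model()
  # brute-force sweep oracle over a representative reaction subset
  subset <- c("GLCpts", "PGI", "PFK", "LDH_D", "PDH", "PFL", "ACLS",
              "BTDD_RR", "PPC", "CS", "NADH_OPM", "BIOMASS", "EX_glc__D_e")
  wt <- optimize_fluxes(m)$objective_value
  ess <- essential_reactions(m)
  for (rid in subset) {
    ko <- optimize_fluxes(set_reaction_bounds(m, rid, 0, 0))
    dead <- ko$status != "optimal" || ko$objective_value < 0.01 * wt
    expect_identical(rid %in% ess, dead, info = rid)
  }
  # sole transporter gene of the only glucose uptake system is essential;
  # ldhA (redox-compensated by the 2,3-BD branch) is not
  eg <- essential_genes(m)
  expect_true("ptsG" %in% eg)
  expect_false("ldhA" %in% eg)
  expect_false("pfkA" %in% eg)  # isozyme pair pfkA/pfkB
})

test_that("flux response fixes the scanned exchange and masks infeasible points", {
  m <- fixture_model()
  fr <- flux_response(m, "EX_o2_e", c(0, 5, 10, 20, 30), "EX_btd_e")
  expect_true(all(fr$min_objective[fr$feasible] <=
                    fr$max_objective[fr$feasible] + 1e-9))
  # single-value scan reduces to two plain solves
  one <- flux_response(m, "EX_o2_e", 5, "EX_btd_e")
  m5 <- set_reaction_bounds(m, "EX_o2_e", -5, -5)
  expect_equal(one$max_objective,
               optimize_fluxes(m5, "EX_btd_e", "max")$objective_value,
               tolerance = 1e-8)
  expect_equal(one$min_objective,
               optimize_fluxes(m5, "EX_btd_e", "min")$objective_value,
               tolerance = 1e-8)
  # an impossible forced uptake is masked, not interpolated
  frbad <- flux_response(m, "EX_o2_e", c(5, 500), "EX_btd_e")
  expect_true(frbad$feasible[1])
  expect_false(frbad$feasible[2])
  expect_true(is.na(frbad$max_objective[2]))
})

test_that("solution space scan is consistent with direct optimization", {
  m <- fixture_model()
  byp <- kox_byproduct_exchanges()
  surf <- solution_space_scan(m, "EX_btd_e", byp, grid = c(7L, 7L))
  # surface maximum equals the unconstrained biomass optimum
  expect_equal(max(surf$growth, na.rm = TRUE),
               optimize_fluxes(m)$objective_value, tolerance = 1e-6)
  expect_equal(surf$optimum_point[["growth"]],
               optimize_fluxes(m)$objective_value, tolerance = 1e-6)
  # growth is non-negative wherever defined
  expect_true(all(surf$growth >= -1e-9, na.rm = TRUE))

  # cell (0,0) equals optimizing with all product/byproduct secretion shut
  m00 <- set_reaction_bounds(m, "EX_btd_e", 0, 0)
  for (b in byp) m00 <- set_reaction_bounds(m00, b, 0, 0)
  direct <- optimize_fluxes(m00)
  cell <- surf$growth[1, 1]
  if (direct$status == "optimal") {
    expect_equal(cell, direct$objective_value, tolerance = 1e-6)
  } else {
    expect_true(is.na(cell))
  }

  # beyond the optimum cell, growth declines along the product axis
  # (weak monotonicity at the byproduct level nearest the optimum)
  jopt <- which.min(abs(surf$axis2 - surf$optimum_point[["byproduct_rate"]]))
  col <- surf$growth[, jopt]
  iopt <- which.max(col)
  tail_part <- col[iopt:length(col)]
  tail_part <- tail_part[!is.na(tail_part)]
  expect_true(all(diff(tail_part) <= 1e-6))

  expect_error(solution_space_scan(m, "EX_btd_e", character()), "empty")
})
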