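test_that("knockout disables exactly the GPR-dead reactions", {
  m <- fixture_model()
  ko <- apply_gene_knockout(m, "ldhA")
  expect_equal(ko$disabled, "LDH_D")
  expect_equal(ko$model$reactions$LDH_D$upper_bound, 0)
  expect_equal(ko$model$reactions$LDH_D$lower_bound, 0)
  # original untouched
  expect_gt(m$reactions$LDH_D$upper_bound, 0)

  # OR-isozyme reaction survives a single deletion
  expect_equal(apply_gene_knockout(m, "pfkA")$disabled, character())
  expect_equal(apply_gene_knockout(m, "pta")$disabled, character())
  # both isozymes gone: reaction dies
  expect_equal(apply_gene_knockout(m, c("pfkA", "pfkB"))$disabled, "PFK")
  # complex member: all complex reactions die
  expect_true("PDH" %in% apply_gene_knockout(m, "aceE")$disabled)
  expect_setequal(apply_gene_knockout(m, "lpd")$disabled, c("AKGDH", "PDH"))

  expect_error(apply_gene_knockout(m, "xyz"), "unknown gene")
})

test_that("knockout application is idempotent and order-independent", {
  m <- fixture_model()
  g <- c("ldhA", "aceE", "adhE")
  a <- apply_gene_knockout(m, g)
  b <- apply_gene_knockout(a$model, g)
  expect_equal(b$model, a$model)
  expect_setequal(b$disabled, a$disabled)
  c1 <- apply_gene_knockout(m, rev(g))
  expect_equal(c1$model$reactions, a$model$reactions)
})

test_that("no single knockout increases maximal growth (LP restriction)", {
  m <- fixture_model()
  wt <- optimize_fluxes(m)$objective_value
  for (g in m$genes) {
    ko <- apply_gene_knockout(m, g)
    if (length(ko$disabled) == 0L) next
    r <- optimize_fluxes(ko$model)
    mu <- if (r$status == "optimal") r$objective_value else 0
    expect_lte(mu, wt + 1e-6)
  }
})

test_that("knockout scan carries a wild-type baseline consistent with optimal_state", {
  m <- fixture_model()
  byp <- kox_byproduct_exchanges()
  genes <- c("ldhA", "adhE", "pfkA", "ptsG", "pyrF", "budB")
  scan <- knockout_scan(m, "EX_btd_e", byp, genes = genes)
  expect_equal(scan$gene[1], "WT")
  wt <- optimal_state(m, "EX_btd_e", byp)
  expect_equal(scan$growth[1], wt[["growth"]], tolerance = 1e-9)
  expect_equal(scan$product_rate[1], wt[["product_rate"]], tolerance = 1e-9)
  # essential biosynthesis gene: growth ~ 0 recorded, model still feasible
  row_pyr <- scan[scan$gene == "pyrF", ]
  expect_true(row_pyr$feasible)
  expect_lt(row_pyr$growth, 0.01 * wt[["growth"]])
  # carbon-entry knockout cannot even meet maintenance: honest infeasibility
  row_pts <- scan[scan$gene == "ptsG", ]
  expect_false(row_pts$feasible)
  expect_equal(row_pts$growth, 0)
  # production pathway knockout zeroes the product
  expect_lt(scan$product_rate[scan$gene == "budB"], 1e-6)
})

test_that("ranking filters dead candidates and breaks ties lexicographically", {
  dummy <- data.frame(
    gene = c("WT", "b", "a", "dead", "c"),
    growth = c(1, 1, 1, 0.2, 1),
    product_rate = c(5, 7, 7, 99, 7),
    byproduct_rate = c(3, 2, 2, 0, 2),
    feasible = TRUE, stringsAsFactors = FALSE)
  rk <- rank_knockouts(dummy)
  expect_equal(rk$gene, c("a", "b", "c"))  # dead excluded, ties by gene id
})

test_that("consumer detection honors bounds and directionality", {
  m <- fixture_model()
  cons <- consumers_of(m, "pyr_c")
  expect_setequal(cons, c("LDH_D", "PDH", "PFL", "ACLS", "ALATA"))
  # a purely produced metabolite has no consumers except its efflux
  expect_setequal(consumers_of(m, "btd_RR_c"), "BTDt")
  # reversible producer with lb < 0 counts as a consumer
  expect_true("MDH" %in% consumers_of(m, "oaa_c"))
  # blocking the reverse direction removes it
  m2 <- set_reaction_bounds(m, "MDH", lb = 0)
  expect_false("MDH" %in% consumers_of(m2, "oaa_c"))
  expect_error(consumers_of(m, "nope_c"), "unknown metabolite")
})

test_that("pyruvate pool augmentation redirects flux to the product", {
  m <- fixture_model()
  aug <- augment_precursor_pool(m, "pyr_c", grid = NULL)
  expect_true(aug$feasible)
  # never removes a protected or essential reaction
  expect_length(intersect(aug$removed, aug$protected), 0)
  ess <- essential_reactions(m)
  expect_length(intersect(aug$removed, ess), 0)
  # every removed reaction was a pyruvate consumer
  expect_true(all(aug$removed %in% consumers_of(m, "pyr_c")))
  # directions: product up, byproducts down
  expect_gt(aug$after[["product_rate"]], aug$before[["product_rate"]])
  expect_lt(aug$after[["byproduct_rate"]], aug$before[["byproduct_rate"]])
})

test_that("PEP augmentation does not help growth; untouched precursors are no-ops", {
  m <- fixture_model()
  aug <- augment_precursor_pool(m, "pep_c", grid = NULL)
  expect_lte(aug$after[["growth"]], aug$before[["growth"]] + 1e-6)

  # a precursor whose consumers are all protected/essential: nothing happens
  aug2 <- augment_precursor_pool(m, "r5p_c", grid = NULL,
                                 protected_pathway = consumers_of(m, "r5p_c"))
  expect_length(aug2$removed, 0)
  expect_equal(aug2$after, aug2$before, tolerance = 1e-9)
})

test_that("ldhA deletion leaves maximal growth unchanged within 1%", {
  m <- fixture_model()
  wt <- optimize_fluxes(m)$objective_value
  ko <- apply_gene_knockout(m, "ldhA")$model
  mu <- optimize_fluxes(ko)$objective_value
  expect_gt(mu, 0.99 * wt)
})
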