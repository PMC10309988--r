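one_ledger <- function(...) {
  cols <- c(paste0("e", 1:4), "e5_real", "e5_opportunity", paste0("e", 6:18))
  led <- tibble::as_tibble(setNames(as.list(rep(0, length(cols))), cols))
  tibble::as_tibble(utils::modifyList(led, list(...)))
}

test_that("variable costs sum the twelve listed terms under each scenario", {
  ones <- one_ledger()
  ones[] <- 1
  expect_equal(variable_costs(ones, "A"), 12)
  expect_equal(variable_costs(one_ledger(), "A"), 0)
  led <- one_ledger(e5_real = 10, e5_opportunity = 30)
  expect_equal(variable_costs(led, "A"), 10)
  expect_equal(variable_costs(led, "B"), 30)
  expect_error(variable_costs(one_ledger(e3 = -1), "A"),
               class = "acarecon_input_error")
})

test_that("fixed costs sum the six listed terms", {
  ones <- one_ledger()
  ones[] <- 1
  expect_equal(fixed_costs(ones), 6)
  expect_equal(fixed_costs(one_ledger()), 0)
  expect_equal(fixed_costs(one_ledger(e9 = 100, e18 = 50)), 150)
})

test_that("total cost decomposes exactly on random ledgers", {
  led <- random_ledgers(1000, seed = 7)
  expect_equal(total_cost(led, "A"), variable_costs(led, "A") + fixed_costs(led))
  expect_equal(total_cost(led, "B"), variable_costs(led, "B") + fixed_costs(led))
  # the two scenarios differ exactly by the veterinary-services gap
  expect_equal(total_cost(led, "B") - total_cost(led, "A"),
               led$e5_opportunity - led$e5_real)
  led2 <- one_ledger(e5_real = 0, e5_opportunity = 153.6)
  expect_equal(total_cost(led2, "A"), 0)
  expect_equal(total_cost(led2, "B"), 153.6)
})

test_that("milk production cost applies the stated exclusions", {
  led <- one_ledger(e1 = 800, e2 = 100, e14 = 50, e15 = 30, e16 = 20)
  out <- milk_production_cost(led, 1000)
  expect_equal(out$tcm, 800)
  expect_equal(out$cpm, 0.8)
  expect_equal(milk_production_cost(one_ledger(e1 = 300), 1000)$cpm, 0.3)
  # zero litres: TCM still returned, CPM undefined
  zero <- milk_production_cost(led, 0)
  expect_equal(zero$tcm, 800)
  expect_true(is.na(zero$cpm))
  expect_error(milk_production_cost(led, -1), class = "acarecon_input_error")
})

test_that("TCM never exceeds TC_A and CPM is scale invariant", {
  led <- random_ledgers(200, seed = 8)
  litres <- runif(200, 1000, 90000)
  out <- milk_production_cost(led, litres)
  expect_true(all(out$tcm <= total_cost(led, "A") + 1e-9))
  for (c_scale in c(0.5, 3, 117)) {
    scaled <- led
    scaled[] <- lapply(led, function(x) x * c_scale)
    expect_equal(milk_production_cost(scaled, litres * c_scale)$cpm, out$cpm)
  }
})

test_that("revenues and profit follow their accounting identities", {
  expect_equal(total_revenue(tibble::tibble(r1 = 1, r2 = 2, r3 = 3)), 6)
  expect_equal(total_revenue(tibble::tibble(r1 = 0, r2 = 0, r3 = 0)), 0)
  # symmetry over which component holds the amount
  expect_equal(total_revenue(tibble::tibble(r1 = 9, r2 = 0, r3 = 0)),
               total_revenue(tibble::tibble(r1 = 0, r2 = 0, r3 = 9)))
  expect_equal(annual_profit(100, 60), 40)
  expect_equal(annual_profit(60, 100), -40)
  # P_A - P_B = TC_B - TC_A for any ledger
  led <- random_ledgers(100, seed = 9)
  tr <- runif(100, 0, 50000)
  expect_equal(annual_profit(tr, total_cost(led, "A")) -
                 annual_profit(tr, total_cost(led, "B")),
               total_cost(led, "B") - total_cost(led, "A"))
})

test_that("milk revenue is cows x mean seasonal yield x price x days", {
  expect_equal(milk_revenue(10, 10, 10, 0.37), 13505)
  expect_equal(milk_revenue(0, 10, 10, 0.37), 0)
  expect_equal(milk_revenue(7, 8, 12, 0.4), milk_revenue(7, 10, 10, 0.4))
})

test_that("straight-line depreciation and replacement use the default lives", {
  expect_equal(straight_line_depreciation(10000, depreciation_rule("infrastructure")), 500)
  expect_equal(straight_line_depreciation(1100, "equipment"), 100)
  expect_equal(straight_line_depreciation(900, "cow"), 100)
  expect_equal(replacement_cost(900, depreciation_rule("cow")), 100)
  expect_equal(replacement_cost(500, depreciation_rule("bull")), 100)
  expect_equal(replacement_cost(0), 0)
  expect_error(depreciation_rule("cow", useful_life_years = 0),
               class = "acarecon_input_error")
})

test_that("family labour requirement is the ceiling of the milking ratio", {
  expect_identical(family_labor_requirement(18, "manual"), 1L)
  expect_identical(family_labor_requirement(19, "manual"), 2L)
  expect_identical(family_labor_requirement(25, "mechanical"), 1L)
  expect_identical(family_labor_requirement(0, "manual"), 0L)
})

test_that("price deflation is one multiplicative period and monotone", {
  expect_equal(deflate_price(100, 0.0256), 97.44)
  expect_equal(deflate_price(42, 0), 42)
  x <- sort(runif(50, 0, 1000))
  expect_true(all(diff(deflate_price(x)) >= 0))
  expect_error(deflate_price(-1), class = "acarecon_input_error")
})

test_that("mortality costing caps deaths and costs the cheapest first", {
  out <- mortality_cost(100, c(cow = 5), c(cow = 1650.5))
  expect_identical(out$n_costed, 3L)
  expect_equal(out$cost, 3 * 1650.5)
  # cap not binding
  out2 <- mortality_cost(100, c(cow = 2), c(cow = 1650.5))
  expect_identical(out2$n_costed, 2L)
  # composition: depreciation + milk loss + calf value for one cow
  out3 <- mortality_cost(100, c(cow = 1), c(cow = 100 + 1350.5 + 200))
  expect_equal(out3$cost, 1650.5)
  # cheapest-first tie-break when the cap binds across classes
  out4 <- mortality_cost(100, c(cow = 2, calf = 2), c(cow = 1000, calf = 100))
  expect_identical(out4$n_costed, 3L)
  expect_equal(out4$cost, 100 + 100 + 1000)
  expect_error(mortality_cost(0, c(cow = 1), c(cow = 1)),
               class = "acarecon_input_error")
})

test_that("economic summaries satisfy the ledger identities per farm", {
  farms <- generate_cohort(synth_config(seed = 21))$farms
  es <- economic_summary(farms)
  expect_equal(es$tc_a, es$vc_a + es$fc)
  expect_equal(es$tc_b, es$vc_b + es$fc)
  expect_equal(es$p_a, es$tr - es$tc_a)
  expect_true(all(es$tcm <= es$tc_a + 1e-9))
  expect_equal(es$cpm, es$tcm / es$amp)
})

test_that("the professional-insemination flag moves E8 without double count", {
  f <- make_farm(e8 = 120, e5_real = 50, insemination_by_professional = TRUE)
  g <- make_farm(e8 = 120, e5_real = 50, insemination_by_professional = FALSE)
  # totals are unchanged, only the component attribution moves
  expect_equal(economic_summary(f)$tc_a, economic_summary(g)$tc_a)
  mf <- acaricide_cost_metrics(f)
  mg <- acaricide_cost_metrics(g)
  expect_gt(mf$sanitary_cost, mg$sanitary_cost)
  expect_equal(mf$sanitary_cost - mg$sanitary_cost, 120)
})

test_that("acaricide cost metrics match their definitions", {
  f <- make_farm(acaricide_drug_cost = 100, treatment_labor_cost = 30,
                 hemo_repellent_drug_cost = 22.9, e6 = 1000,
                 herd_size_adults = 100L)
  es <- economic_summary(f)
  m <- acaricide_cost_metrics(f, es)
  expect_equal(m$model1_pct_of_tc, 100 * 130 / es$tc_a)
  expect_equal(m$model2_usd_per_adult, 1.30)
  expect_equal(m$model3_pct_of_e6, 12.29)
  expect_equal(m$model4_pct_of_sanitary, 100 * 130 / (1000 + 50 + 30))
  # a zero denominator flags that metric, leaves the rest computed
  z <- make_farm(e6 = 0, acaricide_drug_cost = 0, hemo_repellent_drug_cost = 0)
  mz <- acaricide_cost_metrics(z)
  expect_true(is.na(mz$model3_pct_of_e6))
  expect_false(is.na(mz$model1_pct_of_tc))
  # worked scale: 846 USD over 100 adults is 8.46 per animal
  t <- make_farm(acaricide_drug_cost = 700, treatment_labor_cost = 146,
                 herd_size_adults = 100L)
  expect_equal(acaricide_cost_metrics(t)$model2_usd_per_adult, 8.46)
})
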