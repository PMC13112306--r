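test_that("loaded wage applies oncosts and leave loading on leave weeks", {
  expect_equal(loaded_wage(100000, 0.14, 0.175, 4),
               100000 * 1.14 * (1 + 0.175 * 4 / 52))
  expect_equal(round(loaded_wage(100000), 2), 115534.62)
  expect_equal(loaded_wage(100000, 0, 0, 4), 100000)
  expect_equal(loaded_wage(0), 0)
})

test_that("government revenue loss follows the unhealthy share", {
  co <- default_cost_inputs()
  co$pta_food_ad_revenue <- 1e6
  co$unhealthy_share_pta <- 0.55
  co$main_roads_revenue_loss <- 0       # isolate the PTA component
  g <- government_cost_stream(co, horizon = 30)
  rev <- g[g$category == "govt_revenue_loss", ]
  expect_equal(unique(rev$amount), 550000)
  expect_equal(rev$year, 1:30)
  ## zero unhealthy share -> no revenue-loss entries at all
  co$unhealthy_share_pta <- 0
  g0 <- government_cost_stream(co, horizon = 30)
  expect_false("govt_revenue_loss" %in% g0$category)
})

test_that("the Main Roads component is imputed from the billboard share", {
  co <- default_cost_inputs()
  co$pta_food_ad_revenue <- 1e6
  co$unhealthy_share_pta <- 0.55
  co$main_roads_revenue_loss <- NA_real_
  g <- government_cost_stream(co, horizon = 5)
  rev <- g[g$category == "govt_revenue_loss", ]
  expect_equal(unique(rev$amount), 550000 * (1 + 0.58 / (1 - 0.58)))
})

test_that("legislation cost enters year zero only when enabled", {
  co <- default_cost_inputs()
  g <- government_cost_stream(co, horizon = 10, legislation = TRUE)
  leg <- g[g$category == "legislation", ]
  expect_equal(leg$year, 0)
  expect_equal(leg$amount, 1306180)
  g2 <- government_cost_stream(co, horizon = 10, legislation = FALSE)
  expect_false("legislation" %in% g2$category)
})

test_that("monitoring is the larger of half national cost and one officer", {
  co <- default_cost_inputs()
  co$national_monitoring_cost <- 1e6     # half = 500k > officer wage
  g <- government_cost_stream(co, horizon = 3)
  expect_equal(unique(g$amount[g$category == "monitoring"]), 5e5)
  co$national_monitoring_cost <- 0       # officer wage floor binds
  g2 <- government_cost_stream(co, horizon = 3)
  expect_equal(unique(g2$amount[g2$category == "monitoring"]),
               loaded_wage(co$compliance_officer_wage, 0.14, 0.175, 4))
})

test_that("industry profit loss is revenue x concentration x share x margin", {
  co <- default_cost_inputs()
  co$apn_national_transport_revenue <- 1e8
  expect_equal(industry_profit_loss(co), 1e8 * 0.07 * 0.21 * 0.13)
  expect_equal(industry_profit_loss(co), 191100)
  co$profit_margin <- 0
  expect_equal(nrow(industry_cost_stream(co, horizon = 10)), 0)
  expect_equal(nrow(industry_cost_stream(default_cost_inputs(), horizon = 10,
                                         profit_loss = FALSE)), 0)
})

test_that("benefit monetisation and NPV/BCR arithmetic", {
  ben <- monetise_benefits(1000, 314772, 0)
  expect_equal(ben$monetised_halys, 314772000)
  expect_equal(monetise_benefits(0, 213000, 0)$total_benefits, 0)
  nb <- compute_npv_bcr(0, 28e6)
  expect_equal(nb$npv, -28e6)
  expect_equal(nb$bcr, 0)
  nb0 <- compute_npv_bcr(10, 0)
  expect_false(nb0$bcr_defined)
  expect_equal(nb0$npv, 10)
  expect_identical(nb0$bcr, Inf)
})

test_that("payer shares are discounted fractions that sum to one", {
  ledger <- data.frame(payer = c("government", "industry"),
                       category = c("monitoring", "industry_profit_loss"),
                       year = c(1, 1), amount = c(20e6, 8e6))
  class(ledger) <- c("cost_ledger", "data.frame")
  sh <- payer_shares(ledger)
  expect_equal(sum(sh), 1)
  expect_equal(round(100 * sh[["government"]]), 71)
  govt_only <- ledger[1, ]
  expect_equal(unname(payer_shares(govt_only)), 1)
  equal <- ledger; equal$amount <- c(5, 5)
  expect_equal(unname(payer_shares(equal)), c(0.5, 0.5))
  expect_error(payer_shares(ledger[0, ]), "empty")
})

test_that("CBA identities hold exactly on a full pipeline run", {
  res <- run_cba(default_bundle, build_scenario("primary"))
  expect_identical(res$npv, res$total_benefits - res$total_costs)
  expect_identical(res$bcr, res$total_benefits / res$total_costs)
  expect_identical(res$total_benefits, res$monetised_halys + res$hc_savings)
  expect_equal(sum(res$payer_shares), 1)
  expect_equal(res$govt_costs + res$industry_costs, res$total_costs)
  expect_identical(res$dominant, res$hc_savings > res$total_costs)
})

test_that("raising the discount rate weakly lowers discounted benefits", {
  b <- default_bundle
  rates <- c(0.03, 0.07, 0.12)
  vals <- sapply(rates, function(r) {
    res <- run_cba(b, build_scenario("primary", discount_rate = r))
    res$total_benefits
  })
  expect_true(all(diff(vals) < 0))
})

test_that("cost ledger years stay within the horizon and amounts positive", {
  ledger <- build_cost_ledger(default_cost_inputs(), build_scenario("primary"))
  expect_true(all(ledger$amount > 0))
  expect_true(all(ledger$year >= 0 & ledger$year <= 30))
  expect_setequal(unique(ledger$payer), c("government", "industry"))
})
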