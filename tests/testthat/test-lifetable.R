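test_that("PIF closed forms hold", {
  expect_equal(compute_pif(30, 4, -1, 1, 21), 0)          # flat risk
  expect_equal(compute_pif(30, 4, 0, 1.2, 21), 0)         # no shift
  expect_equal(compute_pif(30, 0, -1, 1.2, 21), 1 - 1 / 1.2,
               tolerance = 1e-12)                         # point mass
  ## point mass below the TMREL is risk-free in both arms
  expect_equal(compute_pif(19, 0, -1, 1.3, 21), 0)
})

test_that("analytic and quadrature PIF routes agree to 1e-6", {
  grid <- expand.grid(mu = c(22, 27, 32), sd = c(2, 4.5),
                      delta = c(-1, -0.2), rr = c(1.03, 1.12, 1.25))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    expect_equal(
      compute_pif(g$mu, g$sd, g$delta, g$rr, 21, method = "analytic"),
      compute_pif(g$mu, g$sd, g$delta, g$rr, 21, method = "quadrature"),
      tolerance = 1e-6)
  }
})

test_that("PIF matches a large-sample simulation oracle", {
  pif <- compute_pif(27, 4.5, -0.5, 1.15, 21)
  expect_equal(pif, oracle_pif_sim(27, 4.5, -0.5, 1.15, 21), tolerance = 2e-3)
})

test_that("incidence adjustment scales by 1 - PIF", {
  expect_equal(adjust_incidence(0.01, 1 - 1 / 1.2), 0.01 / 1.2)
  expect_equal(adjust_incidence(0.01, 0), 0.01)
  expect_equal(adjust_incidence(0, 0.5), 0)
  expect_error(adjust_incidence(0.5, 1), "pif")
})

test_that("single-disease recursion matches closed forms", {
  ## no mortality, no remission: prevalence(t) = 1 - (1 - i)^t
  out <- run_disease_model(incidence = 0.03, horizon = 25)
  expect_equal(out$prevalence, 1 - (1 - 0.03)^(1:25), tolerance = 1e-12)
  ## zero incidence from zero prevalence stays at zero
  out0 <- run_disease_model(incidence = 0, prevalence0 = 0, horizon = 10)
  expect_true(all(out0$prevalence == 0))
  ## full remission: only the current year's cases remain prevalent
  outr <- run_disease_model(incidence = 0.04, remission = 1, horizon = 10)
  expect_true(all(outr$prevalence <= 0.04))
  p <- 0  # independent recursion
  for (t in 1:10) p <- (1 - p) * 0.04
  expect_equal(outr$prevalence[10], p, tolerance = 1e-12)
})

test_that("discounting follows the end-of-year convention", {
  expect_equal(discount_stream(rep(100, 3), 0.07),
               100 / 1.07 + 100 / 1.07^2 + 100 / 1.07^3)
  expect_equal(round(discount_stream(rep(100, 3), 0.07), 2), 262.43)
  expect_equal(discount_stream(c(5, 10, 2), 0), 17)
  expect_equal(discount_stream(107, 0.07), 100)
  expect_equal(discount_stream(c(50, 100), 0.07, years = c(0, 1)),
               50 + 100 / 1.07)
})

test_that("lifetable matches the brute-force oracle on small cases", {
  cases <- list(
    list(ns = 1, horizon = 3, dis = list(
      `type 2 diabetes` = list(incidence = 0.02, prevalence = 0.1,
                               case_fatality = 0.05, remission = 0.01,
                               disability_weight = 0.12,
                               rr_per_bmi_unit = 1.2, tmrel_bmi = 21,
                               unit_cost = 1500))),
    list(ns = 3, horizon = 5, dis = list(
      `ischaemic heart disease` = list(incidence = 0.015, prevalence = 0.08,
                                       case_fatality = 0.08, remission = 0,
                                       disability_weight = 0.15,
                                       rr_per_bmi_unit = 1.1, tmrel_bmi = 21,
                                       unit_cost = 4000),
      `colorectal cancer` = list(incidence = 0.004, prevalence = 0.01,
                                 case_fatality = 0.2, remission = 0.2,
                                 disability_weight = 0.2,
                                 rr_per_bmi_unit = 1.05, tmrel_bmi = 23,
                                 unit_cost = 20000)))
  )
  for (cs in cases) {
    b <- tiny_bundle(n_strata = cs$ns, acm_rate = rep(0.03, cs$ns),
                     diseases = cs$dis)
    delta <- rep(-0.4, cs$ns)
    lt <- run_lifetable(b, delta, horizon = cs$horizon)
    orc <- oracle_lifetable(b, lt$pif, cs$horizon)
    for (arm in c("baseline", "intervention")) {
      expect_equal(lt[[arm]]$alive, orc[[arm]]$alive, tolerance = 1e-9)
      expect_equal(lt[[arm]]$prevalence, orc[[arm]]$prevalence,
                   tolerance = 1e-9)
      expect_equal(lt[[arm]]$haly, orc[[arm]]$haly, tolerance = 1e-9)
      expect_equal(lt[[arm]]$hc_cost, orc[[arm]]$hc_cost, tolerance = 1e-9)
    }
  }
})

test_that("persons are conserved: alive + cumulative deaths = initial cohort", {
  b <- default_bundle
  body <- apply_effect_pathway(b)
  lt <- run_lifetable(b, body$delta_bmi, horizon = 30)
  for (arm in c("baseline", "intervention")) {
    tr <- lt[[arm]]
    cum_deaths <- t(apply(tr$disease_deaths + tr$oc_deaths, 1, cumsum))
    total <- tr$alive + cum_deaths
    expect_equal(total,
                 matrix(b$population$count, nrow(total), ncol(total)),
                 tolerance = 1e-9)
  }
})

test_that("zero BMI change gives bitwise-identical trajectories", {
  b <- default_bundle
  lt <- run_lifetable(b, rep(0, nrow(b$population)), horizon = 20)
  expect_identical(lt$baseline$alive, lt$intervention$alive)
  expect_identical(lt$baseline$prevalence, lt$intervention$prevalence)
  expect_identical(lt$outcome$halys_gained, 0)
  expect_identical(lt$outcome$hc_savings, 0)
})

test_that("a larger BMI reduction yields at least as much benefit", {
  b <- default_bundle
  n <- nrow(b$population)
  lt_small <- run_lifetable(b, rep(-0.1, n), horizon = 20)
  lt_big <- run_lifetable(b, rep(-0.5, n), horizon = 20)
  expect_gte(lt_big$outcome$halys_gained, lt_small$outcome$halys_gained)
  expect_gte(lt_big$outcome$hc_savings, lt_small$outcome$hc_savings)
  expect_gt(lt_small$outcome$halys_gained, 0)
})

test_that("HALYs weight person-years by prevalence and disability weight", {
  ## one stratum of 100 persons, no mortality, one disease held at
  ## prevalence 0.1 with disability weight 0.2 -> 98 HALYs per year
  b <- tiny_bundle(n_strata = 1, count = 100, acm_rate = 0,
                   diseases = list(
                     `stroke` = list(incidence = 0, prevalence = 0.1,
                                     case_fatality = 0, remission = 0,
                                     disability_weight = 0.2,
                                     rr_per_bmi_unit = 1.1, tmrel_bmi = 21,
                                     unit_cost = 500)))
  lt <- run_lifetable(b, 0, horizon = 3)
  expect_equal(as.vector(lt$baseline$haly), rep(98, 3))
  expect_equal(as.vector(lt$baseline$hc_cost), rep(100 * 0.1 * 500, 3))
  expect_true(all(lt$baseline$haly <= lt$baseline$person_years))
})

test_that("disease mortality exceeding all-cause mortality is an error", {
  b <- tiny_bundle(acm_rate = c(0.001, 0.001),
                   diseases = list(
                     `stroke` = list(incidence = 0.01, prevalence = 0.3,
                                     case_fatality = 0.5, remission = 0,
                                     disability_weight = 0.2,
                                     rr_per_bmi_unit = 1.1, tmrel_bmi = 21,
                                     unit_cost = 500)))
  expect_error(run_lifetable(b, rep(0, 2), horizon = 5),
               "exceeds all-cause")
})
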