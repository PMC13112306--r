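# Societal cost-benefit accounting: government and industry cost streams,
# benefit monetisation, net present value and benefit-cost ratio.

#' Fully loaded annual wage
#'
#' Base salary inclusive of salary oncosts and annual leave loading, the
#' latter applied to the annual-leave weeks only.
#'
#' @param base_wage A$/year.
#' @param oncost_rate Salary oncost fraction (default 14 %).
#' @param leave_loading_rate Leave loading fraction (default 17.5 %).
#' @param leave_weeks Weeks of annual leave the loading applies to.
#' @return Loaded wage, A$/year.
#' @examples
#' loaded_wage(100000)   # 115535.38
#' @export
loaded_wage <- function(base_wage, oncost_rate = 0.14,
                        leave_loading_rate = 0.175, leave_weeks = 4) {
  assert_fraction(oncost_rate, "oncost_rate")
  assert_fraction(leave_loading_rate, "leave_loading_rate")
  base_wage * (1 + oncost_rate) * (1 + leave_loading_rate * leave_weeks / 52)
}

#' Annual industry profit loss
#'
#' National transport-advertising revenue of the outdoor advertiser scaled
#' by the jurisdiction's advertising concentration, the unhealthy share of
#' advertisements, and the profit margin.
#'
#' @param costs A `cost_inputs` list.
#' @return A$/year of profit foregone.
#' @export
industry_profit_loss <- function(costs) {
  costs$apn_national_transport_revenue * costs$wa_concentration *
    costs$unhealthy_ad_share * costs$profit_margin
}

annual_monitoring_cost <- function(costs) {
  max(costs$national_monitoring_cost / 2,
      loaded_wage(costs$compliance_officer_wage, costs$oncost_rate,
                  costs$leave_loading_rate, costs$leave_weeks %||% 4))
}

annual_govt_revenue_loss <- function(costs) {
  pta_loss <- costs$pta_food_ad_revenue * costs$unhealthy_share_pta
  main_roads <- costs$main_roads_revenue_loss
  if (is.null(main_roads) || is.na(main_roads)) {
    ## impute the billboard (Main Roads) component from the billboard share
    ## of out-of-home advertising
    main_roads <- pta_loss * costs$billboard_share / (1 - costs$billboard_share)
  }
  pta_loss + main_roads
}

replacement_factor <- function(years, replacement_fraction,
                               replacement_start_year) {
  ifelse(years >= replacement_start_year, 1 - replacement_fraction, 1)
}

#' Government cost stream
#'
#' Policy development (FTE-years at loaded wages) falls in year
#' `phase_in_year`; monitoring (the larger of half the national monitoring
#' cost and one loaded compliance-officer wage) and advertising revenue
#' loss (PTA component at the unhealthy share, plus a Main Roads component
#' imputed from the billboard share) recur annually thereafter.
#' Legislation cost is added in year `phase_in_year` when enabled.
#'
#' @param costs A `cost_inputs` list.
#' @param horizon Last year of the analysis.
#' @param legislation Include the legislation cost.
#' @param revenue_loss Include government advertising revenue loss.
#' @param replacement_fraction Fraction of the revenue loss recovered by
#'   replacement advertising from `replacement_start_year` onwards.
#' @param replacement_start_year Year replacement begins.
#' @param phase_in_year Delay (years) before the policy starts; 0 = start
#'   immediately (development in year 0, recurring items years 1..horizon).
#' @return Ledger data frame: `payer`, `category`, `year`, `amount`.
#' @export
government_cost_stream <- function(costs, horizon = 30, legislation = FALSE,
                                   revenue_loss = TRUE,
                                   replacement_fraction = 0,
                                   replacement_start_year = 2,
                                   phase_in_year = 0) {
  entries <- list()
  dev <- sum(costs$policy_dev_fte_years *
               loaded_wage(costs$base_wage, costs$oncost_rate,
                           costs$leave_loading_rate, costs$leave_weeks %||% 4))
  entries[[1]] <- data.frame(payer = "government", category = "policy_development",
                             year = phase_in_year, amount = dev)
  if (legislation) {
    entries[[length(entries) + 1]] <-
      data.frame(payer = "government", category = "legislation",
                 year = phase_in_year, amount = costs$legislation_cost)
  }
  years <- seq(phase_in_year + 1, horizon)
  entries[[length(entries) + 1]] <-
    data.frame(payer = "government", category = "monitoring", year = years,
               amount = annual_monitoring_cost(costs))
  if (revenue_loss) {
    rf <- replacement_factor(years - phase_in_year, replacement_fraction,
                             replacement_start_year)
    entries[[length(entries) + 1]] <-
      data.frame(payer = "government", category = "govt_revenue_loss",
                 year = years, amount = annual_govt_revenue_loss(costs) * rf)
  }
  out <- do.call(rbind, entries)
  out[out$amount > 0, , drop = FALSE]
}

#' Industry cost stream
#'
#' Annual profit loss to the outdoor advertiser (see
#' [industry_profit_loss()]), years `phase_in_year + 1` to `horizon`,
#' optionally offset by replacement advertising.
#'
#' @inheritParams government_cost_stream
#' @param profit_loss Include the profit loss (FALSE models no revenue
#'   impact on industry).
#' @return Ledger data frame: `payer`, `category`, `year`, `amount`.
#' @export
industry_cost_stream <- function(costs, horizon = 30, profit_loss = TRUE,
                                 replacement_fraction = 0,
                                 replacement_start_year = 2,
                                 phase_in_year = 0) {
  if (!profit_loss) {
    return(data.frame(payer = character(), category = character(),
                      year = integer(), amount = numeric()))
  }
  years <- seq(phase_in_year + 1, horizon)
  rf <- replacement_factor(years - phase_in_year, replacement_fraction,
                           replacement_start_year)
  out <- data.frame(payer = "industry", category = "industry_profit_loss",
                    year = years, amount = industry_profit_loss(costs) * rf)
  out[out$amount > 0, , drop = FALSE]
}

#' Build the full cost ledger for a scenario
#'
#' @param costs A `cost_inputs` list.
#' @param scenario A scenario configuration ([build_scenario()]).
#' @return Combined government + industry ledger (class `cost_ledger`).
#' @export
build_cost_ledger <- function(costs, scenario = build_scenario("primary")) {
  g <- government_cost_stream(
    costs, horizon = scenario$horizon_years,
    legislation = scenario$legislation,
    revenue_loss = scenario$govt_revenue_loss,
    replacement_fraction = scenario$replacement_fraction,
    replacement_start_year = scenario$replacement_start_year,
    phase_in_year = scenario$phase_in_year
  )
  i <- industry_cost_stream(
    costs, horizon = scenario$horizon_years,
    profit_loss = scenario$industry_profit_loss,
    replacement_fraction = scenario$replacement_fraction,
    replacement_start_year = scenario$replacement_start_year,
    phase_in_year = scenario$phase_in_year
  )
  out <- rbind(g, i)
  rownames(out) <- NULL
  class(out) <- c("cost_ledger", "data.frame")
  out
}

#' Discounted cost totals by payer
#'
#' @param ledger A `cost_ledger`.
#' @param rate Discount rate.
#' @return List with `total`, `by_payer` (named vector) and `by_category`.
#' @export
discount_ledger <- function(ledger, rate) {
  disc <- ledger$amount / (1 + rate)^ledger$year
  list(total = sum(disc),
       by_payer = c(tapply(disc, ledger$payer, sum)),
       by_category = c(tapply(disc, ledger$category, sum)))
}

#' Share of discounted costs borne by each payer
#'
#' @param ledger A `cost_ledger`.
#' @param rate Discount rate (0 gives undiscounted shares).
#' @return Named vector of fractions summing to 1.
#' @export
payer_shares <- function(ledger, rate = 0) {
  if (nrow(ledger) == 0) stopf("empty cost ledger")
  d <- discount_ledger(ledger, rate)
  if (d$total <= 0) stopf("total cost is zero; payer shares undefined")
  share <- d$by_payer / d$total
  share[order(names(share))]
}

#' Monetise health benefits
#'
#' HALYs gained are valued at the value of a statistical life year and
#' added to healthcare cost savings.
#'
#' @param halys_gained Discounted HALYs gained.
#' @param vsly Value of a statistical life year, A$ (> 0).
#' @param hc_savings Discounted healthcare cost savings, A$.
#' @return List with `monetised_halys` and `total_benefits`.
#' @export
monetise_benefits <- function(halys_gained, vsly, hc_savings) {
  if (vsly <= 0) stopf("'vsly' must be positive")
  monetised <- halys_gained * vsly
  list(monetised_halys = monetised, total_benefits = monetised + hc_savings)
}

#' Net present value and benefit-cost ratio
#'
#' @param total_benefits,total_costs Discounted totals, A$.
#' @return List with `npv`, `bcr` (`Inf` flagged when costs are zero) and
#'   `bcr_defined`.
#' @examples
#' compute_npv_bcr(1374e6, 28e6)
#' @export
compute_npv_bcr <- function(total_benefits, total_costs) {
  npv <- total_benefits - total_costs
  if (total_costs > 0) {
    list(npv = npv, bcr = total_benefits / total_costs, bcr_defined = TRUE)
  } else {
    list(npv = npv, bcr = Inf, bcr_defined = FALSE)
  }
}
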