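# Declarative scenario configurations: the primary analysis plus the ten
# sensitivity scenarios, and the multi-scenario comparison report.

#' Valid scenario identifiers
#' @return Character vector: `"primary"`, `"s1"` ... `"s10"`.
#' @export
scenario_ids <- function() c("primary", paste0("s", 1:10))

scenario_descriptions <- c(
  primary = "Primary analysis: 30-year horizon, 7% discount rate, 20% effectiveness adjustment, VSLY A$213,000",
  s1 = "Alternative time horizon of 10 years (assumed value)",
  s2 = "Very short time horizon of 4 years",
  s3 = "Further 18% effectiveness reduction for absent bus-shelter coverage",
  s4 = "Comparator-policy effectiveness applied with no adjustments",
  s5 = "Effect applied only to food categories with statistically significant changes",
  s6 = "Contemporary VSLY estimate of A$314,772",
  s7 = "Including the cost of legislation (A$1,306,180)",
  s8 = "No change in advertising revenue for government or industry",
  s9 = "Advertising replaced by products not subject to the restrictions",
  s10 = "Policy phased in after 10 years, at the end of the current advertising contract"
)

#' Build a scenario configuration
#'
#' Returns the primary-analysis configuration with only the deltas the
#' given scenario prescribes: s1/s2 change the horizon (10 and 4 years);
#' s3 adds the 18 % bus-shelter coverage adjustment; s4 removes all
#' effectiveness adjustments; s5 applies the effect only to the
#' significant food categories (chocolate and confectionery; puddings and
#' biscuits); s6 uses the contemporary VSLY (A$314,772); s7 adds the
#' legislation cost; s8 removes both government revenue loss and industry
#' profit loss; s9 assumes full advertising replacement from year 2; s10
#' phases the intervention in after 10 years.
#'
#' @param id One of [scenario_ids()].
#' @param ... Field overrides applied after the scenario deltas.
#' @return A `scenario` list.
#' @examples
#' build_scenario("s2")$horizon_years   # 4
#' @export
build_scenario <- function(id = "primary", ...) {
  if (!id %in% scenario_ids()) {
    stopf("unknown scenario '%s'; valid ids: %s", id,
          paste(scenario_ids(), collapse = ", "))
  }
  sc <- list(
    id = id,
    description = unname(scenario_descriptions[id]),
    horizon_years = 30,
    discount_rate = 0.07,
    adjustments = c(exposure = 0.20),
    significant_categories_only = FALSE,
    significant_categories = c("chocolate and confectionery",
                               "puddings and biscuits"),
    vsly = 213000,
    legislation = FALSE,
    govt_revenue_loss = TRUE,
    industry_profit_loss = TRUE,
    replacement_fraction = 0,
    replacement_start_year = 2,
    phase_in_year = 0
  )
  switch(id,
    primary = NULL,
    s1 = { sc$horizon_years <- 10 },
    s2 = { sc$horizon_years <- 4 },
    s3 = { sc$adjustments <- c(exposure = 0.20, coverage = 0.18) },
    s4 = { sc$adjustments <- numeric(0) },
    s5 = { sc$significant_categories_only <- TRUE },
    s6 = { sc$vsly <- 314772 },
    s7 = { sc$legislation <- TRUE },
    s8 = { sc$govt_revenue_loss <- FALSE; sc$industry_profit_loss <- FALSE },
    s9 = { sc$replacement_fraction <- 1 },
    s10 = { sc$phase_in_year <- 10 }
  )
  dots <- list(...)
  for (nm in names(dots)) sc[[nm]] <- dots[[nm]]
  structure(sc, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario %s> %s\n", x$id, x$description))
  cat(sprintf("  horizon %d y, discount %.0f%%, adjustments [%s], VSLY A$%s\n",
              x$horizon_years, 100 * x$discount_rate,
              paste(x$adjustments, collapse = ", "),
              format(x$vsly, big.mark = ",")))
  invisible(x)
}

#' Run one scenario, optionally with Monte Carlo uncertainty
#'
#' @param bundle A `mslt_bundle`.
#' @param scenario A scenario id or a `scenario` object.
#' @param n_draws Monte Carlo iterations; 0 gives the deterministic point
#'   estimate only.
#' @param seed Master seed for the Monte Carlo draws.
#' @param specs Uncertainty specifications; defaults to
#'   [default_uncertainty_specs()].
#' @return List with `scenario`, `point` (a `cba_result`) and `ui`
#'   (summary data frame, or NULL when `n_draws = 0`).
#' @export
run_scenario <- function(bundle, scenario = "primary", n_draws = 0, seed = 1,
                         specs = default_uncertainty_specs(bundle)) {
  if (is.character(scenario)) scenario <- build_scenario(scenario)
  point <- run_cba(bundle, scenario)
  ui <- NULL
  draws <- NULL
  if (n_draws > 0) {
    pipeline <- function(params) cba_metrics(run_cba(bundle, scenario, params))
    draws <- run_monte_carlo(pipeline, specs, n_draws = n_draws, seed = seed)
    ui <- summarise_draws(draws)
  }
  list(scenario = scenario, point = point, ui = ui, draws = draws)
}

#' Run several scenarios and rank them by benefit-cost ratio
#'
#' All scenarios share the same bundle, uncertainty specifications and
#' master seed, so parameter draws are common across scenarios.
#'
#' @param bundle A `mslt_bundle`.
#' @param ids Scenario ids to run (default: primary and s1..s10).
#' @param n_draws Monte Carlo iterations per scenario (0 = deterministic).
#' @param seed Master seed.
#' @return A `scenario_report`: list of per-scenario results plus a
#'   `summary` data frame ordered by scenario id with a BCR ranking.
#' @export
run_all_scenarios <- function(bundle, ids = scenario_ids(), n_draws = 0,
                              seed = 1) {
  if (!"primary" %in% ids) ids <- c("primary", ids)
  runs <- lapply(ids, function(id) run_scenario(bundle, id, n_draws, seed))
  names(runs) <- ids
  summary <- do.call(rbind, lapply(runs, function(r) {
    p <- r$point
    data.frame(
      scenario = r$scenario$id, description = r$scenario$description,
      weight_change_kg = p$mean_weight_change,
      halys_gained = p$halys_gained, hc_savings = p$hc_savings,
      total_costs = p$total_costs, total_benefits = p$total_benefits,
      npv = p$npv, bcr = p$bcr, stringsAsFactors = FALSE
    )
  }))
  rownames(summary) <- NULL
  summary$bcr_rank <- rank(-summary$bcr, ties.method = "min")
  structure(list(runs = runs, summary = summary), class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report>\n")
  df <- x$summary
  df$npv <- sprintf("%.1fM", df$npv / 1e6)
  df$bcr <- sprintf("%.1f", df$bcr)
  print(df[, c("scenario", "weight_change_kg", "halys_gained", "npv",
               "bcr", "bcr_rank")], digits = 3)
  invisible(x)
}

#' Markdown comparison table for a scenario report
#'
#' Columns mirror the standard reporting layout: weight change, HALYs,
#' costs, healthcare savings, benefits, NPV and BCR (with 95 % UIs when
#' the report carries Monte Carlo draws).
#'
#' @param report A `scenario_report`.
#' @return Character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  fmt_ui <- function(run, metric, scale = 1, digits = 2) {
    p <- run$point[[metric]] / scale
    if (is.null(run$ui)) return(sprintf("%.*f", digits, p))
    row <- run$ui[run$ui$metric == metric, ]
    sprintf("%.*f (%.*f, %.*f)", digits, p, digits, row$lo / scale,
            digits, row$hi / scale)
  }
  lines <- c(
    "| Scenario | Weight change (kg) | HALYs gained | Costs (A$M) | HC savings (A$M) | Benefits (A$M) | NPV (A$M) | BCR |",
    "|---|---|---|---|---|---|---|---|"
  )
  for (run in report$runs) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s | %s | %s | %s |",
      run$scenario$id,
      fmt_ui(run, "mean_weight_change", 1, 3),
      fmt_ui(run, "halys_gained", 1, 0),
      fmt_ui(run, "total_costs", 1e6, 1),
      fmt_ui(run, "hc_savings", 1e6, 1),
      fmt_ui(run, "total_benefits", 1e6, 1),
      fmt_ui(run, "npv", 1e6, 1),
      fmt_ui(run, "bcr", 1, 1)
    ))
  }
  lines
}
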