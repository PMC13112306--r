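# Synthetic Perth-like model inputs with known ground truth.
#
# The generator emulates the stratified tables an applied analysis would
# extract from national health surveys, administrative epidemiology and
# parliamentary records: a closed age/sex-stratified population, per-disease
# epidemiological rates for nine obesity-related diseases (osteoarthritis
# split into hip and knee), unhealthy food consumption by category, and the
# cost/revenue parameters of the policy.  Everything is deterministic under
# a seed, and the ground-truth parameters travel with the bundle so that
# downstream modules can be tested for parameter recovery.

#' Age bands used throughout the model
#'
#' Five-year bands from age 2 to 100; the first band (2--4) is three years
#' wide.  Cohorts are labelled by the band midpoint.
#'
#' @return A data frame with `age_start`, `age_width` and `age_mid`.
#' @export
age_bands <- function() {
  age_start <- c(2L, seq(5L, 95L, by = 5L))
  age_width <- c(3L, rep(5L, 19L))
  data.frame(
    age_start = age_start,
    age_width = age_width,
    age_mid   = age_start + age_width / 2
  )
}

#' Names of the modelled obesity-related diseases
#'
#' Nine diseases enter the model; osteoarthritis is modelled separately for
#' hip and knee, giving ten disease states (a merged single osteoarthritis
#' state is available via `merge_osteoarthritis`).
#'
#' @param merge_osteoarthritis Merge hip and knee osteoarthritis into one
#'   state.
#' @return Character vector of disease names.
#' @export
model_disease_names <- function(merge_osteoarthritis = FALSE) {
  base <- c(
    "type 2 diabetes", "hypertensive heart disease", "ischaemic heart disease",
    "stroke", "osteoarthritis hip", "osteoarthritis knee",
    "kidney cancer", "colorectal cancer", "endometrial cancer", "breast cancer"
  )
  if (merge_osteoarthritis) {
    base <- c(setdiff(base, c("osteoarthritis hip", "osteoarthritis knee")),
              "osteoarthritis")
  }
  base
}

# Per-disease generator parameters.  Incidence follows an exponential age
# gradient anchored at age 60; case fatality is a fixed share of the
# stratum's all-cause mortality so that the other-cause remainder in the
# lifetable stays positive by construction.  Relative risks are log-linear
# per BMI unit above a TMREL of 21 kg/m^2.
disease_param_table <- function(cancer_remission = 0.2,
                                noncancer_remission = 0,
                                merge_osteoarthritis = FALSE) {
  tab <- data.frame(
    name = model_disease_names(FALSE),
    inc60 = c(0.0080, 0.0020, 0.0050, 0.0030, 0.0040, 0.0045,
              0.00030, 0.00090, 0.00035, 0.00150),
    inc_slope = c(0.030, 0.060, 0.070, 0.080, 0.040, 0.040,
                  0.060, 0.060, 0.050, 0.030),
    cf_acm_share = c(0.15, 0.20, 0.50, 0.50, 0.00, 0.00,
                     1.50, 1.50, 1.00, 1.20),
    disability_weight = c(0.07, 0.10, 0.12, 0.22, 0.08, 0.08,
                          0.15, 0.20, 0.20, 0.15),
    rr_per_bmi_unit = c(1.18, 1.12, 1.08, 1.06, 1.05, 1.07,
                        1.06, 1.03, 1.12, 1.05),
    tmrel_bmi = rep(21, 10),
    unit_cost = c(3500, 2800, 6000, 9000, 2500, 2500,
                  18000, 22000, 20000, 16000),
    sex_restrict = c(NA, NA, NA, NA, NA, NA, NA, NA, "F", "F"),
    stringsAsFactors = FALSE
  )
  tab$remission <- ifelse(grepl("cancer", tab$name),
                          cancer_remission, noncancer_remission)
  if (merge_osteoarthritis) {
    oa <- tab$name %in% c("osteoarthritis hip", "osteoarthritis knee")
    merged <- tab[which(oa)[1], ]
    merged$name <- "osteoarthritis"
    merged$inc60 <- sum(tab$inc60[oa])
    tab <- rbind(tab[!oa, ], merged)
    rownames(tab) <- NULL
  }
  tab
}

#' Default generator configuration
#'
#' Settings that define the modelled study conditions: a closed Greater
#' Perth-scale population (about 2.1 million, aged 2+), the advertising
#' restriction effect size from the Transport for London evaluation
#' (-6.7 %, 95 % CI -10.1 to -3.2, on unhealthy food energy purchased) with
#' a 20 % exposure-difference effectiveness adjustment, energy-to-weight
#' conversion constants, and policy cost/revenue parameters.
#'
#' @param population_size Total persons across all strata.
#' @param merge_osteoarthritis Model osteoarthritis as a single state.
#' @param cancer_remission Annual remission probability for cancers
#'   (5-year "cured" convention, 0.2/year).
#' @param noncancer_remission Annual remission probability for the
#'   non-cancer diseases (default 0).
#' @param relative_change,ci_low,ci_high Intervention effect on unhealthy
#'   food energy purchased (fractions; negative = reduction).
#' @param adjustments Named vector of multiplicative effectiveness
#'   reductions, each in \[0,1\].
#' @param epsilon_adult,epsilon_child Steady-state energy-balance constants
#'   (kJ/day of intake change per kg of weight change).
#' @param adult_age Age (years) from which the adult epsilon applies.
#' @param horizon_years,discount_rate Primary-analysis horizon and real
#'   social discount rate.
#' @return A named list; pass to [generate_inputs()].
#' @export
default_config <- function(population_size = 2.1e6,
                           merge_osteoarthritis = FALSE,
                           cancer_remission = 0.2,
                           noncancer_remission = 0,
                           relative_change = -0.067,
                           ci_low = -0.101,
                           ci_high = -0.032,
                           adjustments = c(exposure = 0.20),
                           epsilon_adult = 94,
                           epsilon_child = 420,
                           adult_age = 18,
                           horizon_years = 30,
                           discount_rate = 0.07) {
  list(
    population_size = population_size,
    merge_osteoarthritis = merge_osteoarthritis,
    cancer_remission = cancer_remission,
    noncancer_remission = noncancer_remission,
    effect = list(
      relative_change = relative_change,
      ci_low = ci_low,
      ci_high = ci_high,
      adjustments = as.list(adjustments)
    ),
    epsilon_adult = epsilon_adult,
    epsilon_child = epsilon_child,
    adult_age = adult_age,
    horizon_years = horizon_years,
    discount_rate = discount_rate
  )
}

#' Default policy cost and revenue inputs
#'
#' Wage, monitoring, revenue and profit parameters of the costing model.
#' Shares and rates (salary oncosts 14 %, annual leave loading 17.5 %,
#' unhealthy share of PTA food advertising 55 %, billboard share of
#' out-of-home advertising 58 %, WA advertising concentration 7 %,
#' unhealthy share of all advertising 21 %, outdoor-advertiser profit
#' margin 13 %, legislation cost A$1,306,180, VSLY A$213,000) are the
#' published parameter values; absolute revenue and wage magnitudes are
#' synthetic but set at realistic Australian scales.
#'
#' @return A named list of cost inputs (class `cost_inputs`).
#' @export
default_cost_inputs <- function() {
  structure(list(
    policy_dev_fte_years = c(principal = 0.5, senior_policy_officer = 2,
                             policy_officer = 2),
    base_wage = c(principal = 165000, senior_policy_officer = 125000,
                  policy_officer = 98000),
    compliance_officer_wage = 95000,
    oncost_rate = 0.14,
    leave_loading_rate = 0.175,
    leave_weeks = 4,
    national_monitoring_cost = 250000,
    pta_food_ad_revenue = 9e5,
    unhealthy_share_pta = 0.55,
    billboard_share = 0.58,
    main_roads_revenue_loss = NA_real_,  # NA = impute from billboard share
    apn_national_transport_revenue = 3e8,
    wa_concentration = 0.07,
    unhealthy_ad_share = 0.21,
    profit_margin = 0.13,
    legislation_cost = 1306180,
    vsly = 213000
  ), class = "cost_inputs")
}

validate_config <- function(config) {
  if (!is.list(config)) stopf("config must be a list")
  if (!is.numeric(config$population_size) || config$population_size <= 0) {
    stopf("invalid config: 'population_size' must be a positive number")
  }
  assert_fraction(config$cancer_remission, "cancer_remission")
  assert_fraction(config$noncancer_remission, "noncancer_remission")
  eff <- config$effect
  if (!(eff$ci_low <= eff$relative_change && eff$relative_change <= eff$ci_high)) {
    stopf("invalid config: effect CI must bracket 'relative_change'")
  }
  for (a in unlist(eff$adjustments)) assert_fraction(a, "effect adjustment")
  if (config$epsilon_adult <= 0 || config$epsilon_child <= 0) {
    stopf("invalid config: 'epsilon_adult'/'epsilon_child' must be positive")
  }
  invisible(config)
}

#' Generate a synthetic input bundle
#'
#' Builds an internally consistent set of model inputs: a closed population
#' stratified by 5-year age band and sex with all-cause mortality, height
#' and BMI distribution parameters; per-stratum epidemiology for the ten
#' modelled disease states; unhealthy food consumption by category; and the
#' policy cost inputs.  Identical `config` and `seed` give bit-identical
#' tables.
#'
#' @param config Generator settings, see [default_config()].
#' @param seed Integer seed (required).
#' @param cost_inputs Policy cost inputs, see [default_cost_inputs()].
#' @return A `mslt_bundle`: list with elements `population`, `diseases`
#'   (named list of per-disease data frames), `consumption`, `costs`,
#'   `effect`, `config`, `seed`.
#' @examples
#' b <- generate_inputs(seed = 1)
#' head(b$population)
#' @export
generate_inputs <- function(config = default_config(), seed,
                            cost_inputs = default_cost_inputs()) {
  if (missing(seed)) stopf("'seed' is required")
  validate_config(config)
  set.seed(as.integer(seed))
  bands <- age_bands()
  n_band <- nrow(bands)
  strata <- data.frame(
    age_start = rep(bands$age_start, 2L),
    age_width = rep(bands$age_width, 2L),
    age_mid   = rep(bands$age_mid, 2L),
    sex       = rep(c("F", "M"), each = n_band),
    stringsAsFactors = FALSE
  )
  m <- strata$age_mid
  male <- strata$sex == "M"

  ## population counts: broad urban age pyramid, small multiplicative noise
  w <- ifelse(m < 20, 1.20, ifelse(m < 45, 1.30, ifelse(m < 65, 1.00,
       ifelse(m < 80, 0.60, 0.25)))) * strata$age_width
  w <- w * runif(length(w), 0.95, 1.05)
  count <- round(config$population_size * w / sum(w))

  ## all-cause mortality: Gompertz-type with a childhood floor; males higher
  acm <- pmin(0.6, 2.0e-5 * exp(0.095 * m)) + 2.5e-4
  acm <- acm * ifelse(male, 1.2, 1.0)

  ## mean height: linear growth to adult height by ~18, then flat
  adult_h <- ifelse(male, 1.78, 1.64)
  height <- 0.85 + (adult_h - 0.85) * pmin(1, (m - 2) / 16)

  ## BMI distribution: rises through childhood to an adult mean near 27
  bmi_mean <- 16.5 + 11.2 * pmin(1, (m - 2) / 28) + ifelse(male, 0.3, 0) +
    runif(length(m), -0.3, 0.3)
  bmi_sd <- 3 + 1.5 * pmin(1, (m - 2) / 28)

  population <- data.frame(
    age_start = strata$age_start, age_width = strata$age_width,
    age_mid = strata$age_mid, sex = strata$sex,
    count = as.numeric(count), acm_rate = acm,
    mean_height = height, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    stringsAsFactors = FALSE
  )

  ## diseases
  partab <- disease_param_table(config$cancer_remission,
                                config$noncancer_remission,
                                config$merge_osteoarthritis)
  diseases <- lapply(seq_len(nrow(partab)), function(k) {
    p <- partab[k, ]
    inc <- p$inc60 * exp(p$inc_slope * (m - 60))
    inc <- pmin(inc, 0.08)
    inc[m < 20] <- inc[m < 20] * 0.05          # childhood onset is rare
    if (!is.na(p$sex_restrict)) inc[strata$sex != p$sex_restrict] <- 0
    cf <- pmin(0.95, p$cf_acm_share * acm)
    rem <- rep(p$remission, length(m))
    ## start near (below) the steady state implied by the rates
    prev <- 0.8 * inc / pmax(inc + cf + rem, 1e-12)
    prev <- pmin(prev, 0.25)
    data.frame(
      disease = p$name,
      age_start = strata$age_start, sex = strata$sex,
      incidence = inc, prevalence = prev, case_fatality = cf,
      remission = rem,
      disability_weight = rep(p$disability_weight, length(m)),
      rr_per_bmi_unit = rep(p$rr_per_bmi_unit, length(m)),
      tmrel_bmi = rep(p$tmrel_bmi, length(m)),
      unit_cost = rep(p$unit_cost, length(m)),
      stringsAsFactors = FALSE
    )
  })
  names(diseases) <- partab$name

  ## unhealthy food consumption by category (kJ/person/day)
  cats <- c("chocolate and confectionery", "puddings and biscuits",
            "fast food", "sugary drinks", "salty snacks")
  shares <- c(0.18, 0.15, 0.32, 0.20, 0.15)
  total_kj <- (800 + 1600 * exp(-((m - 25) / 25)^2)) * ifelse(male, 1.1, 1)
  total_kj <- total_kj * runif(length(m), 0.95, 1.05)
  consumption <- do.call(rbind, lapply(seq_along(cats), function(j) {
    data.frame(
      age_start = strata$age_start, sex = strata$sex,
      category = cats[j], mean_kj_per_day = total_kj * shares[j],
      stringsAsFactors = FALSE
    )
  }))
  rownames(consumption) <- NULL

  bundle <- structure(list(
    population = population,
    diseases = diseases,
    consumption = consumption,
    costs = cost_inputs,
    effect = config$effect,
    config = config,
    seed = as.integer(seed)
  ), class = "mslt_bundle")
  validate_bundle(bundle)
  bundle
}

#' @export
print.mslt_bundle <- function(x, ...) {
  cat("<mslt_bundle>\n")
  cat(sprintf("  population : %d strata, %s persons\n",
              nrow(x$population), format(sum(x$population$count), big.mark = ",")))
  cat(sprintf("  diseases   : %d (%s, ...)\n", length(x$diseases),
              paste(head(names(x$diseases), 3), collapse = ", ")))
  cat(sprintf("  consumption: %d categories\n", length(unique(x$consumption$category))))
  cat(sprintf("  effect     : %.3f (adjustments: %s)\n",
              x$effect$relative_change,
              paste(unlist(x$effect$adjustments), collapse = ", ")))
  cat(sprintf("  seed       : %d\n", x$seed))
  invisible(x)
}

# ---- validation ------------------------------------------------------------

validate_population <- function(pop) {
  need <- c("age_start", "age_width", "age_mid", "sex", "count", "acm_rate",
            "mean_height", "bmi_mean", "bmi_sd")
  miss <- setdiff(need, names(pop))
  if (length(miss)) stopf("population table missing column(s): %s",
                          paste(miss, collapse = ", "))
  assert_nonneg(pop$count, "count")
  assert_fraction(pop$acm_rate, "acm_rate", allow_one = FALSE)
  if (any(pop$bmi_sd <= 0)) stopf("population 'bmi_sd' must be positive")
  if (any(pop$mean_height < 0.8 | pop$mean_height > 2.1)) {
    stopf("population 'mean_height' outside [0.8, 2.1] m")
  }
  ## mortality must not decline with age above 35, within sex
  for (s in unique(pop$sex)) {
    sub <- pop[pop$sex == s & pop$age_start >= 35, ]
    sub <- sub[order(sub$age_start), ]
    if (is.unsorted(sub$acm_rate)) {
      stopf("acm_rate decreases with age above 35 for sex %s", s)
    }
  }
  invisible(pop)
}

validate_disease <- function(d, name = d$disease[1]) {
  need <- c("disease", "age_start", "sex", "incidence", "prevalence",
            "case_fatality", "remission", "disability_weight",
            "rr_per_bmi_unit", "tmrel_bmi", "unit_cost")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("disease table '%s' missing column(s): %s", name,
                          paste(miss, collapse = ", "))
  for (col in c("incidence", "prevalence", "case_fatality", "remission")) {
    assert_fraction(d[[col]], paste0(name, ":", col))
  }
  if (any(d$case_fatality + d$remission > 1)) {
    stopf("disease '%s': case_fatality + remission exceeds 1", name)
  }
  if (any(d$disability_weight < 0 | d$disability_weight >= 1)) {
    stopf("disease '%s': disability_weight outside [0,1)", name)
  }
  if (any(d$rr_per_bmi_unit < 1)) {
    stopf("disease '%s': rr_per_bmi_unit must be >= 1", name)
  }
  assert_nonneg(d$unit_cost, paste0(name, ":unit_cost"))
  invisible(d)
}

validate_bundle <- function(bundle) {
  validate_population(bundle$population)
  allowed <- c(model_disease_names(FALSE), "osteoarthritis")
  for (nm in names(bundle$diseases)) {
    if (!nm %in% allowed) {
      stopf("unknown disease '%s'; allowed: %s", nm, paste(allowed, collapse = "; "))
    }
    validate_disease(bundle$diseases[[nm]], nm)
    key_pop <- paste(bundle$population$age_start, bundle$population$sex)
    key_d <- paste(bundle$diseases[[nm]]$age_start, bundle$diseases[[nm]]$sex)
    if (!identical(key_pop, key_d)) {
      stopf("disease '%s' strata do not align with the population table", nm)
    }
  }
  cons <- bundle$consumption
  assert_nonneg(cons$mean_kj_per_day, "mean_kj_per_day")
  if (anyDuplicated(cons[, c("age_start", "sex", "category")])) {
    stopf("consumption categories are duplicated within a stratum")
  }
  co <- bundle$costs
  for (f in c("oncost_rate", "leave_loading_rate", "unhealthy_share_pta",
              "billboard_share", "wa_concentration", "unhealthy_ad_share",
              "profit_margin")) {
    assert_fraction(co[[f]], f)
  }
  for (f in c("national_monitoring_cost", "pta_food_ad_revenue",
              "apn_national_transport_revenue", "legislation_cost", "vsly",
              "compliance_officer_wage")) {
    assert_nonneg(co[[f]], f)
  }
  invisible(bundle)
}

#' Steady-state prevalence implied by constant rates
#'
#' The fixed point of the annual incidence/case-fatality/remission
#' recursion; used as an internal-consistency check on generated
#' epidemiology.
#'
#' @param incidence,case_fatality,remission Annual probabilities.
#' @return Prevalence fraction in \[0,1\].
#' @export
steady_state_prevalence <- function(incidence, case_fatality, remission) {
  incidence / pmax(incidence + case_fatality + remission, .Machine$double.eps)
}

# ---- serialisation ---------------------------------------------------------

#' Write a bundle to a directory of CSV files plus a JSON manifest
#'
#' One CSV per table (`population.csv`, `disease_<slug>.csv`,
#' `consumption.csv`, `costs.csv`), UTF-8, with doubles written at 17
#' significant digits so that [read_bundle()] restores them bit-for-bit.
#' The generator config, effect ground truth and seed go to
#' `manifest.json`.
#'
#' @param bundle A `mslt_bundle`.
#' @param dir Target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_csv_exact(bundle$population, file.path(dir, "population.csv"))
  for (nm in names(bundle$diseases)) {
    write_csv_exact(bundle$diseases[[nm]],
                    file.path(dir, paste0("disease_", slugify(nm), ".csv")))
  }
  write_csv_exact(bundle$consumption, file.path(dir, "consumption.csv"))
  co <- bundle$costs
  rows <- do.call(rbind, lapply(names(co), function(f) {
    v <- co[[f]]
    data.frame(field = f,
               grade = if (is.null(names(v))) NA_character_ else names(v),
               value = as.numeric(v), stringsAsFactors = FALSE)
  }))
  write_csv_exact(rows, file.path(dir, "costs.csv"))
  manifest <- list(config = bundle$config, effect = bundle$effect,
                   seed = bundle$seed,
                   diseases = names(bundle$diseases))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}

## Columns stored as doubles; quoted integral values ("0", "3500") would
## otherwise come back as integers and break exact round-trips.
double_cols <- c("count", "acm_rate", "mean_height", "bmi_mean", "bmi_sd",
                 "age_mid", "incidence", "prevalence", "case_fatality",
                 "remission", "disability_weight", "rr_per_bmi_unit",
                 "tmrel_bmi", "unit_cost", "mean_kj_per_day", "value")

read_table_checked <- function(path) {
  if (!file.exists(path)) stopf("missing input file '%s'", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(double_cols, names(df))) {
    df[[col]] <- as.double(df[[col]])
  }
  df
}

check_rates_file <- function(df, file, cols) {
  for (col in cols) {
    if (!col %in% names(df)) stopf("file '%s': missing column '%s'", file, col)
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0 | df[[col]] > 1)
    if (length(bad)) {
      stopf("file '%s', column '%s', row %d: value %s outside [0,1]",
            file, col, bad[1], format(df[[col]][bad[1]]))
    }
  }
  invisible(df)
}

#' Read a bundle written by [write_bundle()]
#'
#' Validates every table on the way in; malformed input produces an error
#' naming the file, column and row.
#'
#' @param dir Directory containing the CSV files and `manifest.json`.
#' @return A `mslt_bundle`.
#' @export
read_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  pop <- read_table_checked(file.path(dir, "population.csv"))
  check_rates_file(pop, "population.csv", "acm_rate")
  allowed <- c(model_disease_names(FALSE), "osteoarthritis")
  disease_names <- manifest$diseases
  diseases <- lapply(disease_names, function(nm) {
    file <- paste0("disease_", slugify(nm), ".csv")
    d <- read_table_checked(file.path(dir, file))
    if (!identical(d$disease[1], nm) || !d$disease[1] %in% allowed) {
      stopf("file '%s': unknown disease '%s'; allowed names: %s",
            file, d$disease[1], paste(allowed, collapse = "; "))
    }
    check_rates_file(d, file, c("incidence", "prevalence", "case_fatality",
                                "remission"))
    d
  })
  names(diseases) <- disease_names
  cons <- read_table_checked(file.path(dir, "consumption.csv"))
  if (!"mean_kj_per_day" %in% names(cons)) {
    stopf("file 'consumption.csv': missing column 'mean_kj_per_day'")
  }
  crow <- read_table_checked(file.path(dir, "costs.csv"))
  costs <- list()
  for (f in unique(crow$field)) {
    sub <- crow[crow$field == f, ]
    v <- sub$value
    if (!all(is.na(sub$grade))) names(v) <- sub$grade
    costs[[f]] <- v
  }
  class(costs) <- "cost_inputs"
  ## effect adjustments arrive as a JSON object; restore the named list
  eff <- manifest$effect
  eff$adjustments <- as.list(eff$adjustments)
  config <- manifest$config
  config$effect <- eff
  bundle <- structure(list(
    population = pop, diseases = diseases, consumption = cons,
    costs = costs, effect = eff, config = config,
    seed = as.integer(manifest$seed)
  ), class = "mslt_bundle")
  validate_bundle(bundle)
  bundle
}
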