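# Intervention effect pathway: advertising restriction -> change in
# unhealthy food energy purchased -> daily energy intake -> body weight ->
# BMI, per population stratum.

#' Construct an intervention effect specification
#'
#' The effect size is the relative change in unhealthy-food energy
#' purchased (negative = reduction), taken from the Transport for London
#' advertising-restriction evaluation (-6.7 %, 95 % CI -10.1 to -3.2).
#' `adjustments` are multiplicative effectiveness reductions applied on top
#' (e.g. the 20 % adjustment for lower out-of-home advertising exposure in
#' Australian capital cities, or the 18 % adjustment for absent bus-shelter
#' coverage).
#'
#' @param relative_change Fraction, negative for a reduction.
#' @param ci_low,ci_high 95 % CI bounds on `relative_change`.
#' @param adjustments Numeric vector of effectiveness reductions in \[0,1\].
#' @param by_category Optional named vector of category-specific relative
#'   changes; when supplied, the effect applies only to the named
#'   categories (other categories are unaffected).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(relative_change = -0.067,
                        ci_low = -0.101, ci_high = -0.032,
                        adjustments = c(exposure = 0.20),
                        by_category = NULL) {
  adjustments <- unlist(adjustments)
  if (length(adjustments) == 0) adjustments <- numeric(0)
  if (!(ci_low <= relative_change && relative_change <= ci_high)) {
    stopf("effect CI [%s, %s] must bracket relative_change %s",
          ci_low, ci_high, relative_change)
  }
  for (a in adjustments) assert_fraction(a, "adjustment")
  structure(list(relative_change = relative_change,
                 ci_low = ci_low, ci_high = ci_high,
                 adjustments = adjustments,
                 by_category = by_category),
            class = "effect_spec")
}

#' Apply effectiveness adjustments to the base effect size
#'
#' Each adjustment `a` multiplies the effect by `(1 - a)`; the result is
#' independent of the order of adjustments.
#'
#' @param spec An [effect_spec()].
#' @return The adjusted relative change (fraction).
#' @examples
#' adjusted_effect(effect_spec(-0.067, adjustments = 0.20))   # -0.0536
#' @export
adjusted_effect <- function(spec) {
  spec$relative_change * prod(1 - spec$adjustments)
}

#' Effectiveness reduction from absent bus-shelter coverage
#'
#' The comparator policy covers a fraction of bus shelters
#' (`shelter_coverage`), and bus shelters form a share of the
#' jurisdiction's out-of-home media assets (`shelter_asset_share`).  With
#' exposure assumed equivalent across asset types, the effectiveness lost
#' when shelters are excluded is the product of the two.
#'
#' @param shelter_coverage Fraction of bus shelters covered by the
#'   comparator policy.
#' @param shelter_asset_share Share of media assets that are bus shelters.
#' @return Effectiveness reduction (fraction in \[0,1\]).
#' @examples
#' coverage_adjustment(0.90, 0.20)   # 0.18
#' @export
coverage_adjustment <- function(shelter_coverage, shelter_asset_share) {
  assert_fraction(shelter_coverage, "shelter_coverage")
  assert_fraction(shelter_asset_share, "shelter_asset_share")
  shelter_coverage * shelter_asset_share
}

#' Change in daily energy intake by stratum
#'
#' Applies a relative change to unhealthy food consumption.  A scalar
#' effect applies to the stratum's total across all unhealthy categories;
#' a named vector applies category-specific effects (categories not named
#' are unaffected).  No substitution towards other foods is modelled.
#'
#' @param consumption Consumption table (`age_start`, `sex`, `category`,
#'   `mean_kj_per_day`).
#' @param effect Scalar fraction, or named vector of per-category
#'   fractions.
#' @return Data frame with `age_start`, `sex`, `delta_kj_per_day`.
#' @export
intake_change <- function(consumption, effect) {
  key <- paste(consumption$age_start, consumption$sex)
  if (is.null(names(effect))) {
    assert_scalar(effect, "effect")
    delta <- consumption$mean_kj_per_day * effect
  } else {
    known <- unique(consumption$category)
    unknown <- setdiff(names(effect), known)
    if (length(unknown)) {
      stopf("unknown consumption categor%s: %s; table has: %s",
            if (length(unknown) > 1) "ies" else "y",
            paste(unknown, collapse = ", "), paste(known, collapse = "; "))
    }
    eff_vec <- effect[match(consumption$category, names(effect))]
    eff_vec[is.na(eff_vec)] <- 0
    delta <- consumption$mean_kj_per_day * eff_vec
  }
  agg <- rowsum(delta, key, reorder = FALSE)
  first <- !duplicated(key)
  data.frame(age_start = consumption$age_start[first],
             sex = consumption$sex[first],
             delta_kj_per_day = agg[match(unique(key), rownames(agg)), 1],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Convert an energy-intake change to a steady-state weight change
#'
#' Linear energy-balance rule: `delta_weight = delta_kj / epsilon`, with
#' separate constants for adults (94 kJ/day per kg) and children (420
#' kJ/day per kg of growth-adjusted change).  The change is taken to be
#' realised at the end of year 1 and maintained thereafter.
#'
#' @param delta_kj Change in intake, kJ/person/day (vectorised).
#' @param age Age in years (vectorised; decides adult vs child epsilon).
#' @param epsilon_adult,epsilon_child kJ/day per kg.
#' @param adult_age Age from which the adult constant applies.
#' @return Weight change in kg.
#' @export
weight_change <- function(delta_kj, age, epsilon_adult = 94,
                          epsilon_child = 420, adult_age = 18) {
  if (epsilon_adult <= 0 || epsilon_child <= 0) {
    stopf("energy-to-weight constants must be positive")
  }
  eps <- ifelse(age >= adult_age, epsilon_adult, epsilon_child)
  delta_kj / eps
}

#' Convert a weight change to a BMI change
#'
#' @param delta_weight kg (vectorised).
#' @param mean_height metres, positive.
#' @return BMI change in kg/m^2.
#' @export
bmi_change <- function(delta_weight, mean_height) {
  if (any(mean_height <= 0)) stopf("'mean_height' must be positive")
  delta_weight / mean_height^2
}

#' Run the full effect pathway on a bundle
#'
#' Adjusted effect size -> per-stratum intake change -> weight change ->
#' BMI change, with the population-weighted mean weight change attached.
#'
#' @param bundle A `mslt_bundle`.
#' @param spec An [effect_spec()]; defaults to the bundle's ground-truth
#'   effect with its adjustments.
#' @param consumption_scale Multiplier on all consumption values (used by
#'   the uncertainty analysis).
#' @return Data frame (one row per stratum, aligned with
#'   `bundle$population`) with `delta_kj_per_day`, `delta_weight`,
#'   `delta_bmi`; attribute `mean_weight_change` holds the
#'   population-weighted mean (kg).
#' @export
apply_effect_pathway <- function(bundle, spec = NULL, consumption_scale = 1) {
  if (is.null(spec)) {
    eff <- bundle$effect
    spec <- effect_spec(eff$relative_change, eff$ci_low, eff$ci_high,
                        unlist(eff$adjustments))
  }
  cons <- bundle$consumption
  cons$mean_kj_per_day <- cons$mean_kj_per_day * consumption_scale
  if (is.null(spec$by_category)) {
    effect <- adjusted_effect(spec)
  } else {
    effect <- spec$by_category * prod(1 - spec$adjustments)
  }
  ic <- intake_change(cons, effect)
  pop <- bundle$population
  ord <- match(paste(pop$age_start, pop$sex), paste(ic$age_start, ic$sex))
  if (anyNA(ord)) stopf("consumption table does not cover all population strata")
  delta_kj <- ic$delta_kj_per_day[ord]
  cfg <- bundle$config
  dw <- weight_change(delta_kj, pop$age_mid,
                      cfg$epsilon_adult %||% 94, cfg$epsilon_child %||% 420,
                      cfg$adult_age %||% 18)
  db <- bmi_change(dw, pop$mean_height)
  out <- data.frame(age_start = pop$age_start, sex = pop$sex,
                    delta_kj_per_day = delta_kj,
                    delta_weight = dw, delta_bmi = db,
                    stringsAsFactors = FALSE)
  attr(out, "mean_weight_change") <- sum(pop$count * dw) / sum(pop$count)
  out
}
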