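# Hand-built miniature bundles for unit tests; all fields set explicitly
# so expected values can be computed by hand or by the brute-force oracle.

tiny_bundle <- function(n_strata = 2,
                        count = rep(1000, n_strata),
                        acm_rate = rep(0.02, n_strata),
                        bmi_mean = rep(28, n_strata),
                        bmi_sd = rep(4, n_strata),
                        mean_height = rep(1.7, n_strata),
                        diseases = list(
                          `type 2 diabetes` = list(incidence = 0.01,
                                                   prevalence = 0.05,
                                                   case_fatality = 0.1,
                                                   remission = 0,
                                                   disability_weight = 0.1,
                                                   rr_per_bmi_unit = 1.2,
                                                   tmrel_bmi = 21,
                                                   unit_cost = 1000)
                        ),
                        kj_per_day = rep(2000, n_strata)) {
  stopifnot(n_strata <= 4)
  age_start <- c(30L, 35L, 40L, 45L)[seq_len(n_strata)]
  pop <- data.frame(
    age_start = age_start, age_width = 5L, age_mid = age_start + 2.5,
    sex = rep("F", n_strata), count = count, acm_rate = acm_rate,
    mean_height = mean_height, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    stringsAsFactors = FALSE
  )
  dis <- lapply(names(diseases), function(nm) {
    d <- diseases[[nm]]
    data.frame(
      disease = nm, age_start = age_start, sex = "F",
      incidence = rep_len(d$incidence, n_strata),
      prevalence = rep_len(d$prevalence, n_strata),
      case_fatality = rep_len(d$case_fatality, n_strata),
      remission = rep_len(d$remission, n_strata),
      disability_weight = rep_len(d$disability_weight, n_strata),
      rr_per_bmi_unit = rep_len(d$rr_per_bmi_unit, n_strata),
      tmrel_bmi = rep_len(d$tmrel_bmi, n_strata),
      unit_cost = rep_len(d$unit_cost, n_strata),
      stringsAsFactors = FALSE
    )
  })
  names(dis) <- names(diseases)
  cons <- data.frame(age_start = age_start, sex = "F",
                     category = "fast food",
                     mean_kj_per_day = kj_per_day, stringsAsFactors = FALSE)
  structure(list(
    population = pop, diseases = dis, consumption = cons,
    costs = default_cost_inputs(),
    effect = list(relative_change = -0.067, ci_low = -0.101,
                  ci_high = -0.032, adjustments = list(exposure = 0.2)),
    config = default_config(),
    seed = 1L
  ), class = "mslt_bundle")
}

# Default synthetic bundle shared across tests (generated once per run).
default_bundle <- generate_inputs(seed = 42)
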