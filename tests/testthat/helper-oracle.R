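# Independent brute-force oracle for the multi-state lifetable: plain
# nested loops over strata, years and diseases, scalar arithmetic only.
# Deliberately written without reference to the package internals so that
# agreement is a genuine cross-check of the difference equations:
#   - onset among the healthy with prob i; case fatality f and remission r
#     among the prevalent (new cases exempt in their onset year);
#   - prevalence renormalised to survivors of the disease's own mortality;
#   - other-cause mortality = all-cause - sum(prev * f), taken from the
#     baseline run in the intervention arm;
#   - person-years = survivors at end of year; HALY weight
#     1 - min(1, sum(prev * dw)); costs = prev * alive * unit_cost.
oracle_lifetable <- function(bundle, pif, horizon, effect_start_year = 2) {
  pop <- bundle$population
  ns <- nrow(pop)
  nd <- length(bundle$diseases)
  band_starts <- sort(unique(pop$age_start))

  rate_of <- function(s, t, d, col) {
    age <- pop$age_mid[s] + t - 1
    band <- band_starts[max(1, min(sum(band_starts <= age), length(band_starts)))]
    row <- which(pop$age_start == band & pop$sex == pop$sex[s])
    bundle$diseases[[d]][[col]][row]
  }
  acm_of <- function(s, t) {
    age <- pop$age_mid[s] + t - 1
    band <- band_starts[max(1, min(sum(band_starts <= age), length(band_starts)))]
    pop$acm_rate[which(pop$age_start == band & pop$sex == pop$sex[s])]
  }

  run_arm <- function(use_pif, m_oc_base = NULL) {
    alive <- matrix(0, ns, horizon)
    haly <- matrix(0, ns, horizon)
    hc <- matrix(0, ns, horizon)
    prev <- array(0, c(ns, nd, horizon))
    m_oc <- matrix(0, ns, horizon)
    for (s in 1:ns) {
      a <- pop$count[s]
      p <- sapply(1:nd, function(d) bundle$diseases[[d]]$prevalence[s])
      for (t in 1:horizon) {
        dd <- 0
        for (d in 1:nd) dd <- dd + p[d] * rate_of(s, t, d, "case_fatality")
        if (is.null(m_oc_base)) {
          oc <- acm_of(s, t) - dd
          stopifnot(oc >= 0)
        } else {
          oc <- m_oc_base[s, t]
        }
        m_oc[s, t] <- oc
        a_new <- a * (1 - oc - dd)
        p_new <- numeric(nd)
        for (d in 1:nd) {
          i <- rate_of(s, t, d, "incidence")
          if (use_pif && t >= effect_start_year) i <- i * (1 - pif[s, d])
          f <- rate_of(s, t, d, "case_fatality")
          r <- rate_of(s, t, d, "remission")
          p_new[d] <- (p[d] * (1 - f - r) + (1 - p[d]) * i) / (1 - p[d] * f)
        }
        p <- p_new
        a <- a_new
        wsum <- 0
        cost <- 0
        for (d in 1:nd) {
          wsum <- wsum + p[d] * rate_of(s, t, d, "disability_weight")
          cost <- cost + p[d] * a * rate_of(s, t, d, "unit_cost")
        }
        alive[s, t] <- a
        prev[s, , t] <- p
        haly[s, t] <- a * (1 - min(1, wsum))
        hc[s, t] <- cost
      }
    }
    list(alive = alive, prevalence = prev, haly = haly, hc_cost = hc,
         m_oc = m_oc)
  }

  base <- run_arm(FALSE)
  intv <- run_arm(TRUE, m_oc_base = base$m_oc)
  list(baseline = base, intervention = intv)
}

# Simulation oracle for the PIF: large-sample Monte Carlo estimate of
# 1 - E[RR(B + delta)] / E[RR(B)] with B ~ N(mu, sd).
oracle_pif_sim <- function(mu, sd, delta, rr, tau, n = 2e6, seed = 99) {
  set.seed(seed)
  b <- rnorm(n, mu, sd)
  1 - mean(rr^pmax(0, b + delta - tau)) / mean(rr^pmax(0, b - tau))
}
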