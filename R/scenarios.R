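# Intervention scenarios and pandemic condition sets.
#
# The four built-in scenarios vary (a) the uptake-blended intervention
# effect multipliers and (b) the yearly service capacity increments. The
# standard-telehealth scenario ships with its referral-to-specialised-care
# multiplier at 1.00 (telehealth extends existing services online without
# changing referral pathways); the tabulated outlier value can be set
# explicitly via `scenario_spec(..., m_ref = 10)` if a user wants it.
#
# Pandemic conditions install exogenous time profiles: an unemployment
# inflow shock that decays exponentially, amplified for the youth share of
# job losses, and a sense-of-community index that ramps down, holds through
# the period of social disconnection, and ramps back.

#' Define an intervention scenario
#'
#' @param name Scenario label.
#' @param u_max Maximum rate per service: the fraction of delivered services
#'   operating under the intervention once fully implemented, in `[0, 1]`.
#' @param m_rec,m_ref,m_dis,m_aod,m_rel,m_emp,m_home,m_cap,m_onl Effect
#'   multipliers (dimensionless, > 0) on per-service recovery, GP referral
#'   to specialised care (high-distress band only), disengagement, AOD
#'   referral, substance-use relapse, employment initiation, exiting
#'   homelessness, specialised service capacity, and online referral.
#' @param inc_gp,inc_psy,inc_cmhc Yearly service-capacity increments
#'   (services/week per year) for general practice, psychiatrist + allied,
#'   and community mental health.
#' @param start_year Decimal year at which implementation begins.
#' @param ramp_years Years over which uptake ramps linearly to `u_max`.
#' @return An object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(name, u_max = 0,
                          m_rec = 1, m_ref = 1, m_dis = 1, m_aod = 1,
                          m_rel = 1, m_emp = 1, m_home = 1, m_cap = 1,
                          m_onl = 1,
                          inc_gp = 125.85, inc_psy = 216.31, inc_cmhc = 0,
                          start_year = 2021.0, ramp_years = 1.0) {
  mult <- c(m_rec = m_rec, m_ref = m_ref, m_dis = m_dis, m_aod = m_aod,
            m_rel = m_rel, m_emp = m_emp, m_home = m_home, m_cap = m_cap,
            m_onl = m_onl)
  if (any(mult <= 0)) stop("all effect multipliers must be positive")
  if (u_max < 0 || u_max > 1) stop("u_max must lie in [0, 1]")
  structure(list(name = name, u_max = u_max, multipliers = mult,
                 inc_gp = inc_gp, inc_psy = inc_psy, inc_cmhc = inc_cmhc,
                 start_year = start_year, ramp_years = ramp_years),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$name, "\n", sep = "")
  cat(sprintf("  uptake: max %.2f from %.2f over %.1f y\n",
              x$u_max, x$start_year, x$ramp_years))
  nontriv <- x$multipliers[x$multipliers != 1]
  if (length(nontriv))
    cat("  multipliers: ",
        paste(sprintf("%s=%.2f", names(nontriv), nontriv), collapse = ", "), "\n")
  cat(sprintf("  capacity increments/yr: GP %.2f, psy+allied %.2f, CMHC %.2f\n",
              x$inc_gp, x$inc_psy, x$inc_cmhc))
  invisible(x)
}

#' The four built-in intervention scenarios
#'
#' Business as usual; a 20\% increase in the service-capacity growth rate;
#' standard telehealth; and technology-enabled care coordination.
#'
#' @return Named list of [scenario_spec()] objects.
#' @examples
#' builtin_scenarios()[["tech_enabled_coordination"]]
#' @export
builtin_scenarios <- function() {
  list(
    business_as_usual = scenario_spec("business_as_usual"),
    capacity_growth_20 = scenario_spec("capacity_growth_20",
                                       inc_gp = 151.02, inc_psy = 259.57,
                                       inc_cmhc = 75.14),
    standard_telehealth = scenario_spec("standard_telehealth", u_max = 0.70,
                                        m_rec = 1.09, m_ref = 1.00,
                                        m_dis = 0.76, m_rel = 0.93,
                                        m_cap = 1.10),
    tech_enabled_coordination = scenario_spec("tech_enabled_coordination",
                                              u_max = 0.70,
                                              m_rec = 1.18, m_ref = 1.27,
                                              m_dis = 0.52, m_aod = 1.10,
                                              m_rel = 0.87, m_emp = 1.10,
                                              m_home = 1.10, m_cap = 1.10,
                                              m_onl = 1.10)
  )
}

#' Intervention uptake at a point in time
#'
#' Zero before the start year, then a linear ramp to `u_max` over
#' `ramp_years`, then constant at `u_max`.
#'
#' @param t Decimal year (vectorised).
#' @param spec A [scenario_spec()].
#' @return Uptake fraction(s) in `[0, u_max]`.
#' @export
uptake <- function(t, spec) {
  if (spec$u_max == 0) return(rep(0, length(t)))
  el <- t - spec$start_year
  u <- ifelse(el <= 0, 0,
              ifelse(spec$ramp_years > 0, pmin(el / spec$ramp_years, 1), 1))
  u * spec$u_max
}

#' Uptake-blended effective multiplier
#'
#' Population-mix average of covered (`m`) and uncovered (1) services:
#' `1 + u * (m - 1)`. Identity at zero uptake; the full multiplier at full
#' coverage.
#'
#' @param m Intervention effect multiplier (> 0).
#' @param u Uptake fraction in `[0, 1]`.
#' @return The effective multiplier.
#' @examples
#' effective_multiplier(0.52, 0.7)  # 0.664
#' @export
effective_multiplier <- function(m, u) {
  stopifnot(all(m > 0), all(u >= 0), all(u <= 1))
  1 + u * (m - 1)
}

#' Pandemic (COVID-19) condition sets
#'
#' Pre-pandemic conditions are an exact no-op: all shock profiles stay at
#' their baseline constants and the trajectory is bit-identical to a run
#' with no conditions applied. Post-pandemic conditions install an
#' unemployment inflow shock scaled by `unemp_shock_scale` at onset and
#' decaying exponentially at `unemp_decay` per week, amplified on the youth
#' share of job losses by `youth_jobloss_ratio`, and a sense-of-community
#' index that ramps from its baseline to `soc_index` over
#' `years_to_reach_index` years, holds for `duration_disconnection` years,
#' then ramps back over the same ramp time.
#'
#' @param condition `"pre"` or `"post"`, or leave default and override
#'   fields directly.
#' @param youth_jobloss_ratio Relative job-loss rate of the 15-24 group.
#' @param unemp_shock_scale Multiplier on the baseline unemployment inflow
#'   at shock onset.
#' @param unemp_decay Exponential decay rate of the shock (per week).
#' @param soc_index Sense-of-community index reached under the condition.
#' @param years_to_reach_index Ramp time (years) to reach `soc_index`.
#' @param duration_disconnection Years the index is held before recovery.
#' @param shock_onset Decimal year of shock onset.
#' @return An object of class `"covid_conditions"`.
#' @export
covid_conditions <- function(condition = c("pre", "post"),
                             youth_jobloss_ratio = NULL,
                             unemp_shock_scale = NULL,
                             unemp_decay = NULL,
                             soc_index = NULL,
                             years_to_reach_index = NULL,
                             duration_disconnection = NULL,
                             shock_onset = 2020.25) {
  condition <- match.arg(condition)
  base <- if (condition == "pre")
    list(youth_jobloss_ratio = 1.0, unemp_shock_scale = 1.0, unemp_decay = 0,
         soc_index = 9.61, years_to_reach_index = 0,
         duration_disconnection = 0)
  else
    list(youth_jobloss_ratio = 5.0, unemp_shock_scale = 15.0, unemp_decay = 0.05,
         soc_index = 8.24, years_to_reach_index = 1.0,
         duration_disconnection = 2.0)
  ovr <- list(youth_jobloss_ratio = youth_jobloss_ratio,
              unemp_shock_scale = unemp_shock_scale,
              unemp_decay = unemp_decay, soc_index = soc_index,
              years_to_reach_index = years_to_reach_index,
              duration_disconnection = duration_disconnection)
  for (nm in names(ovr)) if (!is.null(ovr[[nm]])) base[[nm]] <- ovr[[nm]]
  base$condition <- condition
  base$shock_onset <- shock_onset
  structure(base, class = "covid_conditions")
}

#' @export
print.covid_conditions <- function(x, ...) {
  cat("<covid_conditions> ", x$condition, "\n", sep = "")
  cat(sprintf("  youth job-loss ratio %.2f; unemployment shock x%.2f decaying %.3f/week\n",
              x$youth_jobloss_ratio, x$unemp_shock_scale, x$unemp_decay))
  cat(sprintf("  sense of community -> %.2f over %.2f y, held %.2f y (onset %.2f)\n",
              x$soc_index, x$years_to_reach_index, x$duration_disconnection,
              x$shock_onset))
  invisible(x)
}

covid_is_noop <- function(covid) {
  covid$unemp_shock_scale == 1 && covid$youth_jobloss_ratio == 1 &&
    covid$years_to_reach_index == 0 && covid$duration_disconnection == 0
}

#' Apply a scenario and condition set to the model parameters
#'
#' Installs the scenario's capacity increments and effect multipliers (the
#' multipliers reach the model through the uptake-blended effective
#' multiplier, re-evaluated every step from the uptake profile) and the
#' pandemic shock profiles as time-varying overrides consumed by
#' [build_model()].
#'
#' @param params An [mhsd_params()] object.
#' @param spec A [scenario_spec()].
#' @param covid A [covid_conditions()] object.
#' @return The modified parameter set, carrying a `"shocks"` attribute.
#' @export
apply_scenario <- function(params, spec, covid = covid_conditions("pre")) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(covid, "covid_conditions"))
  p <- params
  m <- spec$multipliers
  for (nm in names(m)) p[[nm]] <- unname(m[[nm]])

  soc0 <- params$soc_index0
  spec_local <- spec
  # capacity increments follow the baseline schedule until the intervention
  # starts, then the scenario's Table-1 schedule
  inc_step <- function(base, scen) {
    force(base); force(scen); start <- spec$start_year
    function(t, pp) if (t < start) base else scen
  }

  shocks <- list(
    sf_shock("uptake", function(t, pp) uptake(t, spec_local)),
    sf_shock("inc_gp_yr", inc_step(params$inc_gp, spec$inc_gp)),
    sf_shock("inc_psy_yr", inc_step(params$inc_psy, spec$inc_psy)),
    sf_shock("inc_cmhc_yr", inc_step(params$inc_cmhc, spec$inc_cmhc)),
    if (covid_is_noop(covid)) {
      sf_shock("soc_index", function(t, pp) soc0)
    } else {
      on <- covid$shock_onset; ramp <- covid$years_to_reach_index
      hold <- covid$duration_disconnection; target <- covid$soc_index
      sf_shock("soc_index", function(t, pp) {
        el <- t - on
        if (el <= 0) return(soc0)
        if (ramp > 0 && el < ramp)
          return(soc0 + (target - soc0) * el / ramp)
        el2 <- el - max(ramp, 0)
        if (el2 <= hold) return(target)
        el3 <- el2 - hold
        if (ramp > 0 && el3 < ramp)
          return(target + (soc0 - target) * el3 / ramp)
        soc0
      })
    },
    if (covid_is_noop(covid)) {
      sf_shock("unemp_shock", function(t, pp) 1)
    } else {
      on <- covid$shock_onset; sc <- covid$unemp_shock_scale
      dec <- covid$unemp_decay
      sf_shock("unemp_shock", function(t, pp) {
        el <- t - on
        if (el <= 0) return(1)
        1 + (sc - 1) * exp(-dec * el * 52)
      })
    },
    if (covid_is_noop(covid)) {
      sf_shock("youth_amp", function(t, pp) 1)
    } else {
      on <- covid$shock_onset; ratio <- covid$youth_jobloss_ratio
      dec <- covid$unemp_decay
      sf_shock("youth_amp", function(t, pp) {
        el <- t - on
        if (el <= 0) return(1)
        ys <- params$youth_share_unemp
        1 + (ratio - 1) * ys * exp(-dec * el * 52)
      })
    }
  )
  attr(p, "shocks") <- shocks
  attr(p, "scenario") <- spec$name
  attr(p, "covid") <- covid$condition
  p
}

#' Compare scenario outcomes against a baseline
#'
#' Percent reductions `100 * (baseline - scenario) / baseline` for the three
#' cumulative count outcomes, the percentage-point reduction in end-of-
#' horizon high-distress prevalence, and the prevented counts
#' (`baseline - scenario`, rounded to whole events at reporting).
#'
#' @param baseline,scenario `"mhsd_summary"` objects over the same window.
#' @return An object of class `"outcome_comparison"`.
#' @examples
#' b <- structure(list(self_harm_hospitalizations = 12274, suicide_deaths = 953,
#'                     ed_presentations = 81263, prevalence_start = 17.6,
#'                     prevalence_end = 15.6, window = c(2021, 2030)),
#'                class = "mhsd_summary")
#' s <- b; s$self_harm_hospitalizations <- 11430
#' compare_outcomes(b, s)$pct_reduction_self_harm  # 6.876...
#' @export
compare_outcomes <- function(baseline, scenario) {
  if (!isTRUE(all.equal(baseline$window, scenario$window)))
    stop("outcome windows differ between baseline and scenario")
  pct <- function(b, s) {
    if (b == 0) {
      warning("baseline counter is zero; percent reduction undefined")
      return(NA_real_)
    }
    100 * (b - s) / b
  }
  structure(list(
    pct_reduction_self_harm = pct(baseline$self_harm_hospitalizations,
                                  scenario$self_harm_hospitalizations),
    pct_reduction_suicide = pct(baseline$suicide_deaths, scenario$suicide_deaths),
    pct_reduction_ed = pct(baseline$ed_presentations, scenario$ed_presentations),
    pp_reduction_prevalence = baseline$prevalence_end - scenario$prevalence_end,
    prevented_self_harm = baseline$self_harm_hospitalizations -
      scenario$self_harm_hospitalizations,
    prevented_suicides = baseline$suicide_deaths - scenario$suicide_deaths,
    prevented_ed = baseline$ed_presentations - scenario$ed_presentations,
    window = baseline$window), class = "outcome_comparison")
}

#' @export
print.outcome_comparison <- function(x, ...) {
  cat(sprintf("Outcome comparison, %.1f-%.1f (reduction vs baseline):\n",
              x$window[1L], x$window[2L]))
  cat(sprintf("  self-harm hospitalizations  %6.2f%%  (%s prevented)\n",
              x$pct_reduction_self_harm, format(round(x$prevented_self_harm))))
  cat(sprintf("  suicide deaths              %6.2f%%  (%s prevented)\n",
              x$pct_reduction_suicide, format(round(x$prevented_suicides))))
  cat(sprintf("  MH-related ED presentations %6.2f%%  (%s prevented)\n",
              x$pct_reduction_ed, format(round(x$prevented_ed))))
  cat(sprintf("  high-distress prevalence    %6.2f percentage points\n",
              x$pp_reduction_prevalence))
  invisible(x)
}
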