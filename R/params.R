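# Model parameter set: every rate, fraction, multiplier and initial condition
# of the regional model, with bounds, units and sector tags. Values are
# per-week rates unless stated otherwise; capacities are services/week and
# yearly capacity increments are services/week added per year.

mhsd_param_table <- function() {
  p <- function(name, value, min, max, units, sector, description)
    data.frame(name = name, value = value, min = min, max = max, units = units,
               sector = sector, description = description, stringsAsFactors = FALSE)
  rbind(
    # -- population ---------------------------------------------------------
    p("pop_total0", 502524, 3e5, 8e5, "persons", "population",
      "initial regional population (all ages)"),
    p("frac_0_14", 0.18, 0.05, 0.40, "fraction", "population", "initial share aged 0-14"),
    p("frac_15_24", 0.11, 0.05, 0.40, "fraction", "population", "initial share aged 15-24"),
    p("frac_25_64", 0.49, 0.20, 0.70, "fraction", "population", "initial share aged 25-64"),
    p("births_weekly", 110, 0, 500, "persons/week", "population", "birth inflow"),
    p("mig_0_14", 5, 0, 200, "persons/week", "population", "net migration, 0-14"),
    p("mig_15_24", 8, 0, 200, "persons/week", "population", "net migration, 15-24"),
    p("mig_25_64", 25, 0, 200, "persons/week", "population", "net migration, 25-64"),
    p("mig_65p", 22, 0, 200, "persons/week", "population", "net migration, 65+"),
    p("mort_0_14", 0.0002 / 52, 0, 0.001, "fraction/week", "population", "mortality hazard, 0-14"),
    p("mort_15_24", 0.0004 / 52, 0, 0.001, "fraction/week", "population", "mortality hazard, 15-24"),
    p("mort_25_64", 0.002 / 52, 0, 0.002, "fraction/week", "population", "mortality hazard, 25-64"),
    p("mort_65p", 0.03 / 52, 0, 0.01, "fraction/week", "population", "mortality hazard, 65+"),
    # -- psychological distress --------------------------------------------
    p("init_mod_share", 0.195, 0.05, 0.40, "fraction", "distress",
      "initial share of adults with moderate distress (K10 16-21)"),
    p("init_high_share", 0.1901, 0.05, 0.40, "fraction", "distress",
      "initial share of adults with high/very-high distress (K10 22-50)"),
    p("onset_low_mod", 0.0044, 0, 0.05, "fraction/week", "distress",
      "low -> moderate onset hazard (scaled by determinant pressure)"),
    p("onset_mod_high", 0.00461, 0, 0.05, "fraction/week", "distress",
      "moderate -> high onset hazard (scaled by determinant pressure)"),
    p("remit_mod_low", 0.010, 0, 0.10, "fraction/week", "distress",
      "spontaneous moderate -> low remission hazard"),
    p("remit_high_mod", 0.0040, 0, 0.10, "fraction/week", "distress",
      "spontaneous high -> moderate remission hazard"),
    # -- social determinants ------------------------------------------------
    p("unemp0", 30000, 1000, 1e5, "persons", "determinants", "initial unemployed persons"),
    p("unemp_exit", 0.010, 1e-4, 0.5, "fraction/week", "determinants",
      "employment initiation hazard (scaled by the employment multiplier)"),
    p("homeless0", 2500, 100, 2e4, "persons", "determinants", "initial homeless persons"),
    p("homeless_exit", 0.020, 1e-4, 0.5, "fraction/week", "determinants",
      "exit-homelessness hazard (scaled by the housing multiplier)"),
    p("subst0", 25000, 1000, 1e5, "persons", "determinants",
      "initial persons with substance misuse"),
    p("aod_referral_rate", 0.004, 1e-5, 0.2, "fraction/week", "determinants",
      "referral hazard into alcohol-and-other-drugs treatment"),
    p("relapse_frac", 0.40, 0, 1, "fraction", "determinants",
      "fraction of completed AOD treatments that relapse"),
    p("dv_index0", 1.0, 0.1, 10, "index", "determinants", "domestic-violence exposure index"),
    p("early_life_frac0", 0.25, 0.01, 1, "fraction", "determinants",
      "adverse early-life exposure fraction"),
    p("soc_index0", 9.61, 1, 20, "index", "determinants",
      "baseline sense-of-community (social connectedness) index"),
    p("w_unemp", 0.20, 0, 2, "dimensionless", "determinants", "pressure weight: unemployment"),
    p("w_home", 0.10, 0, 2, "dimensionless", "determinants", "pressure weight: homelessness"),
    p("w_subst", 0.20, 0, 2, "dimensionless", "determinants", "pressure weight: substance misuse"),
    p("w_dv", 0.10, 0, 2, "dimensionless", "determinants", "pressure weight: domestic violence"),
    p("w_early", 0.10, 0, 2, "dimensionless", "determinants", "pressure weight: early-life exposure"),
    p("w_soc", 0.60, 0, 2, "dimensionless", "determinants",
      "pressure weight: sense of community (protective)"),
    p("gamma_attempt", 0.7, 0, 2, "dimensionless", "determinants",
      "exponent applying pressure to attempt rates"),
    p("gamma_diseng", 0.5, 0, 2, "dimensionless", "determinants",
      "exponent applying pressure to disengagement"),
    p("youth_share_unemp", 0.15, 0, 1, "fraction", "determinants",
      "youth (15-24) share of the unemployment shock"),
    # -- service system -----------------------------------------------------
    p("cap_gp0", 2000, 0, 2e4, "services/week", "services", "initial GP capacity"),
    p("cap_psy0", 1800, 0, 2e4, "services/week", "services",
      "initial psychiatrist + allied capacity"),
    p("cap_cmhc0", 300, 0, 5e3, "services/week", "services", "initial CMHC capacity"),
    p("cap_onl0", 1200, 0, 1e4, "services/week", "services", "initial online-services capacity"),
    p("cap_out0", 600, 0, 1e4, "services/week", "services", "initial outpatient capacity"),
    p("cap_inp0", 120, 0, 2e3, "services/week", "services", "initial psychiatric inpatient capacity"),
    p("cap_ed0", 400, 0, 5e3, "services/week", "services", "initial ED (MH) capacity"),
    p("inc_gp", 125.85, 0, 1e3, "services/week per year", "services",
      "yearly GP capacity increment"),
    p("inc_psy", 216.31, 0, 1e3, "services/week per year", "services",
      "yearly psychiatrist + allied capacity increment"),
    p("inc_cmhc", 0, 0, 1e3, "services/week per year", "services",
      "yearly CMHC capacity increment"),
    p("inc_onl", 0, 0, 1e3, "services/week per year", "services", "yearly online increment"),
    p("inc_out", 0, 0, 1e3, "services/week per year", "services", "yearly outpatient increment"),
    p("inc_inp", 0, 0, 1e3, "services/week per year", "services", "yearly inpatient increment"),
    p("inc_ed", 0, 0, 1e3, "services/week per year", "services", "yearly ED increment"),
    p("seek_mod_gp", 0.020, 0, 0.5, "fraction/week", "services",
      "GP care-seeking hazard, moderate band"),
    p("seek_high_gp", 0.040, 0, 0.5, "fraction/week", "services",
      "GP care-seeking hazard, high band"),
    p("seek_high_psy", 0.090, 0, 0.5, "fraction/week", "services",
      "direct specialist demand hazard, high band"),
    p("seek_high_cmhc", 0.004, 0, 0.5, "fraction/week", "services",
      "CMHC demand hazard, high band"),
    p("seek_high_out", 0.010, 0, 0.5, "fraction/week", "services",
      "outpatient demand hazard, high band"),
    p("seek_mod_onl", 0.008, 0, 0.5, "fraction/week", "services",
      "direct online demand hazard, moderate band"),
    p("p_ref_high", 0.30, 0, 1, "probability", "services",
      "GP referral probability to specialised care, high band"),
    p("p_ref_onl", 0.15, 0, 1, "probability", "services",
      "GP referral probability to online services, moderate band"),
    p("rec_gp_mod", 0.050, 0, 1, "probability", "services", "per-service recovery, GP/moderate"),
    p("rec_gp_high", 0.020, 0, 1, "probability", "services", "per-service recovery, GP/high"),
    p("rec_psy", 0.0379, 0, 1, "probability", "services",
      "per-service recovery, psychiatrist + allied"),
    p("rec_cmhc", 0.030, 0, 1, "probability", "services", "per-service recovery, CMHC"),
    p("rec_out", 0.015, 0, 1, "probability", "services", "per-service recovery, outpatient"),
    p("rec_onl", 0.030, 0, 1, "probability", "services", "per-service recovery, online"),
    p("rec_inp", 0.100, 0, 1, "probability", "services", "per-admission recovery, inpatient"),
    p("rec_scale", 1.0, 0.2, 5, "dimensionless", "services",
      "global multiplier on all per-service recovery probabilities"),
    p("completion_rate", 0.80, 0.01, 5, "fraction/week", "services",
      "treatment completion hazard (competes with disengagement)"),
    p("diseng_rate", 0.20, 1e-3, 2, "fraction/week", "services",
      "disengagement hazard from waiting and from care"),
    # -- suicidal behaviour -------------------------------------------------
    p("att_high", 3.06e-4, 0, 0.01, "attempts/person/week", "suicidality",
      "attempt rate, high-distress band (scaled by pressure)"),
    p("att_mod", 2e-5, 0, 0.001, "attempts/person/week", "suicidality",
      "attempt rate, moderate band"),
    p("hosp_frac", 1.0, 0, 1, "fraction", "suicidality",
      "fraction of attempts recorded as self-harm hospitalizations"),
    p("case_fatality", 0.0776, 0, 0.5, "fraction", "suicidality",
      "fraction of attempts that are fatal"),
    p("crisis_share", 0.50, 0, 5, "presentations/attempt", "suicidality",
      "MH ED presentations per attempt (crisis pathway)"),
    p("ed_untreated_rate", 0.0022776, 0, 0.05, "presentations/person/week", "suicidality",
      "MH ED presentation rate from untreated high distress"),
    p("care_protect_weeks", 1, 0, 26, "weeks", "suicidality",
      "weeks of 'in care' status conferred per high-band service delivered"),
    p("admit_frac", 0.10, 0, 1, "fraction", "suicidality",
      "fraction of MH ED presentations admitted to psychiatric inpatient care"),
    # -- intervention effect multipliers (identity under business as usual) --
    p("m_rec", 1, 0.1, 10, "dimensionless", "intervention", "effect on per-service recovery"),
    p("m_ref", 1, 0.1, 10, "dimensionless", "intervention",
      "effect on GP referral to specialised care (high band only)"),
    p("m_dis", 1, 0.1, 10, "dimensionless", "intervention", "effect on disengagement"),
    p("m_aod", 1, 0.1, 10, "dimensionless", "intervention", "effect on AOD referral"),
    p("m_rel", 1, 0.1, 10, "dimensionless", "intervention", "effect on substance-use relapse"),
    p("m_emp", 1, 0.1, 10, "dimensionless", "intervention", "effect on employment initiation"),
    p("m_home", 1, 0.1, 10, "dimensionless", "intervention", "effect on exiting homelessness"),
    p("m_cap", 1, 0.1, 10, "dimensionless", "intervention",
      "effect on specialised (psychiatric) service capacity"),
    p("m_onl", 1, 0.1, 10, "dimensionless", "intervention", "effect on online referral")
  )
}

#' Construct the full model parameter set
#'
#' Returns the complete named parameter list of the regional mental health
#' model -- demography, psychological distress transitions, social
#' determinants, service capacities and pathways, suicidal behaviour, and
#' the intervention effect multipliers (all 1 under business as usual).
#' Every parameter carries bounds, units and a sector tag; see
#' [params_table()] for the documented schema.
#'
#' @param ... Name-value overrides of individual parameters.
#' @return A named list of class `"mhsd_params"`.
#' @examples
#' p <- mhsd_params(att_high = 4e-4)
#' p$att_high
#' @export
mhsd_params <- function(...) {
  tab <- mhsd_param_table()
  vals <- as.list(stats::setNames(tab$value, tab$name))
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), tab$name)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    vals[names(dots)] <- dots
  }
  structure(vals, class = "mhsd_params", table = tab)
}

#' Parameter schema table
#'
#' @param params An `"mhsd_params"` object (current values are substituted
#'   into the `value` column).
#' @return A data.frame with columns `name`, `value`, `min`, `max`, `units`,
#'   `sector`, `description`.
#' @export
params_table <- function(params = mhsd_params()) {
  tab <- attr(params, "table")
  if (is.null(tab)) tab <- mhsd_param_table()
  tab$value <- unlist(params[tab$name], use.names = FALSE)
  tab
}

#' @export
print.mhsd_params <- function(x, ...) {
  tab <- params_table(x)
  cat("<mhsd_params> ", nrow(tab), " parameters\n", sep = "")
  for (s in unique(tab$sector)) cat(sprintf("  %-13s %2d\n", s, sum(tab$sector == s)))
  bad <- validate_params(x)
  if (length(bad)) cat("  out of bounds:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' Validate parameter values against their declared bounds
#'
#' @param params An `"mhsd_params"` object.
#' @return Character vector of names of out-of-bounds or missing parameters
#'   (empty if all valid).
#' @export
validate_params <- function(params) {
  tab <- mhsd_param_table()
  bad <- character()
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    v <- params[[nm]]
    if (is.null(v) || !is.finite(v) || v < tab$min[i] || v > tab$max[i])
      bad <- c(bad, nm)
  }
  bad
}

#' Read/write the parameter set as YAML
#'
#' The YAML schema is flat: one block per parameter with `value`, `units`,
#' `min`, `max`, `sector` and `description` fields, so a config file is
#' self-documenting and hand-editable.
#'
#' @param params An `"mhsd_params"` object.
#' @param path File path.
#' @return `write_params_yaml()` returns `path` invisibly;
#'   `read_params_yaml()` returns an `"mhsd_params"` object.
#' @export
write_params_yaml <- function(params, path) {
  tab <- params_table(params)
  out <- lapply(seq_len(nrow(tab)), function(i)
    list(value = tab$value[i], units = tab$units[i], min = tab$min[i],
         max = tab$max[i], sector = tab$sector[i],
         description = tab$description[i]))
  names(out) <- tab$name
  yaml::write_yaml(out, path, precision = 12L)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  vals <- lapply(raw, function(b) if (is.list(b)) b$value else b)
  do.call(mhsd_params, vals)
}
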