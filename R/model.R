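# The concrete regional mental health model: population demography,
# psychological distress (K10 bands), social determinants, capacity-
# constrained service pathways, and suicidal behaviour, expressed as a
# stock-and-flow model for the generic engine.
#
# Structural conventions:
#  * adults are ages 15+; the three distress-band stocks partition the adult
#    population exactly (demographic flows are mirrored onto the bands), so
#    high-band prevalence = high stock / (sum of bands);
#  * service capacities are stocks in services/week growing linearly by
#    their yearly increments; queues hold persons waiting, who remain in
#    their distress band while waiting;
#  * determinant pressure is a weighted power product (Cobb-Douglas) over
#    the determinant levels relative to their baseline references, equal to
#    1 when everything sits at baseline; it scales distress onset, attempt
#    rates and disengagement (the latter two through sector exponents);
#  * intervention multipliers enter through the uptake-blended effective
#    multiplier 1 + u(t) * (m - 1), identity under business as usual.

# names of the time-varying (shock-driven) quantities; the three capacity
# increments are time-profiled so an intervention's investment schedule can
# switch on at its implementation year
MHSD_TV <- c("uptake", "soc_index", "unemp_shock", "youth_amp",
             "inc_gp_yr", "inc_psy_yr", "inc_cmhc_yr")

mhsd_default_shocks <- function(params) {
  soc0 <- params$soc_index0
  ig <- params$inc_gp; ip <- params$inc_psy; ic <- params$inc_cmhc
  list(sf_shock("uptake", function(t, p) 0),
       sf_shock("soc_index", function(t, p) soc0),
       sf_shock("unemp_shock", function(t, p) 1),
       sf_shock("youth_amp", function(t, p) 1),
       sf_shock("inc_gp_yr", function(t, p) ig),
       sf_shock("inc_psy_yr", function(t, p) ip),
       sf_shock("inc_cmhc_yr", function(t, p) ic))
}

#' Social-determinant pressure multiplier
#'
#' Weighted power product over adverse determinant levels relative to their
#' baseline references, times a protective sense-of-community term:
#' `prod((level/ref)^w) * (soc_ref/soc)^w_soc`. Equals 1 when every
#' determinant sits at its reference; non-decreasing in each adverse level
#' and non-increasing in the sense-of-community index.
#'
#' @param levels Named or unnamed numeric vector of adverse determinant
#'   levels (all positive).
#' @param refs Reference (baseline) values, same length as `levels`.
#' @param weights Non-negative exponents, same length as `levels`.
#' @param soc_index,soc_ref Sense-of-community index and its reference
#'   (optional protective term).
#' @param w_soc Exponent of the protective term.
#' @return The dimensionless pressure multiplier.
#' @examples
#' determinant_pressure(2, 1, 0.5)                      # sqrt(2)
#' determinant_pressure(numeric(), numeric(), numeric(),
#'                      soc_index = 8.24, soc_ref = 9.61, w_soc = 1)
#' @export
determinant_pressure <- function(levels, refs, weights,
                                 soc_index = NULL, soc_ref = NULL, w_soc = 0) {
  stopifnot(length(levels) == length(refs), length(levels) == length(weights))
  if (length(levels) && (any(levels <= 0) || any(refs <= 0)))
    stop("determinant levels and references must be positive")
  out <- if (length(levels)) prod((levels / refs)^weights) else 1
  if (!is.null(soc_index)) {
    if (soc_index <= 0 || soc_ref <= 0)
      stop("sense-of-community index and reference must be positive")
    out <- out * (soc_ref / soc_index)^w_soc
  }
  out
}

#' Capacity-constrained service throughput
#'
#' One service channel over a one-week window: total load is current demand
#' plus the waiting queue; at most `capacity` services are delivered, the
#' queue draining proportionally alongside new demand; unserved load is the
#' updated queue.
#'
#' @param demand New demand (persons/week).
#' @param waiting Persons currently waiting.
#' @param capacity Deliverable services/week.
#' @return Named numeric vector `c(served =, newly_waiting =)`.
#' @examples
#' service_throughput(30, 0, 20)   # served 20, newly_waiting 10
#' service_throughput(10, 15, 20)  # served 20, queue drops to 5
#' @export
service_throughput <- function(demand, waiting, capacity) {
  stopifnot(demand >= 0, waiting >= 0, capacity >= 0)
  total <- demand + waiting
  served <- min(total, capacity)
  c(served = served, newly_waiting = total - served)
}

#' Linear capacity growth over a time step
#'
#' @param capacity Current capacity (services/week).
#' @param yearly_increment Services/week added per 52-week year.
#' @param dt Step length in weeks.
#' @return Updated capacity.
#' @examples
#' grow_capacity(1000, 125.85, 52)  # one full year -> 1125.85
#' @export
grow_capacity <- function(capacity, yearly_increment, dt) {
  stopifnot(yearly_increment >= 0)
  capacity + yearly_increment * (dt / 52)
}

# stock and flow name vectors (single source of truth for indices)
mhsd_stock_names <- c("pop_0_14", "pop_15_24", "pop_25_64", "pop_65p",
                      "distress_low", "distress_mod", "distress_high",
                      "unemployed", "homeless", "substance_misuse",
                      "cap_gp", "cap_psy", "cap_cmhc", "cap_onl", "cap_out",
                      "cap_inp", "cap_ed",
                      "wait_gp", "wait_psy", "wait_cmhc", "wait_onl", "wait_out")

mhsd_flow_defs <- function() {
  f <- function(name, from = NA, to = NA) list(name = name, from = from, to = to)
  list(
    f("births", to = "pop_0_14"),
    f("aging_0_15", "pop_0_14", "pop_15_24"),
    f("aging_15_25", "pop_15_24", "pop_25_64"),
    f("aging_25_65", "pop_25_64", "pop_65p"),
    f("deaths_0_14", "pop_0_14"),
    f("deaths_15_24", "pop_15_24"),
    f("deaths_25_64", "pop_25_64"),
    f("deaths_65p", "pop_65p"),
    f("migration_0_14", to = "pop_0_14"),
    f("migration_15_24", to = "pop_15_24"),
    f("migration_25_64", to = "pop_25_64"),
    f("migration_65p", to = "pop_65p"),
    f("distress_entry_youth", to = "distress_low"),
    f("distress_migration_low", to = "distress_low"),
    f("distress_migration_mod", to = "distress_mod"),
    f("distress_migration_high", to = "distress_high"),
    f("distress_mortality_low", "distress_low"),
    f("distress_mortality_mod", "distress_mod"),
    f("distress_mortality_high", "distress_high"),
    f("onset_low_mod", "distress_low", "distress_mod"),
    f("onset_mod_high", "distress_mod", "distress_high"),
    f("remission_mod_low", "distress_mod", "distress_low"),
    f("remission_high_mod", "distress_high", "distress_mod"),
    f("recovery_services_mod", "distress_mod", "distress_low"),
    f("recovery_services_high", "distress_high", "distress_mod"),
    f("unemployment_inflow", to = "unemployed"),
    f("employment_initiation", "unemployed"),
    f("homelessness_inflow", to = "homeless"),
    f("homelessness_exit", "homeless"),
    f("substance_onset", to = "substance_misuse"),
    f("substance_recovery", "substance_misuse"),
    f("capacity_growth_gp", to = "cap_gp"),
    f("capacity_growth_psy", to = "cap_psy"),
    f("capacity_growth_cmhc", to = "cap_cmhc"),
    f("capacity_growth_onl", to = "cap_onl"),
    f("capacity_growth_out", to = "cap_out"),
    f("capacity_growth_inp", to = "cap_inp"),
    f("capacity_growth_ed", to = "cap_ed"),
    f("queue_join_gp", to = "wait_gp"),
    f("queue_serve_gp", "wait_gp"),
    f("queue_disengage_gp", "wait_gp"),
    f("queue_join_psy", to = "wait_psy"),
    f("queue_serve_psy", "wait_psy"),
    f("queue_disengage_psy", "wait_psy"),
    f("queue_join_cmhc", to = "wait_cmhc"),
    f("queue_serve_cmhc", "wait_cmhc"),
    f("queue_disengage_cmhc", "wait_cmhc"),
    f("queue_join_onl", to = "wait_onl"),
    f("queue_serve_onl", "wait_onl"),
    f("queue_disengage_onl", "wait_onl"),
    f("queue_join_out", to = "wait_out"),
    f("queue_serve_out", "wait_out"),
    f("queue_disengage_out", "wait_out"),
    f("attempts"),
    f("self_harm_hospitalization"),
    f("suicide_death", "distress_high"),
    f("suicide_death_pop", "pop_25_64"),
    f("ed_presentation"),
    f("psychiatric_admission")
  )
}

#' Initial stock levels implied by a parameter set
#'
#' @param params An [mhsd_params()] object.
#' @return Named numeric vector over the model's stocks.
#' @export
mhsd_initial_stocks <- function(params) {
  p <- params
  tot <- p$pop_total0
  P0 <- p$frac_0_14 * tot
  P1 <- p$frac_15_24 * tot
  P2 <- p$frac_25_64 * tot
  P3 <- tot - P0 - P1 - P2
  A <- P1 + P2 + P3
  DH <- p$init_high_share * A
  DM <- p$init_mod_share * A
  DL <- A - DH - DM
  stats::setNames(
    c(P0, P1, P2, P3, DL, DM, DH,
      p$unemp0, p$homeless0, p$subst0,
      p$cap_gp0, p$cap_psy0, p$cap_cmhc0, p$cap_onl0, p$cap_out0,
      p$cap_inp0, p$cap_ed0,
      0, 0, 0, 0, 0),
    mhsd_stock_names)
}

#' Build the regional mental health stock-and-flow model
#'
#' Wires the five sectors together: determinant pressure feeds distress
#' onset, attempt rates and disengagement; distress stocks feed service
#' demand; services deliver recoveries that move people down one distress
#' band; capacity stocks grow by their yearly increments; suicidal-behaviour
#' event flows drive the cumulative outcome counters (reset at the epoch).
#'
#' @param params An [mhsd_params()] object (may carry a `"shocks"` attribute
#'   installed by [apply_scenario()]).
#' @param epoch Reset epoch of the outcome counters (decimal year).
#' @return A validated [sf_model()].
#' @export
build_model <- function(params, epoch = 2021.0) {
  bad <- validate_params(params)
  if (length(bad))
    stop("missing or out-of-bounds parameter(s): ", paste(bad, collapse = ", "))
  p <- params
  # freeze every parameter into this frame so the per-step rate function
  # does scoped-variable lookups instead of repeated list indexing
  for (.nm in mhsd_param_table()$name) assign(.nm, p[[.nm]])

  sn <- mhsd_stock_names
  defs <- mhsd_flow_defs()
  fn <- vapply(defs, `[[`, "", "name")
  flows <- lapply(defs, function(d) sf_flow(d$name, d$from, d$to))
  si <- stats::setNames(seq_along(sn), sn)
  fi <- stats::setNames(seq_along(fn), fn)
  nF <- length(fn)

  # frozen scalars (everything constant over a run is resolved here, once)
  aging1 <- 1 / (15 * 52); aging2 <- 1 / (10 * 52); aging3 <- 1 / (40 * 52)
  u_in0 <- p$unemp0 * p$unemp_exit
  hm_in0 <- p$homeless0 * p$homeless_exit
  su_in0 <- p$subst0 * p$aod_referral_rate * (1 - p$relapse_frac)
  inc_wk <- c(p$inc_gp, p$inc_psy, p$inc_cmhc, p$inc_onl, p$inc_out,
              p$inc_inp, p$inc_ed) / 52

  iP0 <- si[["pop_0_14"]]; iP1 <- si[["pop_15_24"]]
  iP2 <- si[["pop_25_64"]]; iP3 <- si[["pop_65p"]]
  iDL <- si[["distress_low"]]; iDM <- si[["distress_mod"]]; iDH <- si[["distress_high"]]
  iU <- si[["unemployed"]]; iHM <- si[["homeless"]]; iSU <- si[["substance_misuse"]]
  iCgp <- si[["cap_gp"]]; iCpsy <- si[["cap_psy"]]; iCcm <- si[["cap_cmhc"]]
  iConl <- si[["cap_onl"]]; iCout <- si[["cap_out"]]; iCinp <- si[["cap_inp"]]
  iWgp <- si[["wait_gp"]]; iWpsy <- si[["wait_psy"]]; iWcm <- si[["wait_cmhc"]]
  iWonl <- si[["wait_onl"]]; iWout <- si[["wait_out"]]

  rate_fun <- function(x, pp, t, tv) {
    r <- numeric(nF)

    P0 <- x[iP0]; P1 <- x[iP1]; P2 <- x[iP2]; P3 <- x[iP3]
    DL <- x[iDL]; DM <- x[iDM]; DH <- x[iDH]
    U <- x[iU]; HM <- x[iHM]; SU <- x[iSU]

    u <- tv[[1L]]      # uptake
    soc <- tv[[2L]]    # soc_index
    f_u <- tv[[3L]]    # unemp_shock
    yamp <- tv[[4L]]   # youth_amp

    em_rec <- 1 + u * (m_rec - 1)
    em_ref <- 1 + u * (m_ref - 1)
    em_dis <- 1 + u * (m_dis - 1)
    em_aod <- 1 + u * (m_aod - 1)
    em_rel <- 1 + u * (m_rel - 1)
    em_emp <- 1 + u * (m_emp - 1)
    em_home <- 1 + u * (m_home - 1)
    em_cap <- 1 + u * (m_cap - 1)
    em_onl <- 1 + u * (m_onl - 1)

    # determinant pressure (static determinants sit at reference: factor 1)
    press <- (U * yamp / unemp0)^w_unemp *
      (HM / homeless0)^w_home *
      (SU / subst0)^w_subst *
      (soc_index0 / soc)^w_soc
    p_att <- press^gamma_attempt
    p_dis <- press^gamma_diseng
    dis_eff <- diseng_rate * em_dis * p_dis
    completion <- completion_rate / (completion_rate + dis_eff)

    # -- demography --------------------------------------------------------
    r[1L] <- births_weekly
    a1 <- aging1 * P0
    r[2L] <- a1
    r[3L] <- aging2 * P1
    r[4L] <- aging3 * P2
    d1 <- mort_15_24 * P1; d2 <- mort_25_64 * P2; d3 <- mort_65p * P3
    r[5L] <- mort_0_14 * P0
    r[6L] <- d1; r[7L] <- d2; r[8L] <- d3
    r[9L] <- mig_0_14; r[10L] <- mig_15_24
    r[11L] <- mig_25_64; r[12L] <- mig_65p
    DT <- DL + DM + DH
    sL <- DL / DT; sM <- DM / DT; sH <- DH / DT
    AM <- mig_15_24 + mig_25_64 + mig_65p
    AD <- d1 + d2 + d3
    r[13L] <- a1
    r[14L] <- AM * sL; r[15L] <- AM * sM; r[16L] <- AM * sH
    r[17L] <- AD * sL; r[18L] <- AD * sM; r[19L] <- AD * sH

    # -- distress transitions ----------------------------------------------
    r[20L] <- onset_low_mod * press * DL
    r[21L] <- onset_mod_high * press * DM
    r[22L] <- remit_mod_low * DM
    r[23L] <- remit_high_mod * DH

    # -- service channels --------------------------------------------------
    # GP (mixed bands; queue composition approximated by the demand mix)
    d_gp_mod <- seek_mod_gp * DM
    d_gp_high <- seek_high_gp * DH
    d_gp <- d_gp_mod + d_gp_high
    Wgp <- x[iWgp]
    tot_gp <- d_gp + Wgp
    served_gp <- min(tot_gp, x[iCgp])
    frac_served_gp <- if (tot_gp > 0) served_gp / tot_gp else 0
    r[39L] <- d_gp * (1 - frac_served_gp)      # queue_join_gp
    r[40L] <- Wgp * frac_served_gp             # queue_serve_gp
    r[41L] <- dis_eff * Wgp                    # queue_disengage_gp
    share_high <- if (d_gp > 0) d_gp_high / d_gp else 0
    served_gp_high <- served_gp * share_high
    served_gp_mod <- served_gp - served_gp_high
    ref_frac_high <- min(1, p_ref_high * em_ref)
    ref_frac_onl <- min(1, p_ref_onl * em_onl)
    ref_spec <- ref_frac_high * served_gp_high
    ref_onl <- ref_frac_onl * served_gp_mod

    # psychiatrist + allied (high band; capacity scaled by em_cap)
    d_psy <- seek_high_psy * DH + ref_spec
    Wpsy <- x[iWpsy]
    tot_psy <- d_psy + Wpsy
    served_psy <- min(tot_psy, x[iCpsy] * em_cap)
    fpsy <- if (tot_psy > 0) served_psy / tot_psy else 0
    r[42L] <- d_psy * (1 - fpsy)
    r[43L] <- Wpsy * fpsy
    r[44L] <- dis_eff * Wpsy

    # CMHC (high band)
    d_cm <- seek_high_cmhc * DH
    Wcm <- x[iWcm]
    tot_cm <- d_cm + Wcm
    served_cm <- min(tot_cm, x[iCcm])
    fcm <- if (tot_cm > 0) served_cm / tot_cm else 0
    r[45L] <- d_cm * (1 - fcm)
    r[46L] <- Wcm * fcm
    r[47L] <- dis_eff * Wcm

    # online (moderate band)
    d_onl <- seek_mod_onl * DM + ref_onl
    Wonl <- x[iWonl]
    tot_onl <- d_onl + Wonl
    served_onl <- min(tot_onl, x[iConl])
    fonl <- if (tot_onl > 0) served_onl / tot_onl else 0
    r[48L] <- d_onl * (1 - fonl)
    r[49L] <- Wonl * fonl
    r[50L] <- dis_eff * Wonl

    # outpatient (high band)
    d_out <- seek_high_out * DH
    Wout <- x[iWout]
    tot_out <- d_out + Wout
    served_out <- min(tot_out, x[iCout])
    fout <- if (tot_out > 0) served_out / tot_out else 0
    r[51L] <- d_out * (1 - fout)
    r[52L] <- Wout * fout
    r[53L] <- dis_eff * Wout

    # -- suicidal behaviour -------------------------------------------------
    attempts <- (att_high * DH + att_mod * DM) * p_att
    r[54L] <- attempts
    r[55L] <- hosp_frac * attempts
    sui <- case_fatality * attempts
    r[56L] <- sui
    r[57L] <- sui
    served_high_tot <- served_psy + served_cm + served_out + served_gp_high
    untreated_high <- max(DH - care_protect_weeks * served_high_tot, 0)
    ed_pres <- crisis_share * attempts + ed_untreated_rate * untreated_high
    r[58L] <- ed_pres
    admissions <- min(admit_frac * ed_pres, x[iCinp])
    r[59L] <- admissions

    # -- recoveries (fed back into the distress sector) --------------------
    recfac <- rec_scale * em_rec
    r[24L] <- recfac * (rec_gp_mod * served_gp_mod * (1 - ref_frac_onl) +
                          rec_onl * served_onl)
    r[25L] <- recfac * (rec_gp_high * served_gp_high * (1 - ref_frac_high) +
                          completion * (rec_psy * served_psy +
                                          rec_cmhc * served_cm +
                                          rec_out * served_out) +
                          rec_inp * admissions)

    # -- social determinants ------------------------------------------------
    r[26L] <- u_in0 * f_u
    r[27L] <- unemp_exit * em_emp * U
    r[28L] <- hm_in0
    r[29L] <- homeless_exit * em_home * HM
    r[30L] <- su_in0
    r[31L] <- aod_referral_rate * em_aod * (1 - relapse_frac * em_rel) * SU

    # -- capacity growth (GP/psy/CMHC increments are time-profiled) ---------
    r[32L] <- tv[[5L]] / 52; r[33L] <- tv[[6L]] / 52; r[34L] <- tv[[7L]] / 52
    r[35L] <- inc_wk[4L]; r[36L] <- inc_wk[5L]; r[37L] <- inc_wk[6L]
    r[38L] <- inc_wk[7L]

    r
  }

  report <- function(x, pp, t, tv) {
    DT <- x[["distress_low"]] + x[["distress_mod"]] + x[["distress_high"]]
    press <- (x[["unemployed"]] * tv[["youth_amp"]] / unemp0)^w_unemp *
      (x[["homeless"]] / homeless0)^w_home *
      (x[["substance_misuse"]] / subst0)^w_subst *
      (soc_index0 / tv[["soc_index"]])^w_soc
    c(prevalence_high = x[["distress_high"]] / DT,
      adults = DT,
      pressure = press,
      uptake = tv[["uptake"]])
  }

  shocks <- attr(params, "shocks")
  if (is.null(shocks)) shocks <- mhsd_default_shocks(params)
  ord <- match(MHSD_TV, vapply(shocks, `[[`, "", "name"))
  if (anyNA(ord)) stop("shock set must define: ", paste(MHSD_TV, collapse = ", "))
  shocks <- shocks[ord]  # rate_fun reads tv by position

  counters <- list(
    sf_counter("self_harm_hospitalizations", "self_harm_hospitalization", epoch),
    sf_counter("suicide_deaths", "suicide_death", epoch),
    sf_counter("ed_presentations", "ed_presentation", epoch))

  sf_model(stocks = mhsd_initial_stocks(params), flows = flows,
           counters = counters, shocks = shocks, rate_fun = rate_fun,
           report = report, name = "regional mental health system")
}

#' Simulate the regional model
#'
#' Convenience wrapper: optionally applies an intervention scenario and a
#' pandemic condition set to the parameters, builds the model and
#' integrates it.
#'
#' @param params An [mhsd_params()] object.
#' @param scenario Optional [scenario_spec()] (or name of a built-in
#'   scenario, e.g. `"business_as_usual"`).
#' @param covid Optional [covid_conditions()] (or `"pre"` / `"post"`).
#' @param config An [sf_config()].
#' @return An `sf_trajectory`.
#' @examples
#' \donttest{
#' tr <- mhsd_simulate(config = sf_config(2011, 2030, dt = 1 / 4))
#' outcome_summary(tr)
#' }
#' @export
mhsd_simulate <- function(params = mhsd_params(), scenario = NULL,
                          covid = NULL, config = sf_config()) {
  if (is.character(scenario)) scenario <- builtin_scenarios()[[scenario]]
  if (is.character(covid)) covid <- covid_conditions(covid)
  if (!is.null(scenario) || !is.null(covid)) {
    if (is.null(scenario)) scenario <- builtin_scenarios()[["business_as_usual"]]
    if (is.null(covid)) covid <- covid_conditions("pre")
    params <- apply_scenario(params, scenario, covid)
  }
  integrate_model(build_model(params), params = params, config = config)
}

#' Cumulative outcomes of a run
#'
#' Reads the three cumulative outcome counters at the end of the horizon and
#' the high-distress prevalence (as a percentage of the modelled adult
#' population) at the start and end of the outcome window.
#'
#' @param traj An `sf_trajectory` from the regional model.
#' @param start,end Outcome window in decimal years; the trajectory must
#'   cover it.
#' @return An object of class `"mhsd_summary"`: a list with
#'   `self_harm_hospitalizations`, `suicide_deaths`, `ed_presentations`
#'   (cumulative counts), `prevalence_start`, `prevalence_end` (percent).
#' @export
outcome_summary <- function(traj, start = 2021, end = 2030) {
  t0 <- traj$times[1L]; t1 <- traj$times[length(traj$times)]
  if (t0 > start + 1e-9 || t1 < end - 1e-9)
    stop(sprintf("trajectory covers [%.2f, %.2f] but the outcome window is [%.2f, %.2f]",
                 t0, t1, start, end))
  prev <- function(tt) {
    if (!is.null(traj$report) && "prevalence_high" %in% colnames(traj$report))
      traj_value_at(traj, tt, "prevalence_high", "report") * 100
    else {
      i <- which.min(abs(traj$times - tt))
      s <- traj$stocks[i, ]
      100 * s[["distress_high"]] /
        (s[["distress_low"]] + s[["distress_mod"]] + s[["distress_high"]])
    }
  }
  cnt <- function(nm) {
    i <- which.min(abs(traj$times - end))
    traj$counter_series[i, nm]
  }
  structure(list(self_harm_hospitalizations = unname(cnt("self_harm_hospitalizations")),
                 suicide_deaths = unname(cnt("suicide_deaths")),
                 ed_presentations = unname(cnt("ed_presentations")),
                 prevalence_start = unname(prev(start)),
                 prevalence_end = unname(prev(end)),
                 window = c(start, end)),
            class = "mhsd_summary")
}

#' @export
print.mhsd_summary <- function(x, ...) {
  cat(sprintf("Cumulative outcomes, %.1f-%.1f:\n", x$window[1L], x$window[2L]))
  cat(sprintf("  self-harm hospitalizations  %10.0f\n", x$self_harm_hospitalizations))
  cat(sprintf("  suicide deaths              %10.0f\n", x$suicide_deaths))
  cat(sprintf("  MH-related ED presentations %10.0f\n", x$ed_presentations))
  cat(sprintf("  high-distress prevalence    %.2f%% (%.0f) -> %.2f%% (%.0f)\n",
              x$prevalence_start, x$window[1L], x$prevalence_end, x$window[2L]))
  invisible(x)
}

#' Export a cumulative outcome summary to CSV
#'
#' @param summary An `"mhsd_summary"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  df <- data.frame(
    quantity = c("self_harm_hospitalizations", "suicide_deaths",
                 "ed_presentations", "prevalence_start_pct", "prevalence_end_pct"),
    value = c(summary$self_harm_hospitalizations, summary$suicide_deaths,
              summary$ed_presentations, summary$prevalence_start,
              summary$prevalence_end))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# yearly historic-style indicator series from a trajectory (for calibration
# against 2011-2017 validation data)
mhsd_yearly_indicators <- function(traj, years = 2011:2017) {
  prev <- vapply(years + 0.5, function(tt)
    traj_value_at(traj, tt, "prevalence_high", "report"), 0)
  data.frame(
    year = rep(years, 5L),
    indicator = rep(c("distress_prevalence", "psychiatric_hospitalizations",
                      "ed_presentations", "self_harm_hospitalizations",
                      "suicide_deaths"), each = length(years)),
    value = c(prev,
              flow_yearly_totals(traj, "psychiatric_admission", years),
              flow_yearly_totals(traj, "ed_presentation", years),
              flow_yearly_totals(traj, "self_harm_hospitalization", years),
              flow_yearly_totals(traj, "suicide_death", years)))
}
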