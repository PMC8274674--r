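# shared fixtures: small hand-built stock-flow models and coarse integration
# settings used to keep the default test run fast

cfg_fast <- function(t_start = 2011, t_end = 2030)
  sf_config(t_start, t_end, dt = 1 / 2, record_every = 2L)

cfg_mid <- function(t_start = 2011, t_end = 2030)
  sf_config(t_start, t_end, dt = 1 / 4, record_every = 4L)

# single decaying stock: dS/dt = -k S per week
decay_model <- function(S0 = 100)
  sf_model(stocks = c(S = S0),
           flows = list(sf_flow("decay", from = "S",
                                rate = function(x, p, t, aux) p$k * x[["S"]])),
           name = "decay")

# closed two-stock exchange (nonlinear rates); total mass is conserved
closed_exchange_model <- function(A0 = 60, B0 = 40)
  sf_model(stocks = c(A = A0, B = B0),
           flows = list(
             sf_flow("ab", from = "A", to = "B",
                     rate = function(x, p, t, aux) 0.05 * x[["A"]]),
             sf_flow("ba", from = "B", to = "A",
                     rate = function(x, p, t, aux) 0.02 * sqrt(x[["B"]] + 1) * x[["B"]] / 40)),
           name = "closed exchange")

# an outcome summary assembled from given numbers (for comparison arithmetic)
make_summary <- function(sh, sd, ed, prev_start, prev_end,
                         window = c(2021, 2030))
  structure(list(self_harm_hospitalizations = sh, suicide_deaths = sd,
                 ed_presentations = ed, prevalence_start = prev_start,
                 prevalence_end = prev_end, window = window),
            class = "mhsd_summary")

# parameters with every pathway into the outcome counters switched off
params_all_off <- function()
  mhsd_params(onset_low_mod = 0, onset_mod_high = 0, att_high = 0,
              att_mod = 0, ed_untreated_rate = 0, crisis_share = 0,
              seek_mod_gp = 0, seek_high_gp = 0, seek_high_psy = 0,
              seek_high_cmhc = 0, seek_high_out = 0, seek_mod_onl = 0)
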