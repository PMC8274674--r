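# Latin hypercube sensitivity analysis over the direct intervention-effect
# parameters, with percentile-interval summaries of the outcome comparisons.
#
# Intervals are the 2.5th/97.5th empirical percentiles (type-7 quantiles) of
# the replicate distribution: a parameter-uncertainty band, explicitly NOT a
# confidence interval.

#' Define a Latin hypercube design
#'
#' Each parameter is sampled from `Uniform(nominal * (1 - h), nominal * (1 + h))`
#' with exactly one draw per equal-probability stratum (the LHS property),
#' column permutations independent across parameters, reproducibly under the
#' seed.
#'
#' @param nominal Named numeric vector of positive nominal parameter values.
#' @param n Number of samples (default 100).
#' @param half_width Relative half-width `h` of the uniform band (default
#'   0.20, i.e. +/-20\% of the nominal value); must be < 1 so sampled values
#'   stay positive.
#' @param seed Integer seed.
#' @return An object of class `"lhs_design"`.
#' @export
lhs_design <- function(nominal, n = 100L, half_width = 0.20, seed = 1L) {
  stopifnot(is.numeric(nominal), length(nominal) >= 1L,
            !is.null(names(nominal)), all(nzchar(names(nominal))))
  if (any(nominal <= 0)) stop("nominal values must be positive")
  if (n < 2L) stop("n must be at least 2")
  if (half_width < 0 || half_width >= 1)
    stop("half_width must lie in [0, 1) so sampled values stay positive")
  structure(list(nominal = nominal, n = as.integer(n),
                 half_width = half_width, seed = as.integer(seed)),
            class = "lhs_design")
}

#' @export
print.lhs_design <- function(x, ...) {
  cat(sprintf("<lhs_design> %d samples, +/-%.0f%%, seed %d\n",
              x$n, 100 * x$half_width, x$seed))
  cat("  parameters:", paste(names(x$nominal), collapse = ", "), "\n")
  invisible(x)
}

#' Draw the Latin hypercube sample
#'
#' @param design An [lhs_design()].
#' @return Numeric matrix `n x k` with one column per parameter; each column
#'   contains exactly one value in each of the `n` equal-width strata of its
#'   uniform band.
#' @examples
#' s <- lhs_sample(lhs_design(c(m = 1), n = 4, half_width = 0.2, seed = 1))
#' sort(floor((s[, "m"] - 0.8) / 0.1))  # 0 1 2 3: one draw per stratum
#' @export
lhs_sample <- function(design) {
  k <- length(design$nominal)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)
  u <- lhs::randomLHS(design$n, k)
  lo <- design$nominal * (1 - design$half_width)
  hi <- design$nominal * (1 + design$half_width)
  out <- sweep(sweep(u, 2L, hi - lo, "*"), 2L, lo, "+")
  colnames(out) <- names(design$nominal)
  out
}

#' Default sensitivity design for a scenario
#'
#' Covers the scenario's direct-effect parameters: the maximum rate per
#' service (when non-zero), every effect multiplier that differs from 1, and
#' every capacity increment that differs from the business-as-usual
#' schedule.
#'
#' @param spec A [scenario_spec()].
#' @param params Baseline [mhsd_params()] (supplies the reference capacity
#'   increments).
#' @param n,half_width,seed Passed to [lhs_design()].
#' @return An [lhs_design()].
#' @export
scenario_lhs_design <- function(spec, params = mhsd_params(), n = 100L,
                                half_width = 0.20, seed = 1L) {
  nom <- c(if (spec$u_max > 0) c(u_max = spec$u_max),
           spec$multipliers[spec$multipliers != 1],
           if (spec$inc_gp != params$inc_gp) c(inc_gp = spec$inc_gp),
           if (spec$inc_psy != params$inc_psy) c(inc_psy = spec$inc_psy),
           if (spec$inc_cmhc != params$inc_cmhc) c(inc_cmhc = spec$inc_cmhc))
  if (!length(nom))
    stop("scenario '", spec$name, "' has no direct-effect parameters to sample")
  lhs_design(nom, n = n, half_width = half_width, seed = seed)
}

# apply one sampled row to a scenario spec
spec_with_draw <- function(spec, draw) {
  for (nm in names(draw)) {
    v <- unname(draw[[nm]])
    if (nm == "u_max") spec$u_max <- min(max(v, 0), 1)
    else if (nm %in% names(spec$multipliers)) spec$multipliers[[nm]] <- max(v, 1e-8)
    else if (nm %in% c("inc_gp", "inc_psy", "inc_cmhc")) spec[[nm]] <- max(v, 0)
    else stop("sampled parameter '", nm, "' is not a scenario direct-effect parameter")
  }
  spec
}

#' Run the Latin hypercube sensitivity analysis
#'
#' For each sampled parameter set the intervention scenario is re-run and
#' compared against the business-as-usual baseline (which does not depend on
#' the sampled direct-effect parameters and is therefore computed once);
#' each comparison metric is summarised by its value at the nominal
#' parameters (central) and the empirical 2.5th/97.5th percentiles across
#' replicates.
#'
#' @param params Baseline [mhsd_params()].
#' @param spec The intervention [scenario_spec()].
#' @param design An [lhs_design()] over the scenario's direct-effect
#'   parameters (default [scenario_lhs_design()]).
#' @param covid A [covid_conditions()] object or `"pre"`/`"post"`.
#' @param config An [sf_config()].
#' @return An object of class `"sensitivity_result"`: `intervals` (one row
#'   per outcome metric with `central`, `lower`, `upper`, `n_replicates`)
#'   and `replicates` (metric values per replicate).
#' @export
run_sensitivity <- function(params = mhsd_params(), spec,
                            design = scenario_lhs_design(spec, params),
                            covid = covid_conditions("pre"),
                            config = sf_config()) {
  if (is.character(covid)) covid <- covid_conditions(covid)
  draws <- lhs_sample(design)
  win_end <- min(2030, config$t_end)
  base_tr <- mhsd_simulate(params, scenario = "business_as_usual",
                           covid = covid, config = config)
  base <- outcome_summary(base_tr, end = win_end)
  metrics <- c("pct_reduction_self_harm", "pct_reduction_suicide",
               "pct_reduction_ed", "pp_reduction_prevalence",
               "prevented_self_harm", "prevented_suicides", "prevented_ed")
  one <- function(sp) {
    tr <- mhsd_simulate(params, scenario = sp, covid = covid, config = config)
    cmp <- compare_outcomes(base, outcome_summary(tr, end = win_end))
    unlist(cmp[metrics])
  }
  central <- one(spec)
  rep_vals <- matrix(NA_real_, design$n, length(metrics),
                     dimnames = list(NULL, metrics))
  failed <- integer()
  for (i in seq_len(design$n)) {
    v <- tryCatch(one(spec_with_draw(spec, draws[i, ])), error = function(e) {
      warning(sprintf("replicate %d failed and was excluded: %s", i,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(v)) failed <- c(failed, i) else rep_vals[i, ] <- v
  }
  if (length(failed) > 0.05 * design$n)
    stop("more than 5% of replicates failed integration (",
         length(failed), " of ", design$n, ")")
  ok <- rep_vals[setdiff(seq_len(design$n), failed), , drop = FALSE]
  qs <- apply(ok, 2L, stats::quantile, probs = c(0.025, 0.975),
              type = 7, names = FALSE)
  intervals <- data.frame(metric = metrics, central = unname(central),
                          lower = qs[1L, ], upper = qs[2L, ],
                          n_replicates = nrow(ok))
  rownames(intervals) <- NULL
  structure(list(intervals = intervals,
                 replicates = as.data.frame(cbind(replicate = setdiff(seq_len(design$n), failed), ok)),
                 design = design, scenario = spec$name,
                 covid = covid$condition),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %s (%s pandemic conditions), %d replicates, +/-%.0f%%\n",
              x$scenario, x$covid, x$intervals$n_replicates[1L],
              100 * x$design$half_width))
  cat("95% intervals (2.5th-97.5th percentiles; not confidence intervals):\n")
  for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  %-26s %9.3f  [%9.3f, %9.3f]\n", x$intervals$metric[i],
                x$intervals$central[i], x$intervals$lower[i],
                x$intervals$upper[i]))
  invisible(x)
}

#' Write sensitivity outputs to CSV
#'
#' @param result A `"sensitivity_result"`.
#' @param intervals_path,replicates_path Output file paths (either may be
#'   `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_sensitivity_csv <- function(result, intervals_path = NULL,
                                  replicates_path = NULL) {
  if (!is.null(intervals_path))
    utils::write.csv(result$intervals, intervals_path, row.names = FALSE)
  if (!is.null(replicates_path))
    utils::write.csv(result$replicates, replicates_path, row.names = FALSE)
  invisible(c(intervals_path, replicates_path))
}
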