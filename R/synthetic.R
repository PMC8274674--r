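# Synthetic historic indicator series (2011-2017) and packaged calibration
# targets, so every other module is testable without any data download.
#
# The generator emulates the statistical shape of regional surveillance
# series for a ~500k population: smooth (linear) trends with Poisson noise
# on yearly event counts and Gaussian noise on the logit scale for the
# distress prevalence. Default trend levels are consistent with the model's
# own business-as-usual trajectory (roughly 1,300 self-harm hospitalizations
# and 100 suicide deaths per year), so that 9-year cumulative forecasts land
# near the printed baseline anchors.

mhsd_historic_indicators <- c("distress_prevalence",
                              "psychiatric_hospitalizations",
                              "ed_presentations",
                              "self_harm_hospitalizations",
                              "suicide_deaths")

#' Default generating trends for the synthetic historic series
#'
#' @return Named list, one element per indicator, each `c(level =, slope =)`
#'   (level at 2011, change per year; prevalence on the proportion scale).
#' @export
default_historic_trends <- function() {
  list(distress_prevalence = c(level = 0.187, slope = -0.00074),
       psychiatric_hospitalizations = c(level = 937, slope = 3.2),
       ed_presentations = c(level = 9372, slope = 32),
       self_harm_hospitalizations = c(level = 1328, slope = 10.7),
       suicide_deaths = c(level = 103, slope = 0.83))
}

#' Generate a synthetic historic indicator series
#'
#' Draws yearly values 2011-2017 for the five validation indicators around
#' linear trends: Poisson counts for the four event indicators, logit-scale
#' Gaussian noise for the distress prevalence. The generating truth is
#' attached for recovery tests.
#'
#' @param trends Named list of `c(level, slope)` per indicator (see
#'   [default_historic_trends()]).
#' @param seed Integer seed; regeneration with the same seed is
#'   bit-identical.
#' @param noise If `FALSE`, the series equals the trend exactly.
#' @param years Years to generate.
#' @param logit_sd Standard deviation of the prevalence noise on the logit
#'   scale.
#' @return A data.frame of class `"synthetic_historic"` with columns `year`,
#'   `indicator`, `value`, and attributes `trends` and `seed`.
#' @export
generate_historic <- function(trends = default_historic_trends(), seed = 1L,
                              noise = TRUE, years = 2011:2017,
                              logit_sd = 0.02) {
  missing_ind <- setdiff(mhsd_historic_indicators, names(trends))
  if (length(missing_ind))
    stop("trends missing for indicator(s): ", paste(missing_ind, collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- lapply(mhsd_historic_indicators, function(ind) {
    tr <- trends[[ind]]
    mu <- tr[["level"]] + tr[["slope"]] * (years - years[1L])
    if (ind == "distress_prevalence") {
      if (any(mu <= 0 | mu >= 1))
        stop("trend implies prevalence outside (0, 1)")
      v <- if (noise) stats::plogis(stats::qlogis(mu) + stats::rnorm(length(mu), 0, logit_sd)) else mu
    } else {
      if (any(mu < 0)) stop("trend implies negative expected counts for ", ind)
      v <- if (noise) stats::rpois(length(mu), mu) else mu
    }
    data.frame(year = years, indicator = ind, value = as.numeric(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, trends = trends, seed = seed,
            class = c("synthetic_historic", "data.frame"))
}

#' Read/write a historic indicator series as CSV
#'
#' Schema: columns `year` (integer), `indicator` (one of the five validation
#' indicators), `value` (numeric; prevalence as a proportion).
#'
#' @param historic A data.frame with columns `year`, `indicator`, `value`.
#' @param path File path.
#' @return `write_historic_csv()` returns `path` invisibly;
#'   `read_historic_csv()` returns the data.frame.
#' @export
write_historic_csv <- function(historic, path) {
  utils::write.csv(as.data.frame(historic)[c("year", "indicator", "value")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_historic_csv
#' @export
read_historic_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "indicator", "value")
  if (!all(need %in% names(df)))
    stop("historic CSV must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Packaged baseline calibration targets
#'
#' Bundles the five forecast anchors of the business-as-usual baseline --
#' cumulative 2021-2030 self-harm hospitalizations (12,274), suicide deaths
#' (953) and MH-related ED presentations (81,263), plus high-distress
#' prevalence at 2021 (17.60\%) and 2030 (15.60\%) -- with default weights
#' and tolerances, alongside a generated synthetic historic series.
#'
#' @param seed Seed for the synthetic historic series.
#' @param include_historic Include the 2011-2017 synthetic series as
#'   low-weight targets.
#' @param historic_weight Weight given to each historic row (anchors have
#'   weight 1).
#' @param anchor_tolerance,historic_tolerance Relative-error tolerances used
#'   by the calibration convergence flag.
#' @return A [calibration_targets()] object.
#' @examples
#' tg <- generate_baseline_anchors()
#' subset(tg, type == "anchor")
#' @export
generate_baseline_anchors <- function(seed = 1L, include_historic = TRUE,
                                      historic_weight = 0.02,
                                      anchor_tolerance = 0.01,
                                      historic_tolerance = 0.05) {
  anchors <- data.frame(
    name = c("cum_self_harm", "cum_suicide", "cum_ed", "prev_2021", "prev_2030"),
    type = "anchor", indicator = NA_character_, year = NA_integer_,
    value = c(12274, 953, 81263, 17.60, 15.60),
    weight = 1, tolerance = anchor_tolerance)
  if (include_historic) {
    h <- generate_historic(seed = seed)
    hrows <- data.frame(
      name = paste0(h$indicator, "_", h$year),
      type = "historic", indicator = h$indicator, year = h$year,
      value = h$value, weight = historic_weight, tolerance = historic_tolerance)
    anchors <- rbind(anchors, hrows)
  }
  calibration_targets(anchors)
}
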