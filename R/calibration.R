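# Constrained calibration of free model parameters against forecast anchors
# and historic indicator series: weighted sum of squared relative errors,
# minimised by bounded derivative-free local search (Nelder-Mead on a
# logit-rescaled box) from Latin-hypercube starting points, with a final
# refinement at the reporting step size.

#' Define calibration targets
#'
#' @param targets A data.frame with columns `name` (unique), `type`
#'   (`"anchor"` for cumulative/prevalence forecast anchors or `"historic"`
#'   for yearly indicator values), `indicator`, `year` (for historic rows),
#'   `value`, `weight` (> 0) and `tolerance` (finite relative-error
#'   tolerance used by the convergence flag).
#' @return The validated data.frame, classed `"calibration_targets"`.
#' @export
calibration_targets <- function(targets) {
  need <- c("name", "type", "indicator", "year", "value", "weight", "tolerance")
  if (!all(need %in% names(targets)))
    stop("targets must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(targets$name)) stop("duplicate target names")
  if (any(!is.finite(targets$weight)) || any(targets$weight <= 0))
    stop("every target needs a positive weight")
  if (any(!is.finite(targets$tolerance)))
    stop("every target needs a finite tolerance")
  if (!all(targets$type %in% c("anchor", "historic")))
    stop("target type must be 'anchor' or 'historic'")
  class(targets) <- c("calibration_targets", "data.frame")
  targets
}

# run the model once and extract every target-comparable quantity
simulate_target_values <- function(params, targets, config) {
  tr <- mhsd_simulate(params, config = config)
  out <- numeric(nrow(targets))
  need_hist <- any(targets$type == "historic")
  yi <- if (need_hist) {
    years <- sort(unique(targets$year[targets$type == "historic"]))
    mhsd_yearly_indicators(tr, years)
  }
  summ <- outcome_summary(tr, end = min(2030, config$t_end))
  for (i in seq_len(nrow(targets))) {
    if (targets$type[i] == "anchor") {
      out[i] <- switch(targets$name[i],
                       cum_self_harm = summ$self_harm_hospitalizations,
                       cum_suicide = summ$suicide_deaths,
                       cum_ed = summ$ed_presentations,
                       prev_2021 = summ$prevalence_start,
                       prev_2030 = summ$prevalence_end,
                       stop("unknown anchor target: ", targets$name[i]))
    } else {
      j <- which(yi$indicator == targets$indicator[i] & yi$year == targets$year[i])
      if (!length(j)) stop("historic target outside simulated years: ", targets$name[i])
      out[i] <- yi$value[j]
    }
  }
  stats::setNames(out, targets$name)
}

# weighted sum of squared relative errors; zero-valued observations fall
# back to absolute error (documented scale: 1 unit of the target)
target_sse <- function(sim, targets) {
  obs <- targets$value
  err <- ifelse(obs == 0, sim - obs, (sim - obs) / obs)
  sum(targets$weight * err^2)
}

#' Calibration objective
#'
#' Weighted sum of squared relative errors between simulated and observed
#' target values, `sum(w * ((sim - obs)/obs)^2)`; zero iff every target is
#' matched exactly. A target whose observed value is zero contributes its
#' absolute error instead (on the target's own unit scale).
#'
#' @param params An [mhsd_params()] object (within bounds).
#' @param targets A [calibration_targets()] object.
#' @param config An [sf_config()] used for the model run.
#' @return Non-negative scalar.
#' @export
objective_value <- function(params, targets, config = sf_config()) {
  bad <- validate_params(params)
  if (length(bad)) stop("parameters out of bounds: ", paste(bad, collapse = ", "))
  sim <- simulate_target_values(params, targets, config)
  v <- target_sse(sim, targets)
  if (!is.finite(v))
    stop("non-finite objective at parameters: ",
         paste(sprintf("%s=%g", names(params), unlist(params)), collapse = ", "))
  v
}

#' Default free-parameter set for baseline calibration
#'
#' The ~10 parameters that most directly shape the baseline anchors:
#' distress onset rates and initial split, the attempt rate and case
#' fatality, the ED rates, the specialist recovery/demand rates. Bounds are
#' +/-30\% of the current value, clipped to the declared parameter bounds.
#'
#' @param params An [mhsd_params()] object providing the centre values.
#' @param rel Half-width of the search box relative to the centre value.
#' @return Named list of `c(lower, upper)` bounds.
#' @export
default_free_set <- function(params = mhsd_params(), rel = 0.30) {
  nms <- c("onset_low_mod", "onset_mod_high", "init_high_share",
           "init_mod_share", "att_high", "case_fatality",
           "ed_untreated_rate", "crisis_share", "rec_psy", "seek_high_psy")
  tab <- mhsd_param_table()
  out <- lapply(nms, function(nm) {
    v <- params[[nm]]
    i <- match(nm, tab$name)
    c(max(v * (1 - rel), tab$min[i]), min(v * (1 + rel), tab$max[i]))
  })
  stats::setNames(out, nms)
}

# bounded Nelder-Mead via a scaled-logit reparametrisation of the box
nm_bounded <- function(fn, x0, lo, hi, maxit) {
  to_z <- function(x) stats::qlogis(pmin(pmax((x - lo) / (hi - lo), 1e-6), 1 - 1e-6))
  to_x <- function(z) lo + (hi - lo) * stats::plogis(z)
  n_eval <- 0L
  wrapped <- function(z) { n_eval <<- n_eval + 1L; fn(to_x(z)) }
  res <- stats::optim(to_z(x0), wrapped, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  list(par = to_x(res$par), value = res$value, n_eval = n_eval)
}

#' Calibrate free model parameters against targets
#'
#' Minimises [objective_value()] over a bounded box of free parameters by
#' multi-start bounded Nelder-Mead: `n_starts` Latin-hypercube starting
#' points (plus the current values) are screened at the search step size,
#' local search proceeds from the best, and the result is refined at the
#' (finer) reporting step size. Fixed seed implies a reproducible fit.
#'
#' @param params Full [mhsd_params()] set; non-free parameters stay pinned.
#' @param targets A [calibration_targets()] object (default: the packaged
#'   baseline anchors, [generate_baseline_anchors()]).
#' @param free Named list of `c(lower, upper)` bounds for the free
#'   parameters, or a character vector of parameter names (bounds then
#'   default to +/-30\% of the current values); zero free parameters is
#'   allowed and evaluates the objective once.
#' @param seed Integer seed (drives the Latin-hypercube starts).
#' @param n_starts Number of Latin-hypercube starting points.
#' @param search_config,final_config Step-size configurations for the search
#'   and refinement phases.
#' @param maxit_search,maxit_final Nelder-Mead iteration budgets.
#' @return An object of class `"mhsd_fit"`: fitted parameter values
#'   (`coef()`), objective value, per-target relative errors, convergence
#'   flag (`TRUE` iff every target's relative error is within its
#'   tolerance), the updated parameter set (`fitted_params()`), seed and
#'   evaluation counts.
#' @export
calibrate <- function(params = mhsd_params(),
                      targets = generate_baseline_anchors(),
                      free = default_free_set(params), seed = 1L,
                      n_starts = 10L,
                      search_config = sf_config(dt = 1 / 4, record_every = 4L),
                      final_config = sf_config(dt = 1 / 16),
                      maxit_search = 150L, maxit_final = 80L) {
  stopifnot(inherits(targets, "calibration_targets"))
  if (is.character(free)) free <- default_free_set(params)[free]
  nms <- names(free)
  k <- length(free)

  make_params <- function(x) {
    p <- params
    for (j in seq_len(k)) p[[nms[j]]] <- unname(x[j])
    p
  }
  rel_errors <- function(p, config) {
    sim <- simulate_target_values(p, targets, config)
    obs <- targets$value
    stats::setNames(ifelse(obs == 0, sim - obs, (sim - obs) / obs), targets$name)
  }

  if (k == 0L) {
    val <- objective_value(params, targets, final_config)
    re <- rel_errors(params, final_config)
    return(structure(list(par = numeric(), value = val, rel_errors = re,
                          converged = all(abs(re) <= targets$tolerance),
                          params = params, free = free, seed = seed,
                          n_eval = 1L), class = "mhsd_fit"))
  }

  lo <- vapply(free, `[`, 0, 1L)
  hi <- vapply(free, `[`, 0, 2L)
  x0 <- pmin(pmax(vapply(nms, function(nm) params[[nm]], 0), lo), hi)

  n_eval <- 0L
  obj_at <- function(x, config) {
    n_eval <<- n_eval + 1L
    sim <- simulate_target_values(make_params(x), targets, config)
    v <- target_sse(sim, targets)
    if (!is.finite(v))
      stop("non-finite objective at ",
           paste(sprintf("%s=%g", nms, x), collapse = ", "))
    v
  }

  # Latin-hypercube starting points, screened at the coarse step size
  starts <- lhs_start_points(lo, hi, n_starts, seed)
  starts <- rbind(x0, starts)
  svals <- apply(starts, 1L, obj_at, config = search_config)
  best <- starts[which.min(svals), ]

  fit1 <- nm_bounded(function(x) obj_at(x, search_config), best, lo, hi,
                     maxit = maxit_search)
  start2 <- if (fit1$value <= min(svals)) fit1$par else best
  fit2 <- nm_bounded(function(x) obj_at(x, final_config), start2, lo, hi,
                     maxit = maxit_final)
  # keep whichever point is best at the final step size
  cand <- list(fit2$par, start2, x0)
  cvals <- vapply(cand, obj_at, 0, config = final_config)
  par <- cand[[which.min(cvals)]]
  value <- min(cvals)

  p_fit <- make_params(par)
  re <- rel_errors(p_fit, final_config)
  structure(list(par = stats::setNames(par, nms), value = value,
                 rel_errors = re,
                 converged = all(abs(re) <= targets$tolerance),
                 params = p_fit, free = free, seed = seed,
                 n_eval = n_eval), class = "mhsd_fit")
}

# LHS start points within [lo, hi]
lhs_start_points <- function(lo, hi, n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  u <- lhs::randomLHS(n, length(lo))
  sweep(sweep(u, 2L, hi - lo, "*"), 2L, lo, "+")
}

#' @export
print.mhsd_fit <- function(x, ...) {
  cat("<mhsd_fit> ", length(x$par), " free parameter(s), seed ", x$seed,
      ", ", x$n_eval, " objective evaluations\n", sep = "")
  cat(sprintf("  objective: %.6g   converged: %s\n", x$value, x$converged))
  if (length(x$par)) {
    cat("  fitted values:\n")
    for (nm in names(x$par)) cat(sprintf("    %-18s %.6g\n", nm, x$par[[nm]]))
  }
  invisible(x)
}

#' @export
summary.mhsd_fit <- function(object, ...) {
  cat("Calibration fit\n")
  print(object)
  cat("  per-target relative errors:\n")
  for (nm in names(object$rel_errors))
    cat(sprintf("    %-34s %+8.4f%%\n", nm, 100 * object$rel_errors[[nm]]))
  invisible(object)
}

#' @export
coef.mhsd_fit <- function(object, ...) object$par

#' Parameter set updated with the fitted values
#'
#' @param fit An `"mhsd_fit"`.
#' @return An [mhsd_params()] object.
#' @export
fitted_params <- function(fit) fit$params

#' Write a calibration fit report
#'
#' @param fit An `"mhsd_fit"`.
#' @param params_path YAML path for the fitted full parameter set (optional).
#' @param report_path CSV path for the per-target relative errors (optional).
#' @return Invisibly, the paths written.
#' @export
write_fit_report <- function(fit, params_path = NULL, report_path = NULL) {
  if (!is.null(params_path)) write_params_yaml(fit$params, params_path)
  if (!is.null(report_path))
    utils::write.csv(data.frame(target = names(fit$rel_errors),
                                relative_error = unname(fit$rel_errors)),
                     report_path, row.names = FALSE)
  invisible(c(params_path, report_path))
}
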