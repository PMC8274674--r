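# Generic fixed-step stock-and-flow engine.
#
# Time convention: simulation time is carried in decimal calendar years, flow
# rates are per *week*, and a model year is exactly 52 weeks, so a step of
# dt weeks advances calendar time by dt/52 years and a default horizon
# 2011--2030 at dt = 1/16 week is 19 x 832 integration steps.

#' Declare a flow between stocks
#'
#' A flow moves material from a source stock to a sink stock at a
#' non-negative rate expressed per week. Either end (or both) may be the
#' model boundary (`NA`): a source-boundary flow injects material, a
#' sink-boundary flow removes it, and a flow with both ends at the boundary
#' is a pure event stream that moves no mass but can drive cumulative
#' counters (e.g. presentations to a service).
#'
#' @param name Unique flow name.
#' @param from Source stock name, or `NA` for the boundary.
#' @param to Sink stock name, or `NA` for the boundary.
#' @param rate Function `function(x, p, t, aux)` returning the flow rate
#'   (units/week) given the named state vector `x`, parameter list `p`,
#'   time `t` in decimal years and the list `aux` of auxiliary values.
#'   May be `NULL` when the enclosing model supplies a vectorised
#'   `rate_fun`.
#' @return An object of class `"sf_flow"`.
#' @seealso [sf_model()], [integrate_model()]
#' @export
sf_flow <- function(name, from = NA_character_, to = NA_character_, rate = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(rate) && !is.function(rate)) stop("'rate' must be a function or NULL")
  structure(list(name = name, from = as.character(from), to = as.character(to),
                 rate = rate),
            class = "sf_flow")
}

#' Declare an auxiliary (algebraic) variable
#'
#' Auxiliaries are algebraic expressions over stocks, parameters, time and
#' previously computed auxiliaries, re-evaluated at every integration step
#' before the flows. Their declared dependency graph must be acyclic.
#'
#' @param name Unique auxiliary name.
#' @param fun Function `function(x, p, t, aux)` returning a scalar.
#' @param deps Character vector of auxiliary names this one depends on
#'   (dependencies on stocks or parameters need not be declared).
#' @return An object of class `"sf_aux"`.
#' @export
sf_aux <- function(name, fun, deps = character()) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  structure(list(name = name, fun = fun, deps = as.character(deps)),
            class = "sf_aux")
}

#' Declare a cumulative counter over flows
#'
#' A counter accumulates `sum(flow rates) * dt` over a set of flows from a
#' reset epoch onwards; before the epoch its value is zero. The default
#' epoch (2021.0) makes "cumulative outcome over the forecast window" a
#' single counter read at the end of the horizon.
#'
#' @param name Counter name.
#' @param flows Character vector of flow names contributing to the counter.
#' @param epoch Decimal year at which accumulation starts.
#' @return An object of class `"sf_counter"`.
#' @export
sf_counter <- function(name, flows, epoch = 2021.0) {
  stopifnot(is.character(name), length(name) == 1L, length(flows) >= 1L)
  structure(list(name = name, flows = as.character(flows), epoch = as.numeric(epoch)),
            class = "sf_counter")
}

#' Declare a time-profiled parameter override (shock)
#'
#' Shocks install exogenous time profiles -- step changes, ramps, decaying
#' pulses -- for named quantities. Profiles are deterministic functions of
#' time (and the base parameters) and are pre-evaluated on the integration
#' grid, then exposed to rate functions each step as the named vector `tv`
#' (and, for per-flow models, as overrides of the same-named parameter).
#'
#' @param name Name of the time-varying quantity the profile drives.
#' @param profile Function `function(t, p)` returning the value at decimal
#'   year `t` under base parameters `p`.
#' @return An object of class `"sf_shock"`.
#' @export
sf_shock <- function(name, profile) {
  stopifnot(is.character(name), length(name) == 1L, is.function(profile))
  structure(list(name = name, profile = profile), class = "sf_shock")
}

#' Assemble a stock-and-flow model
#'
#' @param stocks Named numeric vector of non-negative initial stock levels.
#' @param flows List of [sf_flow()] objects.
#' @param aux Optional list of [sf_aux()] objects.
#' @param counters Optional list of [sf_counter()] objects.
#' @param shocks Optional list of [sf_shock()] objects.
#' @param rate_fun Optional vectorised rate function
#'   `function(x, p, t, tv)` returning the rates of *all* flows (in the
#'   order of `flows`) as one numeric vector; when supplied it replaces the
#'   per-flow `rate` closures and is the fast path used by the full
#'   regional model.
#' @param report Optional function `function(x, p, t, tv)` returning a named
#'   numeric vector of derived quantities recorded alongside the stocks
#'   (e.g. prevalence, pressure indices).
#' @param name Model label used in printing.
#' @return An object of class `"sf_model"`.
#' @seealso [validate_model()], [integrate_model()]
#' @export
sf_model <- function(stocks, flows, aux = list(), counters = list(),
                     shocks = list(), rate_fun = NULL, report = NULL,
                     name = "stock-flow model") {
  m <- structure(list(stocks = stocks, flows = flows, aux = aux,
                      counters = counters, shocks = shocks,
                      rate_fun = rate_fun, report = report, name = name),
                 class = "sf_model")
  m
}

#' @export
print.sf_model <- function(x, ...) {
  cat("<sf_model> ", x$name, "\n", sep = "")
  cat("  stocks:   ", length(x$stocks), "\n", sep = "")
  cat("  flows:    ", length(x$flows), "\n", sep = "")
  cat("  aux:      ", length(x$aux), "\n", sep = "")
  cat("  counters: ", length(x$counters), "\n", sep = "")
  cat("  shocks:   ", length(x$shocks), "\n", sep = "")
  d <- validate_model(x)
  if (length(d)) cat("  diagnostics:", length(d), "(see validate_model())\n")
  invisible(x)
}

# Topological order of auxiliaries; returns list(order=, cycle=) where cycle
# is a character vector of names on a cycle (empty if acyclic).
aux_topo_order <- function(aux) {
  nms <- vapply(aux, `[[`, "", "name")
  n <- length(nms)
  if (n == 0L) return(list(order = integer(), cycle = character()))
  indeg <- integer(n)
  dep_idx <- lapply(aux, function(a) match(intersect(a$deps, nms), nms))
  for (i in seq_len(n)) indeg[i] <- length(dep_idx[[i]])
  order <- integer(0)
  ready <- which(indeg == 0L)
  indeg2 <- indeg
  done <- rep(FALSE, n)
  while (length(ready)) {
    i <- ready[1L]; ready <- ready[-1L]
    done[i] <- TRUE
    order <- c(order, i)
    for (j in seq_len(n)) {
      if (!done[j] && i %in% dep_idx[[j]]) {
        indeg2[j] <- indeg2[j] - 1L
        if (indeg2[j] == 0L) ready <- c(ready, j)
      }
    }
  }
  list(order = order, cycle = if (length(order) < n) nms[!done] else character())
}

#' Validate a stock-and-flow model
#'
#' Checks the structural invariants of an [sf_model()]: unique, declared
#' names; flows referencing existing stocks (or the boundary); an acyclic
#' auxiliary dependency graph; counters referencing existing flows; and a
#' rate available for every flow. Returns diagnostics rather than raising
#' errors so callers can report all problems at once.
#'
#' @param model An [sf_model()].
#' @return Character vector of diagnostic messages; empty iff the model is
#'   well formed.
#' @export
validate_model <- function(model) {
  d <- character()
  sn <- names(model$stocks)
  if (is.null(sn) || any(!nzchar(sn))) d <- c(d, "stocks must be a named numeric vector")
  if (anyDuplicated(sn)) d <- c(d, "duplicate stock names")
  if (any(!is.finite(model$stocks)) || any(model$stocks < 0))
    d <- c(d, "initial stock values must be finite and non-negative")
  fn <- vapply(model$flows, `[[`, "", "name")
  if (anyDuplicated(fn)) d <- c(d, "duplicate flow names")
  for (f in model$flows) {
    for (end in c("from", "to")) {
      s <- f[[end]]
      if (!is.na(s) && !(s %in% sn))
        d <- c(d, sprintf("flow '%s' references undeclared stock '%s'", f$name, s))
    }
    if (is.null(f$rate) && is.null(model$rate_fun))
      d <- c(d, sprintf("flow '%s' has no rate function and the model has no rate_fun", f$name))
  }
  an <- vapply(model$aux, `[[`, "", "name")
  if (anyDuplicated(an)) d <- c(d, "duplicate auxiliary names")
  topo <- aux_topo_order(model$aux)
  if (length(topo$cycle))
    d <- c(d, sprintf("auxiliary dependency cycle involving {%s}",
                      paste(sort(topo$cycle), collapse = ", ")))
  for (ct in model$counters) {
    bad <- setdiff(ct$flows, fn)
    if (length(bad))
      d <- c(d, sprintf("counter '%s' references unknown flow(s): %s",
                        ct$name, paste(bad, collapse = ", ")))
  }
  d
}

#' Integration configuration
#'
#' @param t_start,t_end Horizon in decimal calendar years.
#' @param dt Step size in weeks; the default 1/16 week corresponds to
#'   0.4375 days and gives 832 steps per 52-week model year.
#' @param record_every Number of steps between recorded samples (default 16,
#'   i.e. weekly at the default `dt`).
#' @param scheme Integration scheme: `"euler"` (explicit Euler with
#'   proportional outflow rationing; the default and the scheme assumed for
#'   the regional model) or `"rk4"` (classical 4th-order Runge-Kutta, for
#'   smooth regimes where stocks stay clear of zero; no rationing, stages
#'   evaluated at half steps).
#' @return An object of class `"sf_config"`.
#' @export
sf_config <- function(t_start = 2011, t_end = 2030, dt = 1 / 16,
                      record_every = 16L, scheme = c("euler", "rk4")) {
  scheme <- match.arg(scheme)
  if (!(dt > 0)) stop("dt must be positive")
  if (!(t_end > t_start)) stop("t_end must exceed t_start")
  nsteps <- (t_end - t_start) * 52 / dt
  if (abs(nsteps - round(nsteps)) > 1)
    stop("(t_end - t_start)/dt must be within one step of an integer")
  structure(list(t_start = t_start, t_end = t_end, dt = dt,
                 record_every = as.integer(record_every),
                 scheme = scheme,
                 n_steps = as.integer(round(nsteps))),
            class = "sf_config")
}

#' Integrate a stock-and-flow model
#'
#' Explicit (forward) Euler integration:
#' `stock(t + dt) = stock(t) + dt * (inflows - outflows)`. When a step would
#' drive a stock negative, all outflows from that stock are scaled down by a
#' common factor so the stock is exactly exhausted ("uniform proportional
#' rationing"); the same scaled rate is applied at both ends of each flow so
#' mass is conserved. Auxiliaries are re-evaluated at every step; counters
#' accumulate `flow * dt` from their epoch onwards; shock profiles are
#' pre-evaluated on the time grid.
#'
#' @param model An [sf_model()]; must validate cleanly.
#' @param params Named list of parameters passed to rate functions.
#' @param config An [sf_config()].
#' @return An object of class `"sf_trajectory"` with elements `times`
#'   (decimal years at recorded samples), `stocks` (matrix time x stock),
#'   `flows` (matrix of *rationed* flow rates, time x flow), `counters`
#'   (final values), `counter_series` (matrix time x counter), and `report`
#'   (matrix of reported derived quantities, if the model defines them).
#' @examples
#' m <- sf_model(stocks = c(S = 100),
#'               flows = list(sf_flow("decay", from = "S",
#'                                    rate = function(x, p, t, aux) p$k * x[["S"]])))
#' tr <- integrate_model(m, params = list(k = 0.1),
#'                       config = sf_config(2011, 2012, dt = 1 / 16))
#' tail(tr$stocks[, "S"], 1)  # ~ 100 * exp(-5.2)
#' @export
integrate_model <- function(model, params = list(), config = sf_config()) {
  diag <- validate_model(model)
  if (length(diag))
    stop("model failed validation:\n  - ", paste(diag, collapse = "\n  - "))

  x <- as.numeric(model$stocks)
  snames <- names(model$stocks)
  nS <- length(x)
  fl <- model$flows
  nF <- length(fl)
  fnames <- vapply(fl, `[[`, "", "name")
  from_idx <- match(vapply(fl, `[[`, "", "from"), snames)  # NA = boundary
  to_idx   <- match(vapply(fl, `[[`, "", "to"),   snames)

  # incidence matrices: Aout[s, f] = 1 if flow f leaves stock s; Anet = in - out
  Aout <- matrix(0, nS, nF)
  Anet <- matrix(0, nS, nF)
  for (j in seq_len(nF)) {
    if (!is.na(from_idx[j])) { Aout[from_idx[j], j] <- 1; Anet[from_idx[j], j] <- Anet[from_idx[j], j] - 1 }
    if (!is.na(to_idx[j]))   { Anet[to_idx[j], j] <- Anet[to_idx[j], j] + 1 }
  }
  has_from <- !is.na(from_idx)
  from_pos <- from_idx[has_from]

  dt <- config$dt
  n_steps <- config$n_steps
  dt_years <- dt / 52
  rk4 <- identical(config$scheme, "rk4")
  # the fine grid carries half-steps for the Runge-Kutta stages
  n_fine <- if (rk4) 2L * n_steps else n_steps
  fine_dt_years <- if (rk4) dt_years / 2 else dt_years
  times_all <- config$t_start + (0:n_fine) * fine_dt_years

  # pre-evaluate shock profiles on the grid
  nshock <- length(model$shocks)
  tvnames <- if (nshock) vapply(model$shocks, `[[`, "", "name") else character()
  tvmat <- if (nshock) {
    vapply(model$shocks, function(s) vapply(times_all, s$profile, 0, p = params), numeric(n_fine + 1L))
  } else matrix(0, n_fine + 1L, 0L)

  use_rate_fun <- !is.null(model$rate_fun)
  topo <- aux_topo_order(model$aux)
  aux_ord <- model$aux[topo$order]

  rates_at <- function(x, ti) {
    tv <- if (nshock) stats::setNames(tvmat[ti, ], tvnames) else numeric()
    t_yr <- times_all[ti]
    if (use_rate_fun) {
      r <- model$rate_fun(x, params, t_yr, tv)
    } else {
      p <- params
      if (nshock) for (k in seq_len(nshock)) p[[tvnames[k]]] <- tv[[k]]
      xn <- stats::setNames(x, snames)
      a <- list()
      for (au in aux_ord) a[[au$name]] <- au$fun(xn, p, t_yr, a)
      r <- vapply(fl, function(f) f$rate(xn, p, t_yr, a), 0)
    }
    if (anyNA(r) || any(!is.finite(r))) {
      bad <- fnames[which(!is.finite(r))[1L]]
      stop(sprintf("non-finite rate for flow '%s' at t = %.4f", bad, t_yr))
    }
    r[r < 0] <- 0
    r
  }

  ration <- function(x, r) {
    out_tot <- as.vector(Aout %*% r)
    need <- out_tot * dt
    over <- need > x & need > 0
    if (any(over)) {
      fac <- rep(1, nS)
      fac[over] <- x[over] / need[over]
      r[has_from] <- r[has_from] * fac[from_pos]
    }
    r
  }

  counters <- model$counters
  nC <- length(counters)
  cnames <- if (nC) vapply(counters, `[[`, "", "name") else character()
  cidx <- lapply(counters, function(ct) match(ct$flows, fnames))
  cepoch <- vapply(counters, function(ct) ct$epoch, 0)
  cval <- numeric(nC)

  rec_every <- max(1L, config$record_every)
  rec_steps <- unique(c(seq(0L, n_steps, by = rec_every), n_steps))
  nrec <- length(rec_steps)
  rec_t <- numeric(nrec)
  rec_x <- matrix(NA_real_, nrec, nS, dimnames = list(NULL, snames))
  rec_f <- matrix(NA_real_, nrec, nF, dimnames = list(NULL, fnames))
  rec_c <- matrix(NA_real_, nrec, nC, dimnames = list(NULL, cnames))
  has_report <- is.function(model$report)
  rec_rep <- NULL
  ri <- 1L

  for (step in 0:n_steps) {
    ti <- if (rk4) 2L * step + 1L else step + 1L
    r <- rates_at(x, ti)
    if (!rk4) r <- ration(x, r)

    if (ri <= nrec && step == rec_steps[ri]) {
      rec_t[ri] <- times_all[ti]
      rec_x[ri, ] <- x
      rec_f[ri, ] <- r
      if (nC) rec_c[ri, ] <- cval
      if (has_report) {
        tv <- if (nshock) stats::setNames(tvmat[ti, ], tvnames) else numeric()
        rep_v <- model$report(stats::setNames(x, snames), params, times_all[ti], tv)
        if (is.null(rec_rep)) rec_rep <- matrix(NA_real_, nrec, length(rep_v),
                                                dimnames = list(NULL, names(rep_v)))
        rec_rep[ri, ] <- rep_v
      }
      ri <- ri + 1L
    }
    if (step == n_steps) break

    t_now <- times_all[ti]
    if (rk4) {
      k1 <- r
      x2 <- x + as.vector(Anet %*% k1) * (dt / 2); x2[x2 < 0] <- 0
      k2 <- rates_at(x2, ti + 1L)
      x3 <- x + as.vector(Anet %*% k2) * (dt / 2); x3[x3 < 0] <- 0
      k3 <- rates_at(x3, ti + 1L)
      x4 <- x + as.vector(Anet %*% k3) * dt; x4[x4 < 0] <- 0
      k4 <- rates_at(x4, ti + 2L)
      r <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }
    if (nC) {
      for (k in seq_len(nC)) if (t_now >= cepoch[k]) cval[k] <- cval[k] + sum(r[cidx[[k]]]) * dt
    }
    x <- x + as.vector(Anet %*% r) * dt
    x[x < 0] <- 0  # floating-point guard; rationing keeps true values >= 0
  }

  structure(list(times = rec_t, stocks = rec_x, flows = rec_f,
                 counters = stats::setNames(cval, cnames),
                 counter_series = rec_c, report = rec_rep,
                 config = config, model_name = model$name),
            class = "sf_trajectory")
}

#' @export
print.sf_trajectory <- function(x, ...) {
  cat("<sf_trajectory> ", x$model_name, "\n", sep = "")
  cat(sprintf("  horizon: %.2f .. %.2f (%d samples, dt = %g week)\n",
              x$times[1L], x$times[length(x$times)], length(x$times), x$config$dt))
  cat("  stocks: ", paste(utils::head(colnames(x$stocks), 8L), collapse = ", "),
      if (ncol(x$stocks) > 8L) ", ..." else "", "\n", sep = "")
  if (length(x$counters)) {
    cat("  counters at end of horizon:\n")
    for (nm in names(x$counters))
      cat(sprintf("    %-28s %12.1f\n", nm, x$counters[[nm]]))
  }
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x An `sf_trajectory`.
#' @param row.names,optional Ignored (S3 signature).
#' @param which Which variable groups to include.
#' @param ... Ignored.
#' @return A data.frame with columns `time`, `variable`, `value`.
#' @export
as.data.frame.sf_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                        which = c("stocks", "flows", "counters", "report"),
                                        ...) {
  which <- match.arg(which, several.ok = TRUE)
  pieces <- list()
  grab <- function(mat) {
    if (is.null(mat) || ncol(mat) == 0L) return(NULL)
    data.frame(time = rep(x$times, ncol(mat)),
               variable = rep(colnames(mat), each = nrow(mat)),
               value = as.vector(mat))
  }
  if ("stocks" %in% which) pieces$stocks <- grab(x$stocks)
  if ("flows" %in% which) pieces$flows <- grab(x$flows)
  if ("counters" %in% which) pieces$counters <- grab(x$counter_series)
  if ("report" %in% which) pieces$report <- grab(x$report)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write a trajectory to a tidy CSV file
#'
#' @param traj An `sf_trajectory`.
#' @param path Output file path.
#' @param ... Passed to [as.data.frame.sf_trajectory()].
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, ...) {
  utils::write.csv(as.data.frame(traj, ...), path, row.names = FALSE)
  invisible(path)
}

#' Plot recorded stock series
#'
#' @param x An `sf_trajectory`.
#' @param vars Stock (or report) column names to draw; defaults to all stocks.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sf_trajectory <- function(x, vars = colnames(x$stocks), ...) {
  cols <- intersect(vars, c(colnames(x$stocks), colnames(x$report)))
  if (!length(cols)) stop("no matching variables to plot")
  mat <- cbind(x$stocks, x$report)[, cols, drop = FALSE]
  graphics::matplot(x$times, mat, type = "l", lty = 1, xlab = "year",
                    ylab = "level", ...)
  graphics::legend("topright", legend = cols, lty = 1,
                   col = seq_along(cols), bty = "n", cex = 0.8)
  invisible(x)
}

# Value of a recorded matrix column at (nearest) time t.
traj_value_at <- function(traj, t, column, what = c("stocks", "report", "counters")) {
  what <- match.arg(what)
  mat <- switch(what, stocks = traj$stocks, report = traj$report,
                counters = traj$counter_series)
  i <- which.min(abs(traj$times - t))
  mat[i, column]
}

# Yearly totals of a flow (units/week summed over recorded samples x record
# interval), for comparison with yearly indicator series.
flow_yearly_totals <- function(traj, flow, years) {
  dt_rec <- diff(traj$times[1:2]) * 52  # weeks between records
  vals <- traj$flows[, flow]
  yr <- floor(traj$times + 1e-9)
  out <- vapply(years, function(y) sum(vals[yr == y]) * dt_rec, 0)
  stats::setNames(out, years)
}
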