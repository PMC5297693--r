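# Stress protocols and trajectory integration.
#
# A protocol is a piecewise-constant stress schedule plus an initial state,
# horizon and output sampling step.  Integration is stiff-capable (lsoda with
# the analytic Jacobian) and restarts at every stress discontinuity so no
# interpolation happens across events.

#' Define a stress protocol
#'
#' @param stress either a single stress level applied from time 0, or a
#'   two-column structure (`time`, `stress`) of piecewise-constant segments
#'   with strictly increasing onset times starting at 0.
#' @param horizon total simulated time (> 0).
#' @param dt output sampling step (> 0).
#' @param initial_state starting state; default the origin (all inactive).
#' @param preset optional perturbation preset name understood by
#'   [preset_params()], applied to the parameter set at integration time.
#' @return an object of class `upr_protocol`.
#' @export
#' @examples
#' upr_protocol(stress = 40, horizon = 240)
#' upr_protocol(stress = data.frame(time = c(0, 120), stress = c(40, 0)),
#'              horizon = 480)
upr_protocol <- function(stress, horizon, dt = 1,
                         initial_state = c(perk = 0, ire1 = 0, auto = 0, apop = 0),
                         preset = NULL) {
  if (is.numeric(stress) && length(stress) == 1L) {
    segments <- data.frame(time = 0, stress = stress)
  } else {
    segments <- as.data.frame(stress)
    if (!all(c("time", "stress") %in% names(segments))) {
      stop("stress schedule needs columns 'time' and 'stress'", call. = FALSE)
    }
    segments <- segments[order(segments$time), c("time", "stress")]
  }
  if (segments$time[1L] != 0) stop("the first segment must start at time 0", call. = FALSE)
  if (any(diff(segments$time) <= 0)) stop("segment times must be strictly increasing", call. = FALSE)
  if (any(segments$stress < 0)) stop("stress must be >= 0", call. = FALSE)
  if (!is.numeric(horizon) || horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  structure(
    list(segments = segments, horizon = horizon, dt = dt,
         initial_state = .as_state(initial_state), preset = preset),
    class = "upr_protocol"
  )
}

#' Integrate the model under a protocol
#'
#' Segment-wise stiff integration (`deSolve::lsoda`, relative tolerance
#' 1e-8, absolute 1e-10, analytic Jacobian) with restarts at every stress
#' change.  The returned trajectory carries a `settled` flag: `TRUE` when
#' the residual `max |rhs|` at the final time is below `settle_tol`.
#'
#' @param params a [upr_params] object (its own `stress` field is ignored;
#'   the protocol schedule governs).
#' @param protocol a [upr_protocol] object.
#' @param settle_tol residual threshold for the `settled` flag.
#' @return an object of class `upr_trajectory`: a data frame with columns
#'   `time`, `perk`, `ire1`, `auto`, `apop` and attributes `params`,
#'   `protocol`, `events` (the stress schedule) and `settled`.
#' @export
#' @examples
#' tr <- integrate_protocol(default_params(), upr_protocol(40, horizon = 240))
#' tail(tr, 2)
integrate_protocol <- function(params, protocol, settle_tol = 1e-6) {
  stopifnot(inherits(protocol, "upr_protocol"))
  if (!is.null(protocol$preset)) {
    params <- preset_params(protocol$preset, params)
  }
  seg <- protocol$segments
  bounds <- c(seg$time, protocol$horizon)
  state <- protocol$initial_state
  pieces <- list()
  for (i in seq_len(nrow(seg))) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    if (t1 <= t0) next
    p_seg <- params
    p_seg[["stress"]] <- seg$stress[i]
    times <- unique(c(seq(t0, t1, by = protocol$dt), t1))
    sol <- deSolve::lsoda(
      y = state, times = times, func = .upr_deriv,
      parms = as.numeric(unclass(p_seg)[.upr_param_names]),
      jacfunc = .upr_jac, jactype = "fullusr",
      rtol = 1e-8, atol = 1e-10
    )
    if (attr(sol, "istate")[1L] < 0) {
      stop(sprintf("integration failed in segment %d near t = %.6g", i,
                   max(sol[, "time"])), call. = FALSE)
    }
    sol <- as.data.frame(sol)
    state <- unlist(sol[nrow(sol), .upr_state_names])
    # drop the duplicated segment-start row after the first piece
    if (length(pieces)) sol <- sol[-1L, , drop = FALSE]
    pieces[[length(pieces) + 1L]] <- sol
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  p_final <- params
  p_final[["stress"]] <- seg$stress[nrow(seg)]
  resid <- max(abs(upr_rhs(state, p_final)))
  structure(out,
            class = c("upr_trajectory", "data.frame"),
            params = params, protocol = protocol, events = seg,
            settled = resid < settle_tol, final_residual = resid)
}

# Registered experimental scenarios.  `washout` is built dynamically because
# the wash time references the commitment point of the high-stress run.
.upr_scenario_names <- c("low_stress", "high_stress",
                         "siPERK_high_stress", "IRE1low_high_stress",
                         "washout")

#' Names of the registered simulation scenarios
#' @return character vector of scenario names accepted by [run_scenario()].
#' @export
upr_scenarios <- function() .upr_scenario_names

#' Simulate one of the registered experimental scenarios
#'
#' Scenarios mirror the simulated experiments: step stress at a tolerable
#' (`low_stress`, stress = 25) or excessive (`high_stress`, stress = 40)
#' level, high stress under sensor knockdown (`siPERK_high_stress`,
#' `PERKT` scaled to 0.2; `IRE1low_high_stress`, `IRE1T` scaled to 0.1), and
#' `washout`: high stress until apoptosis commitment, then complete stressor
#' removal.  Commitment is the first time the apoptosis inducer exceeds 90%
#' of its high-branch steady value at stress 40; the wash is applied
#' `wash_delay` time units later.
#'
#' @param name scenario name, one of [upr_scenarios()].
#' @param params base parameter set (default the shipped calibrated set).
#' @param horizon simulated time; default 240 (480 for `washout`).
#' @param dt output sampling step.
#' @param wash_delay post-commitment delay before the stressor is removed
#'   (washout scenario only).
#' @return a `upr_trajectory` with attribute `scenario`.
#' @export
#' @examples
#' tr <- run_scenario("high_stress", horizon = 240)
#' attr(tr, "scenario")
run_scenario <- function(name, params = default_params(), horizon = NULL,
                         dt = 1, wash_delay = 15) {
  if (!name %in% .upr_scenario_names) {
    stop("unknown scenario '", name, "'; see upr_scenarios()", call. = FALSE)
  }
  if (is.null(horizon)) horizon <- if (name == "washout") 480 else 240
  tr <- switch(
    name,
    low_stress = integrate_protocol(params, upr_protocol(25, horizon, dt)),
    high_stress = integrate_protocol(params, upr_protocol(40, horizon, dt)),
    siPERK_high_stress = integrate_protocol(
      params, upr_protocol(40, horizon, dt, preset = "siPERK")),
    IRE1low_high_stress = integrate_protocol(
      params, upr_protocol(40, horizon, dt, preset = "IRE1low")),
    washout = {
      p40 <- params
      p40[["stress"]] <- 40
      ss <- find_steady_states(p40)
      d_high <- max(ss$apop[ss$stable])
      probe <- integrate_protocol(params, upr_protocol(40, horizon, dt))
      idx <- which(probe$apop >= 0.9 * d_high)
      if (!length(idx)) {
        stop("washout: apoptosis never commits within the horizon", call. = FALSE)
      }
      t_commit <- probe$time[idx[1L]]
      t_wash <- min(t_commit + wash_delay, horizon - dt)
      sched <- data.frame(time = c(0, t_wash), stress = c(40, 0))
      out <- integrate_protocol(params, upr_protocol(sched, horizon, dt))
      attr(out, "commit_time") <- t_commit
      attr(out, "wash_time") <- t_wash
      out
    }
  )
  attr(tr, "scenario") <- name
  tr
}

#' @export
print.upr_trajectory <- function(x, ...) {
  ev <- attr(x, "events")
  cat("<upr_trajectory>",
      sprintf("%d samples, t in [%g, %g]", nrow(x), min(x$time), max(x$time)),
      if (!is.null(attr(x, "scenario"))) sprintf("scenario '%s'", attr(x, "scenario")) else "",
      "\n")
  cat("  stress schedule:", paste(sprintf("%g@t=%g", ev$stress, ev$time), collapse = ", "),
      sprintf("; settled: %s\n", attr(x, "settled")))
  print(utils::head(as.data.frame(x), 3))
  cat("  ...\n")
  invisible(x)
}

#' Plot a trajectory
#'
#' One line per variable against time; vertical dotted lines mark stress
#' changes.
#' @param x a `upr_trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.upr_trajectory <- function(x, ...) {
  graphics::matplot(x$time, as.matrix(x[, .upr_state_names]), type = "l",
                    lty = 1, lwd = 2, col = c("black", "blue", "forestgreen", "red"),
                    xlab = "time (a.u.)", ylab = "active fraction (a.u.)", ...)
  ev <- attr(x, "events")
  if (!is.null(ev) && nrow(ev) > 1L) {
    graphics::abline(v = ev$time[-1L], lty = 3, col = "grey40")
  }
  graphics::legend("topright", legend = .upr_state_names, lty = 1, lwd = 2,
                   col = c("black", "blue", "forestgreen", "red"), bty = "n")
  invisible(x)
}
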