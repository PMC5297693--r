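# Qualitative-constraint calibration: the catalogue of machine-checkable
# behaviours the network must exhibit (C1-C8), evaluated on a parameter set;
# log-uniform random search for feasible sets; local robustness table.

.constraint_descriptions <- c(
  C1 = "bistable window with two stable and one unstable steady state",
  C2 = "intact network switch is irreversible (death branch persists to zero stress)",
  C3 = "activation fold SN_on lies between stress 25 and 40",
  C4 = "transient apoptosis peak at low stress (25) decays without sustained onset",
  C5 = "siPERK preset: SN_on beyond 40 and SN_off at positive stress (reversible)",
  C6 = "IRE1-low preset: SN_on below the intact SN_on, SN_off at positive stress",
  C7 = "mutual exclusion: no steady state has both inducers high",
  C8 = "high stress (40): autophagy peak precedes apoptosis half-activation"
)

#' Check the qualitative behaviour constraints of a parameter set
#'
#' Evaluates the eight behavioural constraints that define a calibrated
#' network: C1 bistability (two stable + one unstable state inside the
#' window); C2 irreversibility of the intact switch; C3 activation fold
#' between the low- and high-stress scenario levels (25 < SN_on < 40);
#' C4 decaying transient apoptosis peak at stress 25; C5 siPERK preset
#' pushed beyond stress 40 and made reversible; C6 IRE1-low preset shifted
#' left and made reversible; C7 mutual exclusion of high inducer states
#' across all scanned steady states; C8 autophagy-before-apoptosis ordering
#' at stress 40.  A constraint whose evaluation errors is reported as
#' "undetermined" and fails the overall conjunction.
#'
#' @param params a [upr_params] object.
#' @param n_scan grid points of each signal-response scan (600 gives the
#'   production resolution; the parameter search uses a coarser grid).
#' @param fold_tol fold bisection resolution in stress units.
#' @param horizon trajectory horizon for the kinetic constraints.
#' @return object of class `upr_constraints`: data frame `id`,
#'   `description`, `pass`, `measured`, with attributes `overall` (logical
#'   conjunction) and `details` (curves and measured quantities).
#' @export
#' @examples
#' \donttest{
#' report <- check_constraints(default_params(), n_scan = 120)
#' attr(report, "overall")
#' }
check_constraints <- function(params, n_scan = 600, fold_tol = 0.01, horizon = 240) {
  pass <- stats::setNames(rep(NA, 8L), names(.constraint_descriptions))
  meas <- stats::setNames(rep(NA_character_, 8L), names(.constraint_descriptions))
  details <- list()

  eval_c <- function(id, expr_fun) {
    res <- tryCatch(expr_fun(), error = function(e) {
      meas[[id]] <<- paste("undetermined:", conditionMessage(e))
      NA
    })
    if (!is.na(res["pass"])) {
      pass[[id]] <<- as.logical(res[["pass"]])
      meas[[id]] <<- res[["measured"]]
    }
    invisible(NULL)
  }

  curve_def <- tryCatch(signal_response(params, n = n_scan, fold_tol = fold_tol),
                        error = function(e) NULL)
  details$curve_default <- curve_def

  eval_c("C1", function() {
    if (is.null(curve_def)) stop("default scan failed")
    pts <- curve_def$points
    counts <- vapply(split(pts$stable, pts$stress), sum, integer(1))
    if (!any(counts >= 2)) return(c(pass = FALSE, measured = "monostable over the scan"))
    win <- as.numeric(names(counts)[counts >= 2])
    mid <- win[ceiling(length(win) / 2)]
    pmid <- params
    pmid[["stress"]] <- mid
    ss <- find_steady_states(pmid)
    ok <- sum(ss$stable) == 2L && sum(!ss$stable) == 1L
    c(pass = ok,
      measured = sprintf("window [%.2f, %.2f]; at stress %.2f: %d stable + %d unstable",
                         min(win), max(win), mid, sum(ss$stable), sum(!ss$stable)))
  })

  eval_c("C2", function() {
    if (is.null(curve_def)) stop("default scan failed")
    cls <- classify_reversibility(curve_def)
    c(pass = cls == "irreversible",
      measured = sprintf("reversibility class '%s' (SN_off status: %s)",
                         cls, curve_def$sn_off_status))
  })

  eval_c("C3", function() {
    if (is.null(curve_def)) stop("default scan failed")
    ok <- curve_def$sn_on_status == "found" &&
      curve_def$sn_on > 25 && curve_def$sn_on < 40
    c(pass = ok, measured = sprintf("SN_on = %s (%s)",
                                    format(curve_def$sn_on), curve_def$sn_on_status))
  })

  tr25 <- tryCatch(run_scenario("low_stress", params, horizon = horizon),
                   error = function(e) NULL)
  tr40 <- tryCatch(run_scenario("high_stress", params, horizon = horizon),
                   error = function(e) NULL)
  details$low_stress <- tr25
  details$high_stress <- tr40

  eval_c("C4", function() {
    if (is.null(tr25)) stop("low-stress simulation failed")
    f <- trajectory_features(tr25)
    ok <- isTRUE(f$apop$transient) && is.na(f$apop$onset_time)
    c(pass = ok,
      measured = sprintf("apop peak %.3f at t = %g, final %.3f; transient = %s",
                         f$apop$peak_value, f$apop$peak_time,
                         tr25$apop[nrow(tr25)], f$apop$transient))
  })

  curve_sip <- tryCatch(
    signal_response(preset_params("siPERK", params), n = n_scan, fold_tol = fold_tol),
    error = function(e) NULL)
  details$curve_siPERK <- curve_sip
  eval_c("C5", function() {
    if (is.null(curve_sip)) stop("siPERK scan failed")
    on_ok <- curve_sip$sn_on_status == "above_scan_max" ||
      (curve_sip$sn_on_status == "found" && curve_sip$sn_on > 40)
    off_ok <- curve_sip$sn_off_status == "found" && curve_sip$sn_off > 0
    c(pass = on_ok && off_ok,
      measured = sprintf("SN_on = %s (%s), SN_off = %s (%s)",
                         format(curve_sip$sn_on), curve_sip$sn_on_status,
                         format(curve_sip$sn_off), curve_sip$sn_off_status))
  })

  curve_ire <- tryCatch(
    signal_response(preset_params("IRE1low", params), n = n_scan, fold_tol = fold_tol),
    error = function(e) NULL)
  details$curve_IRE1low <- curve_ire
  eval_c("C6", function() {
    if (is.null(curve_ire) || is.null(curve_def)) stop("IRE1-low scan failed")
    on_ok <- curve_ire$sn_on_status == "found" &&
      curve_def$sn_on_status == "found" && curve_ire$sn_on < curve_def$sn_on
    off_ok <- curve_ire$sn_off_status == "found" && curve_ire$sn_off > 0
    c(pass = on_ok && off_ok,
      measured = sprintf("SN_on = %s (%s) vs default %s; SN_off = %s (%s)",
                         format(curve_ire$sn_on), curve_ire$sn_on_status,
                         format(curve_def$sn_on),
                         format(curve_ire$sn_off), curve_ire$sn_off_status))
  })

  eval_c("C7", function() {
    curves <- Filter(Negate(is.null), list(curve_def, curve_sip, curve_ire))
    if (!length(curves)) stop("no scan available")
    tot <- state_totals(params)
    viol <- 0L
    for (cv in curves) {
      st <- cv$points[cv$points$stable, , drop = FALSE]
      viol <- viol + sum(st$auto > 0.5 * tot[["auto"]] & st$apop > 0.5 * tot[["apop"]])
    }
    c(pass = viol == 0L,
      measured = sprintf("%d stable scan points with both inducers above half-total", viol))
  })

  eval_c("C8", function() {
    if (is.null(tr40)) stop("high-stress simulation failed")
    tot <- state_totals(params)
    t_auto_peak <- tr40$time[which.max(tr40$auto)]
    cross <- which(tr40$apop >= 0.5 * tot[["apop"]])
    if (!length(cross)) return(c(pass = FALSE, measured = "apoptosis never half-activates at stress 40"))
    t_half <- tr40$time[cross[1L]]
    c(pass = t_auto_peak < t_half,
      measured = sprintf("autophagy peak at t = %g, apoptosis half-activation at t = %g",
                         t_auto_peak, t_half))
  })

  out <- data.frame(id = names(.constraint_descriptions),
                    description = unname(.constraint_descriptions),
                    pass = unname(pass), measured = unname(meas),
                    stringsAsFactors = FALSE)
  structure(out, class = c("upr_constraints", "data.frame"),
            overall = all(!is.na(pass)) && all(pass, na.rm = TRUE),
            details = details)
}

#' @export
print.upr_constraints <- function(x, ...) {
  cat("<upr_constraints> overall:",
      if (isTRUE(attr(x, "overall"))) "PASS" else "FAIL", "\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s [%s] %s\n      %s\n", x$id[i],
                if (is.na(x$pass[i])) "??" else if (x$pass[i]) "ok" else "FAIL",
                x$description[i], x$measured[i]))
  }
  invisible(x)
}

#' Shipped search bounds for constraint-based calibration
#'
#' Log-uniform sampling bounds for the rate constants, centred on the
#' shipped defaults with a factor `spread` on either side.  Totals,
#' saturation constants and stress are held fixed: totals set the unit
#' scale, and the small-J (zero-order) regime is a structural modelling
#' choice rather than a free dial.
#'
#' @param spread multiplicative half-width of each bound (default 1.25).
#' @return named list of `c(lower, upper)` bounds.
#' @export
default_search_bounds <- function(spread = 1.25) {
  rates <- c("k_sp", "k_si", "k_ip", "k_pi", "k_dp", "k_di",
             "k_pa", "k_ia", "k_pap", "k_iap", "k_da", "k_dap",
             "k_x_aa", "k_x_apa")
  ctr <- .upr_default_values[rates]
  stats::setNames(lapply(ctr, function(v) c(v / spread, v * spread)), rates)
}

# Cheap analytic + few-point screens applied before the full constraint
# suite.  The sensor cross-activation gain at zero stress,
# R0 = (k_ip * IRE1T / k_dp) * (k_pi * PERKT / k_di), must exceed 1 for the
# intact network (self-sustained sensors keep the death branch alive at
# zero stress) and fall below 1 under both knockdown presets.
.prescreen <- function(params) {
  p <- unclass(params)
  r0 <- function(pt, it) (p[["k_ip"]] * it / p[["k_dp"]]) * (p[["k_pi"]] * pt / p[["k_di"]])
  if (r0(p[["PERKT"]], p[["IRE1T"]]) <= 1) return("sensor feedback not self-sustaining (R0 <= 1)")
  if (r0(0.2 * p[["PERKT"]], p[["IRE1T"]]) >= 1) return("siPERK preset still self-sustaining")
  if (r0(p[["PERKT"]], 0.1 * p[["IRE1T"]]) >= 1) return("IRE1-low preset still self-sustaining")
  count_at <- function(s) {
    ps <- params
    ps[["stress"]] <- s
    ss <- find_steady_states(ps, starts = .canonical_starts(ps), grid = FALSE)
    c(stable = sum(ss$stable), total = nrow(ss))
  }
  c0 <- count_at(0); c25 <- count_at(25); c40 <- count_at(40)
  if (c0[["stable"]] < 2) return("no committed death state at zero stress")
  if (c25[["stable"]] < 2) return("not bistable at stress 25")
  if (c40[["stable"]] != 1) return("still bistable at stress 40 (SN_on >= 40)")
  NULL
}

#' Random search for parameter sets satisfying all constraints
#'
#' Samples candidate sets log-uniformly within `bounds` (parameters not in
#' `bounds` stay at their values in `base`), discards candidates failing
#' cheap structural screens (sensor feedback gain, steady-state counts at
#' stress 0/25/40), and runs the full constraint suite on the survivors.
#'
#' @param bounds named list of `c(lower, upper)` sampling bounds
#'   (default [default_search_bounds()]).
#' @param n_samples number of candidates to draw.
#' @param seed integer seed.
#' @param base parameter set supplying the non-searched values.
#' @param n_scan,fold_tol scan settings forwarded to [check_constraints()]
#'   (coarser than production by default: the search needs ranking, not
#'   publication-resolution folds).
#' @return list with `feasible` (list of `upr_params` passing C1-C8),
#'   `n_screened` (candidates reaching the full suite), `pass_rates`
#'   (per-constraint pass fraction among fully-checked candidates),
#'   `screen_reasons` (table of prescreen rejection reasons), and
#'   `most_violated` (diagnostic when nothing is feasible).
#' @export
search_parameters <- function(bounds = default_search_bounds(), n_samples, seed,
                              base = default_params(), n_scan = 120,
                              fold_tol = 0.05) {
  stopifnot(n_samples >= 0)
  nm <- names(bounds)
  draws <- .with_seed(seed, {
    if (n_samples == 0) matrix(numeric(0), nrow = 0, ncol = length(nm))
    else matrix(exp(stats::runif(n_samples * length(nm),
                                 log(vapply(bounds, `[`, numeric(1), 1L)),
                                 log(vapply(bounds, `[`, numeric(1), 2L)))),
                nrow = n_samples, ncol = length(nm), byrow = TRUE)
  })
  colnames(draws) <- nm

  feasible <- list()
  reasons <- character(0)
  passes <- NULL
  for (i in seq_len(n_samples)) {
    cand <- tryCatch({
      p <- unclass(base)
      p[nm] <- draws[i, ]
      do.call(upr_params, as.list(p))
    }, error = function(e) NULL)
    if (is.null(cand)) {
      reasons <- c(reasons, "structural invariant violated")
      next
    }
    reason <- .prescreen(cand)
    if (!is.null(reason)) {
      reasons <- c(reasons, reason)
      next
    }
    rep <- check_constraints(cand, n_scan = n_scan, fold_tol = fold_tol)
    passes <- rbind(passes, stats::setNames(rep$pass, rep$id))
    if (isTRUE(attr(rep, "overall"))) feasible[[length(feasible) + 1L]] <- cand
  }

  pass_rates <- if (is.null(passes)) NULL else colMeans(passes, na.rm = TRUE)
  most_violated <- if (!length(feasible)) {
    if (!is.null(pass_rates)) names(which.min(pass_rates))
    else if (length(reasons)) names(sort(table(reasons), decreasing = TRUE))[1L]
    else NA_character_
  } else NA_character_

  list(feasible = feasible,
       n_screened = if (is.null(passes)) 0L else nrow(passes),
       pass_rates = pass_rates,
       screen_reasons = if (length(reasons)) table(reasons) else table(character(0)),
       most_violated = most_violated)
}

#' Local robustness of the constraint suite to single-parameter changes
#'
#' Perturbs each rate constant in `which` by `(1 - delta)` and `(1 + delta)`
#' in turn and re-evaluates the constraint suite, reporting per-constraint
#' pass/fail.  The network is expected to be qualitatively robust but not
#' fine-tuning-free: failures are reported, not hidden.  With all 14 rate
#' constants this is 28 full constraint evaluations; use a coarse `n_scan`.
#'
#' @param params parameter set to perturb.
#' @param delta relative perturbation (default 0.1).
#' @param which rate constants to perturb (default all 14).
#' @param n_scan,fold_tol forwarded to [check_constraints()].
#' @return data frame `parameter`, `direction`, one logical column per
#'   constraint, and `overall`.
#' @export
robustness_table <- function(params = default_params(), delta = 0.1,
                             which = names(default_search_bounds()),
                             n_scan = 120, fold_tol = 0.05) {
  rows <- list()
  for (k in which) {
    for (dir in c(-1, 1)) {
      p <- params
      p[[k]] <- unclass(params)[[k]] * (1 + dir * delta)
      rep <- tryCatch(check_constraints(p, n_scan = n_scan, fold_tol = fold_tol),
                      error = function(e) NULL)
      row <- data.frame(parameter = k,
                        direction = if (dir < 0) sprintf("-%d%%", round(100 * delta))
                                    else sprintf("+%d%%", round(100 * delta)))
      if (is.null(rep)) {
        for (id in names(.constraint_descriptions)) row[[id]] <- NA
        row$overall <- FALSE
      } else {
        for (i in seq_len(nrow(rep))) row[[rep$id[i]]] <- rep$pass[i]
        row$overall <- isTRUE(attr(rep, "overall"))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
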