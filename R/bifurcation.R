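# Signal-response (one-parameter bifurcation) analysis: stability-annotated
# steady-state branches of the network versus the stress signal, saddle-node
# fold localisation by bisection on branch existence, and classification of
# switch reversibility.

# Canonical fresh starts used at every stress value: box corners that seed
# the survival branch (autophagy high), the death branch (apoptosis high),
# the origin, and the box centre (which often lands on the saddle).
.canonical_starts <- function(params) {
  tt <- state_totals(params)
  rbind(
    c(0, 0, 0, 0),
    tt * c(0.9, 0.9, 0.95, 0.02),
    tt * c(0.9, 0.9, 0.02, 0.95),
    tt * c(0.5, 0.5, 0.5, 0.5),
    tt * c(0.2, 0.2, 0.2, 0.2)
  )
}

# Steady states at one stress value, warm-started from `warm` (matrix or NULL).
.states_at <- function(params, stress, warm = NULL, dedup_tol = 1e-6) {
  p <- params
  p[["stress"]] <- stress
  starts <- rbind(.canonical_starts(p), warm)
  ss <- find_steady_states(p, starts = starts, grid = FALSE, dedup_tol = dedup_tol)
  # when two stable states were found but no saddle, probe the segment
  # between them: the separatrix crosses it
  if (sum(ss$stable) >= 2L && !any(!ss$stable)) {
    stables <- ss[ss$stable, .upr_state_names, drop = FALSE]
    a <- unlist(stables[1L, ]); b <- unlist(stables[nrow(stables), ])
    mids <- t(vapply(c(0.3, 0.5, 0.7), function(w) a + w * (b - a), numeric(4)))
    ss <- find_steady_states(p, starts = rbind(as.matrix(ss[, .upr_state_names]), mids),
                             grid = FALSE, dedup_tol = dedup_tol)
  }
  ss
}

#' Compute the signal-response curve of the network
#'
#' Scans a stress grid, locating all steady states at each value
#' (nearest-neighbour continuation: every root found at one grid point warms
#' the start set of the next, in both sweep directions), annotates stability,
#' and refines the saddle-node folds by bisection on branch existence down to
#' a stress resolution `fold_tol`.
#'
#' `sn_on` is the stress at which the low (survival) branch disappears;
#' `sn_off` the stress at which the high (death) branch disappears.  Either
#' fold can be absent: `sn_on_status = "above_scan_max"` when the low branch
#' persists to the end of the scan, `sn_off_status = "below_scan_min"` when
#' the death branch still exists at the scan minimum (for a scan starting at
#' stress 0 this is the irreversible-switch signature), and `"no_fold"` when
#' the system is monostable throughout.
#'
#' @param params a [upr_params] object (its `stress` field is ignored).
#' @param stress_range numeric length-2 scan range; default `c(0, 60)`,
#'   bracketing both scenario stress levels (25, 40).
#' @param n number of grid points (>= 2; default 600).
#' @param fold_tol stress resolution of the fold bisection (default 0.01).
#' @return an object of class `upr_curve`: list with `points` (data frame
#'   `stress`, the four state variables, `stable`, `max_re`, `branch_id`),
#'   `sn_on`, `sn_on_status`, `sn_off`, `sn_off_status`, `stress_range`,
#'   `n`, `params`.
#' @export
#' @examples
#' \donttest{
#' curve <- signal_response(default_params(), n = 200)
#' curve$sn_on
#' }
signal_response <- function(params, stress_range = c(0, 60), n = 600, fold_tol = 0.01) {
  stopifnot(length(stress_range) == 2L, stress_range[1] < stress_range[2], n >= 2)
  grid <- seq(stress_range[1], stress_range[2], length.out = n)

  # upward sweep with continuation
  per_point <- vector("list", n)
  warm <- NULL
  for (i in seq_len(n)) {
    ss <- .states_at(params, grid[i], warm = warm)
    per_point[[i]] <- ss
    warm <- as.matrix(ss[, .upr_state_names])
  }
  # downward sweep picks up branches that only connect from above (e.g. the
  # death branch below its fold)
  warm <- NULL
  for (i in rev(seq_len(n))) {
    ss_prev <- per_point[[i]]
    ss <- .states_at(params, grid[i],
                     warm = rbind(warm, as.matrix(ss_prev[, .upr_state_names])))
    per_point[[i]] <- ss
    warm <- as.matrix(ss[, .upr_state_names])
  }

  pts <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(stress = grid[i], per_point[[i]])
  }))
  rownames(pts) <- NULL
  pts$branch_id <- .assign_branches(pts)

  folds <- .locate_folds(params, grid, per_point, fold_tol)

  structure(
    list(points = pts,
         sn_on = folds$sn_on, sn_on_status = folds$sn_on_status,
         sn_off = folds$sn_off, sn_off_status = folds$sn_off_status,
         stress_range = stress_range, n = n, params = params),
    class = "upr_curve"
  )
}

# Greedy nearest-neighbour branch labelling across the stress grid; a root is
# attached to the active branch whose last state is closest (smallest
# state-space jump), otherwise it opens a new branch.
.assign_branches <- function(pts, jump_tol = 0.25) {
  ids <- integer(nrow(pts))
  active <- list()  # branch id -> last state
  next_id <- 1L
  for (s in unique(pts$stress)) {
    idx <- which(pts$stress == s)
    claimed <- character(0)
    for (j in idx) {
      x <- unlist(pts[j, .upr_state_names])
      best <- NA_character_; best_d <- Inf
      for (b in setdiff(names(active), claimed)) {
        d <- max(abs(active[[b]] - x))
        if (d < best_d) { best_d <- d; best <- b }
      }
      if (!is.na(best) && best_d < jump_tol) {
        ids[j] <- as.integer(best)
        claimed <- c(claimed, best)
        active[[best]] <- x
      } else {
        ids[j] <- next_id
        active[[as.character(next_id)]] <- x
        next_id <- next_id + 1L
      }
    }
  }
  ids
}

# Identify the low/high stable branch of a steady-state table.
.low_state <- function(ss) {
  st <- ss[ss$stable, , drop = FALSE]
  if (!nrow(st)) return(NULL)
  unlist(st[which.min(st$apop), .upr_state_names])
}
.high_state <- function(ss) {
  st <- ss[ss$stable, , drop = FALSE]
  if (!nrow(st)) return(NULL)
  unlist(st[which.max(st$apop), .upr_state_names])
}

# Does a branch (identified by a warm-start state) persist at `stress`?
# Newton from the warm start must converge to a stable root that stays close
# to the continuation (no large state-space jump).
.branch_exists_at <- function(params, stress, warm_state, jump_tol = 0.25) {
  p <- params
  p[["stress"]] <- stress
  r <- .newton_root(warm_state, p)
  if (is.null(r)) return(list(exists = FALSE))
  if (max(abs(r - warm_state)) > jump_tol) return(list(exists = FALSE))
  st <- .stability(r, p)
  if (!st$stable) return(list(exists = FALSE))
  list(exists = TRUE, state = r)
}

# Fold localisation by branch continuation.  Starting inside the bistable
# window, the low (survival) branch is followed upward in stress and the
# high (death) branch downward, matching each grid point's stable states by
# smallest state-space jump; the grid point where the branch is lost
# brackets its fold, which bisection on branch existence then refines to
# `tol`.  This does not assume the bistable window's edges coincide with
# the branch folds (the survival branch can be an isola whose low-stress
# fold lies inside a region where the death branch persists).
.locate_folds <- function(params, grid, per_point, tol, jump_tol = 0.25) {
  n <- length(grid)
  two_stable <- vapply(per_point, function(ss) sum(ss$stable) >= 2L, logical(1))

  out <- list(sn_on = NA_real_, sn_on_status = "no_fold",
              sn_off = NA_real_, sn_off_status = "no_fold")
  if (!any(two_stable)) return(out)

  # nearest stable continuation of `state` among the roots at grid point i
  follow <- function(state, i) {
    ss <- per_point[[i]]
    st <- ss[ss$stable, , drop = FALSE]
    if (!nrow(st)) return(NULL)
    d <- apply(st[, .upr_state_names, drop = FALSE], 1,
               function(x) max(abs(x - state)))
    if (min(d) > jump_tol) return(NULL)
    unlist(st[which.min(d), .upr_state_names])
  }

  refine <- function(lo, hi, warm, from_below) {
    # branch exists at `lo` (from_below) or at `hi` (!from_below)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      ex <- .branch_exists_at(params, mid, warm, jump_tol = jump_tol)
      if (ex$exists) {
        warm <- ex$state
        if (from_below) lo <- mid else hi <- mid
      } else {
        if (from_below) hi <- mid else lo <- mid
      }
    }
    (lo + hi) / 2
  }

  win <- range(which(two_stable))

  # SN_on: follow the low branch upward from inside the window
  cur <- .low_state(per_point[[win[1]]])
  i <- win[1]
  while (i < n) {
    nxt <- follow(cur, i + 1L)
    if (is.null(nxt)) break
    cur <- nxt
    i <- i + 1L
  }
  if (i == n) {
    out$sn_on_status <- "above_scan_max"
  } else {
    out$sn_on <- refine(grid[i], grid[i + 1L], cur, from_below = TRUE)
    out$sn_on_status <- "found"
  }

  # SN_off: follow the high branch downward from inside the window
  cur <- .high_state(per_point[[win[2]]])
  i <- win[2]
  while (i > 1L) {
    nxt <- follow(cur, i - 1L)
    if (is.null(nxt)) break
    cur <- nxt
    i <- i - 1L
  }
  if (i == 1L) {
    out$sn_off_status <- "below_scan_min"
  } else {
    out$sn_off <- refine(grid[i - 1L], grid[i], cur, from_below = FALSE)
    out$sn_off_status <- "found"
  }
  out
}

#' Classify the reversibility of the apoptosis switch
#'
#' A curve computed over a range starting at stress 0 is `"irreversible"`
#' when the death branch persists all the way to the scan minimum (its
#' deactivation fold lies at or below zero stress), `"reversible"` when the
#' deactivation fold sits at positive stress, and `"no_switch"` when the
#' response is monostable (no folds).
#'
#' @param curve a `upr_curve` from [signal_response()].
#' @return one of `"irreversible"`, `"reversible"`, `"no_switch"`.
#' @export
classify_reversibility <- function(curve) {
  stopifnot(inherits(curve, "upr_curve"))
  if (curve$sn_off_status == "below_scan_min") return("irreversible")
  if (curve$sn_off_status == "found") {
    return(if (curve$sn_off > 0) "reversible" else "irreversible")
  }
  if (curve$sn_on_status == "above_scan_max") return("no_switch")
  "no_switch"
}

#' Shift of the apoptosis activation threshold between two parameter sets
#'
#' Computes `SN_on(b) - SN_on(a)`: positive when the perturbation moves the
#' activation fold to the right (higher stress needed to switch on death),
#' negative when it moves left.  `+Inf` when the perturbed low branch never
#' disappears within the scan.
#'
#' @param params_a,params_b parameter sets to compare.
#' @param ... passed to [signal_response()].
#' @return signed stress difference (possibly `Inf`).
#' @export
threshold_shift <- function(params_a, params_b, ...) {
  ca <- signal_response(params_a, ...)
  cb <- signal_response(params_b, ...)
  if (ca$sn_on_status != "found") {
    stop("reference curve has no activation fold in the scanned range", call. = FALSE)
  }
  if (cb$sn_on_status == "above_scan_max") return(Inf)
  if (cb$sn_on_status != "found") {
    stop("perturbed curve has no activation fold in the scanned range", call. = FALSE)
  }
  cb$sn_on - ca$sn_on
}

#' Quasi-static stress sweep (hysteresis experiment in the time domain)
#'
#' Steps the stress level along `stresses`, integrating the model for
#' `t_equil` time units at each level from the final state of the previous
#' one.  Sweeping up from the origin and then down from the final state
#' reveals the hysteresis loop of the switch: the upward sweep jumps to the
#' death branch near the activation fold, the downward sweep leaves it near
#' the deactivation fold, or never for an irreversible switch.
#'
#' @param params a [upr_params] object.
#' @param stresses numeric vector of stress levels visited in order.
#' @param t_equil relaxation time at each level.
#' @param initial_state starting state for the first level.
#' @return data frame `stress`, `perk`, `ire1`, `auto`, `apop` (the relaxed
#'   state at each level, in visit order).
#' @export
sweep_stress <- function(params, stresses, t_equil = 400,
                         initial_state = c(perk = 0, ire1 = 0, auto = 0, apop = 0)) {
  state <- .as_state(initial_state)
  rows <- vector("list", length(stresses))
  for (i in seq_along(stresses)) {
    p <- params
    p[["stress"]] <- stresses[i]
    sol <- deSolve::lsoda(state, times = c(0, t_equil), func = .upr_deriv,
                          parms = as.numeric(unclass(p)[.upr_param_names]),
                          jacfunc = .upr_jac, jactype = "fullusr",
                          rtol = 1e-8, atol = 1e-10)
    state <- sol[nrow(sol), .upr_state_names]
    rows[[i]] <- c(stress = stresses[i], state)
  }
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' @export
print.upr_curve <- function(x, ...) {
  cat("<upr_curve> signal-response curve,",
      sprintf("stress in [%g, %g], %d points\n", x$stress_range[1], x$stress_range[2], x$n))
  cat(sprintf("  SN_on:  %s (%s)\n",
              if (is.na(x$sn_on)) "-" else sprintf("%.3f", x$sn_on), x$sn_on_status))
  cat(sprintf("  SN_off: %s (%s)\n",
              if (is.na(x$sn_off)) "-" else sprintf("%.3f", x$sn_off), x$sn_off_status))
  cat("  reversibility:", classify_reversibility(x), "\n")
  invisible(x)
}

#' Plot a signal-response curve
#'
#' Apoptosis-inducer steady state against stress; solid markers for stable
#' branches, open markers for unstable.
#' @param x a `upr_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.upr_curve <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$stress, pts$apop, type = "n",
                 xlab = "ER stress (a.u.)", ylab = "apoptosis inducer (a.u.)", ...)
  st <- pts[pts$stable, ]
  un <- pts[!pts$stable, ]
  graphics::points(st$stress, st$apop, pch = 16, cex = 0.4, col = "red")
  graphics::points(un$stress, un$apop, pch = 1, cex = 0.4, col = "grey40")
  if (!is.na(x$sn_on)) graphics::abline(v = x$sn_on, lty = 3)
  if (!is.na(x$sn_off)) graphics::abline(v = x$sn_off, lty = 3)
  invisible(x)
}

#' Maximum number of coexisting stable steady states over a scan
#'
#' Convenience accessor used to assert bistability: the largest count of
#' simultaneously stable steady states at any scanned stress value.
#'
#' @param curve a `upr_curve`.
#' @return integer.
#' @export
max_stable_states <- function(curve) {
  stopifnot(inherits(curve, "upr_curve"))
  pts <- curve$points
  max(vapply(split(pts$stable, pts$stress), sum, integer(1)))
}
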