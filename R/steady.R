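# Steady-state location by damped Newton iteration with the analytic
# Jacobian, multi-start over the state box, and linear stability from the
# Jacobian eigenvalues.

# One damped Newton run from `start`; returns the root (named) or NULL.
# Hot path: operates on the raw parameter vector via the positional rhs.
.newton_root <- function(start, params, tol = 1e-11, maxit = 60L, box_slack = 1e-8) {
  p <- as.numeric(unclass(params)[.upr_param_names])
  totals <- p[2:5]
  x <- as.numeric(.as_state(start))
  x <- pmin(pmax(x, 0), totals)
  lower <- -0.05 * totals
  upper <- 1.05 * totals
  for (it in seq_len(maxit)) {
    f <- .rhs_fast(x, p)
    if (max(abs(f)) < tol) {
      if (any(x < -box_slack) || any(x > totals + box_slack)) return(NULL)
      x <- pmin(pmax(x, 0), totals)
      names(x) <- .upr_state_names
      return(x)
    }
    J <- .jac_fast(x, p)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    f0 <- sum(f^2)
    repeat {
      # keep iterates near the physical box; roots outside are discarded anyway
      xn <- pmin(pmax(x + lambda * step, lower), upper)
      fn <- .rhs_fast(xn, p)
      if (all(is.finite(fn)) && (sum(fn^2) < f0 || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    if (max(abs(xn - x)) < 1e-14 && max(abs(fn)) > tol) return(NULL)
    x <- xn
  }
  NULL
}

# Default start set: coarse grid over the box plus the origin.
.default_starts <- function(params, levels = c(0.02, 0.5, 0.98)) {
  totals <- state_totals(params)
  g <- expand.grid(perk = levels * totals[["perk"]],
                   ire1 = levels * totals[["ire1"]],
                   auto = levels * totals[["auto"]],
                   apop = levels * totals[["apop"]],
                   KEEP.OUT.ATTRS = FALSE)
  starts <- rbind(as.matrix(g), rep(0, 4))
  colnames(starts) <- .upr_state_names
  starts
}

.dedupe_states <- function(states, tol = 1e-6) {
  if (!length(states)) return(states)
  kept <- list()
  for (s in states) {
    dup <- any(vapply(kept, function(k) max(abs(k - s)) < tol, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- s
  }
  kept
}

# Stability from the leading eigenvalue real part.  Marginal cases are
# re-polished at tighter tolerance before classifying.
.stability <- function(state, params, margin = 1e-9) {
  p <- as.numeric(unclass(params)[.upr_param_names])
  re <- max(Re(eigen(.jac_fast(as.numeric(state), p), only.values = TRUE)$values))
  if (abs(re) <= margin) {
    polished <- .newton_root(state, params, tol = 1e-13)
    if (!is.null(polished)) {
      re <- max(Re(eigen(.jac_fast(as.numeric(polished), p), only.values = TRUE)$values))
    }
  }
  list(stable = re < -margin, max_re = re)
}

#' Locate all steady states of the network within the state box
#'
#' Runs damped Newton iterations from a multi-start grid (plus any
#' caller-supplied warm starts), deduplicates the converged roots, and
#' annotates each with linear stability from the eigenvalues of the analytic
#' Jacobian.
#'
#' @param params a [upr_params] object.
#' @param starts optional numeric matrix of additional start states (columns
#'   `perk, ire1, auto, apop`); the default coarse grid is always included
#'   unless `grid = FALSE`.
#' @param grid include the default 3^4 start grid (default `TRUE`).
#' @param dedup_tol max-norm tolerance below which two roots are considered
#'   the same steady state.
#' @return a data frame with columns `perk`, `ire1`, `auto`, `apop`,
#'   `stable` (logical) and `max_re` (leading eigenvalue real part), ordered
#'   by increasing `apop`.
#' @export
#' @examples
#' find_steady_states(default_params(stress = 40))
find_steady_states <- function(params, starts = NULL, grid = TRUE, dedup_tol = 1e-6) {
  smat <- if (isTRUE(grid)) .default_starts(params) else NULL
  if (!is.null(starts)) {
    starts <- matrix(as.numeric(starts), ncol = 4,
                     dimnames = list(NULL, .upr_state_names))
    smat <- rbind(smat, starts)
  }
  if (is.null(smat) || !nrow(smat)) stop("no start states supplied", call. = FALSE)
  roots <- list()
  for (i in seq_len(nrow(smat))) {
    r <- .newton_root(smat[i, ], params)
    if (!is.null(r)) roots[[length(roots) + 1L]] <- r
  }
  roots <- .dedupe_states(roots, tol = dedup_tol)
  if (!length(roots)) {
    stop("steady-state search failed: no root located (a forward-invariant ",
         "compact box must contain at least one equilibrium)", call. = FALSE)
  }
  st <- lapply(roots, .stability, params = params)
  out <- do.call(rbind, lapply(roots, function(r) as.data.frame(as.list(r))))
  out$stable <- vapply(st, `[[`, logical(1), "stable")
  out$max_re <- vapply(st, `[[`, numeric(1), "max_re")
  out <- out[order(out$apop), , drop = FALSE]
  rownames(out) <- NULL
  out
}
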