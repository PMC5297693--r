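# Parameter container for the four-node ER-stress decision network.
#
# Naming: `stress` is the (dimensionless) ER stress signal; *T suffixes are
# total (active + inactive) capacities; k_* are rate constants; J_* are the
# Michaelis constants of the inducer activation/inactivation fluxes.  Setting
# a J to Inf selects the linear (mass-action) limit of that flux.

.upr_param_names <- c(
  "stress",
  "PERKT", "IRE1T", "AT_auto", "AT_apop",
  "k_sp", "k_si", "k_ip", "k_pi", "k_dp", "k_di",
  "k_pa", "k_ia", "k_pap", "k_iap",
  "k_da", "k_dap", "k_x_aa", "k_x_apa",
  "J_a_on", "J_a_off", "J_ap_on", "J_ap_off"
)

.upr_state_names <- c("perk", "ire1", "auto", "apop")

#' Construct a parameter set for the UPR decision network
#'
#' Bundles all rate constants, total capacities, saturation constants and the
#' ER stress signal of the four-variable model into a validated object.
#' Start from [default_params()] and override individual values rather than
#' supplying all fields by hand.
#'
#' @param ... named numeric scalars; every one of the 23 model parameters must
#'   be present (see Details).
#' @param check if `TRUE` (default), enforce the structural invariants of the
#'   wiring: non-negativity, the strong/weak arrow ordering
#'   `k_ia > k_pa` and `k_pap > k_iap`, and the presence of both the
#'   sensor positive feedback (`k_ip`, `k_pi` > 0) and the double-negative
#'   inducer loop (`k_x_aa`, `k_x_apa` > 0).  Pass `check = FALSE` to build
#'   deliberately degenerate sets (e.g. uncoupled nodes) for analysis.
#'
#' @details
#' Fields: `stress` (signal, a.u.); totals `PERKT`, `IRE1T`, `AT_auto`,
#' `AT_apop`; sensor activation `k_sp`, `k_si` (stress input) and `k_ip`,
#' `k_pi` (mutual cross-activation); sensor inactivation `k_dp`, `k_di`;
#' inducer activation weights `k_pa`, `k_ia` (autophagy) and `k_pap`,
#' `k_iap` (apoptosis); basal inducer inactivation `k_da`, `k_dap`;
#' double-negative couplings `k_x_aa` (apoptosis represses autophagy) and
#' `k_x_apa` (autophagy represses apoptosis); Michaelis constants
#' `J_a_on`, `J_a_off`, `J_ap_on`, `J_ap_off` of the inducer fluxes
#' (zero-order ultrasensitive regime when much smaller than the totals;
#' `Inf` selects the linear mass-action limit).
#'
#' @return an object of class `upr_params` (a named numeric vector).
#' @seealso [default_params()], [knockdown_params()], [preset_params()]
#' @export
#' @examples
#' p <- default_params(stress = 40)
#' p["PERKT"]
upr_params <- function(..., check = TRUE) {
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) && is.list(vals[[1L]])) {
    vals <- vals[[1L]]
  }
  nm <- names(vals)
  missing <- setdiff(.upr_param_names, nm)
  if (length(missing)) {
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(nm, .upr_param_names)
  if (length(extra)) {
    stop("unknown parameters: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  p <- vapply(.upr_param_names, function(k) as.numeric(vals[[k]]), numeric(1))
  if (anyNA(p)) stop("parameters must be numeric and non-missing", call. = FALSE)
  finite_ok <- is.finite(p) | (names(p) %in% c("J_a_on", "J_a_off", "J_ap_on", "J_ap_off") & is.infinite(p) & p > 0)
  if (!all(finite_ok)) stop("parameters must be finite (J_* may be +Inf)", call. = FALSE)
  if (any(p < 0)) stop("all parameters must be >= 0", call. = FALSE)
  obj <- structure(p, class = "upr_params")
  if (isTRUE(check)) validate_params(obj)
  obj
}

#' Validate structural invariants of a parameter set
#'
#' @param params a `upr_params` object.
#' @return `params`, invisibly; errors if an invariant is violated.
#' @keywords internal
validate_params <- function(params) {
  p <- unclass(params)
  if (any(p < 0)) stop("all parameters must be >= 0", call. = FALSE)
  if (!(p[["k_ia"]] > p[["k_pa"]])) {
    stop("wiring requires k_ia > k_pa (IRE-1 acts more strongly on autophagy)", call. = FALSE)
  }
  if (!(p[["k_pap"]] > p[["k_iap"]])) {
    stop("wiring requires k_pap > k_iap (PERK acts more strongly on apoptosis)", call. = FALSE)
  }
  if (!(p[["k_ip"]] > 0 && p[["k_pi"]] > 0)) {
    stop("default wiring requires the PERK<->IRE-1 positive feedback (k_ip, k_pi > 0)", call. = FALSE)
  }
  if (!(p[["k_x_aa"]] > 0 && p[["k_x_apa"]] > 0)) {
    stop("default wiring requires the double-negative inducer loop (k_x_aa, k_x_apa > 0)", call. = FALSE)
  }
  invisible(params)
}

#' The shipped calibrated default parameter set
#'
#' The defaults were found by constraint-based search ([search_parameters()])
#' against the qualitative behaviour catalogue encoded in
#' [check_constraints()]: a bistable apoptosis switch with activation
#' threshold between stress 25 and 40, irreversible for the intact network,
#' rendered reversible (and shifted right/left) by the PERK/IRE-1 knockdown
#' presets, transient apoptosis at low stress, mutual exclusion of the two
#' inducers, and autophagy-before-apoptosis ordering at high stress.
#' Time is dimensionless; under the cosmetic axis mapping of 2.5 minutes per
#' time unit the high-stress apoptosis switch falls near the 90-120 minute
#' analogue of the experimental time courses.
#'
#' @param stress ER stress level to install in the set (default 0).
#' @param ... further overrides of individual parameters by name.
#' @param check forwarded to [upr_params()]; disable to build degenerate
#'   variants (uncoupled nodes, missing feedback legs) for analysis.
#' @return a `upr_params` object.
#' @export
#' @examples
#' default_params(stress = 25)
default_params <- function(stress = 0, ..., check = TRUE) {
  p <- .upr_default_values
  p[["stress"]] <- stress
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), .upr_param_names)
    if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "), call. = FALSE)
    p[names(ov)] <- vapply(ov, as.numeric, numeric(1))
  }
  do.call(upr_params, c(as.list(p), list(check = check)))
}

#' Scale a sensor total, mimicking knockdown of PERK or IRE-1
#'
#' Models siRNA silencing / chemical inhibition of one UPR branch as a
#' reduction of the total sensor capacity (`PERKT` or `IRE1T`); every other
#' parameter is untouched.
#'
#' @param params a `upr_params` object.
#' @param target `"PERK"` or `"IRE1"`.
#' @param fraction remaining fraction of the total, in (0, 1].
#' @return a modified `upr_params` object.
#' @export
#' @examples
#' knockdown_params(default_params(), "PERK", 0.2)["PERKT"]
knockdown_params <- function(params, target = c("PERK", "IRE1"), fraction) {
  target <- match.arg(target)
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be a single number in (0, 1]", call. = FALSE)
  }
  stopifnot(inherits(params, "upr_params"))
  field <- if (target == "PERK") "PERKT" else "IRE1T"
  params[[field]] <- unclass(params)[[field]] * fraction
  params
}

#' Named perturbation presets
#'
#' `"default"` returns the intact network; `"siPERK"` scales `PERKT` by 0.2;
#' `"IRE1low"` scales `IRE1T` by 0.1 (chemical IRE-1 inhibition analogue).
#'
#' @param name preset name.
#' @param params base parameter set the preset is applied to
#'   (default [default_params()]).
#' @return a `upr_params` object.
#' @export
preset_params <- function(name = c("default", "siPERK", "IRE1low"), params = default_params()) {
  name <- match.arg(name)
  switch(name,
    default = params,
    siPERK  = knockdown_params(params, "PERK", 0.2),
    IRE1low = knockdown_params(params, "IRE1", 0.1)
  )
}

#' @export
print.upr_params <- function(x, ...) {
  cat("<upr_params> four-node ER-stress decision network\n")
  cat(sprintf("  stress = %g; totals: PERKT = %g, IRE1T = %g, AT_auto = %g, AT_apop = %g\n",
              x[["stress"]], x[["PERKT"]], x[["IRE1T"]], x[["AT_auto"]], x[["AT_apop"]]))
  rest <- setdiff(.upr_param_names, c("stress", "PERKT", "IRE1T", "AT_auto", "AT_apop"))
  v <- vapply(rest, function(k) x[[k]], numeric(1))
  cat("  rates/saturations:\n")
  print(v)
  invisible(x)
}

#' @export
`[.upr_params` <- function(x, i, ...) {
  out <- NextMethod()
  out
}

#' Replace one parameter, keeping the class
#' @export
#' @keywords internal
`[[<-.upr_params` <- function(x, i, value) {
  if (!i %in% .upr_param_names) stop("unknown parameter: ", i, call. = FALSE)
  y <- unclass(x)
  y[[i]] <- as.numeric(value)
  structure(y, class = "upr_params")
}

# Shipped calibrated default values (frozen output of search_parameters();
# see the methods vignette for the constraint catalogue they satisfy).
.upr_default_values <- c(
  stress   = 0,
  PERKT    = 1, IRE1T = 1, AT_auto = 1, AT_apop = 1,
  k_sp     = 0.003, k_si = 0.003,
  k_ip     = 0.18,  k_pi = 0.18,
  k_dp     = 0.15,  k_di = 0.15,
  k_pa     = 0.07,  k_ia = 0.50,
  k_pap    = 0.105, k_iap = 0.021,
  k_da     = 0.025, k_dap = 0.0042,
  k_x_aa   = 1.0,   k_x_apa = 0.0721,
  J_a_on   = 0.05,  J_a_off = 0.01,
  J_ap_on  = 0.05,  J_ap_off = 0.01
)
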