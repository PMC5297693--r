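# File formats: YAML parameter/scenario configuration, the XPP .ode dialect
# (export and companion reader), and tidy CSV/JSON output of trajectories,
# curves and synthetic time courses.  All numeric output is written at full
# precision so that round trips are exact.

.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.infinite(v)) if (v > 0) "Inf" else "-Inf" else sprintf("%.17g", v)
  }, character(1))
}

#' Write a parameter set (and optional scenario section) as YAML
#'
#' Flat `parameters:` mapping plus an optional named `scenarios:` section.
#'
#' @param params a [upr_params] object.
#' @param path output file.
#' @param scenarios optional named list describing scenarios (stored
#'   verbatim).
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path, scenarios = NULL) {
  stopifnot(inherits(params, "upr_params"))
  cfg <- list(parameters = as.list(unclass(params)))
  if (!is.null(scenarios)) cfg$scenarios <- scenarios
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' Read a parameter set from a YAML configuration
#'
#' @param path file written by [write_params_config()] (or hand-authored
#'   with the same layout; a bare flat mapping is also accepted).
#' @param check forwarded to [upr_params()].
#' @return a `upr_params` object; any `scenarios` section is attached as
#'   attribute `"scenarios"`.
#' @export
read_params_config <- function(path, check = TRUE) {
  cfg <- yaml::read_yaml(path)
  vals <- if (!is.null(cfg$parameters)) cfg$parameters else cfg
  vals <- lapply(vals, function(v) if (is.character(v)) as.numeric(v) else v)
  p <- do.call(upr_params, c(vals[.upr_param_names], list(check = check)))
  if (!is.null(cfg$scenarios)) attr(p, "scenarios") <- cfg$scenarios
  p
}

# Derivative lines of the model in .ode syntax; the Michaelis denominators
# drop out for a flux whose J is infinite (linear limit).
.ode_equations <- function(params) {
  p <- unclass(params)
  actA <- "(k_pa*perk+k_ia*ire1)*(AT_auto-auto)"
  if (is.finite(p[["J_a_on"]])) actA <- paste0(actA, "/(J_a_on+AT_auto-auto)")
  inA <- "(k_da+k_x_aa*apop)*auto"
  if (is.finite(p[["J_a_off"]])) inA <- paste0(inA, "/(J_a_off+auto)")
  actD <- "(k_pap*perk+k_iap*ire1)*(AT_apop-apop)"
  if (is.finite(p[["J_ap_on"]])) actD <- paste0(actD, "/(J_ap_on+AT_apop-apop)")
  inD <- "(k_dap+k_x_apa*auto)*apop"
  if (is.finite(p[["J_ap_off"]])) inD <- paste0(inD, "/(J_ap_off+apop)")
  c(
    "dperk/dt=(k_sp*stress+k_ip*ire1)*(PERKT-perk)-k_dp*perk",
    "dire1/dt=(k_si*stress+k_pi*perk)*(IRE1T-ire1)-k_di*ire1",
    paste0("dauto/dt=", actA, "-", inA),
    paste0("dapop/dt=", actD, "-", inD)
  )
}

#' Export a parameter set as an XPP .ode file
#'
#' Emits the model in the XPP dialect: one derivative line per variable,
#' `par name=value` lines at full precision, `init` lines, and the `done`
#' terminator.  [parse_ode()] reads the emitted file back to an identical
#' parameter set.
#'
#' @param params a [upr_params] object.
#' @param path optional output file; when `NULL` the text is returned only.
#' @param init initial state written to the `init` lines.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
#' @examples
#' cat(head(export_ode(default_params()), 6), sep = "\n")
export_ode <- function(params, path = NULL,
                       init = c(perk = 0, ire1 = 0, auto = 0, apop = 0)) {
  stopifnot(inherits(params, "upr_params"))
  p <- unclass(params)
  init <- .as_state(init)
  lines <- c(
    "# four-node ER stress life-and-death decision network",
    .ode_equations(params),
    sprintf("par %s=%s", .upr_param_names, .fmt_num(p[.upr_param_names])),
    sprintf("init %s=%s", .upr_state_names, .fmt_num(init)),
    "done"
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse an .ode file written by [export_ode()]
#'
#' Companion reader for the package's own .ode dialect: collects
#' `par`/`param` lines into a parameter set and `init` lines into the
#' initial state.
#'
#' @param x path to an .ode file, or its lines as a character vector.
#' @param check forwarded to [upr_params()].
#' @return a `upr_params` object with attributes `"init"` (named initial
#'   state) and `"equations"` (the derivative lines, e.g. for symbolic
#'   cross-checking).
#' @export
parse_ode <- function(x, check = TRUE) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- trimws(lines)
  par_lines <- grep("^(par|param)\\s", lines, value = TRUE)
  kv <- do.call(rbind, lapply(par_lines, function(l) {
    body <- sub("^(par|param)\\s+", "", l)
    parts <- strsplit(body, "=", fixed = TRUE)[[1L]]
    c(trimws(parts[1L]), trimws(parts[2L]))
  }))
  if (is.null(kv)) stop("no par lines found", call. = FALSE)
  vals <- stats::setNames(as.numeric(kv[, 2L]), kv[, 1L])
  params <- do.call(upr_params, c(as.list(vals[.upr_param_names]), list(check = check)))

  init_lines <- grep("^init\\s", lines, value = TRUE)
  if (length(init_lines)) {
    ikv <- do.call(rbind, lapply(init_lines, function(l) {
      body <- sub("^init\\s+", "", l)
      parts <- strsplit(body, "=", fixed = TRUE)[[1L]]
      c(trimws(parts[1L]), trimws(parts[2L]))
    }))
    attr(params, "init") <- stats::setNames(as.numeric(ikv[, 2L]), ikv[, 1L])[.upr_state_names]
  }
  attr(params, "equations") <- grep("^d[a-z0-9]+/dt=", lines, value = TRUE)
  params
}

#' Write a trajectory as tidy CSV
#'
#' Long format: `time`, `variable`, `value`, `scenario`.
#'
#' @param trajectory a `upr_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "upr_trajectory"))
  sc <- attr(trajectory, "scenario")
  if (is.null(sc)) sc <- NA_character_
  long <- do.call(rbind, lapply(.upr_state_names, function(v) {
    data.frame(time = trajectory$time, variable = v,
               value = trajectory[[v]], scenario = sc)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy trajectory CSV back into wide form
#'
#' Data-only round trip of [write_trajectory_csv()]: the generating
#' parameters and protocol are not stored in the CSV.
#'
#' @param path file written by [write_trajectory_csv()].
#' @return data frame `time`, `perk`, `ire1`, `auto`, `apop` with attribute
#'   `scenario`.
#' @export
read_trajectory_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  wide <- stats::reshape(long[, c("time", "variable", "value")],
                         idvar = "time", timevar = "variable",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$time), c("time", .upr_state_names)]
  rownames(wide) <- NULL
  attr(wide, "scenario") <- long$scenario[1L]
  wide
}

#' Write a signal-response curve as CSV plus JSON summary
#'
#' The CSV holds one row per branch point (`stress`, `apop`, `stability`,
#' `branch_id`); the JSON summary records the folds and the reversibility
#' class.
#'
#' @param curve a `upr_curve`.
#' @param csv_path,json_path output files (either may be `NULL` to skip).
#' @return invisible list of the written paths.
#' @export
write_curve <- function(curve, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(curve, "upr_curve"))
  if (!is.null(csv_path)) {
    pts <- curve$points
    out <- data.frame(stress = pts$stress, apop = pts$apop,
                      stability = ifelse(pts$stable, "stable", "unstable"),
                      branch_id = pts$branch_id)
    utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    summary <- list(sn_on = curve$sn_on, sn_on_status = curve$sn_on_status,
                    sn_off = curve$sn_off, sn_off_status = curve$sn_off_status,
                    reversibility = classify_reversibility(curve),
                    stress_range = curve$stress_range, n = curve$n)
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(list(csv = csv_path, json = json_path))
}

#' Write a synthetic time course as tidy CSV with a JSON sidecar
#'
#' @param tc a `upr_timecourse`.
#' @param csv_path output CSV (`time`, `marker`, `replicate`, `intensity`).
#' @param json_path sidecar recording scenario, cv, seed and sampling; by
#'   default `csv_path` with extension `.json`.
#' @return invisible list of the written paths.
#' @export
write_timecourse_csv <- function(tc, csv_path,
                                 json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(tc, "upr_timecourse"))
  utils::write.csv(as.data.frame(tc), csv_path, row.names = FALSE, quote = FALSE)
  side <- list(scenario = attr(tc, "scenario"), cv = attr(tc, "cv"),
               seed = attr(tc, "seed"),
               sampling_interval = attr(tc, "sampling_interval"),
               horizon = attr(tc, "horizon"),
               n_replicates = max(tc$replicate))
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}
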