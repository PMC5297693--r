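# Synthetic densitometry-style readouts: noisy, interval-sampled,
# reference-normalized marker time courses generated from model trajectories.
# These emulate the statistical structure of immunoblot band-intensity
# panels (relative intensities, positive-valued multiplicative noise,
# a handful of replicates) so the phenotype pipeline can be validated
# without any experimental data.

# Preserve the caller's RNG state across internally-seeded draws.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Clean normalized marker matrix (times x markers) for a scenario.
.synth_base <- function(params, scenario, sampling_interval, horizon, trajectory = NULL) {
  if (sampling_interval > horizon) {
    stop("sampling interval larger than the horizon", call. = FALSE)
  }
  if (is.null(trajectory)) {
    trajectory <- run_scenario(scenario, params, horizon = horizon,
                               dt = min(1, sampling_interval))
  }
  times <- seq(0, horizon, by = sampling_interval)
  map <- marker_map()
  base <- vapply(names(map), function(m) {
    v <- stats::approx(trajectory$time, trajectory[[map[[m]]]], xout = times)$y
    mx <- max(v)
    if (mx > 0) v / mx else v
  }, numeric(length(times)))
  list(times = times, base = base, trajectory = trajectory)
}

# Lognormal multiplicative noise with unit mean and coefficient of
# variation `cv`; cv = 0 returns the input unchanged.
.apply_noise <- function(base, cv) {
  if (cv == 0) return(base)
  sdlog <- sqrt(log(1 + cv^2))
  noise <- stats::rlnorm(length(base), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  base * noise
}

#' Generate synthetic marker time courses for a scenario
#'
#' Simulates the scenario, maps the model variables to their experimental
#' markers ([marker_map()]), samples at a fixed interval, normalizes each
#' marker to its maximum over the series (densitometry-style relative
#' intensity), and applies multiplicative lognormal noise of coefficient of
#' variation `cv` independently per replicate.  Fully deterministic given
#' `(seed, inputs)`: replicate `r` uses the sub-seed `seed + 7919 * r`, so
#' replicates are independent yet individually reproducible, and the
#' caller's RNG state is untouched.
#'
#' @param params parameter set (default the shipped calibrated set).
#' @param scenario one of [upr_scenarios()].
#' @param sampling_interval sampling step in model time units (default 6,
#'   the 15-minute analogue under the cosmetic mapping of 2.5 minutes per
#'   model time unit).
#' @param n_replicates number of replicate series (default 3, the usual
#'   number of parallel blot experiments).
#' @param cv coefficient of variation of the multiplicative noise
#'   (default 0.15).
#' @param seed integer seed.
#' @param horizon simulated time (default 120).
#' @return object of class `upr_timecourse`: a long data frame with columns
#'   `time`, `marker`, `replicate`, `intensity`, and attributes `scenario`,
#'   `cv`, `seed`, `sampling_interval`, `params`, `noiseless` (the clean
#'   normalized times-by-markers matrix) and `times`.
#' @export
#' @examples
#' tc <- generate_timecourse(scenario = "high_stress", cv = 0, seed = 1)
#' head(tc)
generate_timecourse <- function(params = default_params(),
                                scenario = "high_stress",
                                sampling_interval = 6, n_replicates = 3,
                                cv = 0.15, seed = 1, horizon = 120) {
  if (!is.numeric(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  sb <- .synth_base(params, scenario, sampling_interval, horizon)
  markers <- colnames(sb$base)
  reps <- lapply(seq_len(n_replicates), function(r) {
    noisy <- .with_seed(seed + 7919 * r, .apply_noise(sb$base, cv))
    data.frame(time = rep(sb$times, times = length(markers)),
               marker = rep(markers, each = length(sb$times)),
               replicate = r,
               intensity = as.vector(noisy))
  })
  out <- do.call(rbind, reps)
  structure(out,
            class = c("upr_timecourse", "data.frame"),
            scenario = scenario, cv = cv, seed = seed,
            sampling_interval = sampling_interval, horizon = horizon,
            params = params, noiseless = sb$base, times = sb$times)
}

# Aggregate the markers of one replicate back onto model variables
# (mean across the markers proxying each variable).
.variable_series <- function(tc, replicate) {
  d <- tc[tc$replicate == replicate, , drop = FALSE]
  map <- marker_map()
  times <- sort(unique(d$time))
  vars <- unique(unname(map))
  out <- data.frame(time = times)
  for (v in vars) {
    mk <- names(map)[map == v]
    sub <- d[d$marker %in% mk, , drop = FALSE]
    agg <- tapply(sub$intensity, sub$time, mean)
    out[[v]] <- as.numeric(agg[as.character(times)])
  }
  out
}

#' Phenotype call from a synthetic marker time course
#'
#' Averages the markers proxying each model variable, extracts timing
#' features on the normalized scale (thresholds relative to each series'
#' maximum), and calls the phenotype, optionally against a reference feature
#' set (for the delayed-death distinction).
#'
#' @param tc a `upr_timecourse`.
#' @param replicate which replicate to call (default 1).
#' @param reference optional reference feature set (see
#'   [call_phenotype()]); typically the noiseless intact-network high-stress
#'   features at the same sampling.
#' @param ... passed to [extract_features()].
#' @return a `upr_phenotype`.
#' @export
phenotype_from_timecourse <- function(tc, replicate = 1, reference = NULL, ...) {
  stopifnot(inherits(tc, "upr_timecourse"))
  vs <- .variable_series(tc, replicate)
  feats <- list(
    auto = extract_features(vs$auto, vs$time, scale = max(vs$auto), ...),
    apop = extract_features(vs$apop, vs$time, scale = max(vs$apop), ...),
    dt = stats::median(diff(vs$time))
  )
  call_phenotype(feats, reference = reference)
}

#' Phenotype recovery rates of the synthetic pipeline
#'
#' For each scenario and noise level, generates `n_replicates` noisy marker
#' time courses, calls the phenotype of each, and reports the fraction of
#' replicates whose call matches the noiseless call of the same scenario.
#' Each scenario is simulated once; noise and calling are repeated per
#' replicate and noise level.
#'
#' @param params parameter set.
#' @param scenarios character vector of scenario names.
#' @param cv_grid noise levels to test.
#' @param n_replicates replicates per scenario and noise level.
#' @param seed integer seed.
#' @param sampling_interval,horizon as in [generate_timecourse()].
#' @param ... passed to [extract_features()] via the phenotype calls.
#' @return data frame `scenario`, `cv`, `recovery`, `noiseless_class`.
#' @export
recovery_study <- function(params = default_params(),
                           scenarios = c("low_stress", "high_stress",
                                         "siPERK_high_stress", "IRE1low_high_stress"),
                           cv_grid = c(0, 0.05, 0.1, 0.2),
                           n_replicates = 50, seed = 1,
                           sampling_interval = 6, horizon = 120, ...) {
  rows <- list()
  for (sc in scenarios) {
    sb <- .synth_base(params, sc, sampling_interval, horizon)
    markers <- colnames(sb$base)
    call_of <- function(mat) {
      tcrep <- data.frame(time = rep(sb$times, times = length(markers)),
                          marker = rep(markers, each = length(sb$times)),
                          replicate = 1L, intensity = as.vector(mat))
      tcrep <- structure(tcrep, class = c("upr_timecourse", "data.frame"))
      phenotype_from_timecourse(tcrep, 1L, reference = .recovery_reference(params, sampling_interval, horizon), ...)$class
    }
    clean_class <- call_of(sb$base)
    for (cv in cv_grid) {
      matched <- vapply(seq_len(n_replicates), function(r) {
        noisy <- .with_seed(seed + 7919 * r + 104729 * match(sc, scenarios) +
                              round(1e6 * cv),
                            .apply_noise(sb$base, cv))
        call_of(noisy) == clean_class
      }, logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, cv = cv, recovery = mean(matched),
        noiseless_class = clean_class)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Noiseless intact-network high-stress features at the given sampling:
# the reference for the delayed-death comparison.  Memoised per call chain.
.recovery_reference <- local({
  cache <- new.env(parent = emptyenv())
  function(params, sampling_interval, horizon) {
    key <- paste(c(unclass(params), sampling_interval, horizon), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    sb <- .synth_base(params, "high_stress", sampling_interval, horizon)
    val <- list(
      auto = extract_features(sb$base[, "LC3II"], sb$times, scale = max(sb$base[, "LC3II"])),
      apop = extract_features(sb$base[, "CHOP"], sb$times, scale = max(sb$base[, "CHOP"])),
      dt = sampling_interval
    )
    cache[[key]] <- val
    val
  }
})

#' @export
print.upr_timecourse <- function(x, ...) {
  cat("<upr_timecourse>",
      sprintf("scenario '%s', %d replicates, cv = %g, seed = %s\n",
              attr(x, "scenario"), max(x$replicate), attr(x, "cv"),
              format(attr(x, "seed"))))
  print(utils::head(as.data.frame(x), 4))
  cat("  ...", nrow(x), "rows\n")
  invisible(x)
}
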