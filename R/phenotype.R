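# Timing-feature extraction from (clean or noisy) time courses and phenotype
# calling: survival, death, delayed death.
#
# Thresholds are fractions of a scale (the variable's total capacity for
# model trajectories, the series maximum for normalized densitometry-style
# data).  A "sustained" crossing must hold for `sustain` consecutive samples,
# which rejects single-sample noise spikes at the default sampling density.

#' Extract timing features from a single time series
#'
#' @param values numeric series (one marker or model variable).
#' @param time sampling times; defaults to `0:(length(values)-1)`.
#' @param scale reference scale the threshold fractions refer to: the
#'   variable's total capacity for model output, or `max(values)` (the
#'   default) for normalized data.
#' @param onset_frac fraction of `scale` defining the "high" threshold used
#'   for the sustained-onset and time-above-threshold features (default 0.5).
#' @param transient_frac lower fraction of `scale` used to detect transient
#'   activation peaks (crossed, then receded; default 0.1).
#' @param sustain number of consecutive above-threshold samples required for
#'   a sustained onset (default 3).
#' @return a list of class `upr_features`: `window` (total time above the
#'   onset threshold), `onset_time` (first sustained crossing belonging to
#'   the terminal activated phase, i.e. after the last sustained
#'   deactivation -- commitment is terminal, so a peak that recedes for good
#'   is never an onset; `NA` if none),
#'   `transient` (`TRUE` when the series crossed the transient threshold and
#'   receded below it by the end without a sustained onset at that level),
#'   `peak_value`, `peak_time`, `undetermined` (series shorter than
#'   `sustain`), plus the sampling step `dt`.
#' @export
#' @examples
#' extract_features(c(0, 0, 1, 1, 1, 0, 0), scale = 1)
extract_features <- function(values, time = NULL, scale = max(values),
                             onset_frac = 0.5, transient_frac = 0.1,
                             sustain = 3L) {
  n <- length(values)
  if (is.null(time)) time <- seq_len(n) - 1
  stopifnot(length(time) == n)
  dt <- if (n > 1L) stats::median(diff(time)) else NA_real_
  if (n < sustain) {
    return(structure(list(window = NA_real_, onset_time = NA_real_,
                          transient = NA, peak_value = NA_real_,
                          peak_time = NA_real_, undetermined = TRUE, dt = dt),
                     class = "upr_features"))
  }
  if (!is.finite(scale) || scale <= 0) {
    # an identically-zero (or degenerate) series: nothing ever active
    return(structure(list(window = 0, onset_time = NA_real_, transient = FALSE,
                          peak_value = max(values), peak_time = time[which.max(values)],
                          undetermined = FALSE, dt = dt),
                     class = "upr_features"))
  }
  thr_on <- onset_frac * scale
  thr_tr <- transient_frac * scale
  above <- values >= thr_on

  window <- sum(above) * dt

  # Sustained onset: commitment is terminal, so the onset must belong to the
  # terminal activated phase.  Any run of >= `sustain` consecutive
  # below-threshold samples counts as a sustained deactivation; the onset is
  # the start of the first >= `sustain` above-threshold run occurring after
  # the last sustained deactivation.  A transient that crosses and then
  # recedes for good is never an onset; isolated noise dips shorter than
  # `sustain` do not break an onset.
  onset <- NA_real_
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  off_sustained <- which(!run$values & run$lengths >= sustain)
  phase_start <- if (length(off_sustained)) ends[max(off_sustained)] + 1L else 1L
  ok <- which(run$values & run$lengths >= sustain & starts >= phase_start)
  if (length(ok)) onset <- time[starts[ok[1L]]]

  crossed_tr <- any(values >= thr_tr)
  receded_tr <- crossed_tr && values[n] < thr_tr
  transient <- receded_tr && is.na(onset)

  structure(list(window = window, onset_time = onset, transient = transient,
                 peak_value = max(values), peak_time = time[which.max(values)],
                 undetermined = FALSE, dt = dt),
            class = "upr_features")
}

#' Timing features of a model trajectory
#'
#' Applies [extract_features()] to the autophagy and apoptosis inducers of a
#' trajectory, with the totals of the generating parameter set as the
#' threshold scale.
#'
#' @param trajectory a `upr_trajectory` (from [integrate_protocol()] or
#'   [run_scenario()]).
#' @param ... passed to [extract_features()] (`onset_frac`, `transient_frac`,
#'   `sustain`).
#' @return list with elements `auto` and `apop` (each `upr_features`) and
#'   `dt`.
#' @export
trajectory_features <- function(trajectory, ...) {
  stopifnot(inherits(trajectory, "upr_trajectory"))
  totals <- state_totals(attr(trajectory, "params"))
  list(
    auto = extract_features(trajectory$auto, trajectory$time,
                            scale = totals[["auto"]], ...),
    apop = extract_features(trajectory$apop, trajectory$time,
                            scale = totals[["apop"]], ...),
    dt = stats::median(diff(trajectory$time))
  )
}

#' Call the cell-fate phenotype from timing features
#'
#' `death` when the apoptosis inducer shows a sustained onset; becomes
#' `delayed_death` when that onset lies more than one sampling step after the
#' reference onset (the intact network under high stress); `survival` when
#' there is no sustained onset (a transient apoptosis peak is still
#' survival); `undetermined` when the series was too short to judge.
#'
#' @param features feature set of the trajectory/time course under study, as
#'   returned by [trajectory_features()] (needs elements `apop`, `auto`,
#'   `dt`).
#' @param reference optional feature set of the reference condition used for
#'   the delayed-death comparison; `NULL` disables the delay refinement.
#' @return object of class `upr_phenotype`: list with `class` (one of
#'   `"survival"`, `"death"`, `"delayed_death"`, `"undetermined"`),
#'   `autophagy_window`, `apoptosis_onset`, `transient_apoptosis`.
#' @export
#' @examples
#' tr <- run_scenario("low_stress", horizon = 240)
#' call_phenotype(trajectory_features(tr))
call_phenotype <- function(features, reference = NULL) {
  ap <- features$apop
  au <- features$auto
  if (isTRUE(ap$undetermined) || isTRUE(au$undetermined)) {
    cls <- "undetermined"
  } else if (!is.na(ap$onset_time)) {
    cls <- "death"
    if (!is.null(reference)) {
      ref_onset <- reference$apop$onset_time
      step <- features$dt
      if (!is.na(ref_onset) && ap$onset_time > ref_onset + step) cls <- "delayed_death"
    }
  } else {
    cls <- "survival"
  }
  structure(list(class = cls,
                 autophagy_window = au$window,
                 apoptosis_onset = ap$onset_time,
                 transient_apoptosis = isTRUE(ap$transient)),
            class = "upr_phenotype")
}

#' @export
print.upr_phenotype <- function(x, ...) {
  cat("<upr_phenotype>", x$class, "\n")
  cat(sprintf("  autophagy window: %s | apoptosis onset: %s | transient apoptosis: %s\n",
              format(x$autophagy_window), format(x$apoptosis_onset),
              x$transient_apoptosis))
  invisible(x)
}

#' Marker-to-variable mapping of the densitometry readouts
#'
#' The experimental markers reported in ER-stress immunoblot panels, mapped
#' onto the model variables they proxy: LC3-II and ULK-555-P report the
#' autophagy inducer; cleaved PARP, CHOP and JNK-P the apoptosis inducer;
#' phosphorylated eiF2-alpha the PERK branch; spliced XBP1 the IRE-1 branch.
#'
#' @return named character vector, marker name -> model variable.
#' @export
marker_map <- function() {
  c(LC3II = "auto", ULK555P = "auto",
    cPARP = "apop", CHOP = "apop", JNKP = "apop",
    eiF2aP = "perk", XBP1s = "ire1")
}
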