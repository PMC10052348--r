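# Impedance-based transport assay (TRACT) analysis: raw impedance traces ->
# cell index -> normalization to the pre-stimulation point -> vehicle
# correction -> net AUC -> percent response -> fixed-slope dose-response fit.

#' Cell index from impedance
#'
#' CI = (Z - Z0) / 15, the instrument's dimensionless impedance measure.
#'
#' @param z impedance (ohm) at any time.
#' @param z0 baseline impedance (ohm) at the start of the experiment.
#' @return dimensionless cell index.
#' @export
cell_index <- function(z, z0) (z - z0) / 15

#' Normalize a cell-index trace to the pre-stimulation point
#'
#' Divides the whole trace by the CI at the last sample at or before the
#' substrate-addition time, so the reference point equals 1 (normalized CI,
#' nCI).
#'
#' @param time time points (minutes), strictly increasing.
#' @param ci cell-index values.
#' @param t_ref substrate-addition time; must fall within the trace span.
#' @return nCI vector.
#' @export
normalize_trace <- function(time, ci, t_ref) {
  stopifnot(length(time) == length(ci), length(time) >= 2, all(diff(time) > 0))
  ref_idx <- which(time <= t_ref)
  assert_that(length(ref_idx) > 0 && t_ref <= time[length(time)],
              "reference time outside the trace span")
  ref <- ci[max(ref_idx)]
  if (!is.finite(ref) || ref == 0) {
    stop("zero cell index at the reference point: well cannot be normalized")
  }
  ci / ref
}

#' Subtract the vehicle/vehicle trace
#'
#' Pointwise subtraction of the double-vehicle (vehicle-pretreated,
#' vehicle-stimulated) nCI trace, removing inhibitor- and
#' substrate-independent drift. Traces on different time grids are
#' linearly interpolated onto the target grid.
#'
#' @param time,nci the trace to correct.
#' @param vehicle_time,vehicle_nci the double-vehicle trace.
#' @return corrected nCI values on `time`'s grid.
#' @export
vehicle_correct <- function(time, nci, vehicle_time, vehicle_nci) {
  stopifnot(length(time) == length(nci),
            length(vehicle_time) == length(vehicle_nci))
  if (max(vehicle_time) < min(time) || min(vehicle_time) > max(time)) {
    stop("vehicle trace does not overlap the trace in time")
  }
  v <- if (identical(time, vehicle_time)) vehicle_nci else {
    stats::approx(vehicle_time, vehicle_nci, xout = time, rule = 2)$y
  }
  nci - v
}

#' Net area under the curve after stimulation
#'
#' Signed trapezoidal integral of the corrected response over a window
#' starting at the stimulation time; area below zero subtracts.
#'
#' @param time,values the corrected trace.
#' @param t_start stimulation time (minutes).
#' @param window window length (minutes; the assay convention is the first
#'   30 minutes).
#' @return signed area (nCI x min).
#' @export
net_auc <- function(time, values, t_start = 0, window = 30) {
  stopifnot(length(time) == length(values), all(diff(time) > 0))
  t_end <- t_start + window
  assert_that(min(time) <= t_start && max(time) >= t_end,
              "trace does not cover the integration window")
  sel <- time >= t_start & time <= t_end
  tt <- time[sel]; vv <- values[sel]
  # close the window edges exactly by interpolation
  if (tt[1] > t_start) {
    tt <- c(t_start, tt); vv <- c(stats::approx(time, values, t_start)$y, vv)
  }
  if (tt[length(tt)] < t_end) {
    tt <- c(tt, t_end); vv <- c(vv, stats::approx(time, values, t_end)$y)
  }
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

#' Percent response relative to vehicle and reference
#'
#' Scales a net AUC so the substrate-only (vehicle) response is 0% and the
#' reference inhibitor response is 100%.
#'
#' @param auc net AUC of the well under analysis.
#' @param auc_vehicle net AUC of vehicle-pretreated, substrate-stimulated
#'   wells.
#' @param auc_reference net AUC of reference-inhibitor wells.
#' @return percent response.
#' @export
percent_normalize <- function(auc, auc_vehicle, auc_reference) {
  den <- auc_reference - auc_vehicle
  if (!is.finite(den) || den == 0) stop("degenerate normalization: reference equals vehicle")
  100 * (auc - auc_vehicle) / den
}

#' Fit a fixed-slope concentration-inhibition curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + 10^(-(pIC50 + log10(c))))`
#' with the pseudo-Hill slope fixed at 1; the response increases with
#' inhibitor concentration (inhibiting reuptake enhances the
#' substrate-induced cellular response) and passes `(bottom + top)/2` at
#' `c = IC50`. Initialization is multi-start over a log-spaced pIC50 grid
#' spanning the tested concentrations plus one log unit on each side.
#'
#' @param concentrations molar concentrations (>= 4 distinct values
#'   spanning >= 2 log units).
#' @param responses percent responses, one per concentration (replicates
#'   should be averaged per concentration first; see [tract_analyze()]).
#' @return object of class `"dose_response_fit"`: `pic50`, `bottom`,
#'   `top`, `residual_se`, `fitted`, `data`.
#' @export
fit_inhibition_curve <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses), all(concentrations > 0))
  conc <- concentrations[order(concentrations)]
  resp <- responses[order(concentrations)]
  assert_that(length(unique(conc)) >= 4, "need at least 4 distinct concentrations")
  span <- log10(max(conc)) - log10(min(conc))
  assert_that(span >= 2, "concentrations must span at least 2 log units")
  if (diff(range(resp)) < 1e-9 * max(1, max(abs(resp)))) {
    stop("no concentration dependence: responses are flat")
  }
  lc <- log10(conc)
  starts <- seq(-max(lc) - 1, -min(lc) + 1, length.out = 12)
  best <- NULL
  for (s0 in starts) {
    fit <- try(minpack.lm::nlsLM(
      resp ~ bottom + (top - bottom) / (1 + 10^(-(pic50 + lc))),
      start = list(bottom = min(resp), top = max(resp), pic50 = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("dose-response fit did not converge from any start")
  cf <- stats::coef(best$fit)
  structure(list(pic50 = unname(cf["pic50"]), bottom = unname(cf["bottom"]),
                 top = unname(cf["top"]),
                 residual_se = sqrt(best$rss / max(1, length(resp) - 3)),
                 fitted = stats::fitted(best$fit),
                 data = data.frame(conc_molar = conc, response = resp)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit (slope fixed at 1): pIC50 %.2f [bottom %.1f%%, top %.1f%%]\n",
              x$pic50, x$bottom, x$top))
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(pic50 = object$pic50, bottom = object$bottom, top = object$top)
}

#' @export
predict.dose_response_fit <- function(object, concentrations = NULL, ...) {
  conc <- concentrations %||% object$data$conc_molar
  object$bottom + (object$top - object$bottom) /
    (1 + 10^(-(object$pic50 + log10(conc))))
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  graphics::plot(log10(x$data$conc_molar), x$data$response,
                 xlab = "log10 concentration (M)", ylab = "response (%)", ...)
  grid_c <- 10^seq(log10(min(x$data$conc_molar)) - 0.5,
                   log10(max(x$data$conc_molar)) + 0.5, length.out = 100)
  graphics::lines(log10(grid_c), predict(x, grid_c))
  invisible(x)
}

#' Analyze a TRACT plate from traces and a plate map
#'
#' Runs the full chain per well (cell index with the well's first sample
#' as baseline, normalization to the last pre-stimulation sample, vehicle/
#' vehicle correction, 30-minute net AUC), percent-normalizes against the
#' substrate-only and reference wells, averages replicates per
#' concentration, and fits one dose-response curve per test compound.
#'
#' @param traces long-format data.frame: `well`, `time_min`,
#'   `impedance_ohm`.
#' @param plate_map data.frame: `well`, `compound` (compound id,
#'   `"vehicle"` or `"reference"`), `conc_molar` (NA for vehicle wells),
#'   `stimulated` (logical: substrate added).
#' @param t_substrate substrate-addition time (minutes).
#' @param window AUC window (minutes).
#' @return list with `fits` (named list of [fit_inhibition_curve()] results
#'   per compound), `responses` (per-well data.frame with AUC and percent
#'   response), and `qc` (wells dropped, with reasons).
#' @export
tract_analyze <- function(traces, plate_map, t_substrate = 0, window = 30) {
  stopifnot(all(c("well", "time_min", "impedance_ohm") %in% names(traces)),
            all(c("well", "compound", "conc_molar", "stimulated") %in% names(plate_map)))
  wells <- split(traces[order(traces$well, traces$time_min), ], traces$well)
  qc <- data.frame(well = character(0), reason = character(0))
  corrected <- list()

  nci_of <- function(w) {
    ci <- cell_index(w$impedance_ohm, w$impedance_ohm[1])
    normalize_trace(w$time_min, ci, t_substrate)
  }
  # double-vehicle correction trace: vehicle pretreatment, no substrate
  vv_wells <- plate_map$well[plate_map$compound == "vehicle" & !plate_map$stimulated]
  assert_that(length(vv_wells) > 0, "plate map has no vehicle/vehicle wells")
  vv <- lapply(vv_wells, function(wl) nci_of(wells[[wl]]))
  vv_time <- wells[[vv_wells[1]]]$time_min
  vv_mean <- Reduce(`+`, vv) / length(vv)

  auc <- rep(NA_real_, nrow(plate_map))
  for (i in seq_len(nrow(plate_map))) {
    wl <- plate_map$well[i]
    w <- wells[[wl]]
    if (is.null(w)) {
      qc <- rbind(qc, data.frame(well = wl, reason = "no trace"))
      next
    }
    res <- try({
      nci <- nci_of(w)
      corr <- vehicle_correct(w$time_min, nci, vv_time, vv_mean)
      auc[i] <- net_auc(w$time_min, corr, t_start = t_substrate, window = window)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      qc <- rbind(qc, data.frame(well = wl, reason = conditionMessage(attr(res, "condition"))))
    }
  }
  stim <- plate_map$stimulated & !is.na(auc)
  auc_vehicle <- mean(auc[stim & plate_map$compound == "vehicle"])
  auc_reference <- mean(auc[stim & plate_map$compound == "reference"])
  responses <- cbind(plate_map, auc = auc,
                     percent = ifelse(stim,
                                      percent_normalize(auc, auc_vehicle, auc_reference),
                                      NA_real_))
  test <- stim & !(plate_map$compound %in% c("vehicle", "reference"))
  fits <- list()
  for (cmp in unique(plate_map$compound[test])) {
    rows <- responses[test & plate_map$compound == cmp, ]
    per_conc <- stats::aggregate(percent ~ conc_molar, data = rows, FUN = mean)
    fits[[cmp]] <- fit_inhibition_curve(per_conc$conc_molar, per_conc$percent)
  }
  list(fits = fits, responses = responses, qc = qc)
}
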