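# Non-compartmental analysis: plasma-profile container, trapezoidal AUC,
# terminal-slope estimation and summary parameters.
#
# Canonical internal units: time in hours, concentration in ng/mL, dose in
# mg, body weight in kg.  Constructors convert from minutes at the boundary.

#' Plasma concentration-time profile
#'
#' Container for one subject's concentration-time samples with dose and body
#' weight metadata.  Times are stored in hours internally; pass
#' `time_unit = "min"` to convert on input.
#'
#' @param times Sample times, strictly increasing, first >= 0.
#' @param concentrations Concentrations in ng/mL, same length, all >= 0.
#' @param dose_mg Administered dose in mg (> 0).
#' @param bw_kg Subject body weight in kg (> 0).
#' @param route `"iv_bolus"` or `"oral"`.
#' @param subject_id Identifier.
#' @param time_unit `"h"` (default) or `"min"`.
#' @return A `plasma_profile` object.
#' @export
plasma_profile <- function(times, concentrations, dose_mg, bw_kg,
                           route = c("iv_bolus", "oral"),
                           subject_id = "subj1", time_unit = c("h", "min")) {
  time_unit <- match.arg(time_unit)
  route <- match.arg(route)
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (time_unit == "min") times <- times / 60
  if (length(times) != length(concentrations))
    stop("times and concentrations must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (length(times) && times[1] < 0) stop("times must be >= 0")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (!is.numeric(dose_mg) || dose_mg <= 0) stop("dose_mg must be > 0")
  if (!is.numeric(bw_kg) || bw_kg <= 0) stop("bw_kg must be > 0")
  structure(list(times = times, concentrations = concentrations,
                 dose_mg = dose_mg, bw_kg = bw_kg, route = route,
                 subject_id = subject_id),
            class = "plasma_profile")
}

#' @export
print.plasma_profile <- function(x, ...) {
  cat(sprintf("Plasma profile '%s' (%s, %.3g mg, BW %.3g kg): %d samples, %.3g-%.3g h\n",
              x$subject_id, x$route, x$dose_mg, x$bw_kg,
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.plasma_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id, time_h = x$times,
             conc_ng_per_ml = x$concentrations, stringsAsFactors = FALSE)
}

#' Trapezoidal AUC to the last sample
#'
#' Linear trapezoid by default; `"linear_log"` uses the linear rule on rising
#' or flat segments and the log-trapezoid on declining segments with both
#' endpoints positive.
#'
#' @param profile A [plasma_profile()], or a numeric time vector when `conc`
#'   is given.
#' @param method `"linear"` (default) or `"linear_log"`.
#' @param conc Optional concentration vector when `profile` is a time vector.
#' @return AUC in ng·h/mL.
#' @export
auc_trapezoid <- function(profile, method = c("linear", "linear_log"),
                          conc = NULL) {
  method <- match.arg(method)
  if (inherits(profile, "plasma_profile")) {
    t <- profile$times; c <- profile$concentrations
  } else {
    t <- as.numeric(profile); c <- as.numeric(conc)
  }
  if (length(t) < 2) stop("at least 2 samples required for AUC")
  dt <- diff(t); c1 <- c[-length(c)]; c2 <- c[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "linear_log") {
    logok <- c2 < c1 & c2 > 0 & c1 > 0
    seg[logok] <- (c1[logok] - c2[logok]) / log(c1[logok] / c2[logok]) * dt[logok]
  }
  sum(seg)
}

#' Terminal slope (lambda_z)
#'
#' Least-squares slope of ln(C) versus time over the last
#' `n_terminal_points` samples, excluding the Cmax sample.  Returns `NA`
#' with a warning when the window contains non-positive concentrations or the
#' fitted slope is not negative (lambda_z not estimable).
#'
#' @param profile A [plasma_profile()].
#' @param n_terminal_points Number of terminal samples (>= 3).
#' @return lambda_z in 1/h, or `NA_real_` when not estimable.
#' @export
fit_lambda_z <- function(profile, n_terminal_points = 3) {
  stopifnot(inherits(profile, "plasma_profile"))
  if (n_terminal_points < 3) stop("need at least 3 terminal points")
  t <- profile$times; c <- profile$concentrations
  imax <- which.max(c)[1]
  idx <- seq_along(t)
  idx <- idx[idx > imax]                       # strictly after Cmax
  idx <- utils::tail(idx, n_terminal_points)
  if (length(idx) < 3) {
    # fall back to the last n points when the peak sits near the end
    idx <- utils::tail(seq_along(t), n_terminal_points)
  }
  if (length(idx) < 3 || any(c[idx] <= 0)) {
    warning("lambda_z not estimable: fewer than 3 positive terminal samples")
    return(NA_real_)
  }
  fit <- stats::lm.fit(cbind(1, t[idx]), log(c[idx]))
  lz <- -fit$coefficients[[2]]
  if (!is.finite(lz) || lz <= 1e-12) {
    warning("lambda_z not estimable: terminal slope is not negative")
    return(NA_real_)
  }
  lz
}

#' Extrapolate AUC to infinity
#'
#' `auc_inf = auc_last + C_last / lambda_z`; when the last concentration is
#' zero no tail is added.
#'
#' @param auc_last AUC to the last sample, ng·h/mL.
#' @param c_last Last observed concentration, ng/mL.
#' @param lambda_z Terminal slope, 1/h (> 0 unless `c_last` is 0).
#' @return AUC extrapolated to infinity, ng·h/mL.
#' @export
extrapolate_auc_inf <- function(auc_last, c_last, lambda_z) {
  if (c_last == 0) return(auc_last)
  if (is.na(lambda_z) || lambda_z <= 0)
    stop("lambda_z must be > 0 to extrapolate AUC to infinity")
  auc_last + c_last / lambda_z
}

#' Peak concentration and its time
#'
#' @param profile A [plasma_profile()].
#' @return Named list `cmax` (ng/mL) and `tmax` (h); ties broken by the
#'   earliest time.
#' @export
cmax_tmax <- function(profile) {
  stopifnot(inherits(profile, "plasma_profile"))
  if (!length(profile$times)) stop("empty profile")
  i <- which.max(profile$concentrations)[1]
  list(cmax = profile$concentrations[i], tmax = profile$times[i])
}

#' Non-compartmental analysis of one profile
#'
#' Computes AUC to the last sample and to infinity (trapezoidal with
#' `C_last/lambda_z` tail), Cmax, Tmax, lambda_z, half-life, and total plasma
#' clearance `CL = Dose / AUC_inf` normalised to body weight.
#'
#' For IV bolus profiles whose first sample is after time zero, the
#' concentration at t = 0 is back-extrapolated log-linearly from the first
#' two samples (standard IV convention) and the initial segment is included
#' in the AUC; disable with `c0_extrapolate = FALSE`.
#'
#' @param profile A [plasma_profile()].
#' @param auc_method Passed to [auc_trapezoid()].
#' @param n_terminal_points Passed to [fit_lambda_z()].
#' @param c0_extrapolate Back-extrapolate C0 for IV bolus profiles.
#' @return One-row data.frame with columns `subject_id`, `auc_last`,
#'   `auc_inf` (ng·h/mL), `cmax` (ng/mL), `tmax` (h), `lambda_z` (1/h),
#'   `half_life` (h), `cl` (mL/min/kg).
#' @export
run_nca <- function(profile, auc_method = "linear", n_terminal_points = 3,
                    c0_extrapolate = TRUE) {
  stopifnot(inherits(profile, "plasma_profile"))
  auc_prof <- profile
  if (c0_extrapolate && profile$route == "iv_bolus" &&
      length(profile$times) >= 2 && profile$times[1] > 0 &&
      all(profile$concentrations[1:2] > 0) &&
      profile$concentrations[2] < profile$concentrations[1]) {
    t12 <- profile$times[1:2]; c12 <- profile$concentrations[1:2]
    slope <- diff(log(c12)) / diff(t12)
    c0 <- exp(log(c12[1]) - slope * t12[1])
    auc_prof$times <- c(0, profile$times)
    auc_prof$concentrations <- c(c0, profile$concentrations)
  }
  auc_last <- auc_trapezoid(auc_prof, method = auc_method)
  lz <- suppressWarnings(fit_lambda_z(profile, n_terminal_points))
  c_last <- utils::tail(profile$concentrations, 1)
  auc_inf <- if (c_last == 0) auc_last
             else if (is.na(lz)) NA_real_
             else extrapolate_auc_inf(auc_last, c_last, lz)
  pk <- cmax_tmax(profile)
  # dose mg -> ng (1e6); AUC ng·h/mL -> CL mL/h -> mL/min -> per kg
  cl <- if (is.na(auc_inf) || auc_inf <= 0) NA_real_
        else profile$dose_mg * 1e6 / auc_inf / 60 / profile$bw_kg
  data.frame(subject_id = profile$subject_id,
             auc_last = auc_last, auc_inf = auc_inf,
             cmax = pk$cmax, tmax = pk$tmax,
             lambda_z = lz,
             half_life = if (is.na(lz)) NA_real_ else log(2) / lz,
             cl = cl, stringsAsFactors = FALSE)
}

#' NCA over a list of profiles
#'
#' @param profiles List of [plasma_profile()] objects.
#' @param ... Passed to [run_nca()].
#' @return data.frame, one row per profile.
#' @export
nca_table <- function(profiles, ...) {
  do.call(rbind, lapply(profiles, run_nca, ...))
}
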