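# Observed-vs-predicted comparison statistics: R ratio, the 0.5-2.0-fold
# acceptance band, and the f1 difference factor for concentration-time
# curves.

#' Simulated/observed ratio
#'
#' @param simulated Simulated parameter value.
#' @param observed Observed parameter value (> 0).
#' @return `simulated / observed`.
#' @export
r_ratio <- function(simulated, observed) {
  if (any(observed <= 0)) stop("observed value must be > 0")
  simulated / observed
}

#' Two-fold acceptance flag
#'
#' A prediction is considered reasonably reliable when its simulated/observed
#' ratio lies between 0.5 and 2.0; the boundaries are inclusive.
#'
#' @param ratio R ratio (> 0).
#' @param low,high Band limits.
#' @return Logical.
#' @export
within_fold <- function(ratio, low = 0.5, high = 2.0) {
  ratio >= low & ratio <= high
}

#' f1 difference factor between two concentration curves
#'
#' `f1 = 100 * sum(|R_i - T_i|) / sum(R_i)` over time-aligned observed (R)
#' and predicted (T) concentrations; 0 means identical curves.  When the
#' predicted curve is sampled on a different grid supply `times_observed`
#' and `times_predicted` and the predicted curve is linearly interpolated to
#' the observed times.
#'
#' @param observed,predicted Concentration vectors.
#' @param times_observed,times_predicted Optional time grids for alignment.
#' @return f1 in percent.
#' @export
f1_difference <- function(observed, predicted,
                          times_observed = NULL, times_predicted = NULL) {
  if (!is.null(times_observed) || !is.null(times_predicted)) {
    if (is.null(times_observed) || is.null(times_predicted))
      stop("supply both time grids or neither")
    predicted <- stats::approx(times_predicted, predicted,
                               xout = times_observed, rule = 2)$y
  }
  if (length(observed) != length(predicted))
    stop("observed and predicted must be time-aligned (equal length)")
  s <- sum(observed)
  if (s <= 0) stop("observed curve sums to zero")
  100 * sum(abs(observed - predicted)) / s
}

#' Observed clinical PK parameters
#'
#' Packaged fixture of the observed human parameter means (AUC ng.h/mL, Cmax
#' ng/mL, median Tmax h) for the three renal-function stages after a 10 mg
#' oral dose.
#'
#' @return data.frame with `stage`, `parameter`, `observed_mean`,
#'   `observed_sd`.
#' @export
observed_human_pk <- function() {
  path <- system.file("extdata", "observed_human_pk.csv", package = "renoscale")
  if (path == "") stop("observed PK fixture not found")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Observed-vs-predicted comparison report
#'
#' Compares predicted parameter values against the packaged observed
#' clinical means for one stage: per-parameter R ratios and two-fold flags,
#' plus the count within the band.
#'
#' @param predictions Named list or vector of predicted values keyed by
#'   parameter (`auc`, `cmax`, ...); every name must exist in the observed
#'   table for the stage.
#' @param stage One of [disease_stages()].
#' @param method Label for the prediction pathway (`"dedrick"`, `"pbpk"`).
#' @param observed Observed table; default [observed_human_pk()].
#' @return A `comparison_report` list: `table` (parameter, observed,
#'   predicted, r_ratio, within_twofold), `n_within`, `stage`, `method`.
#' @export
build_report <- function(predictions, stage, method = "pbpk",
                         observed = observed_human_pk()) {
  stage <- match_stage(stage)
  predictions <- unlist(predictions)
  obs <- observed[observed$stage == stage, ]
  missing <- setdiff(names(predictions), obs$parameter)
  if (length(missing))
    stop("no observed entry for parameter(s): ", paste(missing, collapse = ", "))
  rows <- lapply(names(predictions), function(p) {
    o <- obs$observed_mean[obs$parameter == p]
    rr <- r_ratio(predictions[[p]], o)
    data.frame(parameter = p, observed = o, predicted = predictions[[p]],
               r_ratio = rr, within_twofold = within_fold(rr),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, n_within = sum(tab$within_twofold),
                 n_total = nrow(tab), stage = stage, method = method),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison report (%s, %s): %d/%d parameters within 0.5-2.0-fold\n",
              x$method, x$stage, x$n_within, x$n_total))
  print(x$table, row.names = FALSE)
  invisible(x)
}
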