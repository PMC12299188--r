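# Species-invariant time (simple Dedrick) transformation: normalise a
# profile by dose per body weight and BW^0.25-scaled time, and back-project
# the invariant curve to a human dose and body weight.

#' Dedrick (species-invariant) transformation of a profile
#'
#' Concentration is divided by the dose per body weight (mg/kg) and time (in
#' minutes) by BW^0.25, so profiles from different species generated by the
#' same invariant kinetics superimpose.
#'
#' @param profile A [plasma_profile()] with dose and body weight set.
#' @return A `dedrick_profile`: `transformed_times` (min/kg^0.25),
#'   `transformed_concs` ((ng/mL)/(mg/kg)), `source_species`, `exponent`.
#' @param source_species Label recorded on the output.
#' @export
dedrick_transform <- function(profile, source_species = "rat") {
  stopifnot(inherits(profile, "plasma_profile"))
  if (is.null(profile$dose_mg) || is.null(profile$bw_kg))
    stop("profile must carry dose and body weight")
  dose_per_bw <- profile$dose_mg / profile$bw_kg
  structure(list(
    transformed_times = profile$times * 60 / profile$bw_kg^0.25,
    transformed_concs = profile$concentrations / dose_per_bw,
    source_species = source_species,
    exponent = 0.25
  ), class = "dedrick_profile")
}

#' Back-project an invariant curve to a human profile
#'
#' Inverse of [dedrick_transform()]: concentration is multiplied by the human
#' dose per body weight and invariant time by BW^0.25.
#'
#' @param tprofile A `dedrick_profile`.
#' @param human_dose_mg Human dose, mg (> 0).
#' @param human_bw_kg Human body weight, kg (> 0).
#' @param subject_id Identifier for the projected profile.
#' @return A [plasma_profile()] with `route = "oral"` human metadata.
#' @export
project_to_human <- function(tprofile, human_dose_mg, human_bw_kg,
                             subject_id = "human_pred") {
  stopifnot(inherits(tprofile, "dedrick_profile"))
  if (human_dose_mg <= 0 || human_bw_kg <= 0)
    stop("human dose and body weight must be > 0")
  dose_per_bw <- human_dose_mg / human_bw_kg
  plasma_profile(
    times = tprofile$transformed_times * human_bw_kg^0.25 / 60,
    concentrations = tprofile$transformed_concs * dose_per_bw,
    dose_mg = human_dose_mg, bw_kg = human_bw_kg,
    route = "oral", subject_id = subject_id, time_unit = "h")
}

#' Predict human PK from rat profiles via the Dedrick projection
#'
#' Each rat profile is species-transformed, back-projected to the human dose
#' and body weight, and analysed by trapezoidal NCA; per-animal parameters
#' and their mean +/- SD are returned.
#'
#' @param rat_profiles List of rat [plasma_profile()] objects.
#' @param human_dose_mg Human dose, mg.
#' @param human_bw_kg Human body weight, kg.  Defaults to the normal-stage
#'   representative subject's weight.
#' @param ... Passed to [run_nca()].
#' @return List with `per_animal` (NCA data.frame) and `summary`
#'   (data.frame of mean and sd for `auc_inf`, `auc_last`, `cmax`, `tmax`).
#' @export
predict_human_pk <- function(rat_profiles, human_dose_mg = 10,
                             human_bw_kg = NULL, ...) {
  if (!length(rat_profiles)) stop("at least one rat profile required")
  if (is.null(human_bw_kg))
    human_bw_kg <- representative_subject("normal")$body_weight
  projected <- lapply(seq_along(rat_profiles), function(i) {
    project_to_human(dedrick_transform(rat_profiles[[i]]),
                     human_dose_mg, human_bw_kg,
                     subject_id = sprintf("human_pred_%02d", i))
  })
  per_animal <- nca_table(projected, ...)
  stat_cols <- c("auc_inf", "auc_last", "cmax", "tmax")
  summary <- data.frame(
    parameter = stat_cols,
    mean = vapply(stat_cols, function(k) mean(per_animal[[k]]), numeric(1)),
    sd = vapply(stat_cols, function(k) stats::sd(per_animal[[k]]), numeric(1)),
    stringsAsFactors = FALSE
  )
  list(per_animal = per_animal, summary = summary, projected = projected)
}
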