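# Species-, stage- and subject-level physiology: constants, reference-adult
# organ tables, and virtual-population sampling for the three renal-function
# stages.

.renoscale_env <- new.env(parent = emptyenv())

#' Renal-function disease stages
#'
#' The three renal-function stages modelled throughout the package: healthy
#' subjects (`"normal"`), gentamicin-type moderate renal failure
#' (`"moderate"`) and cisplatin-type severe renal failure (`"severe"`).
#'
#' @return Character vector of the three stage labels.
#' @export
disease_stages <- function() c("normal", "moderate", "severe")

match_stage <- function(stage) {
  if (length(stage) != 1L || !is.character(stage) || !stage %in% disease_stages())
    stop("unknown disease stage: ", paste(stage, collapse = ", "),
         " (expected one of ", paste(disease_stages(), collapse = ", "), ")")
  stage
}

#' Physiological constants table
#'
#' Loads the versioned JSON constants file shipped with the package (renal
#' blood flows, unbound fractions, eGFR stage windows, demographic ranges)
#' and caches it for the session.
#'
#' @return Nested list mirroring the JSON file.
#' @export
physiology_constants <- function() {
  if (is.null(.renoscale_env$constants)) {
    path <- system.file("extdata", "physiology.json", package = "renoscale")
    if (path == "") stop("physiology constants file not found")
    .renoscale_env$constants <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .renoscale_env$constants
}

#' Species physiology for a renal-function stage
#'
#' Pure lookup of the stage-specific renal blood flow (RBF), plasma unbound
#' fraction and reference body weight for rat or human.  RBF values are the
#' per-kg flows used by the renal-clearance correction: human
#' (18.0, 5.24, 3.83) and rat (33.3, 28.0, 18.0) mL/min/kg for
#' (normal, moderate, severe); fu is 0.61 in humans and 0.793 in rats.
#'
#' @param species `"rat"` or `"human"`.
#' @param stage One of [disease_stages()].
#' @return List with `species`, `stage`, `rbf` (mL/min/kg), `fu`
#'   (dimensionless) and `reference_bw` (kg).
#' @export
species_physiology <- function(species, stage) {
  stage <- match_stage(stage)
  cst <- physiology_constants()$species
  if (length(species) != 1L || !species %in% names(cst))
    stop("unknown species: ", paste(species, collapse = ", "))
  sp <- cst[[species]]
  list(species = species, stage = stage,
       rbf = sp$rbf[[stage]], fu = sp$fu, reference_bw = sp$reference_bw)
}

#' eGFR window for a stage
#'
#' @param stage One of [disease_stages()].
#' @return List with `min`, `max` (mL/min/1.73 m^2) and `closed` (whether the
#'   endpoints belong to the window).
#' @export
egfr_window <- function(stage) {
  stage <- match_stage(stage)
  physiology_constants()$egfr_windows[[stage]]
}

#' Demographic ranges for a stage
#'
#' @param stage One of [disease_stages()].
#' @return List of `[min, max]` numeric ranges for `age_years`, `height_cm`,
#'   `weight_kg`, `bmi_kg_m2`.
#' @export
demographic_ranges <- function(stage) {
  stage <- match_stage(stage)
  physiology_constants()$demographics[[stage]]
}

#' Body surface area (DuBois)
#'
#' BSA = 0.007184 * height^0.725 * weight^0.425 with height in cm and weight
#' in kg; used to interconvert eGFR (mL/min/1.73 m^2) and absolute GFR
#' (mL/min).
#'
#' @param height_cm Height in cm.
#' @param weight_kg Weight in kg.
#' @return BSA in m^2.
#' @export
dubois_bsa <- function(height_cm, weight_kg) {
  stopifnot(height_cm > 0, weight_kg > 0)
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' @rdname dubois_bsa
#' @param egfr eGFR in mL/min/1.73 m^2.
#' @param bsa Body surface area in m^2.
#' @export
egfr_to_gfr <- function(egfr, bsa) egfr * bsa / 1.73

#' @rdname dubois_bsa
#' @param gfr Absolute GFR in mL/min.
#' @export
gfr_to_egfr <- function(gfr, bsa) gfr * 1.73 / bsa

# Reference-adult organ composition.  Volumes as fractions of body weight
# (assuming tissue density ~1 kg/L), systemic blood-flow fractions of cardiac
# output.  Standard whole-body reference-man values; the 'rest' compartment
# closes both balances.  Flow fractions sum to 1 (lung receives total CO,
# kidney flow is overridden by the stage RBF when a subject is built).
reference_organs <- function() {
  data.frame(
    organ = c("lung", "adipose", "bone", "brain", "gut", "heart", "kidney",
              "liver", "muscle", "skin", "spleen", "rest"),
    volume_frac = c(0.0076, 0.1600, 0.0856, 0.0200, 0.0171, 0.0047, 0.0044,
                    0.0257, 0.4000, 0.0371, 0.0026, 0.1581),
    # lung carries NA: it receives the whole cardiac output, not a share.
    flow_frac = c(NA, 0.050, 0.050, 0.120, 0.160, 0.040, 0.190,
                  0.065, 0.170, 0.050, 0.030, 0.075),
    stringsAsFactors = FALSE
  )
}

blood_volume_frac <- function() c(arterial = 0.0257, venous = 0.0514)

#' Cardiac output for a body weight
#'
#' Allometric reference: 5.6 L/min (336 L/h) for a 73-kg adult, scaled with
#' body weight to the 3/4 power.
#'
#' @param bw_kg Body weight, kg.
#' @return Cardiac output in L/h.
#' @export
cardiac_output <- function(bw_kg) {
  stopifnot(bw_kg > 0)
  336 * (bw_kg / 73)^0.75
}

build_subject <- function(stage, bw_kg, height_cm, age_years, sex, egfr) {
  stage <- match_stage(stage)
  stopifnot(bw_kg > 0, height_cm > 0)
  ref <- reference_organs()
  co_ref <- cardiac_output(bw_kg)
  vols <- stats::setNames(ref$volume_frac * bw_kg, ref$organ)
  flows <- stats::setNames(ref$flow_frac * co_ref, ref$organ)
  # Stage-specific kidney perfusion: RBF (mL/min/kg) -> L/h
  rbf <- species_physiology("human", stage)$rbf
  flows[["kidney"]] <- rbf * bw_kg * 60 / 1000
  flows[["lung"]] <- sum(flows[setdiff(ref$organ, "lung")])
  bsa <- dubois_bsa(height_cm, bw_kg)
  structure(list(
    stage = stage,
    body_weight = bw_kg,
    height = height_cm,
    age = age_years,
    sex = sex,
    bmi = bw_kg / (height_cm / 100)^2,
    bsa = bsa,
    egfr = egfr,
    gfr = egfr_to_gfr(egfr, bsa),
    rbf = rbf,
    fu = species_physiology("human", stage)$fu,
    hematocrit = 0.45,
    organ_volumes = vols,
    blood_volumes = stats::setNames(blood_volume_frac() * bw_kg,
                                    names(blood_volume_frac())),
    organ_flows = flows,
    cardiac_output = flows[["lung"]]
  ), class = "subject_physiology")
}

#' Representative subject for a stage
#'
#' Deterministic "mean individual" for a stage: the midpoint of every
#' demographic range (normal 76 kg, moderate 90.5 kg, severe 91.5 kg) and the
#' midpoint of the stage eGFR window, with organ volumes scaled by body
#' weight, flows by cardiac output, and kidney perfusion set from the stage
#' renal blood flow.
#'
#' @param stage One of [disease_stages()].
#' @return A `subject_physiology` object.
#' @export
representative_subject <- function(stage) {
  stage <- match_stage(stage)
  dem <- demographic_ranges(stage)
  win <- egfr_window(stage)
  build_subject(stage,
                bw_kg = mean(dem$weight_kg),
                height_cm = mean(dem$height_cm),
                age_years = mean(dem$age_years),
                sex = "male",
                egfr = mean(c(win$min, win$max)))
}

#' Sample a virtual population
#'
#' Draws `n` virtual subjects for a renal-function stage.  Age, height and
#' weight are uniform over the stage's demographic ranges, jointly rejected
#' until the implied BMI also falls in its printed range; eGFR is uniform in
#' the stage window; sex is 50/50 in expectation.  Organ volumes scale with
#' body weight, flows with cardiac output, and the kidney flow is overridden
#' by the stage renal blood flow.  Fully reproducible for a fixed seed.
#'
#' @param stage One of [disease_stages()].
#' @param n Number of subjects (>= 1).
#' @param seed Integer RNG seed.
#' @return List of `subject_physiology` objects.
#' @export
sample_population <- function(stage, n, seed) {
  stage <- match_stage(stage)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("population size n must be >= 1")
  n <- as.integer(n)
  dem <- demographic_ranges(stage)
  win <- egfr_window(stage)
  rng <- local_rng(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      h <- stats::runif(1, dem$height_cm[1], dem$height_cm[2])
      w <- stats::runif(1, dem$weight_kg[1], dem$weight_kg[2])
      bmi <- w / (h / 100)^2
      if (bmi >= dem$bmi_kg_m2[1] && bmi <= dem$bmi_kg_m2[2]) break
    }
    age <- stats::runif(1, dem$age_years[1], dem$age_years[2])
    sex <- if (stats::runif(1) < 0.5) "male" else "female"
    egfr <- stats::runif(1, win$min, win$max)
    build_subject(stage, w, h, age, sex, egfr)
  })
}

# Run expr-free seeded RNG handling: set the seed, restore the caller's RNG
# state on exit of the *calling* function.
local_rng <- function(seed, envir = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  withr::defer({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, envir = envir)
  invisible(seed)
}

#' @export
print.subject_physiology <- function(x, ...) {
  cat(sprintf(
    "Virtual subject (%s stage): %s, %.1f y, %.1f kg, %.0f cm, eGFR %.1f mL/min/1.73m2\n",
    x$stage, x$sex, x$age, x$body_weight, x$height, x$egfr))
  cat(sprintf("  cardiac output %.1f L/h; kidney flow %.2f L/h (RBF %.2f mL/min/kg)\n",
              x$cardiac_output, x$organ_flows[["kidney"]], x$rbf))
  invisible(x)
}

#' Population as a data frame
#'
#' One row per subject with snake_case demographic columns, suitable for CSV
#' export.
#'
#' @param population List of `subject_physiology` objects.
#' @return data.frame.
#' @export
population_table <- function(population) {
  do.call(rbind, lapply(seq_along(population), function(i) {
    s <- population[[i]]
    data.frame(subject_id = i, stage = s$stage, sex = s$sex,
               age_years = s$age, height_cm = s$height,
               weight_kg = s$body_weight, bmi_kg_m2 = s$bmi,
               egfr_ml_min_173m2 = s$egfr, gfr_ml_min = s$gfr,
               cardiac_output_l_h = s$cardiac_output,
               stringsAsFactors = FALSE)
  }))
}
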