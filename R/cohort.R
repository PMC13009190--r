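#' Cohort specification
#'
#' Describes the simulated study population. Defaults mirror the study
#' conditions emulated throughout the package: 88 participants aged 8-19
#' years, 42 of them male, scanned in both hemispheres.
#'
#' @param n_participants Number of participants (default 88).
#' @param age_range Length-2 numeric, years (default `c(8, 19)`).
#' @param sex_ratio Fraction male (default 42/88).
#' @param age_distribution `"uniform"` (default) or `"right_skewed"`, the
#'   latter oversampling the younger 8-12 year range (Beta(1, 1.8)-shaped).
#' @param seed Integer seed; fully determines all random draws.
#' @returns A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 88, age_range = c(8, 19),
                        sex_ratio = 42 / 88,
                        age_distribution = c("uniform", "right_skewed"),
                        seed = 1L) {
  if (n_participants < 1) stop("n_participants must be positive")
  if (length(age_range) != 2 || age_range[2] < age_range[1])
    stop("age_range must be c(min, max) with min <= max")
  structure(list(n_participants = as.integer(n_participants),
                 age_range = age_range, sex_ratio = sex_ratio,
                 age_distribution = match.arg(age_distribution),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a participant-hemisphere cohort table
#'
#' Draws ages and sexes according to a [cohort_spec()] and expands to one row
#' per participant and hemisphere. Reproducible: the same spec (including its
#' seed) always yields an identical table.
#'
#' @param spec A [cohort_spec()].
#' @returns A tibble with columns `participant` (factor), `age` (years),
#'   `sex` (factor F/M), `hemisphere` (factor L/R); `2 * n_participants` rows.
#' @examples
#' generate_cohort(cohort_spec(n_participants = 4, seed = 7))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  withr_seed(spec$seed, {
    u <- runif(n)
    if (spec$age_distribution == "right_skewed") u <- stats::qbeta(u, 1, 1.8)
    ages <- spec$age_range[1] + u * diff(spec$age_range)
    n_male <- round(spec$sex_ratio * n)
    sexes <- sample(rep(c("M", "F"), c(n_male, n - n_male)))
  })
  ids <- sprintf("sub-%03d", seq_len(n))
  tidyr::expand_grid(participant = ids, hemisphere = c("L", "R")) |>
    dplyr::left_join(tibble::tibble(participant = ids, age = ages, sex = sexes),
                     by = "participant") |>
    dplyr::mutate(participant = factor(.data$participant),
                  sex = factor(.data$sex, levels = c("F", "M")),
                  hemisphere = factor(.data$hemisphere, levels = c("L", "R"))) |>
    dplyr::select("participant", "age", "sex", "hemisphere")
}

# Evaluate expr with a local RNG state seeded from `seed`, restoring the
# caller's state afterwards.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Per-parcel linear age/sex effect specification
#'
#' One row per (parcel, parameter): the ground-truth generative model for a
#' parameter value in a parcel is
#' `intercept + slope_age * (age - age_center) + offset_sex * male +
#'  slope_age_sex * (age - age_center) * male + N(0, residual_sd)`,
#' with age centred at `age_center` (default 13.5 y, the cohort mid-point) so
#' intercepts are interpretable as mid-cohort parcel means.
#'
#' @param parcels Character vector of parcel (subfield) names.
#' @param parameter Parameter name; one of the ground-truth field parameters
#'   (`"f_ec"`, `"f_soma"`, `"r_s"`, `"kappa"`, `"d_in"`, `"d_ec"`).
#' @param intercept,slope_age,offset_sex,slope_age_sex,residual_sd Numeric,
#'   recycled across parcels.
#' @returns A tibble with one row per (parcel, parameter).
#' @export
effect_spec <- function(parcels, parameter, intercept, slope_age = 0,
                        offset_sex = 0, slope_age_sex = 0, residual_sd = 0) {
  tibble::tibble(parcel = parcels, parameter = parameter,
                 intercept = intercept, slope_age = slope_age,
                 offset_sex = offset_sex, slope_age_sex = slope_age_sex,
                 residual_sd = residual_sd)
}

#' Default ground-truth effect specification
#'
#' The study conditions the generator emulates: across all five subfields the
#' extracellular signal fraction declines linearly with age and the neurite
#' fraction (its complement with a flat soma fraction) rises, the soma
#' fraction is exactly flat, and (through the compartment mix) mean
#' diffusivity declines; soma radius declines with age in Sub and CA1 only;
#' orientation dispersion carries no age trend. A mild sex-by-age interaction
#' is placed on `f_ec`. Values are mid-cohort parcel means in physical units.
#'
#' @param parcels Subfield names (default the five-subfield set).
#' @param residual_sd_scale Multiplier on all residual SDs (set 0 for
#'   noiseless ground truth).
#' @param ap_gradient If `TRUE`, age slopes are additionally modulated along
#'   the anterior-posterior axis (anterior parcels carry the effect, posterior
#'   none); used to emulate an AP-localised developmental effect.
#' @returns An effect-spec tibble (see [effect_spec()]).
#' @export
default_effect_spec <- function(parcels = subfield_names(),
                                residual_sd_scale = 1, ap_gradient = FALSE) {
  k <- length(parcels)
  rs_slope <- ifelse(parcels %in% c("Sub", "CA1"), -0.06, 0)
  # trends are injected directly on the reported signal fractions: the
  # extracellular fraction declines linearly with age, the soma fraction is
  # flat, and the neurite fraction (their complement) therefore rises with
  # exactly the opposite slope
  fec0 <- seq(0.32, 0.38, length.out = k)
  fsoma0 <- (1 - fec0) * seq(0.66, 0.64, length.out = k)
  spec <- dplyr::bind_rows(
    effect_spec(parcels, "f_ec", intercept = fec0,
                slope_age = -0.008, slope_age_sex = 0.0025,
                residual_sd = 0.015 * residual_sd_scale),
    effect_spec(parcels, "f_soma", intercept = fsoma0,
                slope_age = 0, residual_sd = 0.015 * residual_sd_scale),
    effect_spec(parcels, "r_s", intercept = 7.0, slope_age = rs_slope,
                residual_sd = 0.15 * residual_sd_scale),
    effect_spec(parcels, "kappa", intercept = 1.0,
                residual_sd = 0.05 * residual_sd_scale),
    effect_spec(parcels, "d_in", intercept = 1.7),
    effect_spec(parcels, "d_ec", intercept = 1.0,
                residual_sd = 0.02 * residual_sd_scale)
  )
  attr(spec, "age_center") <- 13.5
  attr(spec, "ap_gradient") <- ap_gradient
  spec
}

#' Subfield and long-axis parcel label sets
#'
#' The proximal-distal subfield labels (with DG and CA4 merged) and the five
#' anterior-posterior long-axis bins used for parcel averaging.
#' @returns Character vector of labels.
#' @export
subfield_names <- function() c("Sub", "CA1", "CA2", "CA3", "DG/CA4")

#' @rdname subfield_names
#' @export
longaxis_names <- function() {
  c("anterior uncus", "anterior lateral", "body anterior",
    "body posterior", "posterior/tail")
}
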