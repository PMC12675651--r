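#' Packaged clinical-variable catalogue
#'
#' Thirty synthetic routine-ICU variables (plus age and one deliberately
#' excluded treatment surrogate, a vasopressor dose) with the distribution
#' each is simulated from and the daily aggregation rule used downstream.
#' Right-skewed laboratory values are log-normal (`location`/`scale` are
#' meanlog/sdlog); pressures, temperatures and blood-gas values are normal.
#' The aggregation rule picks the clinically informative extreme: e.g. the
#' daily maximum for creatinine, the daily minimum for the quick value.
#'
#' @return Data frame with columns `variable`, `dist`, `location`, `scale`,
#'   `aggregation`, `exclude`.
#' @export
clinical_variables <- function() {
  path <- system.file("extdata", "clinical_variables.csv",
                      package = "septaphen", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$exclude <- as.logical(x$exclude)
  x
}

#' Construct a phenotype profile for the synthetic cohort generator
#'
#' A profile describes one latent phenotype: its day-1 prevalence, how each
#' clinical variable's distribution is shifted relative to the reference
#' phenotype (location shift in units of the variable's own scale parameter,
#' plus an optional scale multiplier), the day-to-day transition probabilities
#' on the assessment grid (including the absorbing outcomes `deceased` and
#' `discharged`), and the 30-day mortality applied to patients who survive
#' the grid.
#'
#' @param label Single letter identifying the phenotype ("A", "B", ...).
#' @param prevalence Day-1 prevalence in `[0, 1]`.
#' @param shifts Named numeric vector of location shifts (z-units); variables
#'   not named are unshifted.
#' @param scale_mult Named numeric vector of scale multipliers; default 1.
#' @param mortality_30d Probability of death within 30 days for patients still
#'   alive after the last assessment day, conditional on their last state.
#' @param transition Named probability vector over
#'   `c("A","B","C",...,"deceased","discharged")` (one entry per phenotype
#'   label plus the two absorbing states); must sum to 1.
#' @param focus_probs Named probability vector over infection-focus categories.
#' @return An object of class `phenotype_profile`.
#' @export
phenotype_profile <- function(label, prevalence, shifts = numeric(0),
                              scale_mult = numeric(0), mortality_30d,
                              transition, focus_probs = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  if (prevalence < 0 || prevalence > 1) {
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  }
  if (any(transition < 0) || any(transition > 1) ||
      abs(sum(transition) - 1) > 1e-9) {
    stop("transition probabilities for profile ", label,
         " must be in [0, 1] and sum to 1", call. = FALSE)
  }
  if (mortality_30d < 0 || mortality_30d > 1) {
    stop("mortality_30d must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(label = label, prevalence = prevalence, shifts = shifts,
         scale_mult = scale_mult, mortality_30d = mortality_30d,
         transition = transition, focus_probs = focus_probs),
    class = "phenotype_profile"
  )
}

#' Default three-phenotype profiles
#'
#' Encodes the study conditions the generator emulates: a large mild
#' phenotype A (53%), an intermediate renal phenotype B (41%, creatinine
#' about 1.6x A, reduced urine output, older patients) and a small severe
#' phenotype C (7%, hepatic failure with transaminases about 50x A,
#' INR about 2.5x, lactate about 7x, platelets about 0.4x), with
#' cluster-graded mortality (29/45/92%) and day-to-day transitions in which
#' phenotype B is the most mobile (35% of B moves to A per step).
#'
#' @return List of three [phenotype_profile()] objects.
#' @export
default_profiles <- function() {
  states <- c("A", "B", "C", "deceased", "discharged")
  tr <- function(...) stats::setNames(c(...), states)
  focus_levels <- c("pneumonia", "intra_abdominal", "urinary",
                    "bloodstream", "covid", "other")
  fp <- function(...) stats::setNames(c(...), focus_levels)

  ## B's shifts are twice the z-equivalent of the intermediate phenotype's
  ## location ratios: the generator draws variables independently within a
  ## phenotype, whereas real severity makes them co-vary, so literal ratios
  ## would under-separate the intermediate cluster relative to the cohort
  ## structure the generator is meant to emulate.
  shifts_b <- 2 * c(
    age = 0.64, ast = 0.49, alt = 0.34, bilirubin = 0.56, inr = 1.03,
    aptt = 0.30, quick = -0.67, lactate = 1.01, creatinine = 1.18,
    urea = 0.78, urine_output = -1.15, platelets = -0.21, wbc = 0.81,
    crp = 0.54, lymphocytes_rel = -0.81, map = -1.00, bp_sys = -0.67,
    bp_dia = -0.60, heart_rate = 0.33, base_excess = -0.67, ph = -0.83,
    pco2 = -0.38, horovitz = 0.48, hemoglobin = -0.28, glucose = 0.20,
    albumin = -0.50, fibrinogen = -0.30, procalcitonin = 0.80,
    ntprobnp = 1.62, norepinephrine = 1.50
  )
  shifts_c <- c(
    age = 0.79, ast = 6.80, alt = 5.55, bilirubin = 1.59, inr = 6.74,
    aptt = 1.88, quick = -2.67, lactate = 5.04, creatinine = 1.85,
    urea = 0.84, urine_output = -2.33, platelets = -2.19, wbc = 0.94,
    crp = 0.10, map = -0.60, bp_sys = -1.00, bp_dia = -0.80,
    heart_rate = 1.47, base_excess = -2.33, ph = -3.00, pco2 = 0.25,
    temperature = -1.00, hemoglobin = -0.50, glucose = 0.50,
    albumin = -1.17, fibrinogen = -1.98, procalcitonin = 2.08,
    ntprobnp = 2.90, norepinephrine = 4.00
  )

  list(
    phenotype_profile(
      "A", prevalence = 202 / 384, shifts = numeric(0), mortality_30d = 0.29,
      transition = tr(0.78, 0.06, 0.01, 0.05, 0.10),
      focus_probs = fp(0.39, 0.14, 0.03, 0.03, 0.29, 0.12)
    ),
    phenotype_profile(
      "B", prevalence = 156 / 384, shifts = shifts_b, mortality_30d = 0.45,
      transition = tr(0.35, 0.40, 0.05, 0.15, 0.05),
      focus_probs = fp(0.28, 0.32, 0.10, 0.08, 0.10, 0.12)
    ),
    phenotype_profile(
      "C", prevalence = 26 / 384, shifts = shifts_c,
      scale_mult = c(inr = 2, base_excess = 1.3), mortality_30d = 0.92,
      transition = tr(0.02, 0.05, 0.30, 0.55, 0.08),
      focus_probs = fp(0.19, 0.39, 0.00, 0.15, 0.04, 0.23)
    )
  )
}

#' Default quantification limits for the 13-analyte cytokine panel
#'
#' Per-analyte lower/upper limits of quantification (pg/mL) plus the log-scale
#' location each analyte is simulated around and its per-phenotype shifts
#' (inflammatory analytes highest in phenotype C).
#'
#' @return Data frame with columns `analyte`, `lloq`, `uloq`, `meanlog`,
#'   `sdlog`, `shift_B`, `shift_C`.
#' @export
default_cytokine_limits <- function() {
  data.frame(
    analyte = c("il1b", "ifna2", "ifng", "tnfa", "ccl2", "il6", "il8",
                "il10", "il12p70", "il17a", "il18", "il23", "il33"),
    lloq = c(2, 2, 2, 2, 5, 3, 3, 2, 2, 0.3, 10, 5, 5),
    ## caps reflect typical immunoassay ranges: strongly induced analytes
    ## (IL-6, IL-8, IL-18) routinely exceed them in septic shock, so the
    ## upper-clamp rule is exercised by design
    uloq = c(5000, 5000, 5000, 5000, 10000, 5000, 2000, 5000, 5000,
             500, 5000, 5000, 5000),
    meanlog = c(0.5, 0.2, 1.5, 2.2, log(232), log(136), log(50),
                log(5), 0.3, log(0.5), log(210), 1.0, 0.8),
    sdlog = c(1.2, 1.0, 1.2, 0.9, 0.9, 1.1, 1.1, 1.2, 1.0, 0.8, 1.0,
              1.0, 1.0),
    shift_B = c(0.3, 0.1, 0.3, 0.3, 0.38, 1.0, 0.64, 0.66, 0.2, 0.23,
                0.73, 0.2, 0.2),
    shift_C = c(1.0, 0.3, 0.8, 0.8, 1.48, 2.60, 2.44, 3.11, 0.6, 0.73,
                1.65, 0.6, 0.6),
    stringsAsFactors = FALSE
  )
}
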