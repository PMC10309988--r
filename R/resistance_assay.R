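# Larval packet test processing: two replicate mortality readings per
# acaricide (amitraz 0.1%, alpha-cypermethrin 0.02%, ivermectin 0.1% w/v)
# plus a control, read 24 h after seeding. Survival = 100 - mean mortality,
# classified into four resistance levels:
#   susceptible [0, 10), low [10, 20), medium [20, 50], high (50, 100].
# A farm counts as resistant to an acaricide when its category is medium or
# high, i.e. survival >= 20%.

RESISTANCE_LEVELS <- c("susceptible", "low", "medium", "high")

#' Survival percentage from replicate mortalities
#'
#' Averages the two replicate mortalities and converts to percent survival.
#' With `abbott_correction = TRUE` the mean mortality is corrected for
#' control mortality c as `100 * (m - c) / (100 - c)` (clipped to `[0, 100]`)
#' before conversion. Assays whose control mortality exceeds
#' `control_threshold` are invalid and raise an error.
#'
#' @param rep1_mortality,rep2_mortality Replicate mortalities, percent in
#'   `[0, 100]`.
#' @param control_mortality Control-group mortality, percent (default 0).
#' @param abbott_correction Apply the control correction? Default `FALSE`.
#' @param control_threshold Control mortality above which the assay is
#'   invalid (default 10).
#' @return Survival percentage(s) in `[0, 100]`.
#' @export
#' @examples
#' replicate_survival(80, 90)                          # 15
#' replicate_survival(80, 90, 10, abbott_correction = TRUE)  # 16.67
replicate_survival <- function(rep1_mortality, rep2_mortality,
                               control_mortality = 0,
                               abbott_correction = FALSE,
                               control_threshold = 10) {
  m <- cbind(rep1_mortality, rep2_mortality, control_mortality)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 100)) {
    abort("mortalities must be percentages in [0, 100]",
          class = "acarecon_input_error")
  }
  if (any(control_mortality > control_threshold)) {
    abort(paste0("assay invalid: control mortality above ",
                 control_threshold, "%"),
          class = "acarecon_assay_invalid")
  }
  mbar <- (rep1_mortality + rep2_mortality) / 2
  if (abbott_correction) {
    mbar <- pmin(pmax(100 * (mbar - control_mortality) /
                        (100 - control_mortality), 0), 100)
  }
  100 - mbar
}

#' Classify larval survival into a resistance category
#'
#' @param survival Survival percentage(s) in `[0, 100]`.
#' @return An ordered factor with levels susceptible < low < medium < high.
#' @export
#' @examples
#' classify_survival(c(5, 15, 20, 50, 55))
classify_survival <- function(survival) {
  if (any(!is.finite(survival)) || any(survival < 0) || any(survival > 100)) {
    abort("survival must lie in [0, 100]", class = "acarecon_input_error")
  }
  out <- ifelse(survival < 10, "susceptible",
         ifelse(survival < 20, "low",
         ifelse(survival <= 50, "medium", "high")))
  factor(out, levels = RESISTANCE_LEVELS, ordered = TRUE)
}

#' Is a survival level (or category) resistant?
#'
#' Resistant means medium or high resistance, equivalently survival >= 20%.
#'
#' @param x A survival percentage vector or a factor/character of categories.
#' @return Logical vector.
#' @export
is_resistant <- function(x) {
  if (is.numeric(x)) x <- classify_survival(x)
  as.character(x) %in% c("medium", "high")
}

#' Per-farm resistance profiles from assay replicates
#'
#' Computes, for every farm and acaricide, the survival percentage, the
#' four-level category and the binary resistance flag, plus the combined
#' (conjunction) flags for acaricide pairs and the triple.
#'
#' @param farms A farm-record tibble with the assay columns
#'   `am_rep1_mortality`, ..., `iv_control_mortality`.
#' @param abbott_correction Apply control correction (default `FALSE`).
#' @param control_threshold Control mortality above which an assay is invalid
#'   (default 10; set to `Inf` to accept any control).
#' @return A tibble with `farm_id`, per-acaricide `*_survival`, `*_category`,
#'   `*_resistant`, and combined flags `am_cy`, `am_iv`, `cy_iv`, `am_cy_iv`.
#' @export
resistance_profiles <- function(farms, abbott_correction = FALSE,
                                control_threshold = 10) {
  out <- tibble::tibble(farm_id = farms$farm_id)
  for (a in ACARICIDES) {
    p <- ACARICIDE_PREFIX[[a]]
    surv <- replicate_survival(
      farms[[paste0(p, "_rep1_mortality")]],
      farms[[paste0(p, "_rep2_mortality")]],
      farms[[paste0(p, "_control_mortality")]],
      abbott_correction = abbott_correction,
      control_threshold = control_threshold
    )
    out[[paste0(a, "_survival")]] <- surv
    out[[paste0(a, "_category")]] <- classify_survival(surv)
    out[[paste0(a, "_resistant")]] <- is_resistant(surv)
  }
  out$am_cy <- out$amitraz_resistant & out$cypermethrin_resistant
  out$am_iv <- out$amitraz_resistant & out$ivermectin_resistant
  out$cy_iv <- out$cypermethrin_resistant & out$ivermectin_resistant
  out$am_cy_iv <- out$am_cy & out$ivermectin_resistant
  out
}

#' Farm-level high-infestation flag from animal tick counts
#'
#' An animal is highly infested when its tick count reaches
#' `animal_threshold`; the farm is flagged when the fraction of highly
#' infested sampled animals reaches `farm_fraction`. The thresholds come from
#' an external field methodology and are configuration values with no
#' built-in default beyond the arguments shown.
#'
#' @param animal_tick_counts Tick counts for the sampled animals (>= 1
#'   animal).
#' @param animal_threshold Count at which an animal is highly infested.
#' @param farm_fraction Fraction of highly infested animals at which the farm
#'   is flagged.
#' @return `TRUE`/`FALSE`.
#' @export
#' @examples
#' infestation_status(c(30, 0, 0, 0, 0), animal_threshold = 20,
#'                    farm_fraction = 0.2)
infestation_status <- function(animal_tick_counts, animal_threshold,
                               farm_fraction) {
  if (length(animal_tick_counts) == 0) {
    abort("at least one sampled animal is required",
          class = "acarecon_input_error")
  }
  if (animal_threshold <= 0 || farm_fraction <= 0) {
    abort("rule parameters must be positive", class = "acarecon_input_error")
  }
  if (any(animal_tick_counts < 0)) {
    abort("tick counts must be non-negative", class = "acarecon_input_error")
  }
  mean(animal_tick_counts >= animal_threshold) >= farm_fraction
}
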