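#' Contraindication rule set
#'
#' Thresholds for antibiotic-specific warnings: Vancomycin is flagged for
#' patients with a creatinine above `vanc_creatinine_max` or (at least)
#' stage-1 acute kidney injury; Ceftriaxone for an alanine transaminase above
#' `ceft_alt_max` (five times the upper reference range) or a bilirubin total
#' above twice the sex-specific upper range. All thresholds can be adjusted
#' to site guidelines or individual assessment.
#'
#' @param vanc_creatinine_max Creatinine ceiling for Vancomycin (mg/dl).
#' @param aki_creatinine_delta Creatinine increase defining stage-1 AKI
#'   (mg/dl) within `aki_delta_window_h`.
#' @param aki_delta_window_h Window for the delta criterion (hours).
#' @param aki_baseline_ratio Ratio over baseline creatinine defining AKI.
#' @param aki_baseline_window_h Baseline look-back window (hours; 7 days).
#' @param aki_urine_rate Urine output threshold (ml/kg/h).
#' @param aki_urine_min_h Minimum sustained sub-threshold span (hours);
#'   longer spans also qualify.
#' @param ceft_alt_max Alanine transaminase ceiling for Ceftriaxone (U/L).
#' @param ceft_bili_max_male,ceft_bili_max_female Bilirubin total ceilings
#'   (mg/dl).
#' @return A list of class `contra_rules`.
#' @export
contra_rules <- function(vanc_creatinine_max = 2,
                         aki_creatinine_delta = 0.3, aki_delta_window_h = 48,
                         aki_baseline_ratio = 1.5, aki_baseline_window_h = 168,
                         aki_urine_rate = 0.5, aki_urine_min_h = 6,
                         ceft_alt_max = 280,
                         ceft_bili_max_male = 2.4, ceft_bili_max_female = 2.2) {
  vals <- as.list(environment())
  stopifnot(all(unlist(vals) > 0))
  structure(vals, class = "contra_rules")
}

#' Stage-1 acute kidney injury detection
#'
#' Flags stage-1 AKI if any of the guideline criteria holds anywhere in the
#' record: a creatinine increase of at least `aki_creatinine_delta` mg/dl
#' within `aki_delta_window_h` hours; a creatinine reaching
#' `aki_baseline_ratio` times the baseline (the minimum value over the
#' preceding `aki_baseline_window_h` hours); or urine output below
#' `aki_urine_rate` ml/kg/h sustained over a contiguous span of at least
#' `aki_urine_min_h` hours (longer spans also qualify). Urine output is
#' treated as a step function between observations; a span's duration is the
#' time between its first and last sub-threshold observation.
#'
#' @param creatinine Tibble with columns `time_h`, `value` (mg/dl).
#' @param urine Optional tibble with columns `time_h`, `value`; ml/kg/h if
#'   `weight` is `NULL`, else ml/h divided by `weight`.
#' @param weight Patient weight in kg (to convert ml/h urine output).
#' @param rules A [contra_rules()].
#' @return A list with `flag` (logical) and `reasons` (character vector among
#'   `"creatinine_delta"`, `"creatinine_ratio"`, `"urine_output"`).
#' @export
detect_aki_stage1 <- function(creatinine, urine = NULL, weight = NULL,
                              rules = contra_rules()) {
  stopifnot(nrow(creatinine) > 0)
  if (any(creatinine$value < 0) || (!is.null(urine) && any(urine$value < 0))) {
    stop("Negative lab values are not valid.", call. = FALSE)
  }
  cr <- creatinine[order(creatinine$time_h), ]
  reasons <- character()
  tt <- cr$time_h; vv <- cr$value
  n <- length(tt)
  if (n >= 2) {
    for (j in 2:n) {
      prior <- which(tt < tt[j] & tt >= tt[j] - rules$aki_delta_window_h)
      if (length(prior) && any(vv[j] - vv[prior] >= rules$aki_creatinine_delta)) {
        reasons <- c(reasons, "creatinine_delta"); break
      }
    }
    for (j in 2:n) {
      prior <- which(tt < tt[j] & tt >= tt[j] - rules$aki_baseline_window_h)
      if (length(prior) && vv[j] >= rules$aki_baseline_ratio * min(vv[prior])) {
        reasons <- c(reasons, "creatinine_ratio"); break
      }
    }
  }
  if (!is.null(urine) && nrow(urine) >= 2) {
    ur <- urine[order(urine$time_h), ]
    rate <- if (is.null(weight)) ur$value else ur$value / weight
    below <- rate < rules$aki_urine_rate
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (ur$time_h[ends[k]] - ur$time_h[starts[k]] >= rules$aki_urine_min_h) {
        reasons <- c(reasons, "urine_output"); break
      }
    }
  }
  list(flag = length(reasons) > 0, reasons = reasons)
}

#' Enumerate candidate antibiotic options
#'
#' All singletons and unordered pairs over the non-resistant antibiotics, in
#' deterministic lexicographic order.
#'
#' @param available Usable antibiotics.
#' @param resistant Antibiotics with known pathogen resistance (excluded).
#' @return A list of character vectors (the options).
#' @export
enumerate_options <- function(available = antibiotics(), resistant = character()) {
  usable <- setdiff(available, resistant)
  if (!length(usable)) {
    stop("All candidate antibiotics are resistant; refer the patient to the ",
         "attending physician for an alternative regimen.", call. = FALSE)
  }
  treatment_options(usable)
}

#' Contraindication check for one treatment option
#'
#' @param option Character vector of antibiotics (size 1--2).
#' @param labs Tibble with columns `variable`, `value` pooling the observed
#'   history and/or forecast trajectories, in physical units (`creatinine`
#'   mg/dl, `alanine_transaminase` U/L, `bilirubin_total` mg/dl).
#' @param sex `"M"` or `"F"`.
#' @param aki_flag Stage-1 AKI flag from [detect_aki_stage1()].
#' @param rules A [contra_rules()].
#' @return Character vector of warnings (empty if none): subset of
#'   `"vancomycin_creatinine"`, `"vancomycin_aki"`, `"ceftriaxone_alt"`,
#'   `"ceftriaxone_bilirubin"`.
#' @export
check_contraindications <- function(option, labs, sex, aki_flag = FALSE,
                                    rules = contra_rules()) {
  if (!sex %in% c("M", "F")) stop("Unknown sex code: ", sex, call. = FALSE)
  peak <- function(v) {
    x <- labs$value[labs$variable == v]
    if (length(x)) max(x) else -Inf
  }
  w <- character()
  if ("Vancomycin" %in% option) {
    if (peak("creatinine") > rules$vanc_creatinine_max) w <- c(w, "vancomycin_creatinine")
    if (isTRUE(aki_flag)) w <- c(w, "vancomycin_aki")
  }
  if ("Ceftriaxone" %in% option) {
    if (peak("alanine_transaminase") > rules$ceft_alt_max) w <- c(w, "ceftriaxone_alt")
    bili_max <- if (sex == "M") rules$ceft_bili_max_male else rules$ceft_bili_max_female
    if (peak("bilirubin_total") > bili_max) w <- c(w, "ceftriaxone_bilirubin")
  }
  w
}
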