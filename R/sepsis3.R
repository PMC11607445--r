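#' SOFA scoring configuration
#'
#' Breakpoint tables mapping raw measurements to the six SOFA organ subscores
#' (levels 0--4), plus the trailing window over which the worst value is
#' aggregated. Tables are data, not code: sites can replace any component to
#' match local conventions (vasopressor-tier details in particular vary
#' between pipelines).
#'
#' Each subscore is a list of components; a component maps one variable via
#' `direction` and four strictly monotone `breaks`:
#' `direction = "increasing"` scores `sum(value >= breaks)` (higher is worse,
#' e.g. bilirubin), `direction = "decreasing"` scores `sum(value < breaks)`
#' (lower is worse, e.g. platelets). A subscore with several components takes
#' their maximum (e.g. cardiovascular: hypotension or vasopressor tier). The
#' default renal table uses creatinine only; sites using urine-output criteria
#' can add a component.
#'
#' @param window_h Trailing window in hours for the worst-value aggregation.
#' @param closure Window closure for the rolling aggregation: `"left_open"`
#'   aggregates over `(t - window, t]`, `"closed"` over `[t - window, t]`.
#' @param subscores Named list of subscore component tables (see Details).
#' @return An object of class `sofa_config`.
#' @export
sofa_config <- function(window_h = 24,
                        closure = c("left_open", "closed"),
                        subscores = default_sofa_tables()) {
  stopifnot(window_h > 0)
  closure <- match.arg(closure)
  for (ss in subscores) {
    for (comp in ss) {
      stopifnot(length(comp$breaks) == 4L)
      d <- diff(comp$breaks)
      if (comp$direction == "increasing") stopifnot(all(d > 0)) else stopifnot(all(d < 0))
    }
  }
  structure(list(window_h = window_h, closure = closure, subscores = subscores),
            class = "sofa_config")
}

#' @rdname sofa_config
#' @export
default_sofa_tables <- function() {
  list(
    respiration = list(
      list(variable = "pf_ratio", direction = "decreasing", breaks = c(400, 300, 200, 100))
    ),
    coagulation = list(
      list(variable = "platelets", direction = "decreasing", breaks = c(150, 100, 50, 20))
    ),
    liver = list(
      list(variable = "bilirubin_total", direction = "increasing", breaks = c(1.2, 2.0, 6.0, 12.0))
    ),
    cardiovascular = list(
      list(variable = "map", direction = "decreasing", breaks = c(70, 0, -1, -2)),
      list(variable = "vasopressor_level", direction = "increasing", breaks = c(1, 2, 3, 4))
    ),
    cns = list(
      list(variable = "gcs", direction = "decreasing", breaks = c(15, 13, 10, 6))
    ),
    renal = list(
      list(variable = "creatinine", direction = "increasing", breaks = c(1.2, 2.0, 3.5, 5.0))
    )
  )
}

score_component <- function(value, comp) {
  if (comp$direction == "increasing") {
    rowSums(outer(value, comp$breaks, ">="))
  } else {
    rowSums(outer(value, comp$breaks, "<"))
  }
}

#' Map raw measurements to SOFA subscore levels
#'
#' @param measurements Tibble with columns `patient_id`, `time_h`, `variable`,
#'   `value`; units must match the configured tables.
#' @param config A [sofa_config()].
#' @param strict Error on variables that map to no subscore component
#'   (default); with `strict = FALSE` they are silently dropped.
#' @return Tibble with columns `patient_id`, `time_h`, `subscore`, `level`
#'   (integer 0--4).
#' @export
sofa_subscores <- function(measurements, config = sofa_config(), strict = TRUE) {
  var_map <- purrr::imap_dfr(config$subscores, function(comps, nm) {
    tibble::tibble(subscore = nm, variable = vapply(comps, `[[`, "", "variable"))
  })
  unknown <- setdiff(unique(measurements$variable), var_map$variable)
  if (strict && length(unknown)) {
    stop("No SOFA subscore table maps variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  purrr::imap_dfr(config$subscores, function(comps, nm) {
    purrr::map_dfr(comps, function(comp) {
      rows <- measurements[measurements$variable == comp$variable, , drop = FALSE]
      if (!nrow(rows)) return(NULL)
      tibble::tibble(patient_id = rows$patient_id, time_h = rows$time_h,
                     subscore = nm,
                     level = as.integer(score_component(rows$value, comp)))
    })
  }) |>
    # several components of one subscore observed at the same instant: worst
    dplyr::group_by(.data$patient_id, .data$time_h, .data$subscore) |>
    dplyr::summarise(level = max(.data$level), .groups = "drop") |>
    dplyr::arrange(.data$patient_id, .data$time_h, .data$subscore)
}

#' Trailing-window worst-value SOFA aggregation
#'
#' For each evaluation time, each subscore contributes the maximum level
#' observed in the trailing window; a subscore with no observation in the
#' window carries its last known level forward, and is 0 before its first
#' observation. The total is bounded in \[0, 24\].
#'
#' @param subscores Output of [sofa_subscores()].
#' @param config A [sofa_config()] (supplies window and closure).
#' @param eval_times Numeric vector of evaluation times; defaults per patient
#'   to the integer hours spanning that patient's observations.
#' @return Tibble with columns `patient_id`, `time_h`, `sofa`.
#' @export
sofa_rolling <- function(subscores, config = sofa_config(), eval_times = NULL) {
  if (!nrow(subscores)) {
    return(tibble::tibble(patient_id = character(), time_h = numeric(), sofa = numeric()))
  }
  w <- config$window_h
  left_open <- config$closure == "left_open"
  all_ss <- names(config$subscores)
  subscores |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      et <- if (is.null(eval_times)) seq(floor(min(df$time_h)), ceiling(max(df$time_h))) else eval_times
      total <- numeric(length(et))
      for (ss in all_ss) {
        d <- df[df$subscore == ss, , drop = FALSE]
        if (!nrow(d)) next
        d <- d[order(d$time_h), , drop = FALSE]
        for (i in seq_along(et)) {
          t <- et[i]
          lo <- t - w
          inw <- if (left_open) d$time_h > lo & d$time_h <= t else d$time_h >= lo & d$time_h <= t
          if (any(inw)) {
            total[i] <- total[i] + max(d$level[inw])
          } else {
            past <- which(d$time_h <= t)
            if (length(past)) total[i] <- total[i] + d$level[past[length(past)]]
          }
        }
      }
      tibble::tibble(time_h = et, sofa = pmin(pmax(total, 0), 24))
    }) |>
    dplyr::ungroup()
}

#' Suspicion-of-infection (SOI) detection
#'
#' A suspicion of infection is an antibiotic administration followed by a
#' microbiological culture sampling within 24 h, or a culture sampling
#' followed by an antibiotic administration within 72 h (both windows
#' inclusive on both ends). The SOI time is the earlier event of the
#' qualifying pair.
#'
#' @param abx_events Tibble with columns `patient_id`, `time_h` (antibiotic
#'   administrations).
#' @param culture_events Tibble with columns `patient_id`, `time_h` (culture
#'   samplings).
#' @return Tibble with columns `patient_id`, `soi_time_h`,
#'   `antibiotic_time_h`, `culture_time_h`, one row per qualifying pair.
#' @export
detect_soi <- function(abx_events, culture_events) {
  empty <- tibble::tibble(patient_id = character(), soi_time_h = numeric(),
                          antibiotic_time_h = numeric(), culture_time_h = numeric())
  if (!nrow(abx_events) || !nrow(culture_events)) return(empty)
  stopifnot(all(is.finite(abx_events$time_h)), all(is.finite(culture_events$time_h)))
  pairs <- dplyr::inner_join(
    dplyr::select(abx_events, "patient_id", antibiotic_time_h = "time_h"),
    dplyr::select(culture_events, "patient_id", culture_time_h = "time_h"),
    by = "patient_id", relationship = "many-to-many"
  )
  gap_ca <- pairs$culture_time_h - pairs$antibiotic_time_h
  ok <- (gap_ca >= 0 & gap_ca <= 24) | (gap_ca <= 0 & -gap_ca <= 72)
  pairs <- pairs[ok, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  pairs$soi_time_h <- pmin(pairs$antibiotic_time_h, pairs$culture_time_h)
  dplyr::arrange(
    dplyr::select(pairs, "patient_id", "soi_time_h", "antibiotic_time_h", "culture_time_h"),
    .data$patient_id, .data$soi_time_h
  )
}

#' Sepsis-3 onset labeling
#'
#' A patient is septic if any SOFA value greater than or equal to 2 lies in
#' the window from 48 h before to 24 h after some suspicion of infection
#' (window inclusive on both ends); the onset is the SOI time of the earliest
#' qualifying SOI.
#'
#' @param sofa_series Tibble with columns `patient_id`, `time_h`, `sofa`.
#' @param soi_events Output of [detect_soi()].
#' @param sofa_min SOFA threshold (default 2).
#' @param before_h,after_h Window extent around the SOI (defaults 48 and 24).
#' @return Tibble with one row per patient appearing in either input:
#'   `patient_id`, `septic` (logical), `onset_h` (`NA` if not septic).
#' @export
label_sepsis_onset <- function(sofa_series, soi_events, sofa_min = 2,
                               before_h = 48, after_h = 24) {
  ids <- sort(union(unique(sofa_series$patient_id), unique(soi_events$patient_id)))
  res <- purrr::map_dfr(ids, function(id) {
    soi <- sort(unique(soi_events$soi_time_h[soi_events$patient_id == id]))
    sofa <- sofa_series[sofa_series$patient_id == id, , drop = FALSE]
    onset <- NA_real_
    for (s in soi) {
      hit <- sofa$sofa >= sofa_min & sofa$time_h >= s - before_h & sofa$time_h <= s + after_h
      if (any(hit)) { onset <- s; break }
    }
    tibble::tibble(patient_id = id, septic = !is.na(onset), onset_h = onset)
  })
  res
}
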