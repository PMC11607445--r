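# Counterfactual forecasting under candidate options and the iterative,
# contraindication-aware antibiotic selection loop.

# shared machinery: encode to the decision hour, inject each candidate
# option's indicator into the treatment channels of the value-update segment
# at hour t (and nothing else), advance one hour, decode.
forecast_options_core <- function(model, tens, t, horizon, options) {
  abx <- antibiotics()
  M <- model$dims$M; K <- tens$K
  n <- length(tens$ids)
  Tn <- tens$horizon_h
  stopifnot(t >= 0, t <= Tn, horizon >= 1)
  pr <- model$params
  dm <- model$dims
  ss <- model$config$substeps
  if (t >= 1) {
    enc <- encode_core(NULL, model, pr, tens, t)
    xhat_t <- enc$xhat[[t]]
  }
  preds <- vector("list", length(options))
  for (oi in seq_along(options)) {
    ind_mat <- matrix(as.numeric(abx %in% options[[oi]]), n, M, byrow = TRUE)
    if (t == 0) {
      x0in <- tens$x0in
      x0in[, K + seq_len(M)] <- ind_mat
      x0 <- mlp_fwd(NULL, x0in, pr$g_eta)
      xanchor <- cde_segment(NULL, x0, tens$dXt, pr$F, dm$P, dm$C, ss)
    } else {
      dXv_t <- tens$dXv[[t]]
      dXv_t[, 1L + 2L * K + seq_len(M)] <- ind_mat - matrix(tens$a[, t, ], n, M)
      x_t <- cde_segment(NULL, xhat_t, dXv_t, pr$F, dm$P, dm$C, ss)
      xanchor <- cde_segment(NULL, x_t, tens$dXt, pr$F, dm$P, dm$C, ss)
    }
    members <- decoder_members(model)
    yh <- array(0, c(n, horizon, dm$R),
                dimnames = list(tens$ids, NULL, tens$outcomes))
    for (pm in members) {
      states <- decode_core(NULL, model, pm, xanchor, tens$d, horizon - 1L)
      for (h in seq_len(horizon)) {
        st <- states[[h]]
        if (any(!is.finite(st))) stop("Decoder integration diverged.", call. = FALSE)
        yh[, h, ] <- yh[, h, ] + mlp_fwd(NULL, st, pm$h_alpha_dec) / length(members)
      }
    }
    # de-normalize to physical units
    stt <- tens$prep$stats
    for (r in seq_len(dm$R)) {
      v <- tens$outcomes[r]
      yh[, , r] <- yh[, , r] * stt$sd[stt$variable == v] + stt$mean[stt$variable == v]
    }
    preds[[oi]] <- yh
  }
  list(hours = t + seq_len(horizon), preds = preds,
       labels = vapply(options, option_label, ""))
}

#' Counterfactual outcome forecast under a candidate antibiotic option
#'
#' Sets the control path's treatment channels to the option's indicator at
#' the decision hour, re-encodes to `t + 1` and decodes the uncontrolled
#' long-term forecast (the decoder embodies "treatment continues unchanged").
#' Querying the factually administered option reproduces the factual
#' long-term forecast exactly.
#'
#' @param model A trained [tecde_model()].
#' @param tens [prepare_tensors()] object for the cohort.
#' @param option Character vector of antibiotics (size 1--2).
#' @param t Decision hour (data up to `t` are assimilated).
#' @param horizon Forecast horizon in hours past `t`.
#' @param patients Optional subset of patient ids.
#' @return Tibble `patient_id`, `option`, `time_h`, `outcome`, `yhat`
#'   (physical units).
#' @export
forecast_under_option <- function(model, tens, option, t, horizon = 48,
                                  patients = NULL) {
  if (!is.null(patients)) tens <- tensors_subset(tens, patients)
  fc <- forecast_options_core(model, tens, t, horizon, list(option))
  yh <- fc$preds[[1L]]
  purrr::map_dfr(seq_along(tens$outcomes), function(r) {
    tibble::tibble(
      patient_id = rep(tens$ids, times = length(fc$hours)),
      option = fc$labels[1L],
      time_h = rep(fc$hours, each = length(tens$ids)),
      outcome = tens$outcomes[r],
      yhat = as.numeric(yh[, , r])
    )
  }) |>
    dplyr::arrange(.data$patient_id, .data$time_h, .data$outcome)
}

# per-patient resistant antibiotics known by time t
known_resistance <- function(micro, t) {
  micro |>
    dplyr::filter(.data$result_time_h <= t, !is.na(.data$resistant_to)) |>
    dplyr::distinct(.data$patient_id, .data$resistant_to)
}

#' Select the optimal antibiotic option at a decision time
#'
#' Forecasts the SOFA score and side-effect labs under every candidate
#' option (antibiotics with known pathogen resistance are excluded), checks
#' contraindications against both the observed history and the
#' option-specific forecasts, and selects the option minimizing the forecast
#' SOFA at `t + horizon`. In `"constrained"` mode warned options are skipped
#' while any warning-free candidate exists (if every candidate is warned the
#' SOFA minimizer is recommended with its warnings attached, configurable to
#' a hard refusal); `"unconstrained"` ignores warnings. Ties are broken
#' toward fewer antibiotics, then lexicographically (the de-escalation
#' preference).
#'
#' @inheritParams forecast_under_option
#' @param cohort The raw cohort list (observed labs, microbiology, statics).
#' @param rules A [contra_rules()].
#' @param mode `"constrained"` or `"unconstrained"`.
#' @param threshold_scope Evaluate contraindication thresholds on the
#'   observed history, the forecasts, or both (default).
#' @param on_all_warned `"recommend"` (default) or `"refuse"`.
#' @param tie_margin Practical-equivalence margin (SOFA units): among
#'   permitted options whose forecast end-point SOFA lies within this margin
#'   of the minimum, the option with the fewest antibiotics (then
#'   lexicographic) is preferred -- treatments of similar predicted efficacy
#'   resolve toward the least side-effect burden. The default 0 keeps the
#'   selection an exact argmin.
#' @return A tibble of class `abx_decision`: one row per (patient, option)
#'   with forecast end-point SOFA, warnings and the selection flag.
#' @export
select_optimal <- function(model, tens, cohort, t, horizon = 48,
                           rules = contra_rules(),
                           mode = c("constrained", "unconstrained"),
                           patients = NULL,
                           threshold_scope = c("both", "observed", "forecast"),
                           on_all_warned = c("recommend", "refuse"),
                           tie_margin = 0) {
  mode <- match.arg(mode)
  threshold_scope <- match.arg(threshold_scope)
  on_all_warned <- match.arg(on_all_warned)
  if (!is.null(patients)) tens <- tensors_subset(tens, patients)
  ids <- tens$ids
  n <- length(ids)
  opts <- treatment_options()
  labels <- vapply(opts, option_label, "")
  n_abx <- vapply(opts, length, 1L)
  fc <- forecast_options_core(model, tens, t, horizon, opts)
  sofa_idx <- match("sofa", tens$outcomes)
  sofa_end <- vapply(fc$preds, function(yh) yh[, length(fc$hours), sofa_idx], numeric(n))
  sofa_end <- matrix(sofa_end, n, length(opts))

  res <- known_resistance(cohort$micro, t)
  obs <- cohort$observations |>
    dplyr::filter(.data$patient_id %in% ids, .data$time_h <= t,
                  .data$variable %in% c("creatinine", "alanine_transaminase",
                                        "bilirubin_total"))
  sex <- cohort$statics$sex[match(ids, cohort$statics$patient_id)]
  pref <- order(n_abx, labels)          # tie-break priority
  rank_of <- integer(length(opts)); rank_of[pref] <- seq_along(opts)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- ids[i]
    res_i <- res$resistant_to[res$patient_id == id]
    allowed <- !vapply(opts, function(o) any(o %in% res_i), TRUE)
    if (!any(allowed)) {
      stop("All candidate antibiotics are resistant for patient ", id,
           "; refer to the attending physician.", call. = FALSE)
    }
    obs_i <- obs[obs$patient_id == id, c("time_h", "variable", "value")]
    warn_i <- vector("list", length(opts))
    for (oi in seq_along(opts)) {
      if (!allowed[oi]) { warn_i[[oi]] <- character(); next }
      fc_i <- purrr::map_dfr(seq_along(tens$outcomes), function(r) {
        tibble::tibble(time_h = fc$hours, variable = tens$outcomes[r],
                       value = fc$preds[[oi]][i, , r])
      })
      labs <- switch(threshold_scope,
        both = dplyr::bind_rows(obs_i, fc_i),
        observed = obs_i,
        forecast = fc_i
      )
      creat <- labs[labs$variable == "creatinine", c("time_h", "value")]
      aki <- if (nrow(creat)) detect_aki_stage1(creat, rules = rules)$flag else FALSE
      warn_i[[oi]] <- check_contraindications(opts[[oi]], labs, sex[i], aki, rules)
    }
    warned <- vapply(warn_i, function(w) length(w) > 0, TRUE)
    pick_from <- function(mask) {
      cand <- which(mask)
      near <- cand[sofa_end[i, cand] <= min(sofa_end[i, cand]) + tie_margin]
      near[order(rank_of[near], sofa_end[i, near])][1L]
    }
    all_warned <- FALSE
    if (mode == "unconstrained") {
      sel <- pick_from(allowed)
    } else if (any(allowed & !warned)) {
      sel <- pick_from(allowed & !warned)
    } else if (on_all_warned == "recommend") {
      sel <- pick_from(allowed)
      all_warned <- TRUE
    } else {
      sel <- NA_integer_
      all_warned <- TRUE
    }
    rows[[i]] <- tibble::tibble(
      patient_id = id, decision_time_h = t, horizon_h = horizon,
      option = labels, n_antibiotics = n_abx,
      excluded_resistant = !allowed,
      sofa_pred_end = sofa_end[i, ],
      warned = warned,
      warnings = vapply(warn_i, paste, "", collapse = ";"),
      selected = if (is.na(sel)) rep(FALSE, length(opts)) else seq_along(opts) == sel,
      all_candidates_warned = all_warned
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("abx_decision", class(out))
  out
}

#' Iterate the antibiotic selection over the clinical schedule
#'
#' Decisions at sepsis onset (horizon 48 h) and then every 24 h (horizon
#' 24 h), each re-assimilating all data observed so far. Mid-window
#' re-decisions are triggered by newly arriving resistance results. A
#' de-escalation notification is emitted when the observed SOFA score is
#' non-increasing and strictly lower over the trailing 48 h; fungal or viral
#' culture results notify the attending physician without altering the
#' antibiotic ranking.
#'
#' @inheritParams select_optimal
#' @param until_h Last scheduled decision hour (defaults to the grid
#'   horizon).
#' @return A list of class `abx_plan`: `decisions` (bound
#'   [select_optimal()] records) and `notifications` (tibble `patient_id`,
#'   `time_h`, `type`, `detail`).
#' @export
plan_iterations <- function(model, tens, cohort, rules = contra_rules(),
                            mode = "constrained", patients = NULL,
                            until_h = NULL) {
  if (!is.null(patients)) tens <- tensors_subset(tens, patients)
  ids <- tens$ids
  Tn <- tens$horizon_h
  until_h <- min(until_h %||% Tn, Tn)
  sched <- unique(c(0, seq(48, until_h, by = 24)))
  decisions <- purrr::map(sched, function(t) {
    select_optimal(model, tens, cohort, t, horizon = if (t == 0) 48 else 24,
                   rules = rules, mode = mode)
  })

  micro <- dplyr::filter(cohort$micro, .data$patient_id %in% ids)
  notif <- list()
  # fungal / viral pathogen notifications at result time
  fv <- dplyr::filter(micro, .data$organism_class %in% c("fungal", "viral"))
  if (nrow(fv)) {
    notif[[length(notif) + 1L]] <- tibble::tibble(
      patient_id = fv$patient_id, time_h = fv$result_time_h,
      type = "pathogen_notification", detail = fv$organism_class
    )
  }
  # resistance results between scheduled decisions trigger a re-decision
  rr <- dplyr::filter(micro, !is.na(.data$resistant_to),
                      .data$result_time_h <= until_h,
                      !(round(.data$result_time_h) %in% sched))
  if (nrow(rr)) {
    for (k in seq_len(nrow(rr))) {
      t_re <- ceiling(rr$result_time_h[k])
      if (t_re > Tn) next
      decisions[[length(decisions) + 1L]] <- select_optimal(
        model, tens, cohort, t_re, horizon = 24, rules = rules, mode = mode,
        patients = rr$patient_id[k]
      )
      notif[[length(notif) + 1L]] <- tibble::tibble(
        patient_id = rr$patient_id[k], time_h = rr$result_time_h[k],
        type = "resistance_redecision", detail = rr$resistant_to[k]
      )
    }
  }
  # de-escalation: observed SOFA non-increasing and strictly lower over 48 h
  sofa_obs <- dplyr::filter(cohort$observations, .data$patient_id %in% ids,
                            .data$variable == "sofa")
  for (t in sched[sched >= 48]) {
    win <- dplyr::filter(sofa_obs, .data$time_h >= t - 48, .data$time_h <= t)
    dec <- win |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::arrange(.data$time_h, .by_group = TRUE) |>
      dplyr::summarise(deesc = dplyr::n() >= 2 && all(diff(.data$value) <= 0) &&
                         dplyr::last(.data$value) < dplyr::first(.data$value),
                       .groups = "drop") |>
      dplyr::filter(.data$deesc)
    if (nrow(dec)) {
      notif[[length(notif) + 1L]] <- tibble::tibble(
        patient_id = dec$patient_id, time_h = t,
        type = "deescalation", detail = "observed SOFA decreasing over 48 h"
      )
    }
  }
  notifications <- if (length(notif)) {
    dplyr::arrange(dplyr::bind_rows(notif), .data$patient_id, .data$time_h)
  } else {
    tibble::tibble(patient_id = character(), time_h = numeric(),
                   type = character(), detail = character())
  }
  structure(list(decisions = dplyr::bind_rows(decisions),
                 notifications = notifications, schedule = sched),
            class = "abx_plan")
}
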