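#' Simulate a confounded synthetic sepsis cohort with counterfactual ground truth
#'
#' Generates an irregularly sampled, heavily missing synthetic ICU cohort
#' (long-format observation, treatment-interval, microbiology and static
#' tables) together with the full counterfactual outcome paths of every
#' candidate antibiotic option from every decision time. All counterfactual
#' paths of a patient reuse one Brownian draw (shared noise), so option
#' contrasts are noise-free and the stored best-option labels are a sharp
#' oracle for treatment-selection methods.
#'
#' Latent severity follows Euler--Maruyama integration of a mean-reverting
#' diffusion with per-option drift; the continuous SOFA score is the latent
#' severity clipped to \[0, 24\]. Creatinine gains a positive drift under
#' Vancomycin, bilirubin total and alanine transaminase under Ceftriaxone.
#' Treatment options are drawn at decision times (0 h, 48 h, then every 24 h)
#' from a softmax policy scored on the current SOFA and creatinine values.
#'
#' @param config A [sim_config()].
#' @return A list of class `abx_sim` with elements `cohort` (list of tibbles
#'   `observations`, `treatments`, `micro`, `statics`) and `truth` (list with
#'   pathogen classes, hourly factual states, the counterfactual path array,
#'   policy log-probabilities and best-option labels).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  H <- config$horizon_h
  dt <- config$dt_h
  nsteps <- as.integer(round(H / dt))
  stopifnot(abs(nsteps * dt - H) < 1e-9)
  per_hour <- as.integer(round(1 / dt))
  hours <- 0:H

  ids <- sprintf("P%04d", seq_len(n))
  opts <- treatment_options()
  opt_labels <- vapply(opts, option_label, "")
  n_opt <- length(opts)
  classes <- pathogen_classes()

  # statics and pathogen class
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- pmin(pmax(round(stats::rnorm(n, 66, 13)), 18), 95)
  height <- round(stats::rnorm(n, ifelse(sex == "M", 176, 163), 7), 1)
  weight <- round(pmax(stats::rnorm(n, ifelse(sex == "M", 84, 72), 14), 40), 1)
  pclass <- sample(classes, n, replace = TRUE, prob = config$pathogen_class_probs)

  # per-option drifts on severity and labs
  opt_drift <- vapply(opts, function(o) {
    colSums(config$efficacy_matrix[o, , drop = FALSE])
  }, numeric(length(classes)))           # classes x options
  dyn_labs <- c("creatinine", "bilirubin_total", "alanine_transaminase")
  opt_tox <- matrix(0, n_opt, length(dyn_labs), dimnames = list(opt_labels, dyn_labs))
  for (oi in seq_len(n_opt)) {
    for (ab in opts[[oi]]) {
      tx <- config$toxicity[[ab]]
      if (!is.null(tx)) opt_tox[oi, names(tx)] <- opt_tox[oi, names(tx)] + tx
    }
  }
  drift_by_patient <- function(opt_idx) {
    # severity drift for each patient given current option index
    opt_drift[cbind(match(pclass, classes), opt_idx)]
  }

  # baselines, shifted by pathogen class (class partially observable in labs)
  shift <- function(var) {
    vapply(pclass, function(cl) {
      s <- config$class_lab_shift[[cl]]
      if (!is.null(s) && var %in% names(s)) s[[var]] else 0
    }, 0)
  }
  u <- pmin(pmax(stats::rnorm(n, 11, 2.5), 3), 20)
  state <- list(
    creatinine = pmax(stats::rnorm(n, 0.9, 0.15) + shift("creatinine"), 0.3),
    bilirubin_total = pmax(stats::rnorm(n, 0.8, 0.2) + shift("bilirubin_total"), 0.1),
    alanine_transaminase = pmax(stats::rnorm(n, 30, 8) + shift("alanine_transaminase"), 5),
    anion_gap = stats::rnorm(n, 12, 2),
    lactate = pmax(stats::rnorm(n, 1.8, 0.5), 0.2),
    chloride = stats::rnorm(n, 102, 3)
  )
  chloride_base <- state$chloride

  # shared Brownian increments (one draw reused by every counterfactual path)
  dW_u <- matrix(stats::rnorm(n * nsteps), n, nsteps) * sqrt(dt)
  dW_lab <- lapply(dyn_labs, function(v) matrix(stats::rnorm(n * nsteps), n, nsteps) * sqrt(dt))
  names(dW_lab) <- dyn_labs
  dW_aux <- lapply(c("anion_gap", "lactate", "chloride"), function(v)
    matrix(stats::rnorm(n * nsteps), n, nsteps) * sqrt(dt))
  names(dW_aux) <- c("anion_gap", "lactate", "chloride")

  decision_times <- unique(c(0, seq(48, max(48, H - 24), by = 24)))
  decision_times <- decision_times[decision_times < H]
  n_dec <- length(decision_times)
  dec_steps <- as.integer(round(decision_times / dt)) + 1L  # step index at which decision applies

  sevc <- config$sev_coupling
  sref <- config$sev_coupling_ref
  kappa <- config$mean_reversion
  m_set <- config$severity_setpoint
  sd_u <- config$latent_noise_sd
  sd_lab <- config$lab_noise_sd

  # one Euler--Maruyama step of (u, dynamic labs); `s` indexes the noise column
  step_state <- function(u, labs, opt_idx, s) {
    du <- (kappa * (m_set - u) + drift_by_patient(opt_idx)) * dt
    u_new <- u + du + sd_u * dW_u[, s]
    for (v in dyn_labs) {
      dl <- (sevc[[v]] * (u - sref) + opt_tox[cbind(opt_idx, match(v, dyn_labs))]) * dt
      labs[[v]] <- pmax(labs[[v]] + dl + sd_lab[[v]] * dW_lab[[v]][, s], 0.01)
    }
    list(u = u_new, labs = labs)
  }

  # ---- factual pass ----------------------------------------------------
  fact_u <- matrix(NA_real_, n, nsteps + 1L)
  fact_labs <- lapply(dyn_labs, function(v) matrix(NA_real_, n, nsteps + 1L))
  names(fact_labs) <- dyn_labs
  aux_hourly <- lapply(names(dW_aux), function(v) matrix(NA_real_, n, H + 1L))
  names(aux_hourly) <- names(dW_aux)
  fact_u[, 1L] <- u
  for (v in dyn_labs) fact_labs[[v]][, 1L] <- state[[v]]
  for (v in names(dW_aux)) aux_hourly[[v]][, 1L] <- state[[v]]

  cur_opt <- rep(1L, n)
  fact_opt_at_dec <- matrix(NA_integer_, n, n_dec)
  policy_logp <- matrix(NA_real_, n, n_dec)
  cur_u <- u
  cur_labs <- state[dyn_labs]
  aux <- state[c("anion_gap", "lactate", "chloride")]
  n_abx_opt <- vapply(opts, length, 1L)
  has_vanc <- vapply(opts, function(o) "Vancomycin" %in% o, TRUE)

  for (s in seq_len(nsteps)) {
    t_now <- (s - 1L) * dt
    di <- match(s, dec_steps)
    if (!is.na(di)) {
      sofa_now <- pmin(pmax(cur_u, 0), 24)
      score <- outer(sofa_now, n_abx_opt) * 0.15 - 0.6 * outer(cur_labs$creatinine, as.numeric(has_vanc))
      logits <- score / config$policy_temperature
      logits <- logits - apply(logits, 1L, max)
      p <- exp(logits) / rowSums(exp(logits))
      r <- stats::runif(n)
      cum <- t(apply(p, 1L, cumsum))
      cur_opt <- max.col(cum >= r, ties.method = "first")
      fact_opt_at_dec[, di] <- cur_opt
      policy_logp[, di] <- log(p[cbind(seq_len(n), cur_opt)])
    }
    # auxiliary (non-outcome) variables: OU around baseline plus coupling
    aux$anion_gap <- aux$anion_gap +
      (0.05 * (12 - aux$anion_gap) + sevc[["anion_gap"]] * (cur_u - sref)) * dt +
      0.25 * dW_aux$anion_gap[, s]
    aux$lactate <- pmax(aux$lactate +
      (0.05 * (1.5 - aux$lactate) + sevc[["lactate"]] * (cur_u - sref)) * dt +
      0.06 * dW_aux$lactate[, s], 0.05)
    aux$chloride <- aux$chloride + 0.05 * (chloride_base - aux$chloride) * dt +
      0.3 * dW_aux$chloride[, s]
    st <- step_state(cur_u, cur_labs, cur_opt, s)
    cur_u <- st$u; cur_labs <- st$labs
    fact_u[, s + 1L] <- cur_u
    for (v in dyn_labs) fact_labs[[v]][, s + 1L] <- cur_labs[[v]]
    if (s %% per_hour == 0L) {
      hcol <- s %/% per_hour + 1L
      for (v in names(aux)) aux_hourly[[v]][, hcol] <- aux[[v]]
    }
  }
  hour_cols <- seq(1L, nsteps + 1L, by = per_hour)
  fact_hourly <- array(NA_real_, c(n, H + 1L, 4L),
                       dimnames = list(ids, NULL, c("sofa", dyn_labs)))
  fact_hourly[, , "sofa"] <- pmin(pmax(fact_u[, hour_cols], 0), 24)
  for (v in dyn_labs) fact_hourly[, , v] <- fact_labs[[v]][, hour_cols]

  # ---- counterfactual passes (shared noise) ----------------------------
  cf <- array(NA_real_, c(n, n_dec, n_opt, H + 1L, 4L),
              dimnames = list(ids, paste0("t", decision_times), opt_labels,
                              NULL, c("sofa", dyn_labs)))
  for (di in seq_len(n_dec)) {
    s0 <- dec_steps[di]
    pre_hours <- which(hour_cols < s0)
    for (oi in seq_len(n_opt)) {
      cf_u <- fact_u[, s0]
      cf_labs <- lapply(dyn_labs, function(v) fact_labs[[v]][, s0])
      names(cf_labs) <- dyn_labs
      traj_u <- fact_u
      traj_labs <- fact_labs
      for (s in s0:nsteps) {
        st <- step_state(cf_u, cf_labs, rep(oi, n), s)
        cf_u <- st$u; cf_labs <- st$labs
        traj_u[, s + 1L] <- cf_u
        for (v in dyn_labs) traj_labs[[v]][, s + 1L] <- cf_labs[[v]]
      }
      cf[, di, oi, , "sofa"] <- pmin(pmax(traj_u[, hour_cols], 0), 24)
      for (v in dyn_labs) cf[, di, oi, , v] <- traj_labs[[v]][, hour_cols]
    }
  }

  # best option 48 h after the first decision (ties: fewest antibiotics, then
  # lexicographic -- the de-escalation preference)
  sofa_48 <- cf[, 1L, , as.integer(decision_times[1L]) + 48L + 1L, "sofa", drop = FALSE]
  sofa_48 <- matrix(sofa_48, n, n_opt)
  best_idx <- apply(sofa_48, 1L, function(x) {
    cand <- which(x <= min(x) + 1e-9)
    cand[order(n_abx_opt[cand], opt_labels[cand])][1L]
  })
  best_option_48h <- opt_labels[best_idx]

  # ---- observation process --------------------------------------------
  vars <- names(config$obs_rates)
  obs_list <- vector("list", length(vars))
  state_hourly_of <- function(v) {
    if (v == "sofa") fact_hourly[, , "sofa"]
    else if (v %in% dyn_labs) fact_hourly[, , v]
    else aux_hourly[[v]]
  }
  # state on the fine grid for value lookup at raw observation times
  state_fine_of <- function(v) {
    if (v == "sofa") pmin(pmax(fact_u, 0), 24)
    else if (v %in% dyn_labs) fact_labs[[v]]
    else NULL
  }
  for (k in seq_along(vars)) {
    v <- vars[k]
    counts <- stats::rpois(n, config$obs_rates[[v]] * H)
    pid <- rep.int(seq_len(n), counts)
    t_raw <- stats::runif(sum(counts), 0, H)
    if (v == "sofa") {  # always anchor the record with an onset SOFA value
      pid <- c(seq_len(n), pid)
      t_raw <- c(rep(0, n), t_raw)
      n_forced <- n
    } else {            # admission panel: most labs are drawn on ICU entry
      adm <- which(stats::runif(n) < 0.9)
      pid <- c(adm, pid)
      t_raw <- c(stats::runif(length(adm), 0, 0.45), t_raw)
      n_forced <- length(adm)
    }
    keep <- c(rep(TRUE, n_forced),
              stats::runif(length(t_raw) - n_forced) >= config$missing_frac)
    pid <- pid[keep]; t_raw <- t_raw[keep]
    fine <- state_fine_of(v)
    if (is.null(fine)) {
      val <- state_hourly_of(v)[cbind(pid, pmin(round(t_raw), H) + 1L)]
    } else {
      val <- fine[cbind(pid, pmin(as.integer(round(t_raw / dt)), nsteps) + 1L)]
    }
    obs_list[[k]] <- tibble::tibble(patient_id = ids[pid], time_h = t_raw,
                                    variable = v, value = val)
  }
  observations <- dplyr::arrange(dplyr::bind_rows(obs_list),
                                 .data$patient_id, .data$time_h, .data$variable)

  # ---- treatment intervals and microbiology ----------------------------
  dec_ends <- c(decision_times[-1L], H)
  trt <- purrr::map_dfr(seq_len(n_dec), function(di) {
    oi <- fact_opt_at_dec[, di]
    purrr::map_dfr(seq_len(n_opt), function(o) {
      who <- which(oi == o)
      if (!length(who)) return(NULL)
      tidyr::crossing(patient_id = ids[who], antibiotic = opts[[o]]) |>
        dplyr::mutate(start_h = decision_times[di], end_h = dec_ends[di],
                      .before = "antibiotic")
    })
  }) |>
    dplyr::arrange(.data$patient_id, .data$start_h, .data$antibiotic) |>
    dplyr::select("patient_id", "start_h", "end_h", "antibiotic")

  sample_t <- stats::runif(n, 0, 2)
  result_t <- sample_t + stats::runif(n, 48, 72)
  bacterial <- pclass %in% c("gram_pos", "gram_neg", "mixed")
  res_flag <- bacterial & stats::runif(n) < config$resistance_prob
  res_ab <- ifelse(res_flag, sample(antibiotics(), n, replace = TRUE), NA_character_)
  micro <- tibble::tibble(patient_id = ids, sample_time_h = sample_t,
                          result_time_h = result_t, organism_class = pclass,
                          resistant_to = res_ab)

  statics <- tibble::tibble(patient_id = ids, sex = sex, age = age,
                            height = height, weight = weight)

  truth <- list(
    pathogen_class = stats::setNames(pclass, ids),
    decision_times = decision_times,
    options = opt_labels,
    factual_hourly = fact_hourly,
    factual_option = matrix(opt_labels[fact_opt_at_dec], n, n_dec,
                            dimnames = list(ids, paste0("t", decision_times))),
    policy_logp = `dimnames<-`(policy_logp, list(ids, paste0("t", decision_times))),
    cf_paths = cf,
    best_option_48h = stats::setNames(best_option_48h, ids)
  )
  structure(list(
    cohort = list(observations = observations, treatments = trt,
                  micro = micro, statics = statics),
    truth = truth, config = config
  ), class = "abx_sim")
}

#' @export
print.abx_sim <- function(x, ...) {
  cat("<abx_sim> synthetic sepsis cohort\n")
  cat("  patients:     ", x$config$n_patients, "\n")
  cat("  horizon:      ", x$config$horizon_h, "h\n")
  cat("  observations: ", nrow(x$cohort$observations), "\n")
  cat("  decisions at: ", paste(x$truth$decision_times, collapse = ", "), "h\n")
  invisible(x)
}

#' Retrieve a stored counterfactual outcome path
#'
#' Accessor for the simulator's noise-shared ground truth: the outcome path a
#' patient would have followed had a given antibiotic option been applied
#' from a decision time onward.
#'
#' @param truth The `truth` element of [simulate_cohort()].
#' @param patient_id Patient identifier.
#' @param option A treatment option (character vector of antibiotics or an
#'   option label such as `"Ceftriaxone + Vancomycin"`).
#' @param t_start A decision time (hours).
#' @param horizon Hours past `t_start` to return (must fit in the simulated
#'   horizon).
#' @return A tibble with columns `time_h`, `variable`, `value` for the
#'   outcomes `sofa`, `creatinine`, `bilirubin_total`, `alanine_transaminase`.
#' @export
counterfactual_outcomes <- function(truth, patient_id, option, t_start, horizon) {
  lab <- if (length(option) > 1 || !option %in% truth$options) option_label(option) else option
  if (!lab %in% truth$options) {
    stop("Unknown treatment option: ", lab, call. = FALSE)
  }
  di <- match(t_start, truth$decision_times)
  if (is.na(di)) {
    stop("`t_start` must be one of the decision times: ",
         paste(truth$decision_times, collapse = ", "), call. = FALSE)
  }
  n_hours <- dim(truth$cf_paths)[4L] - 1L
  if (t_start + horizon > n_hours) stop("horizon exceeds the simulated horizon.", call. = FALSE)
  if (!patient_id %in% rownames(truth$cf_paths)) stop("Unknown patient.", call. = FALSE)
  hrs <- t_start:(t_start + horizon)
  vars <- dimnames(truth$cf_paths)[[5L]]
  purrr::map_dfr(vars, function(v) {
    tibble::tibble(time_h = hrs, variable = v,
                   value = truth$cf_paths[patient_id, di, lab, hrs + 1L, v])
  })
}
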