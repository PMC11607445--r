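# Evaluation procedures: forecast-error grids, counterfactual side-effect
# contrasts, counterfactual/factual matching and average treatment
# improvement -- all runnable on the synthetic cohort.

#' Forecast-error grid in units of variance
#'
#' For each (observation time `o`, forecast horizon `h`) cell the encoder
#' assimilates the patient's data up to `o`, the decoder forecasts to
#' `o + h`, and the squared error against the observations at `o + h` is
#' accumulated and divided by the variable's variance over all observations
#' entering the grid (population variance of the pooled targets, so a
#' predict-the-global-mean baseline pools to exactly 1).
#'
#' @param model A trained [tecde_model()].
#' @param tens Held-out cohort tensors.
#' @param variable Variable to score (an outcome).
#' @param obs_times Observation times `o` (hours).
#' @param horizons Forecast horizons `h >= 1` (hours).
#' @param lab_smoothing Average each cell over 5 consecutive observation-time
#'   cells (centered moving average), as appropriate for sparsely measured
#'   labs.
#' @param predictor `"model"` or the `"global_mean"` baseline.
#' @return A tibble of class `mse_grid` with columns `obs_time_h`,
#'   `horizon_h`, `mse` (variance units), `n`; attributes carry the variable
#'   and the variance normalizer.
#' @export
mse_grid <- function(model, tens, variable = "sofa",
                     obs_times = seq(0, 48, by = 4), horizons = 1:48,
                     lab_smoothing = FALSE,
                     predictor = c("model", "global_mean")) {
  predictor <- match.arg(predictor)
  r <- match(variable, tens$outcomes)
  if (is.na(r)) stop("`variable` must be one of the outcomes.", call. = FALSE)
  Tn <- tens$horizon_h
  obs_times <- obs_times[obs_times + 1L <= Tn]
  Hmax <- max(horizons)
  stt <- tens$prep$stats
  mu_v <- stt$mean[stt$variable == variable]
  sd_v <- stt$sd[stt$variable == variable]
  y_phys <- tens$z_obs[, , r] * sd_v + mu_v      # NA where unobserved

  enc <- encode_core(NULL, model, model$params, tens, min(max(obs_times) + 1L, Tn))
  members <- decoder_members(model)
  cells <- list()
  targets <- c()
  for (o in obs_times) {
    anchor <- enc$xhat[[o + 1L]]
    H <- min(Hmax, Tn - o)
    states_m <- lapply(members, function(pm)
      decode_core(NULL, model, pm, anchor, tens$d, H - 1L))
    for (h in horizons[horizons <= H]) {
      yobs <- y_phys[, o + h + 1L]
      sel <- !is.na(yobs)
      nn <- sum(sel)
      if (nn == 0) {
        cells[[length(cells) + 1L]] <- tibble::tibble(obs_time_h = o, horizon_h = h,
                                                      sse = NA_real_, n = 0L)
        next
      }
      yhat <- if (predictor == "model") {
        p <- Reduce(`+`, lapply(seq_along(members), function(k) {
          mlp_fwd(NULL, states_m[[k]][[h]], members[[k]]$h_alpha_dec)[, r]
        })) / length(members) * sd_v + mu_v
        p[sel]
      } else rep(NA_real_, nn)  # filled after the global mean is known
      cells[[length(cells) + 1L]] <- tibble::tibble(
        obs_time_h = o, horizon_h = h,
        sse = if (predictor == "model") sum((yhat - yobs[sel])^2) else NA_real_,
        n = nn
      )
      targets <- c(targets, yobs[sel])
      if (predictor == "global_mean") {
        cells[[length(cells)]]$sse <- sum(yobs[sel]^2)  # placeholder; centered below
      }
    }
  }
  grid <- dplyr::bind_rows(cells)
  gmean <- mean(targets)
  gvar <- mean((targets - gmean)^2)
  if (predictor == "global_mean") {
    # sum (y - gmean)^2 = sum y^2 - 2 gmean sum y + n gmean^2; recompute directly
    grid2 <- list(); k <- 0
    for (o in obs_times) for (h in horizons[horizons <= min(Hmax, Tn - o)]) {
      yobs <- y_phys[, o + h + 1L]; sel <- !is.na(yobs)
      k <- k + 1L
      grid2[[k]] <- tibble::tibble(obs_time_h = o, horizon_h = h,
                                   sse = if (sum(sel)) sum((yobs[sel] - gmean)^2) else NA_real_,
                                   n = sum(sel))
    }
    grid <- dplyr::bind_rows(grid2)
  }
  grid$mse <- grid$sse / (grid$n * gvar)
  if (lab_smoothing) {
    grid <- grid |>
      dplyr::group_by(.data$horizon_h) |>
      dplyr::arrange(.data$obs_time_h, .by_group = TRUE) |>
      dplyr::mutate(mse = smooth5(.data$mse)) |>
      dplyr::ungroup()
  }
  out <- dplyr::select(grid, "obs_time_h", "horizon_h", "mse", "n")
  attr(out, "variable") <- variable
  attr(out, "variance") <- gvar
  class(out) <- c("mse_grid", class(out))
  out
}

# centered 5-cell moving average, NA-aware, shrinking at the edges
smooth5 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - 2):min(n, i + 2)
    mean(x[w], na.rm = TRUE)
  }, 0)
}

# the factually administered option (label) in force at hour t
factual_option_at <- function(cohort, t) {
  cohort$treatments |>
    dplyr::filter(.data$start_h <= t, .data$end_h > t) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(option = option_label(unique(.data$antibiotic)), .groups = "drop")
}

#' Counterfactual side-effect contrast between two antibiotics
#'
#' Excludes patients treated with multiple antibiotics, draws a balanced
#' sample across the factual single-treatment groups without replacement,
#' and for each sampled patient simulates both antibiotics of the pair from
#' the factual treatment start, returning the per-patient differences
#' (first minus second antibiotic) of the side-effect labs over time.
#'
#' @inheritParams mse_grid
#' @param cohort Raw cohort list.
#' @param abx_pair The two antibiotics to contrast (default Vancomycin
#'   versus Ceftriaxone).
#' @param t_start Treatment start hour from which both options are
#'   simulated.
#' @param horizon Forecast horizon (72 h).
#' @param seed Seed for the balanced sampling.
#' @return A tibble of class `abx_contrast`: `patient_id`, `time_h`,
#'   `outcome`, `delta`.
#' @export
side_effect_contrast <- function(model, tens, cohort,
                                 abx_pair = c("Vancomycin", "Ceftriaxone"),
                                 t_start = 0, horizon = 72, seed = 1L) {
  stopifnot(length(abx_pair) == 2)
  fo <- factual_option_at(cohort, t_start)
  singles <- fo[!grepl(" \\+ ", fo$option) & fo$patient_id %in% tens$ids, ]
  counts <- table(singles$option)
  if (length(counts) < 2 || any(counts == 0)) {
    stop("A factual single-treatment group is empty; cannot draw a balanced sample.",
         call. = FALSE)
  }
  set.seed(seed)
  m <- min(counts)
  sampled <- unlist(lapply(names(counts), function(g) {
    ids <- singles$patient_id[singles$option == g]
    sample(ids, m)
  }))
  sub <- tensors_subset(tens, sort(sampled))
  fc <- forecast_options_core(model, sub, t_start, horizon,
                              list(abx_pair[1], abx_pair[2]))
  labs <- setdiff(tens$outcomes, "sofa")
  out <- purrr::map_dfr(labs, function(v) {
    rr <- match(v, tens$outcomes)
    dl <- fc$preds[[1L]][, , rr] - fc$preds[[2L]][, , rr]
    tibble::tibble(patient_id = rep(sub$ids, times = length(fc$hours)),
                   time_h = rep(fc$hours, each = length(sub$ids)),
                   outcome = v, delta = as.numeric(dl))
  })
  attr(out, "abx_pair") <- abx_pair
  attr(out, "group_counts") <- counts
  attr(out, "sampled_per_group") <- m
  class(out) <- c("abx_contrast", class(out))
  out
}

#' Counterfactual and factual matching of SOFA trajectories
#'
#' Counterfactual arm: for patients whose factual treatment differs from the
#' selected optimum, match to the nearest patient (Euclidean distance over
#' all normalized covariates at sepsis onset) factually given that optimum,
#' and average the absolute difference between the predicted SOFA under the
#' optimum and the matched patient's observed SOFA. Factual arm: match each
#' patient to the most similar patient under the same factual treatment and
#' compare observed against observed -- a patient-variability baseline.
#'
#' @inheritParams side_effect_contrast
#' @param decisions A [select_optimal()] record at the first treatment time.
#' @param onset_window_h Only patients first treated within this window of
#'   onset enter (hours).
#' @param horizon Hours of trajectory compared.
#' @param conf_level Confidence level of the normal-approximation interval
#'   over matched pairs.
#' @return A tibble of class `abx_matching`: `time_h`, `arm`,
#'   `mean_abs_diff`, `lo`, `hi`, `n_pairs`.
#' @export
counterfactual_matching <- function(model, tens, cohort, decisions,
                                    onset_window_h = 3, horizon = 48,
                                    conf_level = 0.95) {
  ids <- tens$ids
  first_trt <- cohort$treatments |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(first_h = min(.data$start_h), .groups = "drop")
  eligible <- first_trt$patient_id[first_trt$first_h <= onset_window_h]
  eligible <- intersect(ids, eligible)
  fo <- factual_option_at(cohort, 0)
  fopt <- stats::setNames(fo$option, fo$patient_id)
  sel <- decisions |>
    dplyr::filter(.data$selected) |>
    dplyr::select("patient_id", opt = "option")
  sopt <- stats::setNames(sel$opt, sel$patient_id)

  X <- cbind(tens$z0, tens$d)   # normalized covariates at onset
  rownames(X) <- ids
  # observed SOFA trajectory, carried forward between measurements so that a
  # matched pair contributes at every hour
  stt <- tens$prep$stats
  sofa_obs <- tens$z_filled[, , match("sofa", tens$outcomes)] *
    stt$sd[stt$variable == "sofa"] + stt$mean[stt$variable == "sofa"]

  nearest <- function(id, pool) {
    pool <- setdiff(pool, id)
    if (!length(pool)) return(NA_character_)
    dd <- sqrt(rowSums((X[pool, , drop = FALSE] -
                          matrix(X[id, ], length(pool), ncol(X), byrow = TRUE))^2))
    pool[order(dd, pool)][1L]    # ties broken by patient id
  }

  hrs <- seq_len(horizon)
  pairs_cf <- list(); pairs_f <- list()
  for (id in eligible) {
    if (is.na(fopt[id] %||% NA) || is.na(sopt[id] %||% NA)) next
    # factual arm
    mf <- nearest(id, eligible[fopt[eligible] == fopt[id] & !is.na(fopt[eligible])])
    if (!is.na(mf)) {
      d_f <- abs(sofa_obs[id, hrs + 1L] - sofa_obs[mf, hrs + 1L])
      pairs_f[[id]] <- d_f
    }
    # counterfactual arm
    if (fopt[id] != sopt[id]) {
      mc <- nearest(id, eligible[fopt[eligible] == sopt[id] & !is.na(fopt[eligible])])
      if (!is.na(mc)) {
        opt_members <- strsplit(sopt[id], " \\+ ")[[1L]]
        pred <- forecast_under_option(model, tens, opt_members, t = 0,
                                      horizon = horizon, patients = id)
        pred_sofa <- pred$yhat[pred$outcome == "sofa"][hrs]
        pairs_cf[[id]] <- abs(pred_sofa - sofa_obs[mc, hrs + 1L])
      }
    }
  }
  if (!length(pairs_cf) && !length(pairs_f)) {
    stop("No eligible matched pairs.", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  summarize_arm <- function(lst, arm) {
    if (!length(lst)) return(NULL)
    m <- do.call(rbind, lst)
    purrr::map_dfr(seq_len(ncol(m)), function(j) {
      x <- m[, j][!is.na(m[, j])]
      tibble::tibble(time_h = hrs[j], arm = arm,
                     mean_abs_diff = mean(x),
                     lo = mean(x) - z * stats::sd(x) / sqrt(length(x)),
                     hi = mean(x) + z * stats::sd(x) / sqrt(length(x)),
                     n_pairs = length(x))
    })
  }
  out <- dplyr::bind_rows(summarize_arm(pairs_cf, "counterfactual"),
                          summarize_arm(pairs_f, "factual"))
  class(out) <- c("abx_matching", class(out))
  out
}

#' Average treatment improvement of the selected optimum over the factual
#'
#' Per patient, the difference of the forecast SOFA trajectory under the
#' selected optimal option and under the factual option, from the first
#' treatment time over the initial 48 h phase, averaged over patients with a
#' normal-approximation confidence band; the area under the mean curve
#' (trapezoid rule) summarizes the treatment effect integrated over time.
#' In unconstrained mode the improvement at the selection horizon is
#' non-positive by construction of the minimizer.
#'
#' @inheritParams counterfactual_matching
#' @param rules A [contra_rules()].
#' @param modes Constraint modes to report.
#' @param horizon Selection and forecast horizon (48 h).
#' @return A list of class `abx_improvement`: `curve` (tibble `mode`,
#'   `time_h`, `mean_delta`, `lo`, `hi`) and `area` (named numeric,
#'   SOFA-hours).
#' @export
average_treatment_improvement <- function(model, tens, cohort,
                                          rules = contra_rules(),
                                          modes = c("constrained", "unconstrained"),
                                          horizon = 48, conf_level = 0.95) {
  opts <- treatment_options()
  labels <- vapply(opts, option_label, "")
  fc <- forecast_options_core(model, tens, 0, horizon, opts)
  sofa_idx <- match("sofa", tens$outcomes)
  fo <- factual_option_at(cohort, 0)
  fidx <- match(fo$option[match(tens$ids, fo$patient_id)], labels)
  keep <- !is.na(fidx)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  curve <- list(); area <- c()
  for (mode in modes) {
    dec <- select_optimal(model, tens, cohort, 0, horizon, rules, mode)
    sel <- dec |> dplyr::filter(.data$selected)
    sidx <- match(sel$option[match(tens$ids, sel$patient_id)], labels)
    delta <- matrix(NA_real_, length(tens$ids), horizon)
    for (i in which(keep & !is.na(sidx))) {
      delta[i, ] <- fc$preds[[sidx[i]]][i, , sofa_idx] - fc$preds[[fidx[i]]][i, , sofa_idx]
    }
    ok <- stats::complete.cases(delta)
    dm <- colMeans(delta[ok, , drop = FALSE])
    dse <- apply(delta[ok, , drop = FALSE], 2L, stats::sd) / sqrt(sum(ok))
    curve[[mode]] <- tibble::tibble(mode = mode, time_h = fc$hours,
                                    mean_delta = dm, lo = dm - z * dse,
                                    hi = dm + z * dse, n = sum(ok))
    area[mode] <- sum(diff(fc$hours) * (utils::head(dm, -1) + utils::tail(dm, -1)) / 2)
  }
  structure(list(curve = dplyr::bind_rows(curve), area = area),
            class = "abx_improvement")
}

#' Treatment predictability of the frozen latent state (balancing probe)
#'
#' Fits a logistic probe on the training-split latent states to predict the
#' concurrent administration of one antibiotic, and reports the held-out
#' area under the ROC curve (rank statistic). A well-balanced latent
#' representation is less predictive of treatment, so the AUC decreases with
#' the balancing weight.
#'
#' @param model A trained [tecde_model()].
#' @param tens_train,tens_eval Tensors of the probe-fitting and held-out
#'   splits.
#' @param antibiotic Treatment channel to probe.
#' @param from_h First grid hour whose latent enters the probe.
#' @return The held-out AUC (scalar in \[0, 1\]).
#' @export
latent_treatment_auc <- function(model, tens_train, tens_eval,
                                 antibiotic = "Vancomycin", from_h = 2L) {
  m <- match(antibiotic, antibiotics())
  stopifnot(!is.na(m))
  collect <- function(tens) {
    Tn <- tens$horizon_h
    enc <- encode_core(NULL, model, model$params, tens, Tn)
    hrs <- seq(from_h, Tn)
    X <- do.call(rbind, enc$xhat[hrs])
    y <- as.numeric(vapply(hrs, function(j) tens$a[, j + 1L, m], numeric(length(tens$ids))))
    list(X = X, y = y)
  }
  tr <- collect(tens_train)
  ev <- collect(tens_eval)
  df_tr <- data.frame(y = tr$y, tr$X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr, family = stats::binomial()))
  score <- stats::predict(fit, newdata = data.frame(ev$X), type = "link")
  y <- ev$y
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("Degenerate probe target.", call. = FALSE)
  w <- suppressWarnings(stats::wilcox.test(score[y == 1], score[y == 0]))$statistic
  as.numeric(w) / (n1 * n0)
}
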