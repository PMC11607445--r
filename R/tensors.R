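#' Fit the preprocessing pipeline on a training cohort
#'
#' Runs the coverage filter and the binned Spearman screen, fits the
#' per-variable normalization statistics (time-dependent variables and
#' numeric statics) on the given (training) split, and returns a frozen
#' preprocessing specification that [prepare_tensors()] applies unchanged to
#' any split.
#'
#' @param cohort Cohort list (`observations`, `treatments`, `micro`,
#'   `statics`).
#' @param coverage_min,spearman_min,bin_width_h Selection thresholds, see
#'   [filter_by_coverage()] and [select_by_spearman()].
#' @param outcomes Outcome variables (always retained).
#' @param norm_scope `"train"` (default) fits normalization on this cohort
#'   only and re-applies it elsewhere; the alternative label `"pooled"` is
#'   purely descriptive -- pass the pooled cohort here to reproduce pooled
#'   statistics.
#' @return An object of class `abx_prep` with the retained `variables`, the
#'   normalization tables and the selection `report`.
#' @export
fit_preprocess <- function(cohort, coverage_min = 0.5, spearman_min = 0.3,
                           bin_width_h = 12,
                           outcomes = c("sofa", "creatinine", "bilirubin_total",
                                        "alanine_transaminase"),
                           norm_scope = c("train", "pooled")) {
  norm_scope <- match.arg(norm_scope)
  obs <- cohort$observations
  cov_rep <- filter_by_coverage(obs, coverage_min,
                                patient_ids = cohort$statics$patient_id)
  covered <- cov_rep$variable[cov_rep$kept]
  sp_rep <- select_by_spearman(dplyr::filter(obs, .data$variable %in% covered),
                               spearman_min, bin_width_h, always_keep = outcomes)
  variables <- sp_rep$variable[sp_rep$selected]
  variables <- c(outcomes, sort(setdiff(variables, outcomes)))
  stats_tbl <- fit_normalization(dplyr::filter(obs, .data$variable %in% variables))
  st <- cohort$statics
  static_stats <- tibble::tibble(
    variable = c("age", "height", "weight"),
    mean = c(mean(st$age), mean(st$height), mean(st$weight)),
    sd = c(stats::sd(st$age), stats::sd(st$height), stats::sd(st$weight))
  )
  structure(list(variables = variables, outcomes = outcomes,
                 stats = stats_tbl, static_stats = static_stats,
                 report = dplyr::left_join(cov_rep, sp_rep, by = "variable"),
                 norm_scope = norm_scope),
            class = "abx_prep")
}

#' Build model-ready arrays from a cohort
#'
#' Applies a frozen preprocessing specification: restricts to the selected
#' variables, rounds timestamps to the hourly grid, normalizes, builds the
#' observation / cumulative-mask / treatment arrays, KNN-imputes the initial
#' value vector, and precomputes the rectilinear control-path increments that
#' drive the encoder CDE.
#'
#' The control channels are ordered (time, K variable channels, K cumulative
#' mask channels, M treatment channels). Each grid hour contributes two
#' rectilinear segments: a time advance at held values, then a value update
#' at constant time, so the path restricted to `[0, t]` depends only on data
#' with timestamps at most `t`.
#'
#' @param cohort Cohort list.
#' @param prep An [fit_preprocess()] object.
#' @param horizon_h Grid horizon (last hour); defaults to the latest rounded
#'   observation hour in the cohort.
#' @param knn_k Neighbours for the initial-value imputation.
#' @param mask_scale Divisor applied to cumulative-mask channels before they
#'   enter the control path (keeps their increments on the same order as the
#'   normalized variables).
#' @return An object of class `abx_tensors`; a list of arrays plus metadata.
#' @export
prepare_tensors <- function(cohort, prep, horizon_h = NULL, knn_k = 10,
                            mask_scale = 10) {
  obs <- cohort$observations |>
    dplyr::filter(.data$variable %in% prep$variables) |>
    round_to_hours()
  if (is.null(horizon_h)) horizon_h <- max(obs$time_h)
  obs <- dplyr::filter(obs, .data$time_h <= horizon_h)
  obs_n <- apply_normalization(obs, prep$stats)

  ids <- sort(unique(cohort$statics$patient_id))
  n <- length(ids)
  K <- length(prep$variables)
  abx <- antibiotics()
  M <- length(abx)
  Tn <- as.integer(horizon_h)
  vars <- prep$variables

  idx_p <- match(obs_n$patient_id, ids)
  idx_v <- match(obs_n$variable, vars)
  idx_t <- as.integer(obs_n$time_h) + 1L

  z_obs <- array(NA_real_, c(n, Tn + 1L, K), dimnames = list(ids, NULL, vars))
  z_obs[cbind(idx_p, idx_t, idx_v)] <- obs_n$value
  obs01 <- array(0, c(n, Tn + 1L, K), dimnames = list(ids, NULL, vars))
  obs01[cbind(idx_p, idx_t, idx_v)] <- 1
  cum <- obs01
  for (j in 2:(Tn + 1L)) cum[, j, ] <- cum[, j - 1L, ] + obs01[, j, ]

  # treatments: a^m(t) = 1 while ongoing (start inclusive, end exclusive)
  a <- array(0, c(n, Tn + 1L, M), dimnames = list(ids, NULL, abx))
  trt <- cohort$treatments
  if (nrow(trt)) {
    for (r in seq_len(nrow(trt))) {
      i <- match(trt$patient_id[r], ids)
      m <- match(trt$antibiotic[r], abx)
      if (is.na(i) || is.na(m)) next
      h0 <- max(0L, ceiling(trt$start_h[r]))
      h1 <- min(Tn, ceiling(trt$end_h[r]) - 1L)
      if (h1 >= h0) a[i, (h0 + 1L):(h1 + 1L), m] <- 1
    }
  }

  # statics: sex as indicator, numeric statics normalized
  st <- cohort$statics[match(ids, cohort$statics$patient_id), ]
  ss <- prep$static_stats
  d <- cbind(
    sex_male = as.numeric(st$sex == "M"),
    age = (st$age - ss$mean[ss$variable == "age"]) / ss$sd[ss$variable == "age"],
    height = (st$height - ss$mean[ss$variable == "height"]) / ss$sd[ss$variable == "height"],
    weight = (st$weight - ss$mean[ss$variable == "weight"]) / ss$sd[ss$variable == "weight"]
  )
  rownames(d) <- ids

  z0 <- matrix(z_obs[, 1L, ], n, K, dimnames = list(ids, vars))
  z0_imp <- if (anyNA(z0)) knn_impute_initial(z0, k = knn_k) else z0

  z_filled <- z_obs
  z_filled[, 1L, ] <- z0_imp
  for (j in 2:(Tn + 1L)) {
    cur <- matrix(z_filled[, j, ], n, K)
    prev <- matrix(z_filled[, j - 1L, ], n, K)
    cur[is.na(cur)] <- prev[is.na(cur)]
    z_filled[, j, ] <- cur
  }

  C <- 1L + 2L * K + M
  dXv <- vector("list", Tn)
  cumsc <- cum / mask_scale
  for (j in seq_len(Tn)) {
    dXv[[j]] <- cbind(
      0,
      matrix(z_filled[, j + 1L, ] - z_filled[, j, ], n, K),
      matrix(cumsc[, j + 1L, ] - cumsc[, j, ], n, K),
      matrix(a[, j + 1L, ] - a[, j, ], n, M)
    )
  }
  dXt <- cbind(1, matrix(0, n, C - 1L))

  out_idx <- match(prep$outcomes, vars)
  # dense cubes for the compiled training path: slice j corresponds to grid
  # hour j (targets and treatments), matching the one-step-lead states
  R <- length(prep$outcomes)
  y_cube <- array(0, c(n, R, Tn))
  ymask_cube <- array(0, c(n, R, Tn))
  a_cube <- array(0, c(n, M, Tn))
  dXv_cube <- array(0, c(n, C, Tn))
  for (j in seq_len(Tn)) {
    yj <- matrix(z_obs[, j + 1L, out_idx], n, R)
    mj <- matrix(obs01[, j + 1L, out_idx], n, R)
    yj[is.na(yj)] <- 0
    y_cube[, , j] <- yj
    ymask_cube[, , j] <- mj
    a_cube[, , j] <- matrix(a[, j + 1L, ], n, M)
    dXv_cube[, , j] <- dXv[[j]]
  }
  structure(list(
    ids = ids, variables = vars, outcomes = prep$outcomes, out_idx = out_idx,
    horizon_h = Tn, K = K, M = M, C = C, D = ncol(d),
    z_obs = z_obs, obs01 = obs01, cum = cum, a = a, d = d,
    z0 = z0_imp, z_filled = z_filled, dXv = dXv, dXt = dXt,
    y_cube = y_cube, ymask_cube = ymask_cube, a_cube = a_cube,
    dXv_cube = dXv_cube,
    x0in = cbind(z0_imp, matrix(a[, 1L, ], n, M), d),
    prep = prep, mask_scale = mask_scale
  ), class = "abx_tensors")
}

# restrict a tensor object to a subset of patients (by id)
tensors_subset <- function(tens, ids) {
  i <- match(ids, tens$ids)
  stopifnot(!anyNA(i))
  out <- tens
  out$ids <- tens$ids[i]
  for (nm in c("z_obs", "obs01", "cum", "a", "z_filled")) out[[nm]] <- tens[[nm]][i, , , drop = FALSE]
  out$d <- tens$d[i, , drop = FALSE]
  out$z0 <- tens$z0[i, , drop = FALSE]
  out$x0in <- tens$x0in[i, , drop = FALSE]
  out$dXv <- lapply(tens$dXv, function(m) m[i, , drop = FALSE])
  out$dXt <- tens$dXt[i, , drop = FALSE]
  for (nm in c("y_cube", "ymask_cube", "a_cube", "dXv_cube")) {
    out[[nm]] <- tens[[nm]][i, , , drop = FALSE]
  }
  out
}

#' Rectilinear control path for a single patient
#'
#' Builds the piecewise-linear control driving the encoder CDE: the knot
#' sequence alternates a time advance at held channel values with a value
#' update at constant time (time-then-value ordering), so the path on
#' `[0, t]` is bit-identical whether or not data after `t` exist.
#'
#' @param tens An [prepare_tensors()] object.
#' @param patient_id Patient to extract.
#' @return An object of class `control_path` with elements `knots` (matrix,
#'   one row per knot), `eval(s)` and `deriv(s)` (piecewise-linear evaluator
#'   and its piecewise-constant derivative on the knot parameter
#'   `s in [0, 2T]`).
#' @export
build_rectilinear_path <- function(tens, patient_id) {
  i <- match(patient_id, tens$ids)
  if (is.na(i)) stop("Unknown patient.", call. = FALSE)
  if (anyNA(tens$z0[i, ])) stop("Initial values must be imputed first.", call. = FALSE)
  Tn <- tens$horizon_h
  C <- tens$C
  chan <- c("time", tens$variables, paste0("cum_", tens$variables), antibiotics())
  knots <- matrix(NA_real_, 2L * Tn + 1L, C, dimnames = list(NULL, chan))
  row_at <- function(j) c(j - 1L,
                          tens$z_filled[i, j, ],
                          tens$cum[i, j, ] / tens$mask_scale,
                          tens$a[i, j, ])
  knots[1L, ] <- row_at(1L)
  for (j in seq_len(Tn)) {
    held <- knots[2L * j - 1L, ]
    held["time"] <- j
    knots[2L * j, ] <- held          # time advance
    knots[2L * j + 1L, ] <- row_at(j + 1L)  # value update at constant time
  }
  s_grid <- 0:(2L * Tn)
  evalf <- function(s) {
    stopifnot(s >= 0, s <= 2 * Tn)
    lo <- floor(s); hi <- ceiling(s)
    if (lo == hi) return(knots[lo + 1L, ])
    (hi - s) * knots[lo + 1L, ] + (s - lo) * knots[hi + 1L, ]
  }
  derivf <- function(s) {
    stopifnot(s >= 0, s < 2 * Tn)
    lo <- floor(s)
    knots[lo + 2L, ] - knots[lo + 1L, ]
  }
  structure(list(knots = knots, s_grid = s_grid, eval = evalf, deriv = derivf,
                 horizon_h = Tn, channels = chan),
            class = "control_path")
}
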