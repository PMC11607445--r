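#' Variable coverage filter
#'
#' Keeps a variable iff the fraction of patients with at least one
#' observation is at least `coverage_min` (a variable measured in exactly the
#' threshold fraction is kept; only variables measured in *less* than the
#' threshold are excluded).
#'
#' @param observations Long observation tibble (`patient_id`, `time_h`,
#'   `variable`, `value`).
#' @param coverage_min Minimum fraction of patients covered (default 0.5).
#' @param patient_ids Optional full patient roster; defaults to the patients
#'   appearing in `observations`.
#' @return Tibble with columns `variable`, `coverage`, `kept`.
#' @export
filter_by_coverage <- function(observations, coverage_min = 0.5, patient_ids = NULL) {
  stopifnot(nrow(observations) > 0)
  if (is.null(patient_ids)) patient_ids <- unique(observations$patient_id)
  n <- length(patient_ids)
  observations |>
    dplyr::filter(.data$patient_id %in% patient_ids) |>
    dplyr::distinct(.data$variable, .data$patient_id) |>
    dplyr::count(.data$variable, name = "n_patients") |>
    dplyr::mutate(coverage = .data$n_patients / n, kept = .data$coverage >= coverage_min) |>
    dplyr::select("variable", "coverage", "kept")
}

#' Spearman screening against the SOFA score in time bins
#'
#' Divides the record into `bin_width_h` intervals; within each bin, pools
#' per-patient bin aggregates (within-bin means) of the candidate variable
#' and of SOFA, and computes the Spearman rank correlation across patients.
#' A variable is selected iff its maximum absolute correlation over bins
#' exceeds `spearman_min`; bins with fewer than 3 complete pairs are skipped.
#' SOFA itself and the outcome labs are always retained.
#'
#' @inheritParams filter_by_coverage
#' @param spearman_min Selection threshold on `max |rho|` (default 0.3;
#'   strictly-greater rule).
#' @param bin_width_h Bin width in hours (default 12).
#' @param sofa_var Name of the SOFA variable.
#' @param always_keep Variables retained regardless of the screen.
#' @param aggregate `"binned_mean"` (default) pools per-patient within-bin
#'   means; `"raw"` pools raw observations matched to the nearest SOFA value
#'   in the same bin.
#' @return Tibble with columns `variable`, `max_abs_rho`, `selected`.
#' @export
select_by_spearman <- function(observations, spearman_min = 0.3, bin_width_h = 12,
                               sofa_var = "sofa",
                               always_keep = c("sofa", "creatinine",
                                               "bilirubin_total", "alanine_transaminase"),
                               aggregate = c("binned_mean", "raw")) {
  aggregate <- match.arg(aggregate)
  stopifnot(sofa_var %in% observations$variable)
  binned <- observations |>
    dplyr::mutate(bin = floor(.data$time_h / bin_width_h)) |>
    dplyr::group_by(.data$patient_id, .data$bin, .data$variable) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  sofa <- binned |>
    dplyr::filter(.data$variable == sofa_var) |>
    dplyr::select("patient_id", "bin", sofa = "value")
  rho <- binned |>
    dplyr::filter(.data$variable != sofa_var) |>
    dplyr::inner_join(sofa, by = c("patient_id", "bin")) |>
    dplyr::group_by(.data$variable, .data$bin) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(
      rho = suppressWarnings(stats::cor(.data$value, .data$sofa, method = "spearman")),
      .groups = "drop"
    ) |>
    dplyr::filter(is.finite(.data$rho)) |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(max_abs_rho = max(abs(.data$rho)), .groups = "drop")
  all_vars <- setdiff(unique(observations$variable), sofa_var)
  out <- tibble::tibble(variable = all_vars) |>
    dplyr::left_join(rho, by = "variable") |>
    dplyr::mutate(
      max_abs_rho = dplyr::coalesce(.data$max_abs_rho, 0),
      selected = .data$max_abs_rho > spearman_min | .data$variable %in% always_keep
    )
  dplyr::bind_rows(
    tibble::tibble(variable = sofa_var, max_abs_rho = 1, selected = TRUE), out
  )
}

#' Fit and apply per-variable normalization
#'
#' `fit_normalization()` computes per-variable mean and standard deviation
#' pooled over all patients and times of the fitting split;
#' `apply_normalization()` applies the affine map `(value - mean) / sd`
#' unchanged to any split. Fitting on the training split only (the default
#' usage) keeps validation/test statistics out of the model.
#'
#' @inheritParams filter_by_coverage
#' @param variables Variables to fit; defaults to all present.
#' @return `fit_normalization()`: tibble `variable`, `mean`, `sd`.
#' @export
fit_normalization <- function(observations, variables = NULL) {
  if (is.null(variables)) variables <- unique(observations$variable)
  st <- observations |>
    dplyr::filter(.data$variable %in% variables) |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop")
  bad <- st$variable[is.na(st$sd) | st$sd == 0]
  if (length(bad)) {
    stop("Degenerate variable(s) with zero variance on the fitting split: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  st
}

#' @rdname fit_normalization
#' @param stats_tbl Output of `fit_normalization()`.
#' @return `apply_normalization()`: the observation tibble with `value`
#'   replaced by its z-score.
#' @export
apply_normalization <- function(observations, stats_tbl) {
  observations |>
    dplyr::inner_join(stats_tbl, by = "variable") |>
    dplyr::mutate(value = (.data$value - .data$mean) / .data$sd) |>
    dplyr::select(-"mean", -"sd")
}

#' K-nearest-neighbour imputation of initial-value vectors
#'
#' Completes missing entries of each row by the mean of that entry over the
#' `k` nearest rows, with distances computed on commonly observed entries
#' (NaN-Euclidean: squared differences over shared entries, rescaled by the
#' fraction of shared entries). Inputs are expected on the normalized scale.
#'
#' @param x Numeric matrix (rows = patients, columns = variables) with `NA`
#'   for missing entries.
#' @param k Number of neighbours.
#' @return The completed matrix.
#' @export
knn_impute_initial <- function(x, k = 10) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (any(rowSums(!is.na(x)) == 0)) {
    stop("Cannot impute a patient with all initial values missing.", call. = FALSE)
  }
  p <- ncol(x)
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  # pairwise NaN-Euclidean distances
  sq <- x0^2
  cross <- tcrossprod(x0)
  sum_sq_i <- sq %*% t(obs)          # sum over shared dims of x_i^2
  sum_sq_j <- obs %*% t(sq)
  d2 <- sum_sq_i + sum_sq_j - 2 * cross
  shared <- tcrossprod(obs * 1)
  d2 <- ifelse(shared > 0, d2 * p / pmax(shared, 1), Inf)
  diag(d2) <- Inf
  out <- x
  for (i in seq_len(nrow(x))) {
    miss <- which(!obs[i, ])
    if (!length(miss)) next
    for (j in miss) {
      donors <- which(obs[, j] & is.finite(d2[i, ]))
      if (!length(donors)) next
      kk <- min(k, length(donors))
      nearest <- donors[order(d2[i, donors])][seq_len(kk)]
      out[i, j] <- mean(x[nearest, j])
    }
  }
  if (anyNA(out)) stop("Imputation failed: no donors for some entries.", call. = FALSE)
  out
}

#' Round observation times to the hourly grid
#'
#' Timestamps are rounded to the nearest hour; when several observations of
#' one variable collide in the same hour, the observation with the latest raw
#' timestamp wins (`collision = "latest"`, the causality-preserving default)
#' or they are averaged (`collision = "mean"`).
#'
#' @inheritParams filter_by_coverage
#' @param collision Collision rule within a (patient, variable, hour) cell.
#' @return The observation tibble with integer `time_h`.
#' @export
round_to_hours <- function(observations, collision = c("latest", "mean")) {
  collision <- match.arg(collision)
  obs <- dplyr::mutate(observations, hour = round(.data$time_h))
  if (collision == "latest") {
    obs <- obs |>
      dplyr::group_by(.data$patient_id, .data$variable, .data$hour) |>
      dplyr::slice_max(.data$time_h, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  } else {
    obs <- obs |>
      dplyr::group_by(.data$patient_id, .data$variable, .data$hour) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  obs |>
    dplyr::transmute(patient_id = .data$patient_id, time_h = as.numeric(.data$hour),
                     variable = .data$variable, value = .data$value) |>
    dplyr::arrange(.data$patient_id, .data$time_h, .data$variable)
}

#' Cumulative observation-count masks
#'
#' One mask channel per variable holding the cumulative number of
#' observations of that variable up to and including each grid hour
#' (non-decreasing; all zero for a never-observed variable).
#'
#' @param observations Hour-gridded observation tibble for one or more
#'   patients.
#' @param horizon_h Last grid hour.
#' @param variables Variables to produce masks for.
#' @return Tibble `patient_id`, `time_h`, `variable`, `cum_obs`.
#' @export
cumulative_masks <- function(observations, horizon_h, variables = NULL) {
  if (is.null(variables)) variables <- sort(unique(observations$variable))
  grid <- tidyr::crossing(patient_id = unique(observations$patient_id),
                          variable = variables, time_h = 0:horizon_h)
  counts <- observations |>
    dplyr::filter(.data$variable %in% variables) |>
    dplyr::count(.data$patient_id, .data$variable, .data$time_h)
  grid |>
    dplyr::left_join(counts, by = c("patient_id", "variable", "time_h")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::arrange(.data$patient_id, .data$variable, .data$time_h) |>
    dplyr::group_by(.data$patient_id, .data$variable) |>
    dplyr::mutate(cum_obs = cumsum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "time_h", "variable", "cum_obs")
}
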