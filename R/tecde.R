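#' Construct a treatment-effect CDE model
#'
#' The encoder is a neural controlled differential equation driven by the
#' rectilinear control path over (time, variables, cumulative masks,
#' treatments); the decoder is an uncontrolled neural ODE initialized from a
#' transformation of the encoder's latent disease state; two heads map the
#' latent state to outcome forecasts and treatment probabilities. All maps
#' are two-hidden-layer perceptrons with tanh activations. Integration uses
#' fixed-step classical Runge--Kutta on the hourly knot grid (each rectilinear
#' segment is an autonomous ODE because the control derivative is piecewise
#' constant), which makes every forward pass exactly reproducible.
#'
#' @param n_vars Number of selected time-dependent variables (K).
#' @param n_outcomes Number of outcome channels (R); the first `n_outcomes`
#'   variables are the outcomes.
#' @param n_treatments Number of binary treatment channels (M).
#' @param n_static Number of static covariates (D).
#' @param latent_dim Latent state dimension (P).
#' @param hidden Hidden width of the vector fields and initial maps.
#' @param head_hidden Hidden width of the outcome/treatment heads.
#' @param substeps Runge--Kutta substeps per rectilinear segment.
#' @param eps_h Encoder forecast horizon (hours; the one-step lead).
#' @param treatment_link `"logistic"` (independent per antibiotic, the
#'   default: antibiotic pairs co-occur) or `"softmax"`.
#' @param seed Seed for parameter initialization.
#' @return An object of class `tecde_model`.
#' @export
tecde_model <- function(n_vars, n_outcomes = 4L, n_treatments = 3L, n_static = 4L,
                        latent_dim = 6L, hidden = 24L, head_hidden = 16L,
                        substeps = 2L, eps_h = 1, treatment_link = c("logistic", "softmax"),
                        seed = 1L) {
  treatment_link <- match.arg(treatment_link)
  K <- as.integer(n_vars); M <- as.integer(n_treatments); D <- as.integer(n_static)
  R <- as.integer(n_outcomes); P <- as.integer(latent_dim)
  C <- 1L + 2L * K + M
  set.seed(seed)
  params <- list(
    g_eta = mlp_params(K + M + D, hidden, P),
    F = mlp_params(P, hidden, P * C, scale_out = 0.1),
    g_phi = mlp_params(P + D, hidden, P),
    f = mlp_params(P, hidden, P, scale_out = 0.1),
    h_alpha = mlp_params(P, head_hidden, R),
    h_beta = mlp_params(P, head_hidden, M),
    h_alpha_dec = mlp_params(P, head_hidden, R)
  )
  structure(list(
    params = params,
    dims = list(K = K, M = M, D = D, R = R, P = P, C = C,
                hidden = hidden, head_hidden = head_hidden),
    config = list(substeps = as.integer(substeps), eps_h = eps_h,
                  treatment_link = treatment_link, seed = as.integer(seed)),
    prep = NULL, history = NULL
  ), class = "tecde_model")
}

mlp_params <- function(d_in, h, d_out, scale_out = 1) {
  init <- function(a, b, s = 1) matrix(stats::rnorm(a * b, sd = s / sqrt(a)), a, b)
  list(W1 = init(d_in, h), b1 = numeric(h),
       W2 = init(h, h), b2 = numeric(h),
       W3 = init(h, d_out, scale_out), b3 = numeric(d_out))
}

# forward through a two-hidden-layer tanh MLP (fused tape op)
mlp_fwd <- function(tape, x, pn) ag_mlp(tape, x, pn)

# one rectilinear segment of the encoder CDE: dx/ds = F(x) dX, s in [0,1],
# dX the constant n x C control increment of the segment; classical RK4
cde_segment <- function(tape, x, dX, Fp, P, C, substeps) {
  h <- 1 / substeps
  Fc <- function(z) ag_mlp(tape, z, Fp, dX, P, C)
  for (s in seq_len(substeps)) {
    k1 <- Fc(x)
    k2 <- Fc(ag_lincomb(tape, c(1, h / 2), list(x, k1)))
    k3 <- Fc(ag_lincomb(tape, c(1, h / 2), list(x, k2)))
    k4 <- Fc(ag_lincomb(tape, c(1, h), list(x, k3)))
    x <- ag_lincomb(tape, c(1, h / 6, h / 3, h / 3, h / 6), list(x, k1, k2, k3, k4))
  }
  x
}

# one hour of the autonomous decoder ODE dx/ds = f(x)
ode_segment <- function(tape, x, fp, substeps) {
  h <- 1 / substeps
  for (s in seq_len(substeps)) {
    k1 <- mlp_fwd(tape, x, fp)
    k2 <- mlp_fwd(tape, ag_lincomb(tape, c(1, h / 2), list(x, k1)), fp)
    k3 <- mlp_fwd(tape, ag_lincomb(tape, c(1, h / 2), list(x, k2)), fp)
    k4 <- mlp_fwd(tape, ag_lincomb(tape, c(1, h), list(x, k3)), fp)
    x <- ag_lincomb(tape, c(1, h / 6, h / 3, h / 3, h / 6), list(x, k1, k2, k3, k4))
  }
  x
}

# run the encoder over a tensor batch up to hour `t_end`; returns the initial
# state, the pre-update states xhat[[j]] (time advanced to hour j, data <= j-1;
# the one-step-lead latent) and the post-update states xpost[[j]] (data <= j)
encode_core <- function(tape, model, pn, tens, t_end) {
  dm <- model$dims
  x <- mlp_fwd(tape, tens$x0in, pn$g_eta)
  xhat <- vector("list", t_end)
  xpost <- vector("list", t_end)
  x0 <- x
  ss <- model$config$substeps
  for (j in seq_len(t_end)) {
    xh <- cde_segment(tape, x, tens$dXt, pn$F, dm$P, dm$C, ss)
    x <- cde_segment(tape, xh, tens$dXv[[j]], pn$F, dm$P, dm$C, ss)
    xhat[[j]] <- xh
    xpost[[j]] <- x
  }
  list(x0 = x0, xhat = xhat, xpost = xpost)
}

# full parameter sets of the decoder ensemble (the primary parameters plus
# any re-fitted decoder groups); forecasts average over these members
decoder_members <- function(model) {
  members <- list(model$params)
  for (extra in model$decoder_ensemble %||% list()) {
    pm <- model$params
    pm[c("g_phi", "f", "h_alpha_dec")] <- extra
    members[[length(members) + 1L]] <- pm
  }
  members
}

# decode from an anchor latent state for `horizon` hours; returns the list of
# states (element 1 = the transformed initial state at the anchor hour)
decode_core <- function(tape, model, pn, x_anchor, d, horizon) {
  x <- mlp_fwd(tape, ag_cbind(tape, x_anchor, d), pn$g_phi)
  states <- vector("list", horizon + 1L)
  states[[1L]] <- x
  ss <- model$config$substeps
  for (j in seq_len(horizon)) {
    x <- ode_segment(tape, x, pn$f, ss)
    states[[j + 1L]] <- x
  }
  states
}

head_probs <- function(tape, model, pn, x) {
  logits <- mlp_fwd(tape, x, pn$h_beta)
  if (model$config$treatment_link == "logistic") {
    ag_sigmoid(tape, logits)
  } else {
    lv <- vof(logits)
    e <- exp(lv - apply(lv, 1L, max))
    p <- e / rowSums(e)
    if (!ag_is(logits)) p else ag_new(tape, p, list(logits), function(g) {
      list(p * (g - rowSums(g * p)))
    })
  }
}

#' Encode a patient record into a latent trajectory
#'
#' Assimilates all observations and treatments up to `t_end` through the
#' encoder CDE. The returned one-step-lead states at hour `t` depend only on
#' data with timestamps strictly before `t` (online updateability).
#'
#' @param model A [tecde_model()].
#' @param tens An [prepare_tensors()] object.
#' @param t_end Last hour to assimilate (defaults to the grid horizon).
#' @param patients Optional subset of patient ids.
#' @return A tibble with columns `patient_id`, `time_h`, `provenance`
#'   (`"encoder"`), `lead` (`TRUE` for the one-step-lead state at `time_h`,
#'   `FALSE` for the assimilated state), and `x1 ... xP`.
#' @export
encode <- function(model, tens, t_end = NULL, patients = NULL) {
  if (!is.null(patients)) tens <- tensors_subset(tens, patients)
  if (is.null(t_end)) t_end <- tens$horizon_h
  stopifnot(t_end >= 1, t_end <= tens$horizon_h)
  enc <- encode_core(NULL, model, model$params, tens, t_end)
  P <- model$dims$P
  xc <- function(m) stats::setNames(as.data.frame(m), paste0("x", seq_len(P)))
  rows <- list(tibble::tibble(patient_id = tens$ids, time_h = 0, provenance = "encoder",
                              lead = FALSE, !!!xc(enc$x0)))
  for (j in seq_len(t_end)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(patient_id = tens$ids, time_h = j,
                                                provenance = "encoder", lead = TRUE,
                                                !!!xc(enc$xhat[[j]]))
    rows[[length(rows) + 1L]] <- tibble::tibble(patient_id = tens$ids, time_h = j,
                                                provenance = "encoder", lead = FALSE,
                                                !!!xc(enc$xpost[[j]]))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$patient_id, .data$time_h, .data$lead)
}

#' Decode a long-term latent trajectory from an anchor state
#'
#' Evolves the uncontrolled decoder ODE from a transformation of the anchor
#' latent state; no future data or treatments enter.
#'
#' @param model A [tecde_model()].
#' @param x_anchor Numeric matrix (patients x P) or vector of length P.
#' @param d Static covariate matrix (patients x D) aligned with `x_anchor`.
#' @param t_anchor Anchor time (hours), used to label the output grid.
#' @param t_horizon End of the forecast (hours, `> t_anchor`).
#' @param patient_id Optional ids for labeling.
#' @return A tibble like [encode()] with `provenance = "decoder"` on the
#'   hourly grid `t_anchor ... t_horizon`.
#' @export
decode <- function(model, x_anchor, d, t_anchor, t_horizon, patient_id = NULL) {
  stopifnot(t_horizon > t_anchor)
  if (is.null(dim(x_anchor))) x_anchor <- matrix(x_anchor, 1L)
  if (is.null(dim(d))) d <- matrix(d, 1L)
  if (is.null(patient_id)) patient_id <- rownames(x_anchor) %||% as.character(seq_len(nrow(x_anchor)))
  H <- as.integer(round(t_horizon - t_anchor))
  states <- decode_core(NULL, model, model$params, x_anchor, d, H)
  P <- model$dims$P
  xc <- function(m) stats::setNames(as.data.frame(m), paste0("x", seq_len(P)))
  purrr::map_dfr(seq_along(states), function(j) {
    if (any(!is.finite(states[[j]]))) stop("Decoder integration diverged (non-finite state).", call. = FALSE)
    tibble::tibble(patient_id = patient_id, time_h = t_anchor + j - 1L,
                   provenance = "decoder", lead = FALSE, !!!xc(states[[j]]))
  })
}

#' Apply the outcome and treatment heads to a latent trajectory
#'
#' @param model A [tecde_model()].
#' @param trajectory A tibble from [encode()] or [decode()].
#' @param head Outcome head to use: the encoder head (`"encoder"`) or the
#'   decoder variant (`"decoder"`).
#' @return The trajectory tibble with outcome forecast columns (normalized
#'   units, named after the outcomes when the model carries preprocessing
#'   metadata, else `yhat1..R`) and treatment probability columns `p_*`.
#' @export
apply_heads <- function(model, trajectory, head = c("encoder", "decoder")) {
  head <- match.arg(head)
  stopifnot(nrow(trajectory) > 0)
  P <- model$dims$P
  x <- as.matrix(trajectory[paste0("x", seq_len(P))])
  hp <- if (head == "encoder") model$params$h_alpha else model$params$h_alpha_dec
  yhat <- mlp_fwd(NULL, x, hp)
  p <- head_probs(NULL, model, model$params, x)
  ynames <- if (!is.null(model$prep)) model$prep$outcomes else paste0("yhat", seq_len(model$dims$R))
  colnames(yhat) <- paste0("yhat_", ynames)
  colnames(p) <- paste0("p_", abbreviate(gsub("[^A-Za-z]", "", antibiotics()), 8))
  dplyr::bind_cols(trajectory, tibble::as_tibble(yhat), tibble::as_tibble(p))
}

#' Rolling one-hour-ahead outcome forecasts
#'
#' For every grid hour `t >= 1`, the encoder assimilates all data up to
#' `t - 1`, advances one hour, and the outcome head predicts the outcomes at
#' `t`; concatenation over `t` yields the one-hour forecast track.
#'
#' @inheritParams encode
#' @param denormalize Return forecasts in physical units (requires the model
#'   to carry preprocessing metadata from training).
#' @return Tibble `patient_id`, `time_h`, `outcome`, `yhat`.
#' @export
rolling_one_hour_forecast <- function(model, tens, t_end = NULL, patients = NULL,
                                      denormalize = TRUE) {
  if (!is.null(patients)) tens <- tensors_subset(tens, patients)
  if (is.null(t_end)) t_end <- tens$horizon_h
  enc <- encode_core(NULL, model, model$params, tens, t_end)
  out <- vector("list", t_end)
  for (j in seq_len(t_end)) {
    yh <- mlp_fwd(NULL, enc$xhat[[j]], model$params$h_alpha)
    colnames(yh) <- tens$outcomes
    out[[j]] <- tibble::as_tibble(yh) |>
      dplyr::mutate(patient_id = tens$ids, time_h = j, .before = 1) |>
      tidyr::pivot_longer(dplyr::all_of(tens$outcomes), names_to = "outcome",
                          values_to = "yhat")
  }
  res <- dplyr::bind_rows(out)
  if (denormalize) res <- denormalize_forecasts(res, tens$prep)
  dplyr::arrange(res, .data$patient_id, .data$time_h, .data$outcome)
}

denormalize_forecasts <- function(df, prep, col = "yhat") {
  st <- prep$stats
  df |>
    dplyr::left_join(st, by = c(outcome = "variable")) |>
    dplyr::mutate(!!col := .data[[col]] * .data$sd + .data$mean) |>
    dplyr::select(-"mean", -"sd")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the parameters, model configuration, preprocessing
#' specification (normalization statistics and the selected-variable list)
#' and a format version field in a single archive.
#'
#' @param model A [tecde_model()].
#' @param path File path (conventionally `.rds`).
#' @return `save_tecde()` returns `path` invisibly; `load_tecde()` the model.
#' @export
save_tecde <- function(model, path) {
  stopifnot(inherits(model, "tecde_model"))
  obj <- list(version = 1L, params = model$params, dims = model$dims,
              config = model$config, prep = model$prep,
              history = model$history, train_config = model$train_config,
              decoder_ensemble = model$decoder_ensemble)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_tecde
#' @export
load_tecde <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version)) stop("Not a model checkpoint (missing version field).", call. = FALSE)
  structure(list(params = obj$params, dims = obj$dims, config = obj$config,
                 prep = obj$prep, history = obj$history,
                 train_config = obj$train_config,
                 decoder_ensemble = obj$decoder_ensemble),
            class = "tecde_model")
}
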