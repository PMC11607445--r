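# encoder/decoder neural differential equations: zero fields, causality,
# solver accuracy, heads, rolling forecasts

ns <- asNamespace("abxselect")

zeroed_field <- function(model, group) {
  model$params[[group]]$W3[] <- 0
  model$params[[group]]$b3[] <- 0
  model
}

test_that("a zero encoder vector field freezes the latent state", {
  pipe <- small_pipeline()
  tens <- pipe$tens_test
  m <- zeroed_field(tecde_model(n_vars = tens$K, seed = 5), "F")
  enc <- ns$encode_core(NULL, m, m$params, tens, 20)
  x0 <- ns$mlp_fwd(NULL, tens$x0in, m$params$g_eta)
  expect_equal(enc$xhat[[20]], x0, tolerance = 1e-14)
  expect_equal(enc$xpost[[7]], x0, tolerance = 1e-14)
})

test_that("a zero decoder field yields a constant trajectory from g_phi", {
  pipe <- small_pipeline()
  tens <- pipe$tens_test
  m <- zeroed_field(tecde_model(n_vars = tens$K, seed = 5), "f")
  x_anchor <- matrix(stats::rnorm(length(tens$ids) * m$dims$P), ncol = m$dims$P)
  st <- ns$decode_core(NULL, m, m$params, x_anchor, tens$d, 10)
  init <- ns$mlp_fwd(NULL, cbind(x_anchor, tens$d), m$params$g_phi)
  for (j in seq_along(st)) expect_equal(st[[j]], init, tolerance = 1e-14)
})

test_that("encoding is online-updateable: future data never move past states", {
  pipe <- small_pipeline()
  coh <- cohort_subset(pipe$sim$cohort, pipe$split$test)
  tens <- prepare_tensors(coh, pipe$prep, horizon_h = 96)
  m <- small_model()
  t_cut <- 60L
  coh2 <- coh
  coh2$observations <- dplyr::bind_rows(
    coh$observations,
    tibble::tibble(patient_id = tens$ids, time_h = 80.3,
                   variable = "sofa", value = 19)
  )
  tens2 <- prepare_tensors(coh2, pipe$prep, horizon_h = 96)
  e1 <- ns$encode_core(NULL, m, m$params, tens, t_cut)
  e2 <- ns$encode_core(NULL, m, m$params, tens2, t_cut)
  expect_identical(e1$xhat[[t_cut]], e2$xhat[[t_cut]])
  expect_identical(e1$xpost[[t_cut]], e2$xpost[[t_cut]])
  f1 <- rolling_one_hour_forecast(m, tens, t_end = t_cut)
  f2 <- rolling_one_hour_forecast(m, tens2, t_end = t_cut)
  expect_identical(f1, f2)
})

test_that("the CDE solver matches a dense-grid Euler oracle on toy models", {
  set.seed(91)
  P <- 3L; C <- 6L
  Fp <- ns$mlp_params(P, 8L, P * C)
  x0 <- matrix(stats::rnorm(4 * P), 4, P)
  segs <- list(cbind(1, matrix(0, 4, C - 1)),
               matrix(stats::rnorm(4 * C, sd = 0.4), 4, C))
  euler <- function(x, dX, nst) {
    h <- 1 / nst
    for (s in seq_len(nst)) {
      Fo <- ns$ag_mlp(NULL, x, Fp)
      k <- matrix(0, nrow(x), P)
      for (p in seq_len(P)) k[, p] <- rowSums(Fo[, ((p - 1) * C + 1):(p * C), drop = FALSE] * dX)
      x <- x + h * k
    }
    x
  }
  x_rk <- x0; x_eu <- x0
  for (d in segs) {
    x_rk <- ns$cde_segment(NULL, x_rk, d, Fp, P, C, 2L)
    x_eu <- euler(x_eu, d, 10000L)
  }
  expect_lt(max(abs(x_rk - x_eu)) / max(abs(x_eu)), 1e-3)
})

test_that("the decoder ODE matches dense Euler and the linear-field closed form", {
  set.seed(92)
  P <- 3L
  fp <- ns$mlp_params(P, 8L, P)
  x0 <- matrix(stats::rnorm(4 * P), 4, P)
  euler <- function(x, nst, hours) {
    h <- 1 / nst
    for (s in seq_len(nst * hours)) x <- x + h * ns$ag_mlp(NULL, x, fp)
    x
  }
  x_rk <- x0
  for (t in 1:3) x_rk <- ns$ode_segment(NULL, x_rk, fp, 2L)
  expect_lt(max(abs(x_rk - euler(x0, 10000L, 3L))) / max(abs(x_rk)), 1e-3)

  # epsilon-linearized MLP representing f(x) = -x: closed-form decay
  eps <- 1e-3; H <- 8L
  W1 <- matrix(0, P, H); diag(W1[seq_len(P), seq_len(P)]) <- eps
  W2 <- matrix(0, H, H); diag(W2[seq_len(P), seq_len(P)]) <- eps
  W3 <- matrix(0, H, P); diag(W3[seq_len(P), seq_len(P)]) <- -1 / eps^2
  lin <- list(W1 = W1, b1 = numeric(H), W2 = W2, b2 = numeric(H),
              W3 = W3, b3 = numeric(P))
  xs <- x0
  for (t in 1:5) xs <- ns$ode_segment(NULL, xs, lin, 8L)
  expect_lt(max(abs(xs - x0 * exp(-5))) / max(abs(x0 * exp(-5))), 1e-3)
})

test_that("autonomous decoding has the semigroup (restart) property", {
  set.seed(93)
  P <- 3L
  fp <- ns$mlp_params(P, 8L, P)
  x0 <- matrix(stats::rnorm(2 * P), 2, P)
  x_ab <- x0
  for (t in 1:5) x_ab <- ns$ode_segment(NULL, x_ab, fp, 2L)
  x_bc <- x_ab
  for (t in 1:3) x_bc <- ns$ode_segment(NULL, x_bc, fp, 2L)
  x_ac <- x0
  for (t in 1:8) x_ac <- ns$ode_segment(NULL, x_ac, fp, 2L)
  expect_identical(x_bc, x_ac)
})

test_that("halving the solver step barely changes the outputs", {
  pipe <- small_pipeline()
  tens <- tensors_subset_test <- pipe$tens_test
  m2 <- tecde_model(n_vars = tens$K, substeps = 2L, seed = 5)
  m4 <- tecde_model(n_vars = tens$K, substeps = 4L, seed = 5)
  e2 <- ns$encode_core(NULL, m2, m2$params, tens, 48)
  e4 <- ns$encode_core(NULL, m4, m4$params, tens, 48)
  expect_lt(max(abs(e2$xhat[[48]] - e4$xhat[[48]])), 1e-4)
})

test_that("heads behave: zero treatment head gives 0.5, affine case by hand", {
  pipe <- small_pipeline()
  m <- tecde_model(n_vars = pipe$tens_test$K, seed = 5)
  for (nm in names(m$params$h_beta)) m$params$h_beta[[nm]][] <- 0
  traj <- encode(m, pipe$tens_test, t_end = 3)
  out <- apply_heads(m, traj)
  pcols <- grep("^p_", names(out), value = TRUE)
  expect_equal(length(pcols), 3L)
  for (pc in pcols) expect_true(all(out[[pc]] == 0.5))
  # hand-computed two-hidden-layer head on a 2-state toy
  hp <- ns$mlp_params(2L, 3L, 1L)
  x <- matrix(c(0.3, -0.2), 1, 2)
  want <- tanh(tanh(x %*% hp$W1 + rep(hp$b1, each = 1)) %*% hp$W2 +
                 rep(hp$b2, each = 1)) %*% hp$W3 + hp$b3
  expect_equal(ns$mlp_fwd(NULL, x, hp), want, tolerance = 1e-14)
})

test_that("rolling one-hour forecasts equal a manual encode-and-head loop", {
  pipe <- small_pipeline()
  tens <- pipe$tens_test
  m <- small_model()
  t_end <- 12L
  track <- rolling_one_hour_forecast(m, tens, t_end = t_end, denormalize = FALSE)
  enc <- ns$encode_core(NULL, m, m$params, tens, t_end)
  for (j in c(1L, 5L, 12L)) {
    yh <- ns$mlp_fwd(NULL, enc$xhat[[j]], m$params$h_alpha)
    for (r in seq_along(tens$outcomes)) {
      got <- track$yhat[track$time_h == j & track$outcome == tens$outcomes[r]]
      ord <- order(tens$ids)
      expect_equal(unname(got), unname(yh[ord, r]), tolerance = 1e-12)
    }
  }
})

test_that("model checkpoints round-trip parameters, metadata and ensemble", {
  m <- tecde_model(n_vars = 5, seed = 77)
  m$decoder_ensemble <- list(m$params[c("g_phi", "f", "h_alpha_dec")])
  p <- withr::local_tempfile(fileext = ".rds")
  save_tecde(m, p)
  m2 <- load_tecde(p)
  expect_identical(m2$params, m$params)
  expect_identical(m2$dims, m$dims)
  expect_identical(m2$config, m$config)
  expect_length(m2$decoder_ensemble, 1)
  expect_s3_class(m2, "tecde_model")
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_tecde(bad), "version")
})
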