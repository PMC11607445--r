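# losses, balancing mechanisms, splitting, two-stage training behaviour

ns <- asNamespace("abxselect")

test_that("outcome loss follows its masked-mean definition", {
  y <- array(0, c(1, 3, 2)); yh <- y
  expect_equal(outcome_loss(yh, y), 0)
  y1 <- array(NA_real_, c(1, 2, 1)); y1[1, 2, 1] <- 1
  yh1 <- array(3, c(1, 2, 1))
  expect_equal(outcome_loss(yh1, y1), 4)   # single observed entry, error 2
  expect_error(outcome_loss(yh1, array(NA_real_, c(1, 2, 1))), "no observed")
  set.seed(31)
  y2 <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  yh2 <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  m2 <- array(rbinom(30, 1, 0.6), c(2, 5, 3))
  want <- 0; cnt <- 0
  for (i in 1:2) for (j in 2:5) for (r in 1:3) if (m2[i, j, r] == 1) {
    want <- want + (yh2[i, j, r] - y2[i, j, r])^2; cnt <- cnt + 1
  }
  expect_equal(outcome_loss(yh2, y2, m2, t_start = 2), want / cnt)
})

test_that("treatment loss matches its closed forms and symmetries", {
  a <- array(c(0, 1, 1, 0), c(1, 2, 2))
  p_half <- array(0.5, dim(a))
  expect_equal(treatment_loss(p_half, a), log(2))
  p_match <- a; p_match[] <- pmin(pmax(a, 1e-7), 1 - 1e-7)
  expect_warning(v <- treatment_loss(a, a), "clipped")
  expect_lt(treatment_loss(p_match, a), 1e-5)
  set.seed(32)
  p <- array(runif(12, 0.05, 0.95), c(1, 4, 3))
  aa <- array(rbinom(12, 1, 0.5), c(1, 4, 3))
  perm <- sample(4)
  expect_equal(treatment_loss(p, aa),
               treatment_loss(p[, perm, , drop = FALSE], aa[, perm, , drop = FALSE]))
})

test_that("combined objective reduces to supervised at mu = 0 and to hand arithmetic", {
  expect_identical(combined_loss(0.37, 5, 0), 0.37)
  expect_equal(combined_loss(1, 0.5, 2, "negated_term"), 0)
  expect_error(combined_loss(1, 1, -1), "non-negative")
})

test_that("both balancing mechanisms give identical encoder gradients", {
  pipe <- small_pipeline()
  tens <- ns$tensors_subset(pipe$tens_test, pipe$tens_test$ids[1:5])
  m <- tecde_model(n_vars = tens$K, seed = 13)
  grads_with <- function(mech) {
    tape <- ns$ag_tape()
    pn <- ns$params_as_nodes(tape, m$params, c("g_eta", "F", "h_alpha", "h_beta"))
    ls <- ns$stage1_loss(tape, m, pn, tens, 0.8, mech, 1)
    ns$ag_backward(tape, ls$total)
    g <- ns$grads_of(pn, c("g_eta", "F", "h_alpha", "h_beta"))
    if (mech == "negated_term") g$h_beta <- lapply(g$h_beta, function(x) -x)
    g
  }
  g_rev <- grads_with("gradient_reversal")
  g_neg <- grads_with("negated_term")
  for (grp in c("g_eta", "F")) {
    for (w in names(g_rev[[grp]])) {
      expect_equal(g_rev[[grp]][[w]], g_neg[[grp]][[w]], tolerance = 1e-12)
    }
  }
  # after the head-gradient sign flip the full updates coincide as well
  for (w in names(g_rev$h_beta)) {
    expect_equal(g_rev$h_beta[[w]], g_neg$h_beta[[w]], tolerance = 1e-12)
  }
})

test_that("compiled losses and gradients agree with the reverse-mode tape", {
  pipe <- small_pipeline()
  tens <- ns$tensors_subset(pipe$tens_test, pipe$tens_test$ids[1:6])
  m <- tecde_model(n_vars = tens$K, seed = 17)
  mu <- 0.6
  tape <- ns$ag_tape()
  pn <- ns$params_as_nodes(tape, m$params, c("g_eta", "F", "h_alpha", "h_beta"))
  ls <- ns$stage1_loss(tape, m, pn, tens, mu, "gradient_reversal", 1)
  ns$ag_backward(tape, ls$total)
  gR <- ns$grads_of(pn, c("g_eta", "F", "h_alpha", "h_beta"))
  out <- ns$cpp_stage1(m$params, tens$x0in, tens$dXt, tens$dXv_cube,
                       tens$y_cube, tens$ymask_cube, tens$a_cube,
                       mu, 1L, m$config$substeps, TRUE, integer(0))
  # restricting the balancing hours must match the tape as well
  bh <- c(5L, 20L)
  tape_b <- ns$ag_tape()
  pn_b <- ns$params_as_nodes(tape_b, m$params, c("g_eta", "F", "h_alpha", "h_beta"))
  ls_b <- ns$stage1_loss(tape_b, m, pn_b, tens, mu, "gradient_reversal", 1,
                         balance_hours = bh)
  out_b <- ns$cpp_stage1(m$params, tens$x0in, tens$dXt, tens$dXv_cube,
                         tens$y_cube, tens$ymask_cube, tens$a_cube,
                         mu, 1L, m$config$substeps, FALSE, bh)
  expect_equal(out_b$L_a, ns$as_scalar(ls_b$L_a), tolerance = 1e-10)
  expect_equal(out$L_y, ns$as_scalar(ls$L_y), tolerance = 1e-10)
  expect_equal(out$L_a, ns$as_scalar(ls$L_a), tolerance = 1e-10)
  for (g in names(gR)) for (w in names(gR[[g]])) {
    expect_equal(as.numeric(out$grads[[g]][[w]]), as.numeric(gR[[g]][[w]]),
                 tolerance = 1e-8)
  }
  # stage 2
  enc <- ns$encode_core(NULL, m, m$params, tens, tens$horizon_h)
  anchors <- c(3L, 20L, 50L)
  tape2 <- ns$ag_tape()
  pn2 <- ns$params_as_nodes(tape2, m$params, c("g_phi", "f", "h_alpha_dec"))
  l2 <- ns$stage2_loss(tape2, m, pn2, tens, enc$xhat, anchors, 24)
  ns$ag_backward(tape2, l2)
  g2R <- ns$grads_of(pn2, c("g_phi", "f", "h_alpha_dec"))
  ecpp <- ns$cpp_encode(m$params, tens$x0in, tens$dXt, tens$dXv_cube,
                        tens$horizon_h, m$config$substeps)
  out2 <- ns$cpp_stage2(m$params, ecpp$xhat, tens$d, tens$y_cube,
                        tens$ymask_cube, anchors, 24L, m$config$substeps, TRUE)
  expect_equal(out2$total, ns$as_scalar(l2), tolerance = 1e-10)
  for (g in names(g2R)) for (w in names(g2R[[g]])) {
    expect_equal(as.numeric(out2$grads[[g]][[w]]), as.numeric(g2R[[g]][[w]]),
                 tolerance = 1e-8)
  }
})

test_that("patient-level splits are sized, disjoint and reproducible", {
  ids <- sprintf("P%03d", 1:100)
  sp <- split_cohort(ids, c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(lengths(sp), c(train = 80L, val = 10L, test = 10L))
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(unlist(sp), ids)
  expect_identical(split_cohort(ids, seed = 4), sp)
  expect_error(split_cohort(ids[1:2]), "at least 3")
})

test_that("training reduces the validation outcome loss from initialization", {
  pipe <- small_pipeline()
  m <- tecde_model(n_vars = pipe$tens_train$K, seed = 19)
  init_val <- ns$cpp_stage1(m$params, pipe$tens_val$x0in, pipe$tens_val$dXt,
                            pipe$tens_val$dXv_cube, pipe$tens_val$y_cube,
                            pipe$tens_val$ymask_cube, pipe$tens_val$a_cube,
                            0, 1L, m$config$substeps, FALSE, integer(0))$L_y
  fit <- small_model()
  h <- tidy(fit)
  expect_lt(min(h$val_outcome[h$stage == "encoder"]), init_val)
  expect_true(all(c("encoder", "decoder") %in% h$stage))
})

test_that("early stopping halts after `patience` non-improving epochs", {
  pipe <- small_pipeline()
  tens <- ns$tensors_subset(pipe$tens_train, pipe$tens_train$ids[1:8])
  m <- tecde_model(n_vars = tens$K, seed = 23)
  # zero learning rate: the validation loss can never improve after epoch 1
  fit <- train_two_stage(m, tens, tens,
                         train_config(mu = 0, lr = 0, epochs_stage1 = 10,
                                      epochs_stage2 = 0, patience = 2,
                                      batch_size = 8, seed = 5))
  expect_lte(max(tidy(fit)$epoch), 3)
})

test_that("training is deterministic under a fixed seed", {
  pipe <- small_pipeline()
  tens <- ns$tensors_subset(pipe$tens_train, pipe$tens_train$ids[1:10])
  cfg <- train_config(mu = 0.5, epochs_stage1 = 2, epochs_stage2 = 2,
                      batch_size = 5, seed = 99)
  f1 <- train_two_stage(tecde_model(n_vars = tens$K, seed = 1), tens, tens, cfg)
  f2 <- train_two_stage(tecde_model(n_vars = tens$K, seed = 1), tens, tens, cfg)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$params, f2$params)
})
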