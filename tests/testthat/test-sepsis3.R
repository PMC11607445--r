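# SOFA subscores, rolling-worst aggregation, SOI detection, Sepsis-3 labels

test_that("healthy panels score zero and saturated panels score four", {
  healthy <- tibble::tibble(
    patient_id = "A", time_h = 1,
    variable = c("pf_ratio", "platelets", "bilirubin_total", "map", "gcs", "creatinine"),
    value = c(450, 300, 0.5, 85, 15, 0.8)
  )
  ss <- sofa_subscores(healthy)
  expect_true(all(ss$level == 0L))
  worst <- tibble::tibble(
    patient_id = "A", time_h = 1,
    variable = c("pf_ratio", "platelets", "bilirubin_total", "vasopressor_level",
                 "gcs", "creatinine"),
    value = c(50, 10, 20, 4, 3, 9)
  )
  sw <- sofa_subscores(worst)
  expect_true(all(sw$level == 4L))
  # hypotension alone caps the cardiovascular subscore at 1
  map_only <- tibble::tibble(patient_id = "A", time_h = 1, variable = "map", value = 30)
  expect_equal(sofa_subscores(map_only)$level, 1L)
  expect_error(sofa_subscores(dplyr::mutate(healthy, variable = "lactate")),
               "maps variable")
})

test_that("subscore levels agree with an independent hand-written lookup", {
  # plain if-else chains, structurally unrelated to the package's outer() scan
  oracle <- function(variable, value) {
    switch(variable,
      pf_ratio = if (value < 100) 4 else if (value < 200) 3 else if (value < 300) 2 else if (value < 400) 1 else 0,
      platelets = if (value < 20) 4 else if (value < 50) 3 else if (value < 100) 2 else if (value < 150) 1 else 0,
      bilirubin_total = if (value >= 12) 4 else if (value >= 6) 3 else if (value >= 2) 2 else if (value >= 1.2) 1 else 0,
      map = if (value < 70) 1 else 0,
      vasopressor_level = max(0, min(4, floor(value))),
      gcs = if (value < 6) 4 else if (value < 10) 3 else if (value < 13) 2 else if (value < 15) 1 else 0,
      creatinine = if (value >= 5) 4 else if (value >= 3.5) 3 else if (value >= 2) 2 else if (value >= 1.2) 1 else 0
    )
  }
  panel <- random_sofa_panel(300, seed = 31)
  got <- sofa_subscores(panel)
  joined <- dplyr::inner_join(panel, got, by = c("patient_id", "time_h"))
  expect_gt(nrow(joined), 250)
  for (i in seq_len(nrow(joined))) {
    expect_identical(joined$level[i],
                     as.integer(oracle(joined$variable[i], joined$value[i])))
  }
})

test_that("rolling worst: constants sum, spikes persist for exactly one window", {
  const <- tidyr::crossing(patient_id = "A", time_h = 0:30,
                           subscore = c("liver", "renal")) |>
    dplyr::mutate(level = ifelse(.data$subscore == "liver", 2L, 1L))
  r <- sofa_rolling(const, sofa_config())
  expect_true(all(r$sofa == 3))
  spike <- tibble::tibble(patient_id = "A",
                          time_h = c(0, 10, 11, 12, 40),
                          subscore = "cns", level = c(0L, 0L, 4L, 0L, 0L))
  r2 <- sofa_rolling(spike, sofa_config(), eval_times = 0:40)
  # trailing window (t - 24, t]: the spike at 11 is in scope for t in [11, 35)
  expect_true(all(r2$sofa[r2$time_h %in% 11:34] == 4))
  expect_true(all(r2$sofa[r2$time_h < 11] == 0))
  expect_true(all(r2$sofa[r2$time_h >= 35] == 0))
  allfour <- tidyr::crossing(patient_id = "A", time_h = c(0, 5),
                             subscore = names(default_sofa_tables())) |>
    dplyr::mutate(level = 4L)
  expect_true(all(sofa_rolling(allfour, sofa_config())$sofa == 24))
})

test_that("rolling worst matches a brute-force sliding-window scan with carry-forward", {
  set.seed(41)
  cfg <- sofa_config()
  ss_names <- names(cfg$subscores)
  for (rep in 1:40) {
    n <- sample(3:25, 1)
    log <- tibble::tibble(patient_id = "A",
                          time_h = sort(stats::runif(n, 0, 60)),
                          subscore = sample(ss_names, n, replace = TRUE),
                          level = sample(0:4, n, replace = TRUE))
    et <- sort(stats::runif(6, 0, 60))
    got <- sofa_rolling(log, cfg, eval_times = et)
    want <- vapply(et, function(t) {
      tot <- 0
      for (s in ss_names) {
        d <- log[log$subscore == s, ]
        inw <- d$level[d$time_h > t - 24 & d$time_h <= t]
        if (length(inw)) tot <- tot + max(inw)
        else {
          past <- d[d$time_h <= t, ]
          if (nrow(past)) tot <- tot + past$level[which.max(past$time_h)]
        }
      }
      min(max(tot, 0), 24)
    }, 0)
    expect_equal(got$sofa, want)
  }
})

test_that("SOI windows follow the antibiotic-culture pairing rules", {
  abx <- tibble::tibble(patient_id = "A", time_h = 0)
  expect_equal(detect_soi(abx, tibble::tibble(patient_id = "A", time_h = 24))$soi_time_h, 0)
  expect_equal(detect_soi(tibble::tibble(patient_id = "A", time_h = 72),
                          tibble::tibble(patient_id = "A", time_h = 0))$soi_time_h, 0)
  expect_equal(nrow(detect_soi(abx, tibble::tibble(patient_id = "A", time_h = 25))), 0L)
  expect_equal(nrow(detect_soi(tibble::tibble(patient_id = "A", time_h = 73),
                               tibble::tibble(patient_id = "A", time_h = 0))), 0L)
  # culture before antibiotic within 72 h: SOI at the culture time
  got <- detect_soi(tibble::tibble(patient_id = "A", time_h = 50),
                    tibble::tibble(patient_id = "A", time_h = 10))
  expect_equal(got$soi_time_h, 10)
  expect_equal(nrow(detect_soi(abx[0, ], abx[0, ])), 0L)
})

test_that("Sepsis-3 labeling honours the -48/+24 h window and threshold", {
  soi <- tibble::tibble(patient_id = "A", soi_time_h = 100,
                        antibiotic_time_h = 100, culture_time_h = 101)
  at <- function(t, s) tibble::tibble(patient_id = "A", time_h = t, sofa = s)
  expect_true(label_sepsis_onset(at(52, 2), soi)$septic)    # exactly soi - 48
  expect_true(label_sepsis_onset(at(124, 2), soi)$septic)   # exactly soi + 24
  expect_false(label_sepsis_onset(at(51.9, 2), soi)$septic)
  expect_false(label_sepsis_onset(at(124.1, 2), soi)$septic)
  expect_false(label_sepsis_onset(at(100, 1), soi)$septic)
  # earliest qualifying SOI wins
  soi2 <- dplyr::bind_rows(soi, dplyr::mutate(soi, soi_time_h = 60))
  expect_equal(label_sepsis_onset(at(80, 3), soi2)$onset_h, 60)
})

test_that("labels are invariant under time translation of the whole record", {
  set.seed(51)
  for (rep in 1:20) {
    n_s <- sample(2:10, 1); n_e <- sample(1:4, 1)
    sofa <- tibble::tibble(patient_id = "A", time_h = stats::runif(n_s, 0, 150),
                           sofa = sample(0:5, n_s, replace = TRUE))
    abx <- tibble::tibble(patient_id = "A", time_h = stats::runif(n_e, 0, 150))
    cult <- tibble::tibble(patient_id = "A", time_h = stats::runif(n_e, 0, 150))
    lab0 <- label_sepsis_onset(sofa, detect_soi(abx, cult))
    shift <- stats::runif(1, 10, 500)
    lab1 <- label_sepsis_onset(dplyr::mutate(sofa, time_h = time_h + shift),
                               detect_soi(dplyr::mutate(abx, time_h = time_h + shift),
                                          dplyr::mutate(cult, time_h = time_h + shift)))
    expect_identical(lab0$septic, lab1$septic)
    if (lab0$septic) expect_equal(lab1$onset_h, lab0$onset_h + shift)
  }
})

test_that("sepsis labeling agrees with an exhaustive pair scan on random logs", {
  set.seed(61)
  for (rep in 1:150) {
    n_a <- sample(0:3, 1); n_c <- sample(0:3, 1); n_s <- sample(1:6, 1)
    abx <- tibble::tibble(patient_id = "A", time_h = stats::runif(n_a, 0, 120))
    cult <- tibble::tibble(patient_id = "A", time_h = stats::runif(n_c, 0, 120))
    sofa <- tibble::tibble(patient_id = "A", time_h = stats::runif(n_s, 0, 120),
                           sofa = sample(0:4, n_s, replace = TRUE))
    # oracle: triple loop over (antibiotic, culture, SOFA sample)
    best <- Inf
    for (ta in abx$time_h) for (tc in cult$time_h) {
      ok <- (tc - ta >= 0 && tc - ta <= 24) || (ta - tc >= 0 && ta - tc <= 72)
      if (!ok) next
      s0 <- min(ta, tc)
      if (any(sofa$sofa >= 2 & sofa$time_h >= s0 - 48 & sofa$time_h <= s0 + 24)) {
        best <- min(best, s0)
      }
    }
    got <- label_sepsis_onset(sofa, detect_soi(abx, cult))
    if (is.finite(best)) {
      expect_true(got$septic)
      expect_equal(got$onset_h, best)
    } else if (nrow(got)) {
      expect_false(got$septic)
    }
  }
})
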