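# Shared fixtures, built once per test run. The small cohort and the tiny
# trained model back the fast unit tests; the full-scale study fixture for
# the acceptance suite lives in helper-study.R and is built lazily.

fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(fixture_env$sim)) {
    fixture_env$sim <- simulate_cohort(sim_config(n_patients = 60, seed = 101L))
  }
  fixture_env$sim
}

cohort_subset <- function(cohort, ids) {
  lapply(cohort, function(tb) tb[tb$patient_id %in% ids, , drop = FALSE])
}

small_pipeline <- function() {
  if (is.null(fixture_env$pipe)) {
    sim <- small_sim()
    ids <- sim$cohort$statics$patient_id
    sp <- split_cohort(ids, c(0.7, 0.15, 0.15), seed = 2L)
    prep <- fit_preprocess(cohort_subset(sim$cohort, sp$train))
    pipe <- list(
      sim = sim, split = sp, prep = prep,
      tens_train = prepare_tensors(cohort_subset(sim$cohort, sp$train), prep, horizon_h = 96),
      tens_val = prepare_tensors(cohort_subset(sim$cohort, sp$val), prep, horizon_h = 96),
      tens_test = prepare_tensors(cohort_subset(sim$cohort, sp$test), prep, horizon_h = 96)
    )
    fixture_env$pipe <- pipe
  }
  fixture_env$pipe
}

# a lightly trained model: enough structure for selector/evaluation tests,
# not meant to be accurate
small_model <- function() {
  if (is.null(fixture_env$model)) {
    pipe <- small_pipeline()
    m <- tecde_model(n_vars = pipe$tens_train$K, seed = 3L)
    fixture_env$model <- train_two_stage(
      m, pipe$tens_train, pipe$tens_val,
      train_config(mu = 0.5, epochs_stage1 = 3L, epochs_stage2 = 3L,
                   batch_size = 42L, seed = 7L)
    )
  }
  fixture_env$model
}

# random measurement panel for the SOFA rule tests
random_sofa_panel <- function(n, seed) {
  set.seed(seed)
  vars <- c("pf_ratio", "platelets", "bilirubin_total", "map",
            "vasopressor_level", "gcs", "creatinine")
  ranges <- list(pf_ratio = c(60, 500), platelets = c(5, 400),
                 bilirubin_total = c(0.2, 15), map = c(40, 110),
                 vasopressor_level = c(0, 4), gcs = c(3, 15),
                 creatinine = c(0.4, 7))
  purrr::map_dfr(seq_len(n), function(i) {
    v <- sample(vars, 1)
    tibble::tibble(patient_id = sample(c("A", "B"), 1),
                   time_h = stats::runif(1, 0, 72), variable = v,
                   value = if (v %in% c("gcs", "vasopressor_level")) {
                     sample(seq(ranges[[v]][1], ranges[[v]][2]), 1)
                   } else stats::runif(1, ranges[[v]][1], ranges[[v]][2]))
  })
}
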