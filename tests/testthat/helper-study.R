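# Full-scale study fixture for the acceptance suite: a 500-patient
# confounded cohort, two stage-1 balancing arms (mu = 0, 1; all-hours
# balancing) and the three-stage treatment-selection model. Built lazily on
# first use and cached for the session.

study_train_configs <- function() {
  list(
    arms = train_config(mu = 1, epochs_stage1 = 80L, batch_size = 100L,
                        lr = 0.01, patience = 12L),
    select = train_config(mu = 1, epochs_stage1 = 60L, epochs_stage2 = 40L,
                          epochs_stage3 = 40L, lr3 = 0.003,
                          batch_size = 100L, lr = 0.01, patience = 12L,
                          anchors_per_epoch = 10L,
                          anchors_include = c(1L, 49L, 73L),
                          balance_hours = c(48L, 72L))
  )
}

study_fixture <- function() {
  if (is.null(fixture_env$study)) {
    cfgs <- study_train_configs()
    fixture_env$study <- synthetic_study(
      n_patients = 500L, seed = 7L, mus = c(0, 1),
      config = cfgs$arms, select_config = cfgs$select
    )
  }
  fixture_env$study
}
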