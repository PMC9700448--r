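# Shared fixtures, built in code.

# Observed subprocess moments (minutes): the model's canonical inputs.
table1_moments <- function() {
  data.frame(
    name = c("registration", "triage", "assessment", "referral_to_medicine",
             "decision_to_admit", "room_allocation", "physical_transfer"),
    mean = c(14, 17, 14.2, 175.3, 525.5, 163.6, 66.4),
    sd = c(1.9, 3.7, 4.5, 38.1, 93.5, 28.8, 12.2),
    stringsAsFactors = FALSE)
}

# Calibration is the most expensive fixture; build it once per test run.
.test_cache <- new.env(parent = emptyenv())

calibrated_config <- function() {
  if (is.null(.test_cache$ccfg)) {
    cal <- calibrate_service_times(admission_config(), tol = 2,
                                   eval_reps = 2, eval_days = 1500,
                                   master_seed = 101L)
    .test_cache$ccfg <- cal$config
    .test_cache$cal_report <- cal$report
  }
  .test_cache$ccfg
}

calibration_report <- function() {
  calibrated_config()
  .test_cache$cal_report
}

# A tiny direct-mode config whose stage durations are all deterministic.
deterministic_config <- function(stage_minutes = 60) {
  cfg <- admission_config()
  cfg$subprocesses$mean <- rep(stage_minutes, 7)
  cfg$subprocesses$sd <- rep(0, 7)
  cfg
}
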