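# Shared expensive fixtures, built once per test run.
# Simulations use the frozen calibrated parameter set shipped in extdata.

shared_cal <- function() {
  if (is.null(.fix$shared)) .fix$shared <- calibrated_params()
  .fix$shared
}

sim_version <- function(version) {
  key <- paste0("sim_", version)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- simulate_circuit(cv_config(version, shared_cal()))
  .fix[[key]]
}

suite_fixture <- function() {
  if (is.null(.fix$suite))
    .fix$suite <- suppressWarnings(run_all_versions(shared_cal()))
  .fix$suite
}

sens_fixture <- function() {
  if (is.null(.fix$sens))
    .fix$sens <- suppressWarnings(sensitivity_pm5("ELS", shared_cal()))
  .fix$sens
}

.fix <- new.env(parent = emptyenv())
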