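# Small cohort builders used across test files. Reduced ROI counts keep the
# suites fast; all criteria exercised on them are independent of whole-brain
# size (the 14 motor ROIs are always present).

reduced_labels <- function(n_extra = 6) {
  labs <- aal90_labels()
  motor <- motor_roi_set(labs)
  c(motor$labels, setdiff(labs, motor$labels)[seq_len(n_extra)])
}

# spec with all planted effects off (null cohort)
null_spec <- function(n_subjects = 43, n_extra = 6, seed = 1L) {
  cohort_spec(n_subjects = n_subjects, roi_labels = reduced_labels(n_extra),
              motor_effect_size = 0, motor_on_increase = 0,
              profile_effect_size = 0, cognition_effect_size = 0,
              seed = seed)
}

# motor-planting-only spec at default effect sizes
motor_spec <- function(n_subjects = 43, n_extra = 6, seed = 1L, ...) {
  cohort_spec(n_subjects = n_subjects, roi_labels = reduced_labels(n_extra),
              profile_effect_size = 0, cognition_effect_size = 0,
              seed = seed, ...)
}

# profile-planting-only spec (motor and cognition effects off)
profile_spec <- function(n_subjects = 43, n_extra = 6, seed = 1L, ...) {
  labs <- reduced_labels(n_extra)
  cohort_spec(n_subjects = n_subjects, roi_labels = labs,
              motor_effect_size = 0, motor_on_increase = 0,
              cognition_effect_size = 0, seed = seed, ...)
}
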