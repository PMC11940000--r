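# Hand-built micro fixtures used across test files.

toy_emg <- function(L = 800, seed = 1, scale = 1) {
  set.seed(seed)
  matrix(stats::rnorm(7 * L, sd = scale), nrow = 7)
}

toy_recording <- function(id = "R1", participant = 1L, emg = toy_emg(),
                          grasp = 1L, action = 1L, weight = 500,
                          span1 = 60, span2 = 0, th = 2L, fs = 1000) {
  raw_recording(id = id, participant = participant, task = 110L, et = 5L,
                emg = emg, sampling_rate_hz = fs, product_dh = 7L,
                weight_g = weight, span1_mm = span1, span2_mm = span2,
                grasp_dh = grasp, action_dh = action, task_height = th)
}

toy_bundle <- function(recs) {
  parts <- unique(vapply(recs, `[[`, integer(1), "participant"))
  profs <- lapply(parts, function(p) mvc_profile(p, rep(10, 7)))
  dataset_bundle(recs, profs, provenance = "test")
}

# A small generated bundle big enough to curate, split 1/1/1 and train on.
small_trainable_bundle <- function(seed = 11) {
  generate_dataset(synth_config(
    n_subjects = 3, recordings_per_subject = list(type = "constant", n = 14),
    p_nonreaching = 0.1, p_free_grasp = 0.05, p_all_null = 0,
    p_leading_nulls = 0, seed = seed))
}

small_curation_config <- function() {
  curation_config(n_test_subjects = 1L, n_val_subjects = 1L)
}
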