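# Shared fixture builders (all data generated in code, no files)

# Hand-built true_cores object with controlled truth and uniform segment
# cancer fractions; bypasses the stochastic generator for noiseless and
# boundary tests.
make_true_cores <- function(true_proportion, true_intensity,
                            cancer_fraction = 0.5, marker_id = "M1",
                            patient_id = NULL) {
  n <- length(true_proportion)
  if (is.null(patient_id)) patient_id <- sprintf("p%05d", seq_len(n))
  core_id <- sprintf("%s_%s_c1", marker_id, patient_id)
  cores <- data.frame(
    core_id = core_id, patient_id = patient_id, marker_id = marker_id,
    true_proportion = true_proportion, true_intensity = true_intensity,
    true_h = true_proportion * true_intensity
  )
  segments <- data.frame(
    core_id = rep(core_id, each = 36L),
    segment_index = rep(0:35, times = n),
    cancer_fraction = rep(cancer_fraction, length.out = 36L * n)
  )
  structure(list(cores = cores, segments = segments),
            class = "true_cores")
}

# One valid classification row, with overridable fields
cls_row <- function(core_id = "c1", segment_index = 14L,
                    cancer_present = TRUE, proportion_bin = 3L,
                    intensity = 2L) {
  data.frame(core_id = core_id, segment_index = segment_index,
             cancer_present = cancer_present,
             proportion_bin = proportion_bin, intensity = intensity)
}

no_cancer_row <- function(core_id = "c1", segment_index = 14L) {
  cls_row(core_id, segment_index, FALSE, NA_integer_, NA_integer_)
}

# Small uniform-random valid classification table
random_classifications <- function(n, n_cores = 3, seed = 1,
                                   segments = central_segment_indices()) {
  withr::with_seed(seed, {
    cancer <- runif(n) < 0.8
    bin <- ifelse(cancer, sample(0:5, n, TRUE), NA_integer_)
    data.frame(
      core_id = sprintf("c%d", sample.int(n_cores, n, TRUE)),
      segment_index = sample(segments, n, TRUE),
      cancer_present = cancer,
      proportion_bin = bin,
      intensity = ifelse(cancer & bin > 0L, sample(1:3, n, TRUE),
                         NA_integer_)
    )
  })
}
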