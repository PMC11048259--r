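# Shared fixtures, generated in code at test time.

# small single-site cohort datastore (B-mode frames at `size` pixels)
make_tiny_store <- function(site = "HTX_B", n_subjects = 4, per_class = 6,
                            size = 32, seed = 11, severity = 1) {
  params <- phantom_params(image_size = size, severity = severity,
                           base_seed = seed)
  cohort <- generate_cohort(params, n_subjects,
                            frames_per_class = per_class, sites = site)
  build_datastore(cohort_to_frames(cohort, n_sections = 5, target = size))
}

tiny_frame <- function(size = 16, value = 0.5) {
  efastcnn:::new_frame(matrix(value, size, size), "RUQ", "subjX", "negative",
                       1L)
}

subject_ids <- function(n) sprintf("subj%02d", seq_len(n))
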