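# Small shared fixtures, generated in code at test time.

tiny_design <- function(n_participants = 2, repetitions = 1,
                        angles = tibble::tibble(joint = "knee",
                                                plane = "sagittal")) {
  cod_design(n_participants = n_participants, repetitions = repetitions,
             angles = angles)
}

# Brute-force oracle: first/last index of the longest strictly-above run.
brute_longest_run <- function(force, threshold) {
  best <- c(NA_integer_, NA_integer_)
  best_len <- 0L
  for (s in seq_along(force)) {
    for (e in s:length(force)) {
      if (all(force[s:e] > threshold) && (e - s + 1L) > best_len) {
        best <- c(s, e)
        best_len <- e - s + 1L
      }
    }
  }
  best
}
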