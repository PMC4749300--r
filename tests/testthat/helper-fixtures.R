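# Shared fixtures, all built in code at test time.

lpt32 <- lpt_basis(32)

# single synthetic beat wrapped in a one-beat annotated record
one_beat_record <- function(..., fs = 250) {
  bt <- make_beat(beat_params(...), fs = fs)
  rec <- ecg_record(matrix(bt$samples, ncol = 1), fs,
                    data.frame(fiducial = bt$fiducial, label = "normal"))
  annotate_isoelectric(rec)
}

# pattern vector of a single clean beat with the given ST parameters
beat_pattern <- function(...) {
  rec <- one_beat_record(...)
  extract_pattern_vector(rec, 1, 1)
}

# small deterministic interval corpus (list of patterns + labels)
toy_corpus <- function(n_classes = 20, M = 8, seed = 99) {
  set.seed(seed)
  lapply(seq_len(n_classes), function(i)
    list(patterns = matrix(rnorm(5 * M), 5, M), label = "no_deviation"))
}
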