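# Internal helpers.

# Deterministic per-replicate seed streams: one master seed spawns an
# n_reps x n_streams matrix of independent 31-bit seeds, so that every
# experiment is a pure function of (configuration, n_reps, seed) and
# different randomness consumers (data, test data, posterior draws) never
# share a stream.
.seed_streams <- function(seed, n_reps, n_streams = 3L) {
  set.seed(seed)
  matrix(sample.int(2147483646L, n_reps * n_streams), n_reps, n_streams)
}
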