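# Shared fixtures, built in code at test time.

# small, fast seizure record: few channels, defaults otherwise
make_seizure <- function(seed = 1, n_channels = 3, ...) {
  gen_seizure_record(synthetic_spec(n_channels = n_channels, seed = seed, ...))
}

# tiny record for I/O shape tests
make_tiny_record <- function(n_ch = 4, n_s = 10, fs = 10, seed = 1) {
  set.seed(seed)
  eeg_record(matrix(rnorm(n_ch * n_s), nrow = n_ch), fs = fs)
}

# iid-noise trajectory around a constant level
make_flat_trajectory <- function(n = 170, level = 0.9, sigma = 0.02,
                                 seed = 1) {
  set.seed(seed)
  trajectory(seq_len(n), level + rnorm(n, sd = sigma))
}
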