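# Shared fixture builders: everything is generated in code at test time.

# A recording from a named list of channel vectors, names "g.m" (e.g. "1.2").
mk_rec <- function(channels, label = NULL, rate = 100) {
  sig <- lapply(names(channels), function(nm) {
    gm <- as.integer(strsplit(nm, ".", fixed = TRUE)[[1]])
    uniaxial_signal(channels[[nm]], sensor = gm[1], axis = gm[2],
                    sample_rate = rate)
  })
  movement_recording(sig, label = label)
}

# Small clean ensemble: H classes x n trials, zero corruption unless
# overridden, so trials equal their class templates exactly.
clean_ensemble <- function(H = 3, n_trials = 4, base_len = 40, seed = 42, ...) {
  cfg <- synthetic_config(H = H, G = 2, axes_per_sensor = 3,
                          n_trials = n_trials, base_len = base_len,
                          seed = seed, ...)
  generate_dataset(cfg)
}

labels_of <- function(recs) vapply(recs, `[[`, integer(1), "label")
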