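#!/usr/bin/env Rscript
# Stage 3 -- synthetic EEG for a demo-scale study.
#
# Simulates 4 participants per domain, two blocks each (spectral and
# durational), at 900 Hz over the 9-channel analysis grid with 1/f noise,
# a generic event-locked ERP, the per-condition MMN injections (asymmetric
# deviants only in speech-spectral) and a 2% artifact rate. Recordings are
# written as EDF+ with the event annotations embedded so the next stage
# can start from files alone, as it would with real data.

library(rovingmmn)

cfg <- run_config(
  n_per_domain = 4, lead_in = 4, train_lengths = 4:6, reps_per_length = 6,
  sample_rate = 900, target_rate = 300, channels = analysis_grid(),
  noise = noise_spec(exponent = 1, rms = 8), artifact_rate = 0.02,
  seed = 42)

dir.create("scratch/edf", recursive = TRUE, showWarnings = FALSE)
saveRDS(cfg, "scratch/run_config.rds")

n_files <- 0
for (domain in c("speech", "tone")) {
  for (p in seq_len(cfg$n_per_domain)) {
    participant <- sprintf("%s-%02d", substr(domain, 1, 2), p)
    for (dimension in c("spectral", "durational")) {
      rec <- simulate_block(cfg, participant, domain, dimension)
      path <- sprintf("scratch/edf/%s_%s.edf", participant, dimension)
      write_edf(rec, path, phys_range = 1000)
      n_files <- n_files + 1
    }
  }
}
cat(sprintf("wrote %d EDF blocks (%d events each) under scratch/edf/\n",
            n_files, cfg$lead_in +
              2 * sum(rep(cfg$train_lengths, cfg$reps_per_length))))
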