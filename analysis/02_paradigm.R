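#!/usr/bin/env Rscript
# Stage 2 -- roving-standard sequence generation.
#
# Generates the four presentation blocks (domain x dimension) under the
# standard plan: 8 lead-in tokens, 100 trains per stimulus with lengths
# 4-8 each occurring 20 times, SOA 1.09 s. Writes BIDS-like events TSVs
# and a bookkeeping summary confirming the exact token counts and timing.

library(rovingmmn)

dir.create("results/events", recursive = TRUE, showWarnings = FALSE)

summary_rows <- list()
for (domain in c("speech", "tone")) {
  for (dimension in c("spectral", "durational")) {
    pre <- if (domain == "speech") "f" else "t"
    stims <- if (dimension == "spectral")
      c(paste0(pre, "e220"), paste0(pre, "a220"))
    else c(paste0(pre, "e180"), paste0(pre, "e360"))
    plan <- roving_plan(stim_a = stims[1], stim_b = stims[2],
                        seed = child_seed(42, paste(domain, dimension)))
    ev <- generate_sequence(plan)
    write_events(ev, sprintf("results/events/%s_%s.tsv", domain, dimension))
    d <- total_duration(ev, plan)
    summary_rows[[paste(domain, dimension)]] <- data.frame(
      domain = domain, dimension = dimension,
      n_stim_a = sum(ev$stimulus == stims[1]),
      n_stim_b = sum(ev$stimulus == stims[2]),
      n_total = nrow(ev),
      n_deviants = sum(ev$role == "deviant"),
      n_standards = sum(ev$role == "standard"),
      minutes = round(d$minutes, 2))
  }
}
summary <- do.call(rbind, summary_rows)
write.csv(summary, "results/paradigm_summary.csv", row.names = FALSE)
print(summary, row.names = FALSE)
cat(sprintf("\nEach block presents %d + %d = %d tokens in %d min.\n",
            summary$n_stim_a[1], summary$n_stim_b[1], summary$n_total[1],
            round(summary$minutes[1])))
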