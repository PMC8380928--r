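#!/usr/bin/env Rscript
# Stage 5 -- contrast-coded mixed-effects analysis.
#
# Fits the linear mixed-effects model to results/mmn.csv: main effects and
# all two-/three-way interactions of Domain, Dimension and Deviant, plus
# the Laterality and Anteriority channel contrasts, with a per-participant
# random intercept and slopes for Dimension and Deviant (Satterthwaite
# tests). Unpacks the three-way interaction into model-estimated cell
# means with 95% CIs and the CI-exclusion asymmetry decision per cell.

library(rovingmmn)

mmn <- read.csv("results/mmn.csv", stringsAsFactors = FALSE)
fit <- fit_mmn_model(mmn)

cat(sprintf("fit on %d rows, %d participants%s\n\n", nrow(mmn),
            length(unique(mmn$participant)),
            if (fit$singular) " (note: singular random-effects fit)" else ""))
print(transform(fit$coefficients, estimate = round(estimate, 1),
                se = round(se, 1), df = round(df, 1), t = round(t, 2),
                p = signif(p, 2)), row.names = FALSE)

cm <- estimate_cell_means(fit)
fl <- asymmetry_flags(cm)
write.csv(fit$coefficients, "results/fixed_effects.csv", row.names = FALSE)
write.csv(cm, "results/cell_means.csv", row.names = FALSE)
write.csv(fl, "results/asymmetry.csv", row.names = FALSE)

cat("\nmodel-estimated cell means (uV*ms):\n")
print(transform(cm, estimate = round(estimate, 1), se = round(se, 1),
                lo = round(lo, 1), hi = round(hi, 1)), row.names = FALSE)
cat("\nasymmetry decisions (one deviant's 95% CI excludes the other's mean):\n")
print(transform(fl, mean_prominent = round(mean_prominent, 1),
                mean_nonprominent = round(mean_nonprominent, 1),
                difference = round(difference, 1)), row.names = FALSE)
cat(paste0("\nNote: at this demo scale (4 participants per domain, 18\n",
           "trains per stimulus) the design is deliberately underpowered;\n",
           "stage 6 runs the powered recovery study at 16 participants\n",
           "per domain and full train counts.\n"))
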