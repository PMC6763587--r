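#!/usr/bin/env Rscript
# Step 1: synthesize a five-phase, two-cap study with known ground truth.
#
# Writes one EDF (+ JSON sidecar) per subject, cap and phase under
# results/study/, plus manifest.json with the full ground truth (subject
# iAPF offsets, per-phase targets, injected channel failures, impedances).
# This driver uses a reduced replica of the study conditions (4 subjects,
# 128 samples/s) so it runs in about a minute; scripts/acceptance.R runs
# the full 17-subject study at 1024 samples/s.

library(alphacog)

out_dir <- "results/study"
cfg <- synth_study_config(n_subjects = 4, n_excluded_no_alpha = 1,
                         seed = 2026, fs = 128, phase3_s = 120)
man <- synthesize_study(cfg, out_dir)

n_edf <- length(list.files(out_dir, pattern = "\\.edf$"))
cat(sprintf("Wrote %d recordings (%d subjects x %d caps x 5 phases) to %s\n",
            n_edf, cfg$n_subjects, length(cfg$cap_types), out_dir))
cat("Alpha-deficient subjects (will fail the presence gate):\n")
for (s in names(man$deficient_subjects)) {
  cat(sprintf("  subject %s: zero alpha in phase %s\n", s,
              man$deficient_subjects[[s]]))
}
cat(sprintf("Subject iAPF offsets (Hz, centred): %s\n",
            paste(sprintf("%+.3f", man$subject_offsets), collapse = ", ")))
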