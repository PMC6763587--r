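#!/usr/bin/env Rscript
# Step 2: channel quality control and reliability.
#
# Runs the deterministic bad-channel detector (isoelectric / saturated /
# artifactual, > 30 s cumulative) on every phase segment of the simulated
# study, writes per-segment QC reports and the channel-reliability table,
# and exports per-electrode topographic grand averages (reliability and
# impedance) as plotting-ready delimited text under results/.

library(alphacog)

study_dir <- "results/study"
if (!dir.exists(study_dir)) stop("run analysis/01_simulate_study.R first")
man <- jsonlite::read_json(file.path(study_dir, "manifest.json"))

rel_rows <- list(); topo_rows <- list()
for (u in man$units) {
  rec <- read_edf(file.path(study_dir, u$file))
  for (seg in segment_by_phase(rec)) {
    qc <- detect_bad_channels(seg)
    rel_rows[[length(rel_rows) + 1L]] <-
      channel_reliability(qc, u$subject, u$cap_type, u$phase_id)
    topo_rows[[length(topo_rows) + 1L]] <- data.frame(
      subject = u$subject, cap_type = u$cap_type,
      electrode = qc$channel, value = as.numeric(qc_good(qc)))
  }
}
rel <- do.call(rbind, rel_rows)
write.table(rel, "results/reliability.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (ct in c("gel", "dry")) {
  topo <- do.call(rbind, topo_rows)
  topo <- topo[topo$cap_type == ct, ]
  tg <- topographic_grand_average(topo, cap_montage(ct))
  write_topographic(tg, sprintf("results/topo_reliability_%s.tsv", ct))
}
imp <- do.call(rbind, lapply(man$impedances_dry, as.data.frame))
write_topographic(
  topographic_grand_average(data.frame(electrode = imp$electrode,
                                       value = imp$start_kohm)),
  "results/topo_impedance_dry_start.tsv")

cat("Mean channel reliability (% retained) by cap and phase:\n")
print(aggregate(reliability ~ cap_type + phase_id, rel, mean), digits = 3)
cat(sprintf("Dry-cap impedance: start %.0f kOhm, end %.0f kOhm (grand means)\n",
            mean(imp$start_kohm), mean(imp$end_kohm)))
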