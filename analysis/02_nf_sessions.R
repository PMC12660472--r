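#!/usr/bin/env Rscript
# Stage 2: score NF sessions — veridical for experimental subjects, yoked
# sham for controls — and summarise the blinding analogue.
#
# Each session is three 10-min runs; after every 26-s meditation block the
# engine re-fits the cumulative GLM, re-selects the 33% most deactivated
# target voxels, residualizes against the confound ROI and maps the block
# score onto a 20-level thermometer.

library(nfmed)

seed <- 1L
out <- "results/02_nf_sessions"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

acq <- nf_acquisition()
design <- make_block_design(acq)
n_pairs <- 10

displayed <- actual <- matrix(NA_real_, 18, n_pairs)
for (s in seq_len(n_pairs)) {
  donor_runs <- lapply(1:3, function(r)
    simulate_roi_run(design, acq, nf_ground_truth(seed = seed + 10 * s + r)))
  donor_log <- run_nf_session(donor_runs, nf_config())
  recip_runs <- lapply(1:3, function(r)
    simulate_roi_run(design, acq,
                     nf_ground_truth(seed = seed + 1000 + 10 * s + r)))
  sham <- sham_schedule(sprintf("sub-exp%03d", s), donor_log)
  recip_log <- run_nf_session(recip_runs, nf_config(mode = "sham"), sham)
  write_session_log(donor_log,
                    file.path(out, sprintf("veridical_%02d.csv", s)))
  write_session_log(recip_log,
                    file.path(out, sprintf("sham_%02d.csv", s)))
  displayed[, s] <- recip_log$displayed_psc
  actual[, s] <- recip_log$residual_psc
}

cat(sprintf("scored %d veridical + %d sham sessions (18 blocks each)\n",
            n_pairs, n_pairs))
blind <- sham_blinding_pvalues(displayed, actual)
write.csv(blind, file.path(out, "blinding_check.csv"), row.names = FALSE)
cat(sprintf("blinding analogue: %d/%d pairs non-significant (p > 0.05)\n",
            sum(blind$p > 0.05), n_pairs))
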