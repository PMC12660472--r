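#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Produces one behavioural cohort (19 analysable subjects per group, the
# study's size) and one subject's three NF runs written as NIfTI + BIDS-style
# events, so later stages can be run file-based as well as in memory.

library(nfmed)

seed <- 1L
out <- "results/01_simulate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

acq <- nf_acquisition()                      # TR 0.8 s, 10-min runs
design <- make_block_design(acq)             # 3 x 51 s rest, 6 x 26 s meditation
cat(sprintf("design: %d events, %d meditation blocks, %d volumes/run\n",
            nrow(design$events), design$n_meditation, acq$n_volumes))
write_events_tsv(design$events, file.path(out, "events.tsv"))

cohort <- simulate_cohort(cohort_config(seed = seed))
write_cohort_csv(cohort, file.path(out, "cohort.csv"))
cat(sprintf("cohort: %d subjects (%d per group)\n", nrow(cohort),
            nrow(cohort) / 2))

run <- simulate_roi_run(design, acq, nf_ground_truth(seed = seed))
paths <- write_roi_run(run, out, prefix = "sub-exp001_run-01")
cat("example run written:", paths$target, "\n")
cat(sprintf("  target ROI %d voxels, %d signal-carrying\n",
            nrow(run$target), length(run$signal_voxels)))
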