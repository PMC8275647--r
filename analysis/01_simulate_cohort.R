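#!/usr/bin/env Rscript
# Simulate the study's two-arm paired physiological cohort: a biofeedback
# group (n = 15) whose resting heart rate falls and SDNN rises from T1 to
# T2, and a control group (n = 17) with no systematic change. Each
# subject/session gets a raw pulse + respiration recording written in BIDS
# physio layout under results/cohort/, with the generating parameters in a
# manifest for later scoring.

suppressPackageStartupMessages(library(neurocardiac))

seed <- 20
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# group-level parameters: T1 means/SDs and paired changes for HR (bpm) and
# SDNN (ms); the biofeedback arm improves, the control arm drifts around 0
arms <- list(
  biofeedback = list(n = 15, hr_t1 = c(70.1, 9.6), d_hr = c(-5.2, 7.3),
                     sdnn_t1 = c(54.4, 14.9), d_sdnn = c(8.6, 14.3)),
  control = list(n = 17, hr_t1 = c(67.9, 8.1), d_hr = c(1.7, 7.9),
                 sdnn_t1 = c(68.9, 30.7), d_sdnn = c(-5.9, 27.5))
)

set.seed(seed)
manifest <- list()
sub_id <- 0L
duration <- 300   # s of resting recording per session
fs <- 100

for (arm in names(arms)) {
  a <- arms[[arm]]
  for (i in seq_len(a$n)) {
    sub_id <- sub_id + 1L
    hr1 <- max(45, rnorm(1, a$hr_t1[1], a$hr_t1[2]))
    hr2 <- max(45, hr1 + rnorm(1, a$d_hr[1], a$d_hr[2]))
    sd1 <- max(15, rnorm(1, a$sdnn_t1[1], a$sdnn_t1[2]))
    sd2 <- max(15, sd1 + rnorm(1, a$d_sdnn[1], a$d_sdnn[2]))
    br <- min(28, max(8, rnorm(1, 15.5, 3.5)))
    for (ses in 1:2) {
      cfg <- sim_config(seed = seed * 1000L + sub_id * 10L + ses,
                        duration = duration, fs_physio = fs,
                        mean_ibi = 60000 / c(hr1, hr2)[ses],
                        target_sdnn = c(sd1, sd2)[ses], resp_rate = br)
      ibi <- gen_ibi_series(cfg)
      pulse <- gen_pulse_waveform(ibi, fs = fs, noise_sd = 0.03,
                                  seed = cfg$seed)
      resp <- gen_respiration(cfg)
      n <- min(length(pulse$samples), length(resp$samples))
      pulse$samples <- pulse$samples[1:n]
      resp$samples <- resp$samples[1:n]
      write_physio(list(pulse = pulse, respiration = resp),
                   file.path(out_dir, sprintf("sub-%02d_ses-%d_physio.tsv.gz",
                                              sub_id, ses)))
    }
    manifest[[length(manifest) + 1L]] <- data.frame(
      subject = sprintf("sub-%02d", sub_id), group = arm,
      true_hr_t1 = hr1, true_hr_t2 = hr2,
      true_sdnn_t1 = sd1, true_sdnn_t2 = sd2, true_br = br)
  }
}

manifest <- do.call(rbind, manifest)
write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("Simulated ", nrow(manifest), " subjects x 2 sessions into ",
        out_dir)
message("Biofeedback arm planted change: HR ",
        arms$biofeedback$d_hr[1], " bpm, SDNN +",
        arms$biofeedback$d_sdnn[1], " ms")
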