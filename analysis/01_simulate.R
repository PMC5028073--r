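#!/usr/bin/env Rscript
# Step 1: simulate the eight-condition virtual shuffleboard experiment.
#
# Eight friction coefficients come from ideal stop-times uniform on [3, 5] s
# (mu = 2L/(g t^2); the four longest times are the low-friction conditions).
# Each condition is a 10 x 50-trial blocked series generated by the linear
# inter-trial error-correction model about an on-GEM operating point
# (lambda_w = 0.76 nearly tangent, lambda_s = -0.03 transverse at 80 deg).
# Writes one CSV per condition under results/data/.

suppressPackageStartupMessages(library(gemfluct))

seed <- 20260921L
out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

times <- seq(3, 5, length.out = 8)
exp8 <- simulate_experiment(times = times, seed = seed)
write.csv(data.frame(condition = names(exp8), time_s = times,
                     mu = friction_set(times)),
          file.path(out_dir, "conditions.csv"), row.names = FALSE)

for (nm in names(exp8)) {
  ts <- exp8[[nm]]
  path <- file.path(out_dir, paste0(nm, ".csv"))
  write_trials(ts, path, participant = "sim", condition = nm)
  fr <- gem_frame(operating_point(ts), ts$cfg)
  message(sprintf(
    "%s: mu = %.5f, %d trials, passive sensitivity s = %.1f, sd(e) = %.3f",
    nm, ts$cfg$mu, nrow(ts$records), fr$s, sd(ts$records$e)))
}
writeLines(as.character(seed), file.path(out_dir, "seed.txt"))
message("Wrote ", length(exp8), " condition files to ", out_dir)
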