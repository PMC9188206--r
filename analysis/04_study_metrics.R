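#!/usr/bin/env Rscript

# Worked pharmacodynamic / efficacy arithmetic on a small illustrative
# xenograft table: caliper-derived volumes, growth inhibition vs control,
# per-animal regression with its median, and comparative-Ct relative
# quantification of a target gene against a reference gene.

library(derscore)

dir.create("results", showWarnings = FALSE)

# caliper measurements (mm) at baseline and day 18, 5 animals per arm
arms <- data.frame(
  animal = sprintf("m%02d", 1:10),
  arm = rep(c("vehicle", "treated"), each = 5),
  d0 = c(5.0, 5.2, 4.8, 5.1, 5.0, 5.0, 4.9, 5.1, 5.2, 5.0),
  D0 = c(8.0, 7.8, 8.2, 8.0, 7.9, 8.0, 8.1, 7.9, 8.0, 8.2),
  d1 = c(7.9, 8.1, 7.6, 8.0, 7.8, 4.1, 3.6, 4.4, 3.2, 3.9),
  D1 = c(12.5, 12.9, 12.1, 12.6, 12.4, 6.3, 5.8, 6.6, 5.1, 6.2))

arms$V0 <- tumor_volume(arms$d0, arms$D0)
arms$V1 <- tumor_volume(arms$d1, arms$D1)
arms$delta <- arms$V1 - arms$V0
write.table(arms, "results/xenograft_volumes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

treated <- arms[arms$arm == "treated", ]
vehicle <- arms[arms$arm == "vehicle", ]
tgi <- tgi_percent(treated$delta, vehicle$delta)
cat(sprintf("TGI on volume change from baseline: %.0f%%\n", tgi))
reg <- regression_percent(treated$V0, treated$V1)
cat(sprintf("per-animal regression: %s; median %.0f%% (%d/%d regressing)\n",
            paste(sprintf("%.0f%%", reg), collapse = ", "),
            median_regression(treated$V0, treated$V1), sum(reg > 0),
            nrow(treated)))

# comparative-Ct quantification of a canonical target vs a vehicle calibrator
rq <- relative_quantification(c(target = 26.4, reference = 18.1),  # treated
                              c(target = 24.1, reference = 18.0))  # vehicle
cat(sprintf("target mRNA: ddCt = %.2f, RQ = %.2f (%.0f%% inhibition vs control)\n",
            rq$delta_delta_ct, rq$rq, 100 * (1 - rq$rq)))
cat("wrote results/xenograft_volumes.tsv\n")
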