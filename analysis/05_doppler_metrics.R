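#!/usr/bin/env Rscript
# Doppler envelope analysis: beat segmentation and 10-beat-averaged
# peak / end-diastolic / cycle-mean velocities, on (a) a synthetic noisy
# envelope with known truth and (b) envelopes reconstructed from the
# published flow-velocity table for the cuffed and contralateral
# carotids.

library(cuffmap)

dir.create("results", showWarnings = FALSE)

cat("== synthetic envelope (noise 0.2 cm/s, 10% breathing) ==\n")
g <- gen_doppler_trace(seed = 1)
m <- beat_metrics(g$trace, segment_beats(g$trace, 7), 10)
comp <- rbind(estimated = m$averages, truth = g$truth$mean_metrics)
print(round(comp, 2))

# published 10-beat averages (cm/s): mean / peak / end-diastolic
tab <- data.frame(
  vessel = c("fwd_LC-U", "fwd_LC-D", "fwd_RC",
             "rev_LC-U", "rev_LC-D", "rev_RC"),
  mean = c(7.4, 20.2, 14.0, 5.5, 7.9, 11.9),
  peak = c(13.6, 53.1, 47.0, 17.8, 24.6, 29.0),
  edv = c(4.5, 9.4, 8.4, 2.1, 5.5, 5.8))

rec <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
  g <- doppler_trace_from_metrics(tab$peak[i], tab$edv[i], tab$mean[i],
                                  seed = 1)
  m <- beat_metrics(g$trace, segment_beats(g$trace, 7), 10,
                    denoise = FALSE)
  data.frame(vessel = tab$vessel[i], t(m$averages))
}))
write.csv(rec, "results/doppler_metrics.csv", row.names = FALSE)

cat("\n== reconstructed flow-velocity table (10-beat averages) ==\n")
print(rec, row.names = FALSE)
r <- function(v) rec$cycle_mean[rec$vessel == v]
cat(sprintf("\nforward: upstream/contralateral = %.2f (flow roughly halved)\n",
            r("fwd_LC-U") / r("fwd_RC")))
cat(sprintf("forward: downstream/upstream    = %.2f (jet, roughly tripled)\n",
            r("fwd_LC-D") / r("fwd_LC-U")))
cat(sprintf("reversed: upstream/contralateral = %.2f (again halved)\n",
            r("rev_LC-U") / r("rev_RC")))
cat(sprintf("reversed: downstream/upstream   = %.2f (increase < 50%%, no jet)\n",
            r("rev_LC-D") / r("rev_LC-U")))
cat(sprintf("\nangle correction example: 10 cm/s at 58 deg -> %.1f cm/s\n",
            angle_correct(10, 58)))
cat("\nwrote results/doppler_metrics.csv\n")
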