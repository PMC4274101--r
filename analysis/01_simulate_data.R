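#!/usr/bin/env Rscript
# Generate one example of every synthetic input with its ground truth:
# an en-face two-channel stack (TIFF + YAML sidecar), a cuffed lumen
# geometry (centerline + contour CSV), a pulsatile Doppler envelope
# (CSV) and a wall-shear-stress surface field (CSV).  Downstream scripts
# regenerate what they need; these files document the interchange
# formats.

library(cuffmap)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

cat("== en-face stack (conventional cuff, default degradation) ==\n")
g <- gen_enface_stack(seed = seed)
print(g$stack)
write_enface_stack(g$stack, file.path(out, "stack_forward.tif"))
write_truth_json(list(x_um = g$truth$x, uptake = g$truth$uptake,
                      peak_centers = as.list(g$truth$peak_centers),
                      seed = seed),
                 file.path(out, "stack_forward_truth.json"))

cat("\n== lumen geometry around the cuff ==\n")
gl <- gen_lumen_geometry(seed = seed)
print(gl$geometry)
write_geometry_csv(gl$geometry,
                   file.path(out, "centerline.csv"),
                   file.path(out, "contours.csv"))
write_truth_json(gl$truth[c("x", "bore_diameter", "lumen_diameter",
                            "throat_x")],
                 file.path(out, "geometry_truth.json"))

cat("\n== Doppler envelope (12 beats, 10% breathing modulation) ==\n")
gd <- gen_doppler_trace(seed = seed)
write_trace_csv(gd$trace, file.path(out, "doppler_trace.csv"))
write_truth_json(list(mean_metrics = as.list(gd$truth$mean_metrics),
                      heart_rate_hz = gd$truth$heart_rate_hz),
                 file.path(out, "doppler_truth.json"))
cat(sprintf("true 10-beat metrics: peak %.1f, EDV %.1f, mean %.1f cm/s\n",
            gd$truth$mean_metrics["peak_v"], gd$truth$mean_metrics["edv"],
            gd$truth$mean_metrics["cycle_mean"]))

cat("\n== WSS surface field (quasi-1D longitudinal pattern + noise) ==\n")
area <- pi * (gl$truth$lumen_diameter / 2)^2
q1d <- quasi_1d_stenosis(gl$truth$x, area, Q = 2e-8)
pattern <- approxfun(q1d$x_um, q1d$tau_pa, rule = 2)
f <- gen_surface_field(gl$geometry, pattern, noise = 0.5, seed = seed)
write_field_csv(f$field, file.path(out, "wss_field.csv"))
cat(sprintf("field: %d nodes, tau range %.2f - %.1f Pa\n",
            nrow(f$field), min(f$field$value), max(f$field$value)))

cat("\nwrote inputs to", out, "\n")
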