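#!/usr/bin/env Rscript
# Closed-form escape mechanics: the grip-friction laws at the compressions
# of interest, the Reynolds-number regime, section areas, pressure drag and
# mass x acceleration on a synthetic struggling movement, and the lever
# force balance. Writes results/mechanics_summary.json and force traces.

library(struggleR)
dir.create("results", showWarnings = FALSE)

out <- list()

## grip friction at the escape-threshold compressions
dw <- c(0.124, 0.154, 0.156, 0.11, 0.22)
out$friction <- data.frame(dw = dw,
                           fitted_uN = fitted_friction(dw),
                           hooke_uN = hooke_friction(dw))
cat("Fitted friction (uN) at dw =", dw, ":",
    sprintf("%.2f", fitted_friction(dw)), "\n")
cat(sprintf("Hooke expansion: %.1f dw^2 %+.2f dw;  mu = tan(4.5 deg) = %.3f\n",
            hooke_coefficients()["quadratic"],
            hooke_coefficients()["linear"], friction_coefficient(4.5)))

## flow regime during struggling (tail sweep ~85 mm/s over ~2 mm)
out$reynolds_struggling <- reynolds(v = 0.085, L = 0.002)
cat(sprintf("Struggling Reynolds number: %.1f -> pressure drag dominates\n",
            out$reynolds_struggling))

## body sections
body <- body_model()
out$section_areas_rostral_half <- rev(section_areas(body, 5,
                                                    span = c(0, 2.5)))
cat("Rostral-half section areas (head-to-mid, mm^2):",
    sprintf("%.2f", out$section_areas_rostral_half), "\n")

## forces on a synthetic struggling movement
b <- make_tracked_movement(wave_spec("struggling", noise_sd = 0, seed = 1))
drag <- pressure_drag(body, b)
macc <- mass_acceleration(body, b, lowpass_hz = 50)
mid <- 100:(nrow(drag$total) - 100)
out$peak_drag_uN <- max(drag$total$Fmag[mid], na.rm = TRUE)
out$peak_mass_acc_uN <- max(macc$total$Fmag[mid], na.rm = TRUE)
cat(sprintf("Peak |drag| %.2f uN, peak |mass*acc| %.2f uN (synthetic wave)\n",
            out$peak_drag_uN, out$peak_mass_acc_uN))
write.csv(drag$total, "results/drag_trace.csv", row.names = FALSE)
write.csv(macc$total, "results/mass_acc_trace.csv", row.names = FALSE)

## lever balance at the struggling escape threshold
lv <- lever_escape(F1 = out$peak_mass_acc_uN, L1 = 2, L2 = 1.4,
                   alpha = 20, friction = fitted_friction(0.124))
out$lever <- lv
cat(sprintf("Lever: F2x = %.2f uN vs friction %.2f uN -> %s\n",
            lv$F2x, fitted_friction(0.124),
            if (lv$escapes) "escape" else "stuck"))

jsonlite::write_json(out, "results/mechanics_summary.json",
                     auto_unbox = TRUE, digits = NA, na = "null")
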