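#!/usr/bin/env Rscript
# Validation of the Monte-Carlo light transport against closed forms:
# Beer-Lambert attenuation in a non-scattering slab, and the
# diffusion-theory effective attenuation mu_eff = sqrt(3 mu_a (mu_a + mus'))
# for the chicken-breast-like medium (0.3 and 10 /cm: mu_eff ~ 3.04 /cm).

library(cryopa)

# --- Beer-Lambert: pencil beam, mu_a = 1 /cm, no scattering -------------
d <- c(21L, 21L, 45L)
ph <- optical_phantom(array(1, d), array(0, d), 0, array(0L, d), 0.5)
em <- run_mc(ph, beam_spec(0), 1e6, seed = 11)
z <- (seq_len(d[3]) - 0.5) * 0.05
Fax <- fluence_from_energy(em, ph)[11, 11, ] * 0.05^2
bl_err <- max(abs(Fax[z <= 2] / beer_lambert_oracle(1, z[z <= 2]) - 1))
cat(sprintf("Beer-Lambert: max on-axis relative error to z = 2 cm: %.2e\n", bl_err))

# --- Diffusion decay: wide beam, wide slab ------------------------------
d2 <- c(80L, 80L, 60L)
g <- 0.9
ph2 <- optical_phantom(array(0.3, d2), array(10 / (1 - g), d2), g,
                       array(0L, d2), 1)
em2 <- run_mc(ph2, beam_spec(4), 2e5, seed = 12)
z2 <- (seq_len(d2[3]) - 0.5) * 0.1
Fax2 <- apply(fluence_from_energy(em2, ph2)[38:43, 38:43, ], 3, mean)
sel <- z2 >= 1.5 & z2 <= 4
fit <- lm(log(Fax2[sel]) ~ z2[sel])
mu_eff <- sqrt(3 * 0.3 * (0.3 + 10))
cat(sprintf("Diffusion: fitted decay %.3f /cm vs mu_eff %.3f /cm (%.1f%% off)\n",
            -coef(fit)[2], mu_eff, 100 * abs(-coef(fit)[2] / mu_eff - 1)))

dir.create("results", showWarnings = FALSE)
export_results(
  data.frame(check = c("beer_lambert_max_rel_err", "diffusion_decay_per_cm",
                       "mu_eff_theory_per_cm"),
             value = c(bl_err, -coef(fit)[2], mu_eff)),
  "results", "transport_checks")

# Energy bookkeeping of the second run (holds on every run)
cons <- sum(em2$values) + em2$escaped + em2$rr_lost - em2$rr_gained
cat(sprintf("Energy conservation residual: %.2e\n", abs(cons - 1)))
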