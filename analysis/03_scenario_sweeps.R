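#!/usr/bin/env Rscript
# The three simulation scenarios: how trace-domain SNR at the target
# arrival time changes with intermediate-medium temperature when
# (a) only the Grueneisen parameter follows temperature,
# (b) only the reduced scattering coefficient does,
# (c) both do.
#
# Full study conditions are depths 5-30 mm (step 5) and temperatures
# 5-35 degC (step 5); this driver runs depths 10/20/30 mm and
# temperatures 5/20/35 degC at 1e5 photons so it completes in minutes.
# Pass --full for the complete grid.

library(cryopa)

full <- "--full" %in% commandArgs(trailingOnly = TRUE)
depths <- if (full) seq(5, 30, by = 5) else c(10, 20, 30)
temps <- if (full) seq(5, 35, by = 5) else c(5, 20, 35)
n_photons <- 1e5
model <- thermo_model()

dir.create("results", showWarnings = FALSE)
all <- list()
for (sc in c("gamma_only", "mus_only", "both")) {
  cat(sprintf("== scenario %s ==\n", sc))
  sw <- run_scenario_sweep(sc, depths = depths, temperatures = temps,
                           n_photons = n_photons, seed = 20, model = model,
                           verbose = TRUE)
  all[[sc]] <- sw
  d <- delta_snr_from_sweep(sw, t_warm = 35, t_cold = 5)
  for (i in seq_len(nrow(d)))
    cat(sprintf("  depth %2g mm: SNR(5) - SNR(35) = %+.3f dB\n",
                d$depth[i], d$delta_snr_db[i]))
}
sweep <- do.call(rbind, all)
export_results(sweep, "results", "scenario_sweeps",
               manifest = list(n_photons = n_photons, seed = 20,
                               analytic_gamma_dsnr_db =
                                 delta_snr_analytic(35, 5, model)))

cat(sprintf("\nGamma-only improvement is exactly the analytic %.3f dB at every depth\n",
            delta_snr_analytic(35, 5, model)))
cat("(shared-fluence protocol); the combined scenario adds the scattering gain on top.\n")
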