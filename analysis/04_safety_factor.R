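#!/usr/bin/env Rscript
# Safety factor for conduction along a 900-cell endocardial fiber.
#
# Computes the charge-ratio safety factor in control, under homogeneous HF
# remodeling, and with a 25-cell fibroblast cluster inserted mid-fiber.
# Findings: SF ~ 1.8 along the uniform fiber, very slightly reduced by HF;
# inside the fibroblast cluster SF falls to ~1, and distal to the cluster
# propagation fails under the default (per-area) fibroblast coupling - see
# the methods vignette for the capacitance-weighted variant in which the
# wave crosses the cluster with a long delay.

library(hfstrand)
dir.create("results", showWarnings = FALSE)

sf_fiber <- function(mode, cluster = NULL, cfg = sim_config(n_beats = 3)) {
  lay <- build_transmural_layout("GPB", c(ENDO = 900))
  if (!is.null(cluster)) lay <- insert_patchy_fibrosis(lay, cluster, 438)
  nodes <- make_node_states(lay, build_profile("GPB", mode))
  pre <- solve_strand(lay, nodes, cfg, 2000, stim_times = c(0, 1000), t0 = 0,
                      sample_interval = 1000, record_cai = FALSE)
  tr <- solve_strand(lay, pre$nodes, cfg, 400, stim_times = 2000, t0 = 2000,
                     track_from = 2000, sample_interval = 0.05,
                     record_cai = FALSE)
  idx <- 380:520
  data.frame(cell = idx, class = lay$node_class[idx],
             SF = safety_factor(tr, lay, nodes_idx = idx))
}

out <- rbind(
  cbind(scenario = "control", sf_fiber("CONTROL")),
  cbind(scenario = "hf", sf_fiber("HF_HOMOG")),
  cbind(scenario = "hf_cluster25", sf_fiber("HF_HOMOG", 25)))
write.csv(out, "results/safety_factor.csv", row.names = FALSE)
for (sc in unique(out$scenario)) {
  d <- out[out$scenario == sc, ]
  cat(sprintf("%-13s SF median %.2f  range [%.2f, %.2f]\n", sc,
              median(d$SF, na.rm = TRUE), min(d$SF, na.rm = TRUE),
              max(d$SF, na.rm = TRUE)))
}
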