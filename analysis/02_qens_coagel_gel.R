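#!/usr/bin/env Rscript
# QENS analysis of the ordered phases.
#
# Coagel (315 K, heating): internal motion only — methyl 3-fold
# reorientation plus uniaxial jump rotation of a 15% mobile chain-hydrogen
# fraction.  Gel (308 K, cooling): the same internal model with a 64%
# mobile fraction, plus slow Fickian lateral diffusion.  Spectra are
# generated at the measured parameter values with Poisson counting noise,
# then pushed through the full inference chain (per-Q decomposition ->
# EISF fit -> HWHM fit -> Fickian fit) to confirm the chain returns the
# generating physics.
#
# Writes: results/qens_ordered_phases.csv

suppressPackageStartupMessages(library(qensbilayer))
dir.create("results", showWarnings = FALSE)

qv <- seq(0.5, 1.8, by = 0.1)
tau_from_Dr <- function(Dr_per_s, N_s = 12) 2 * sin(pi / N_s)^2 / (Dr_per_s * 1e-12)

cases <- list(
  coagel = list(phase = "coagel", T_K = 315,
                params = gel_coagel_params(p_x = 0.15, a = 1.7,
                                           tau = tau_from_Dr(5.3e10),
                                           tau_MG = 6.7),
                lateral = NULL),
  gel = list(phase = "gel", T_K = 308,
             params = gel_coagel_params(p_x = 0.64, a = 1.8,
                                        tau = tau_from_Dr(6.8e10),
                                        tau_MG = 5.2),
             lateral = lateral_model(0.3e-6)))

rows <- lapply(names(cases), function(nm) {
  cs <- cases[[nm]]
  ds <- generate_qens_dataset(cs$phase, cs$params, cs$lateral, q = qv,
                              noise = "poisson", peak_counts = 1e4,
                              seed = 300 + match(nm, names(cases)))
  ch <- qens_inference_chain(ds$spectra, ds$resolution, cs$phase,
                             n_starts = 3, seed = 17)
  cat(sprintf(
    "%s (%d K): p_x = %.3f (true %.2f), a = %.2f A (true %.2f), D_r = %.2g 1/s, tau_MG = %.2f ps\n",
    nm, cs$T_K, ch$eisf$p_x, cs$params$p_x, ch$eisf$a, cs$params$a,
    ch$hwhm$D_r_per_s, ch$hwhm$tau_MG))
  d_lat <- if (is.null(ch$fickian)) NA_real_ else ch$fickian$D_lat_cm2s
  if (!is.na(d_lat))
    cat(sprintf("  lateral D = %.2g cm^2/s (true %.2g)\n", d_lat,
                cs$lateral$D_lat_cm2s))
  data.frame(phase = nm, T_K = cs$T_K,
             p_x = ch$eisf$p_x, a_A = ch$eisf$a,
             D_r_per_s = ch$hwhm$D_r_per_s, tau_MG_ps = ch$hwhm$tau_MG,
             D_lat_cm2s = d_lat,
             p_x_true = cs$params$p_x, a_true = cs$params$a)
})
utils::write.csv(do.call(rbind, rows), "results/qens_ordered_phases.csv",
                 row.names = FALSE)
cat("note: the methyl residence time tau_MG carries ~5% of the quasielastic\n",
    "weight and is weakly identified from a single dataset (see the methods\n",
    "vignette); the chain geometry and rotational rates above are the robust\n",
    "quantities.\n", sep = "")
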