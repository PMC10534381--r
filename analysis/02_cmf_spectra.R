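#!/usr/bin/env Rscript
# Dielectric response of the three species: single-shell Clausius-Mossotti
# spectra over 1 kHz - 100 MHz in the default buffer, the calibrated
# operating point, and the resulting DEP force-scale ordering.

suppressMessages(library(depchip))
dir.create("results", showWarnings = FALSE)

med <- medium_props()
f0 <- default_drive_frequency()
cat(sprintf("buffer: sigma = %g S/m, eps_r = %g; drive frequency %g kHz\n",
            med$conductivity_S_m, med$rel_permittivity, f0 / 1e3))

spectra <- do.call(rbind, lapply(c("CTC", "WBC", "PLT"), function(sp) {
  s <- cmf_spectrum(sp, med, freq_hz = 10^seq(3, 8, length.out = 201))
  s$species <- sp
  s
}))
write.csv(spectra, "results/cmf_spectra.csv", row.names = FALSE)

op <- do.call(rbind, lapply(c("CTC", "WBC", "PLT"), function(sp) {
  cell <- cell_species(sp)
  K <- species_cmf(cell, med, 2 * pi * f0)
  Rp <- cell$diameter_um / 2
  data.frame(species = sp, Rp_um = Rp, re_K = K,
             force_scale_um3 = abs(Rp^3 * K),
             drift_scale_um2 = abs(Rp^2 * K))
}))
print(op, digits = 3)
write.csv(op, "results/operating_point.csv", row.names = FALSE)

stopifnot(check_force_ordering(med, 2 * pi * f0))
cat("force ordering |F_WBC| > |F_CTC| > |F_PLT| holds at the operating point;\n")
cat("all three species are nDEP (pushed away from the electrodes).\n")
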