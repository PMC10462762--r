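#!/usr/bin/env Rscript
# MALDI-TOF readout of coat-protein modification: estimate the mean display
# density of DBCO-functionalized phage across the five target densities,
# demonstrate sialic-acid ghost-peak correction on a disialylated
# conjugate, and track a two-step glycosidase conversion over time.
# Outputs: results/maldi_density.tsv, results/ghost_correction.tsv,
# results/timecourse.tsv.

suppressPackageStartupMessages(library(ligar))
dir.create("results", showWarnings = FALSE)

species <- predict_species_masses()[1:2]  # pviii, dbco_pviii
masses <- setNames(vapply(species, `[[`, numeric(1), "expected_mass"),
                   vapply(species, `[[`, character(1), "name"))

# density series at instrument-typical noise (SNR ~ 100)
dens <- c(50, 150, 500, 750, 1000)
est <- vapply(seq_along(dens), function(i) {
  f <- dens[i] / 2700
  sim <- simulate_spectrum(c(pviii = 1 - f, dbco_pviii = f), masses,
                           sigma = 3, noise_sd = 0.01, baseline = c(0.02, 5e-5),
                           mz_range = c(4900, 5900), seed = 400 + i)
  fit <- fit_peaks(preprocess_spectrum(sim$spectrum), species)
  estimate_density(quantify_species(fit), species)$mean_density
}, numeric(1))
tab <- data.frame(true_density = dens, estimated_density = est,
                  error = est - dens)
write.table(tab, "results/maldi_density.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("density recovery from simulated spectra:")
message(paste(capture.output(print(tab, row.names = FALSE)), collapse = "\n"))
message(paste("note: at 50 glycans/virion the DBCO-pVIII peak is ~2% of the",
              "base peak, at the detection limit for this noise level;",
              "estimates there are dominated by noise in the small peak."))

# ghost correction on a disialylated conjugate (30% in-source loss)
g <- glycan_structure("A2G2S2", composition = c(Hex = 5, HexNAc = 4, Neu5Ac = 2))
spg <- predict_species_masses(glycan = g, include = c("pviii", "conjugate"))
gm <- setNames(vapply(spg, `[[`, numeric(1), "expected_mass"),
               vapply(spg, `[[`, character(1), "name"))
sim <- simulate_spectrum(c(pviii = 0.6, A2G2S2 = 0.4), gm[c("pviii", "A2G2S2")],
                         sialic_counts = c(pviii = 0, A2G2S2 = 2),
                         ghost_fraction = 0.3, noise_sd = 0.005,
                         mz_range = c(4800, 8500), seed = 410)
fits <- fit_peaks(preprocess_spectrum(sim$spectrum), spg)
fr_on <- quantify_species(fits, ghost_correct = TRUE)
fr_off <- quantify_species(fits, ghost_correct = FALSE)
gtab <- data.frame(species = names(fr_on),
                   fraction_corrected = round(unname(fr_on), 4),
                   fraction_uncorrected = round(unname(fr_off[names(fr_on)]), 4))
write.table(gtab, "results/ghost_correction.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("ghost correction (true conjugate fraction 0.40):")
message(paste(capture.output(print(gtab, row.names = FALSE)), collapse = "\n"))

# beta-galactosidase-style sequential conversion S -> I -> P
k1 <- 1.2; k2 <- 0.6
frac_at <- function(t) {
  S <- exp(-k1 * t)
  I <- k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  P <- max(1 - S - I, 0)
  c(S2 = S, I1 = I, P1 = P) / (S + I + P)
}
tmass <- c(S2 = 7000, I1 = 6800, P1 = 6600)
smod <- list(species_model("S2", 7000), species_model("I1", 6800),
             species_model("P1", 6600))
times <- c(0.25, 0.5, 1, 2, 4, 8)
specs <- lapply(times, function(t) {
  s <- simulate_spectrum(frac_at(t), tmass, sigma = 3, noise_sd = 0.005,
                         mz_range = c(6300, 7300), seed = round(420 + 10 * t))$spectrum
  s$time <- t
  s
})
tc <- conversion_timecourse(specs, smod)
write.table(round(tc, 2), "results/timecourse.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("conversion time course (% of each species):")
message(paste(capture.output(print(round(tc, 1), row.names = FALSE)), collapse = "\n"))
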